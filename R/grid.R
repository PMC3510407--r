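#' One-dimensional vertex-centred grid
#'
#' Nodes at `0, dx, ..., L_x` (vessels sit exactly on the end nodes).
#'
#' @param L_x domain length (inter-vessel distance), um.
#' @param dx node spacing, um (default 5).
#' @return An object of class `"grid_1d"` with fields `L_x`, `dx` (um),
#'   `n` (node count) and `x` (node positions, um).
#' @examples
#' grid_1d(300)$n # 61 nodes
#' @export
grid_1d <- function(L_x, dx = 5) {
  if (!(is.numeric(dx) && dx > 0)) stop("dx must be positive")
  n <- round(L_x / dx) + 1L
  if (abs((n - 1L) * dx - L_x) > 1e-9 * L_x)
    stop("L_x must be an integer multiple of dx")
  if (n < 5) stop("grid needs at least 5 nodes (L_x too small for dx)")
  structure(list(L_x = L_x, dx = dx, n = as.integer(n),
                 x = seq(0, L_x, by = dx)),
            class = "grid_1d")
}

#' @export
print.grid_1d <- function(x, ...) {
  cat(sprintf("1-D grid: %g um, dx = %g um, %d nodes\n", x$L_x, x$dx, x$n))
  invisible(x)
}

#' Boundary capillary specification
#'
#' Each end of the domain hosts a capillary that exchanges oxygen with the
#' tissue through a Robin condition (transmural gradient
#' `(O2_v - O2)/J` feeding the tissue).  A vessel thromboses at
#' `occlusion_time`; from then on it either stops exchanging oxygen
#' entirely (`occluded_mode = "sealed"`, the default: a clot blocks
#' exchange) or keeps exchanging against a zero-oxygen lumen
#' (`"sink"`).
#'
#' @param side `"left"` or `"right"`.
#' @param O2_v vessel oxygen, mmHg.
#' @param J oxygen exchange length, cm.
#' @param occlusion_time time of thrombosis, s (`Inf` = never).
#' @param occluded_mode `"sealed"` or `"sink"`.
#' @return An object of class `"vessel_spec"`.
#' @export
vessel_spec <- function(side = c("left", "right"), O2_v = 60, J = 0.1,
                        occlusion_time = Inf,
                        occluded_mode = c("sealed", "sink")) {
  side <- match.arg(side)
  occluded_mode <- match.arg(occluded_mode)
  if (!(is.numeric(O2_v) && O2_v >= 0)) stop("O2_v must be >= 0")
  if (!(is.numeric(J) && J > 0)) stop("exchange length J must be positive")
  if (is.na(occlusion_time)) occlusion_time <- Inf
  structure(list(side = side, O2_v = O2_v, J = J,
                 occlusion_time = occlusion_time,
                 occluded_mode = occluded_mode),
            class = "vessel_spec")
}

#' Construct the pair of boundary vessels with an occlusion schedule
#'
#' Both capillaries carry 60 mmHg with exchange length 0.1 cm; pass an
#' occlusion time (seconds, 0 = thrombosed from the start, `Inf` or `NA` =
#' stays functional) per side.  `vessel_pair(0, Inf)` is the canonical
#' single-occlusion experiment; `vessel_pair(Inf, Inf)` the no-occlusion
#' control.
#'
#' @param occlude_left_at,occlude_right_at occlusion times, s.
#' @param O2_v,J vessel oxygen (mmHg) and exchange length (cm).
#' @return A list with components `left` and `right` ([vessel_spec()]s).
#' @export
vessel_pair <- function(occlude_left_at = 0, occlude_right_at = Inf,
                        O2_v = 60, J = 0.1) {
  list(left = vessel_spec("left", O2_v, J, occlude_left_at),
       right = vessel_spec("right", O2_v, J, occlude_right_at))
}

.pack_vessel <- function(v) {
  c(v$O2_v, v$J, v$occlusion_time,
    if (identical(v$occluded_mode, "sink")) 1 else 0)
}
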