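#' Second-order Laplacian with zero-flux (Neumann) walls
#'
#' Central three-point stencil in the interior; at the walls the ghost node
#' mirrors the first interior node, so the boundary value is
#' `2 (f[2] - f[1]) / dx^2` (second-order zero-flux closure).  Exact for
#' quadratics in the interior.
#'
#' @param field numeric vector (length >= 3).
#' @param dx node spacing, in the length unit of choice.
#' @return Numeric vector of second differences (field units / length^2).
#' @export
laplacian_neumann <- function(field, dx) {
  n <- length(field)
  if (n < 3) stop("need at least 3 nodes")
  out <- numeric(n)
  out[2:(n - 1)] <- (field[1:(n - 2)] - 2 * field[2:(n - 1)] + field[3:n]) / dx^2
  out[1] <- 2 * (field[2] - field[1]) / dx^2
  out[n] <- 2 * (field[n - 1] - field[n]) / dx^2
  out
}

#' Oxygen Laplacian with capillary-exchange (Robin) boundaries
#'
#' Interior stencil as in [laplacian_neumann()].  At a functional vessel the
#' ghost node is set so that the centred gradient at the wall equals the
#' transmural exchange law (oxygen flows into the tissue when the vessel is
#' richer, out when it is poorer), which adds
#' `2 D_O2 / (J dx) * (O2_v - O2_wall)` to the boundary tendency once
#' multiplied by `D_O2`; this function returns the bare Laplacian-plus-
#' exchange term in units of field / length^2, i.e. the exchange
#' contribution here is `2 (O2_v - O2_wall) / (J dx)`.  After a vessel's
#' occlusion time the wall reverts to zero flux (`"sealed"`) or exchanges
#' against a zero-oxygen lumen (`"sink"`).
#'
#' @param O2 oxygen vector, mmHg.
#' @param dx node spacing, cm (the exchange length `J` is in cm).
#' @param left,right [vessel_spec()]s.
#' @param t current time, s (decides occlusion state).
#' @return Numeric vector, mmHg/cm^2.
#' @export
laplacian_robin_oxygen <- function(O2, dx, left, right, t = 0) {
  out <- laplacian_neumann(O2, dx)
  n <- length(O2)
  bc <- function(v, value) {
    if (t < v$occlusion_time) {
      2 * (v$O2_v - value) / (v$J * dx)
    } else if (identical(v$occluded_mode, "sink")) {
      2 * (0 - value) / (v$J * dx)
    } else {
      0
    }
  }
  out[1] <- out[1] + bc(left, O2[1])
  out[n] <- out[n] + bc(right, O2[n])
  out
}

#' Full semi-discrete right-hand side
#'
#' Assembles the method-of-lines tendencies of all four fields: Fickian
#' diffusion with zero-flux walls for the viable cell densities (glioma
#' cells do not intravasate), no transport for necrotic material, oxygen
#' diffusion with capillary exchange, plus the pointwise reaction terms of
#' [cell_reaction_rhs()] and [oxygen_uptake_rhs()].
#'
#' This R-level entry point delegates to the compiled kernel used by the
#' integrators, so what you inspect here is exactly what is integrated.
#'
#' @param state a [tissue_state()].
#' @param params a [model_parameters()].
#' @param vessels a `list(left =, right =)` of [vessel_spec()]s
#'   (see [vessel_pair()]).
#' @return A list of tendency vectors `du_n`, `du_h`, `du_d`, `dO2` (1/s and
#'   mmHg/s).
#' @export
semidiscrete_rhs <- function(state, params, vessels) {
  grid <- state$grid
  dy <- .rhs_kernel(.state_to_vec(state), state$t, grid$n, grid$dx * 1e-4,
                    .pack_params(params),
                    .pack_vessel(vessels$left), .pack_vessel(vessels$right))
  n <- grid$n
  list(du_n = dy[seq_len(n)], du_h = dy[n + seq_len(n)],
       du_d = dy[2 * n + seq_len(n)], dO2 = dy[3 * n + seq_len(n)])
}
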