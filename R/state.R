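#' Tissue state on a grid
#'
#' Snapshot of the four fields at one time: normoxic, hypoxic and necrotic
#' densities (fractions of capacity) and oxygen (mmHg).
#'
#' @param grid a [grid_1d()].
#' @param u_n,u_h,u_d,O2 numeric vectors of length `grid$n`; scalars are
#'   recycled.
#' @param t time, s.
#' @return An object of class `"tissue_state"`.
#' @export
tissue_state <- function(grid, u_n = 0, u_h = 0, u_d = 0, O2 = 24, t = 0) {
  n <- grid$n
  fields <- list(u_n = u_n, u_h = u_h, u_d = u_d, O2 = O2)
  fields <- lapply(fields, function(f) {
    if (length(f) == 1) f <- rep(f, n)
    if (length(f) != n) stop("field length must match grid node count")
    f
  })
  st <- c(list(t = t, grid = grid), fields)
  class(st) <- "tissue_state"
  validate_state(st)
}

validate_state <- function(st, tol = 0) {
  for (nm in c("u_n", "u_h", "u_d", "O2")) {
    f <- st[[nm]]
    if (any(!is.finite(f))) stop("non-finite values in ", nm)
    if (min(f) < -tol)
      stop(sprintf("negative values in %s (min %.3e)", nm, min(f)))
  }
  st
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf(
    "tissue_state at t = %.3g h on %d nodes (%g um)\n",
    x$t / 3600, x$grid$n, x$grid$L_x))
  cat(sprintf("  totals: u_n %.3f  u_h %.3f  u_d %.3f;  O2 %.1f-%.1f mmHg\n",
              mean(x$u_n), mean(x$u_h), mean(x$u_d), min(x$O2), max(x$O2)))
  invisible(x)
}

.state_to_vec <- function(st) c(st$u_n, st$u_h, st$u_d, st$O2)

.vec_to_state <- function(y, grid, t) {
  n <- grid$n
  structure(list(t = t, grid = grid,
                 u_n = y[seq_len(n)], u_h = y[n + seq_len(n)],
                 u_d = y[2 * n + seq_len(n)], O2 = y[3 * n + seq_len(n)]),
            class = "tissue_state")
}

#' Extract one snapshot of a trajectory as a tissue state
#'
#' @param traj a trajectory from [run_simulation()].
#' @param i snapshot index (1-based).
#' @return A `"tissue_state"`.
#' @export
snapshot <- function(traj, i) {
  stopifnot(inherits(traj, "tissue_trajectory"),
            i >= 1, i <= length(traj$times))
  structure(list(t = traj$times[i], grid = traj$grid,
                 u_n = traj$u_n[, i], u_h = traj$u_h[, i],
                 u_d = traj$u_d[, i], O2 = traj$O2[, i]),
            class = "tissue_state")
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  cat(sprintf("tissue_trajectory '%s': %d snapshots, t = 0 .. %.3g d, %s\n",
              x$scenario, length(x$times), max(x$times) / 86400,
              sprintf("%d nodes (%g um)", x$grid$n, x$grid$L_x)))
  cat(sprintf("  integrator: %s; seed %s; fingerprint %s\n",
              x$method, format(x$seed), x$fingerprint))
  invisible(x)
}

#' Long-format data frame of a trajectory
#'
#' One row per (snapshot, node) with columns
#' `time_s, x_um, u_n, u_h, u_d, O2_mmHg`.
#'
#' @param x a trajectory from [run_simulation()].
#' @param ... unused.
#' @return A `data.frame`.
#' @export
as.data.frame.tissue_trajectory <- function(x, ...) {
  ns <- length(x$times)
  n <- x$grid$n
  data.frame(time_s = rep(x$times, each = n),
             x_um = rep(x$grid$x, ns),
             u_n = as.vector(x$u_n), u_h = as.vector(x$u_h),
             u_d = as.vector(x$u_d), O2_mmHg = as.vector(x$O2))
}

# short stable fingerprint of an arbitrary configuration list
.fingerprint <- function(obj) {
  txt <- paste(deparse(obj, control = "all"), collapse = "")
  # 32-bit polynomial rolling hash of the deparsed text (doubles stay exact
  # below 2^53, so the modular arithmetic is lossless)
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
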