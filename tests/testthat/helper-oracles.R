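# Independent brute-force oracles used across the suite.  These are written
# as plain index-by-index loops so they share no code path with the package
# implementation they check.

# term-by-term loop implementation of the full semi-discrete RHS
oracle_rhs <- function(state, params, vessels) {
  g <- state$grid
  n <- g$n
  dx <- g$dx * 1e-4 # cm
  un <- state$u_n; uh <- state$u_h; ud <- state$u_d; o2 <- state$O2
  t <- state$t
  lap <- function(f, i) {
    if (i == 1) 2 * (f[2] - f[1]) / dx^2
    else if (i == n) 2 * (f[n - 1] - f[n]) / dx^2
    else (f[i - 1] - 2 * f[i] + f[i + 1]) / dx^2
  }
  sdown <- function(v, c0) {
    if (identical(params$switch_form, "step")) {
      if (v < c0) 1 else if (v > c0) 0 else 0.5
    } else 0.5 * (1 - tanh((v - c0) / params$delta_O2))
  }
  du_n <- du_h <- du_d <- dO2 <- numeric(n)
  for (i in seq_len(n)) {
    Snh <- sdown(o2[i], params$O2_S)
    Shn <- 1 - Snh
    Shd <- sdown(o2[i], params$O2_D)
    room <- 1 - (un[i] + uh[i] + ud[i])
    du_n[i] <- params$D_n * lap(un, i) + un[i] * room / params$tau_n -
      Snh * un[i] / params$tau_nh + Shn * uh[i] / params$tau_hn
    du_h[i] <- params$D_h * lap(uh, i) + uh[i] * room / params$tau_h +
      Snh * un[i] / params$tau_nh - Shn * uh[i] / params$tau_hn -
      Shd * uh[i] / params$tau_hd
    du_d[i] <- Shd * uh[i] / params$tau_hd
    dO2[i] <- params$D_O2 * lap(o2, i) -
      params$A_n * (un[i] + params$uptake_ratio * uh[i]) * o2[i] /
        (params$O2_T + o2[i])
  }
  for (side in c("left", "right")) {
    v <- vessels[[side]]
    i <- if (side == "left") 1 else n
    if (t < v$occlusion_time)
      dO2[i] <- dO2[i] + params$D_O2 * 2 * (v$O2_v - o2[i]) / (v$J * dx)
    else if (identical(v$occluded_mode, "sink"))
      dO2[i] <- dO2[i] + params$D_O2 * 2 * (0 - o2[i]) / (v$J * dx)
  }
  list(du_n = du_n, du_h = du_h, du_d = du_d, dO2 = dO2)
}

# brute-force relaxation to the steady oxygen profile of a full-density
# normoxic slab with a Dirichlet vessel wall; returns the distance (um) at
# which the profile crosses the hypoxia threshold
oracle_crossing_distance <- function(A, params, vessel_O2 = 60,
                                     L_um = 600, dx_um = 2.5) {
  dx <- dx_um * 1e-4
  n <- round(L_um / dx_um) + 1
  D <- params$D_O2
  O2 <- rep(vessel_O2, n)
  dt <- 0.2 * dx^2 / D
  for (it in 1:400000) {
    lap <- c(0, (O2[1:(n - 2)] - 2 * O2[2:(n - 1)] + O2[3:n]) / dx^2,
             2 * (O2[n - 1] - O2[n]) / dx^2)
    new <- O2 + dt * (D * lap - A * O2 / (params$O2_T + O2))
    new[1] <- vessel_O2
    new[new < 0] <- 0
    if (max(abs(new - O2)) < 1e-12) {
      O2 <- new
      break
    }
    O2 <- new
  }
  k <- which(O2 < params$O2_S)[1]
  if (is.na(k)) return(Inf)
  x <- (seq_len(n) - 1) * dx_um
  x[k - 1] + (O2[k - 1] - params$O2_S) * dx_um / (O2[k - 1] - O2[k])
}

# assemble a synthetic trajectory object from a list of per-snapshot
# viable-density vectors (for metric unit tests)
synthetic_trajectory <- function(grid, times, u_n_list,
                                 u_h_list = NULL, u_d_list = NULL) {
  ns <- length(times)
  zeros <- matrix(0, grid$n, ns)
  mk <- function(lst) if (is.null(lst)) zeros else do.call(cbind, lst)
  structure(list(times = times, u_n = mk(u_n_list), u_h = mk(u_h_list),
                 u_d = mk(u_d_list), O2 = matrix(24, grid$n, ns),
                 grid = grid, method = "synthetic", seed = NA,
                 scenario = "synthetic", fingerprint = "0",
                 clip = list(min_value = 0, n_clipped = 0L)),
            class = "tissue_trajectory")
}

default_scenario_trajectory <- local({
  cache <- new.env()
  function(days = 7, seed = 1) {
    key <- paste0("d", days, "s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- run_scenario(
        scenario_config("single_occlusion", rng_seed = seed),
        model_parameters(), days = days)
    cache[[key]]
  }
})
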