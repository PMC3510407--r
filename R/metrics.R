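#' Thresholds for the morphometric analyses
#'
#' The invasion threshold of 45% of capacity is the density at which a
#' vessel counts as invaded by the tumour; the same level defines
#' hypercellularity for the palisade width by default.  A hypercellular
#' band shorter than `min_width` does not count as a palisade.
#'
#' @param theta_palisade hypercellularity threshold on `u_n + u_h`
#'   (fraction of capacity).
#' @param theta_necrotic threshold on `u_d` for the necrotic core.
#' @param theta_invasion threshold on `u_n + u_h` at the vessel node.
#' @param min_width minimum band width to count as a palisade, um.
#' @param switch_epsilon normoxic share below which the phenotype switch
#'   counts as complete.
#' @return An object of class `"metric_thresholds"`.
#' @export
metric_thresholds <- function(theta_palisade = 0.45, theta_necrotic = 0.10,
                              theta_invasion = 0.45, min_width = 20,
                              switch_epsilon = 0.05) {
  vals <- c(theta_palisade, theta_necrotic, theta_invasion, switch_epsilon)
  if (any(vals <= 0 | vals >= 1))
    stop("thresholds must lie in (0, 1)")
  if (min_width <= 0) stop("min_width must be positive")
  structure(list(theta_palisade = theta_palisade,
                 theta_necrotic = theta_necrotic,
                 theta_invasion = theta_invasion,
                 min_width = min_width,
                 switch_epsilon = switch_epsilon),
            class = "metric_thresholds")
}

# maximal runs of TRUE in a logical vector: matrix with columns from, to
.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(from = starts[r$values], to = ends[r$values])
}

#' Width of the hypercellular (pseudopalisade) band
#'
#' Length of the largest connected run of nodes with viable density
#' `u_n + u_h` above the hypercellularity threshold.  Runs that contain the
#' functional-vessel boundary node are excluded: once the vessel region is
#' recolonised, that perivascular colony is by definition hypercellular but
#' is not the migrating palisade band.
#'
#' @param state a [tissue_state()].
#' @param thresholds a [metric_thresholds()].
#' @param functional_side `"right"` (default), `"left"`, `"both"` or
#'   `"none"`: which boundary nodes host a functional vessel whose colony
#'   must be excluded.
#' @return Width in um (number of nodes times `dx`); 0 if no band.
#' @export
hypercellular_width <- function(state, thresholds = metric_thresholds(),
                                functional_side = "right") {
  mask <- (state$u_n + state$u_h) > thresholds$theta_palisade
  runs <- .runs(mask)
  if (!nrow(runs)) return(0)
  n <- state$grid$n
  excl_left <- functional_side %in% c("left", "both")
  excl_right <- functional_side %in% c("right", "both")
  keep <- rep(TRUE, nrow(runs))
  if (excl_left) keep <- keep & runs[, "from"] > 1L
  if (excl_right) keep <- keep & runs[, "to"] < n
  if (!any(keep)) return(0)
  max(runs[keep, "to"] - runs[keep, "from"] + 1L) * state$grid$dx
}

#' Width of the necrotic core
#'
#' Length of the connected run of nodes with `u_d` above the necrotic
#' threshold that is adjacent to the occluded vessel (contains its boundary
#' node); 0 if that node is below threshold.
#'
#' @param state a [tissue_state()].
#' @param thresholds a [metric_thresholds()].
#' @param occluded_side `"left"` (default) or `"right"`.
#' @return Width in um.
#' @export
necrotic_core_width <- function(state, thresholds = metric_thresholds(),
                                occluded_side = "left") {
  mask <- state$u_d > thresholds$theta_necrotic
  runs <- .runs(mask)
  if (!nrow(runs)) return(0)
  node <- if (identical(occluded_side, "left")) 1L else state$grid$n
  hit <- which(runs[, "from"] <= node & runs[, "to"] >= node)
  if (!length(hit)) return(0)
  unname(runs[hit[1], "to"] - runs[hit[1], "from"] + 1L) * state$grid$dx
}

#' Palisade width across a trajectory
#'
#' @param traj a `"tissue_trajectory"`.
#' @inheritParams hypercellular_width
#' @return Numeric vector of widths (um), one per snapshot.
#' @export
palisade_widths <- function(traj, thresholds = metric_thresholds(),
                            functional_side = "right") {
  vapply(seq_along(traj$times), function(i)
    hypercellular_width(snapshot(traj, i), thresholds, functional_side),
    numeric(1))
}

#' Palisade formation time and lifetime
#'
#' Formation is the first snapshot at which the hypercellular band reaches
#' `min_width`; disappearance the first later snapshot at which it falls
#' back below (including merging into the domain-wide saturated state,
#' which the colony-exclusion rule of [hypercellular_width()] detects as a
#' collapse of the band width).  The lifetime is the difference.
#'
#' @param traj a `"tissue_trajectory"` (at least 2 snapshots).
#' @inheritParams hypercellular_width
#' @return A list: `formation_time` (h, `NA` if the band never forms),
#'   `lifetime` (h; 0 if never formed, `Inf` if it never disappears within
#'   the horizon), and `censored` (`TRUE` if the band outlived the run).
#' @export
palisade_lifetime <- function(traj, thresholds = metric_thresholds(),
                              functional_side = "right") {
  if (length(traj$times) < 2) stop("need at least 2 snapshots")
  w <- palisade_widths(traj, thresholds, functional_side)
  formed <- which(w >= thresholds$min_width)
  if (!length(formed))
    return(list(formation_time = NA_real_, lifetime = 0, censored = FALSE))
  f <- formed[1]
  gone <- which(w < thresholds$min_width & seq_along(w) > f)
  if (!length(gone))
    return(list(formation_time = traj$times[f] / 3600,
                lifetime = Inf, censored = TRUE))
  list(formation_time = traj$times[f] / 3600,
       lifetime = (traj$times[gone[1]] - traj$times[f]) / 3600,
       censored = FALSE)
}

#' Time for a vessel to be invaded by the tumour
#'
#' First time the viable density `u_n + u_h` at the vessel's boundary node
#' exceeds the invasion threshold, linearly interpolated between snapshots
#' to remove cadence bias.
#'
#' @param traj a `"tissue_trajectory"`.
#' @param vessel_side `"right"` (default) or `"left"`.
#' @param thresholds a [metric_thresholds()].
#' @return Time in days; `NA` with attribute `censored_at` (days) if the
#'   threshold is never crossed within the horizon.
#' @export
invasion_time <- function(traj, vessel_side = "right",
                          thresholds = metric_thresholds()) {
  node <- if (identical(vessel_side, "left")) 1L else traj$grid$n
  dens <- traj$u_n[node, ] + traj$u_h[node, ]
  above <- which(dens > thresholds$theta_invasion)
  if (!length(above)) {
    out <- NA_real_
    attr(out, "censored_at") <- max(traj$times) / 86400
    return(out)
  }
  k <- above[1]
  if (k == 1) return(0)
  t1 <- traj$times[k - 1]; t2 <- traj$times[k]
  v1 <- dens[k - 1]; v2 <- dens[k]
  (t1 + (thresholds$theta_invasion - v1) * (t2 - t1) / (v2 - v1)) / 86400
}

#' Completion time of the normoxic-to-hypoxic switch
#'
#' Tracks the normoxic share of the viable population,
#' `sum(u_n) / sum(u_n + u_h)`, over the half of the domain adjacent to the
#' occluded vessel, and reports the first time it falls below
#' `switch_epsilon` (linearly interpolated between snapshots).
#'
#' @param traj a `"tissue_trajectory"`.
#' @param occluded_side `"left"` (default) or `"right"`.
#' @param thresholds a [metric_thresholds()].
#' @return Time in hours; `NA` with attribute `censored_at` (h) if the
#'   switch never completes within the horizon.
#' @export
switch_completion_time <- function(traj, occluded_side = "left",
                                   thresholds = metric_thresholds()) {
  n <- traj$grid$n
  idx <- if (identical(occluded_side, "left")) seq_len(ceiling(n / 2))
         else (n + 1 - seq_len(ceiling(n / 2)))
  num <- colSums(traj$u_n[idx, , drop = FALSE])
  den <- num + colSums(traj$u_h[idx, , drop = FALSE])
  share <- ifelse(den > 0, num / den, 1)
  below <- which(share < thresholds$switch_epsilon)
  if (!length(below)) {
    out <- NA_real_
    attr(out, "censored_at") <- max(traj$times) / 3600
    return(out)
  }
  k <- below[1]
  if (k == 1) return(0)
  t1 <- traj$times[k - 1]; t2 <- traj$times[k]
  v1 <- share[k - 1]; v2 <- share[k]
  (t1 + (thresholds$switch_epsilon - v1) * (t2 - t1) / (v2 - v1)) / 3600
}

#' Absolute cell counts per compartment
#'
#' Trapezoidal integral of each density times the carrying capacity over
#' the domain, for a tissue cross-section of `section` cm (the model is a
#' 1-D transect; counts scale linearly with the assumed section).
#'
#' @param state a [tissue_state()].
#' @param C_M carrying capacity, cell/cm2.
#' @param section cross-section width, cm (default 1).
#' @return Named vector `N_n`, `N_h`, `N_d`, `N_total` (cells).
#' @export
population_totals <- function(state, C_M = 1e6, section = 1) {
  dx_cm <- state$grid$dx * 1e-4
  trap <- function(f) (sum(f) - (f[1] + f[length(f)]) / 2) * dx_cm
  n <- trap(state$u_n) * C_M * section
  h <- trap(state$u_h) * C_M * section
  d <- trap(state$u_d) * C_M * section
  c(N_n = n, N_h = h, N_d = d, N_total = n + h + d)
}

#' Inter-vessel distance sweep
#'
#' Runs the sweep-member scenario (two-colony layout with initial data
#' proportional to the tissue size) for each requested inter-vessel
#' distance and extracts the palisade morphometry: maximal band width,
#' formation time and lifetime, and the final necrotic core width.
#'
#' @param distances inter-vessel distances, um (each in \[50, 700\]).
#' @param params a [model_parameters()].
#' @param thresholds a [metric_thresholds()].
#' @param days horizon per member, days.
#' @param rng_seed seed for the initial oxygen noise (one stream per
#'   member, offset by the member distance so that resumed and fresh
#'   sweeps agree member by member).
#' @param base_cfg optional [scenario_config()] whose seeding/noise settings
#'   the members inherit.
#' @return A `data.frame` with one row per distance: `distance_um`,
#'   `palisade_width_um`, `formation_time_h`, `lifetime_h`, `censored`,
#'   `necrotic_width_um`, `error` (`NA` unless that member failed).
#' @export
distance_sweep <- function(distances, params = model_parameters(),
                           thresholds = metric_thresholds(), days = 16,
                           rng_seed = 1L, base_cfg = NULL) {
  if (any(distances < 50 | distances > 700))
    stop("distances must lie in [50, 700] um")
  rows <- lapply(seq_along(distances), function(i) {
    d <- distances[i]
    out <- data.frame(distance_um = d, palisade_width_um = NA_real_,
                      formation_time_h = NA_real_, lifetime_h = NA_real_,
                      censored = NA, necrotic_width_um = NA_real_,
                      error = NA_character_)
    tryCatch({
      cfg <- sweep_member_config(d, rng_seed = rng_seed + as.integer(d),
                                 base_cfg = base_cfg)
      traj <- run_scenario(cfg, params, days = days)
      w <- palisade_widths(traj, thresholds, functional_side = "right")
      life <- palisade_lifetime(traj, thresholds, functional_side = "right")
      out$palisade_width_um <- max(w)
      out$formation_time_h <- life$formation_time
      out$lifetime_h <- life$lifetime
      out$censored <- life$censored
      out$necrotic_width_um <-
        necrotic_core_width(snapshot(traj, length(traj$times)), thresholds)
    }, error = function(e) out$error <<- conditionMessage(e))
    out
  })
  res <- do.call(rbind, rows)
  res[order(res$distance_um), , drop = FALSE]
}

#' Sweep-member scenario at one inter-vessel distance
#'
#' Two-colony layout scaled proportionally to the tissue size: the seed
#' covers the occluded half and the far-vessel colony and edge smoothing
#' scale with `L_x` relative to the canonical 400 um two-colony scenario.
#'
#' @param distance inter-vessel distance, um.
#' @param rng_seed seed for the oxygen noise.
#' @param base_cfg optional template [scenario_config()].
#' @return A [scenario_config()].
#' @export
sweep_member_config <- function(distance, rng_seed = 1L, base_cfg = NULL) {
  if (is.null(base_cfg))
    base_cfg <- scenario_config("two_colony", rng_seed = rng_seed)
  scale <- distance / 400
  scenario_config("sweep_member", L_x = distance,
                  seed_fraction = base_cfg$seed_fraction,
                  colony_fraction = base_cfg$colony_fraction,
                  edge_width = max(10, base_cfg$edge_width * scale),
                  O2_mean = base_cfg$O2_mean,
                  O2_amplitude = base_cfg$O2_amplitude,
                  rng_seed = rng_seed)
}
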