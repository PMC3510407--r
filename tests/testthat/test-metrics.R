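p <- model_parameters()
th <- metric_thresholds()

test_that("hypercellular width measures constructed box profiles", {
  g <- grid_1d(300)
  empty <- tissue_state(g)
  expect_equal(hypercellular_width(empty, th), 0)
  # 26 nodes at 0.6 -> 130 um
  u <- rep(0, g$n); u[10:35] <- 0.6
  st <- tissue_state(g, u_n = u)
  expect_equal(hypercellular_width(st, th), 130)
  # widths are grid-quantised multiples of dx
  expect_equal(hypercellular_width(st, th) %% g$dx, 0)
  # rescaling that preserves threshold crossings preserves the width
  st2 <- tissue_state(g, u_n = u * 1.3)
  expect_equal(hypercellular_width(st2, th), 130)
})

test_that("bands touching the functional vessel are excluded as colony", {
  g <- grid_1d(300)
  u <- rep(0, g$n)
  u[50:61] <- 0.8 # recolonised right-vessel region
  u[10:20] <- 0.6 # the migrating band
  st <- tissue_state(g, u_n = u)
  expect_equal(hypercellular_width(st, th), 55) # 11 nodes, not 12
  # with no functional vessel both runs compete
  expect_equal(hypercellular_width(st, th, functional_side = "none"), 60)
  # a domain-wide saturated state has no band at all
  sat <- tissue_state(g, u_n = rep(0.9, g$n))
  expect_equal(hypercellular_width(sat, th), 0)
})

test_that("necrotic core width requires adjacency to the occluded vessel", {
  g <- grid_1d(300)
  expect_equal(necrotic_core_width(tissue_state(g), th), 0)
  ud <- rep(0, g$n); ud[1:6] <- 0.2
  expect_equal(necrotic_core_width(tissue_state(g, u_d = ud), th), 30)
  # detached necrosis does not count as the perivascular core
  ud2 <- rep(0, g$n); ud2[10:15] <- 0.2
  expect_equal(necrotic_core_width(tissue_state(g, u_d = ud2), th), 0)
  # and the core can sit at the right vessel when that side is occluded
  ud3 <- rep(0, g$n); ud3[56:61] <- 0.2
  expect_equal(necrotic_core_width(tissue_state(g, u_d = ud3), th,
                                   occluded_side = "right"), 30)
})

test_that("palisade lifetime brackets the band between formation and
           disappearance", {
  g <- grid_1d(300)
  times <- seq(0, 70) * 3600
  mk <- function(width_nodes) {
    u <- rep(0, g$n)
    if (width_nodes > 0) u[10 + seq_len(width_nodes)] <- 0.6
    u
  }
  # band >= 20 um (4+ nodes) exactly from the 10 h to the 57 h snapshot
  widths <- ifelse(times / 3600 >= 10 & times / 3600 < 58, 10, 2)
  traj <- synthetic_trajectory(g, times, lapply(widths, mk))
  life <- palisade_lifetime(traj, th)
  expect_equal(life$formation_time, 10)
  expect_equal(life$lifetime, 48)
  expect_false(life$censored)
  # never forming
  none <- synthetic_trajectory(g, times, lapply(rep(2, 71), mk))
  expect_equal(palisade_lifetime(none, th)$lifetime, 0)
  expect_true(is.na(palisade_lifetime(none, th)$formation_time))
  # never disappearing: censored at the horizon
  always <- synthetic_trajectory(g, times, lapply(rep(10, 71), mk))
  expect_true(is.infinite(palisade_lifetime(always, th)$lifetime))
  expect_true(palisade_lifetime(always, th)$censored)
})

test_that("invasion time interpolates the first threshold crossing", {
  g <- grid_1d(300)
  times <- c(0, 86400, 2 * 86400)
  mk <- function(v) { u <- rep(0, g$n); u[g$n] <- v; u }
  traj <- synthetic_trajectory(g, times, lapply(c(0.1, 0.3, 0.7), mk))
  # crossing of 0.45 between day 1 (0.3) and day 2 (0.7): 1 + 0.15/0.4
  expect_equal(invasion_time(traj, "right", th), 1.375)
  # already above at t = 0
  high <- synthetic_trajectory(g, times, lapply(c(0.5, 0.6, 0.7), mk))
  expect_equal(invasion_time(high, "right", th), 0)
  # never crossing: censored at the horizon
  low <- synthetic_trajectory(g, times, lapply(c(0.1, 0.2, 0.3), mk))
  out <- invasion_time(low, "right", th)
  expect_true(is.na(out))
  expect_equal(attr(out, "censored_at"), 2)
})

test_that("switch completion tracks the occluded-half normoxic share", {
  g <- grid_1d(300)
  times <- seq(0, 6) * 3600
  share <- exp(-seq(0, 6)) # e-folding once per hour
  mkn <- function(s) rep(0.7 * s, g$n)
  mkh <- function(s) rep(0.7 * (1 - s), g$n)
  traj <- synthetic_trajectory(g, times, lapply(share, mkn), lapply(share, mkh))
  # share crosses 0.05 between 2 h (0.135) and 3 h (0.0498)
  got <- switch_completion_time(traj, "left", th)
  expect_gt(got, 2); expect_lt(got, 3)
  # pinned high oxygen: no switch, censored
  ctrl <- synthetic_trajectory(g, times, lapply(rep(1, 7), mkn))
  expect_true(is.na(switch_completion_time(ctrl, "left", th)))
})

test_that("population totals integrate densities against the capacity", {
  g <- grid_1d(300)
  expect_equal(unname(population_totals(tissue_state(g))["N_total"]), 0)
  full <- tissue_state(g, u_n = 1)
  tot <- population_totals(full, C_M = 1e6, section = 1)
  expect_equal(unname(tot["N_n"]), 1e6 * 0.03) # 300 um = 0.03 cm
  expect_equal(unname(tot["N_total"]), unname(tot["N_n"]))
})

test_that("switching-only dynamics conserve the total cell number", {
  pf <- model_parameters(tau_n = Inf, tau_h = Inf)
  tr <- run_simulation(
    make_initial_state(scenario_config("single_occlusion", rng_seed = 1)),
    pf, vessel_pair(0, Inf),
    integrator_config("stiff", t_end = 86400, abs_tol = 1e-12,
                      rel_tol = 1e-10))
  totals <- sapply(seq_along(tr$times), function(i)
    population_totals(snapshot(tr, i))[["N_total"]])
  expect_lt(max(abs(totals / totals[1] - 1)), 1e-8)
})

test_that("more seeded cells never slow the invasion", {
  inv <- sapply(c(0.4, 0.6, 0.8), function(f) {
    cfg <- scenario_config("single_occlusion", seed_fraction = f,
                           rng_seed = 1)
    invasion_time(run_scenario(cfg, p, days = 9))
  })
  expect_true(all(diff(inv) <= 0))
})

test_that("occlusion accelerates invasion of the functional vessel", {
  for (s in 1:3) {
    occl <- invasion_time(run_scenario(
      scenario_config("single_occlusion", rng_seed = s), p, days = 16))
    ctrl <- invasion_time(run_scenario(
      scenario_config("control", rng_seed = s), p, days = 20))
    expect_lt(occl, ctrl)
  }
})

test_that("distance sweep composes per-member scenarios and stays ordered", {
  res <- distance_sweep(c(300, 150), days = 10, rng_seed = 1)
  expect_equal(res$distance_um, c(150, 300))
  expect_true(all(is.na(res$error)))
  expect_true(all(res$palisade_width_um %% 5 == 0))
  # a single-member sweep equals running the member manually
  one <- distance_sweep(300, days = 10, rng_seed = 1)
  cfg <- sweep_member_config(300, rng_seed = 1 + 300)
  traj <- run_scenario(cfg, p, days = 10)
  expect_equal(one$palisade_width_um, max(palisade_widths(traj, th)))
  expect_equal(one$necrotic_width_um,
               necrotic_core_width(snapshot(traj, length(traj$times)), th))
  expect_error(distance_sweep(c(30, 300)), "50, 700")
})

test_that("threshold constructor rejects out-of-range values", {
  expect_error(metric_thresholds(theta_palisade = 0), "0, 1")
  expect_error(metric_thresholds(min_width = -5), "positive")
})
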