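p <- model_parameters()

test_that("stability check reproduces the diffusive step bound", {
  g <- grid_1d(300)
  s <- check_stability(0.01, g, p)
  expect_true(s$ok)
  expect_equal(s$dt_max, (5e-4)^2 / (2 * 1e-5)) # 0.0125 s
  expect_equal(s$limiting, "D_O2")
  expect_false(check_stability(0.02, g, p)$ok)
  # with negligible diffusivities any step is admissible
  tiny <- model_parameters(D_n = 1e-300, D_h = 1e-299, D_O2 = 1e-298)
  expect_true(check_stability(1e6, g, tiny)$ok)
  expect_error(run_simulation(
    make_initial_state(scenario_config("single_occlusion")), p,
    vessel_pair(0, Inf),
    integrator_config("rk4", t_end = 10, dt = 0.02)), "stability")
})

test_that("a zero-length run returns the initial state unchanged", {
  st <- make_initial_state(scenario_config("single_occlusion", rng_seed = 4))
  tr <- run_simulation(st, p, vessel_pair(0, Inf),
                       integrator_config("stiff", t_end = 0))
  expect_length(tr$times, 1)
  expect_equal(tr$u_n[, 1], st$u_n)
  expect_equal(tr$O2[, 1], st$O2)
})

test_that("pure anoxic decay follows the closed-form exponential", {
  g <- grid_1d(20, dx = 5) # 5 nodes
  pf <- model_parameters(D_n = 1e-300, D_h = 1e-299, D_O2 = 1e-298,
                         tau_n = Inf, tau_h = Inf, A_n = 1e-300)
  st <- tissue_state(g, u_h = 0.8, O2 = 0)
  tr <- run_simulation(st, pf, vessel_pair(0, 0),
                       integrator_config("stiff", t_end = pf$tau_hd,
                                         snapshot_interval = pf$tau_hd / 8,
                                         abs_tol = 1e-13, rel_tol = 1e-11))
  # S_hd(0) is within 1e-6 of 1 for the tanh switch; compare against the
  # exact rate of the integrated ODE
  rate <- switching_functions(0, pf)$S_hd / pf$tau_hd
  expect_equal(tr$u_h[3, ], 0.8 * exp(-rate * tr$times), tolerance = 1e-6)
  expect_equal(tr$u_h[3, length(tr$times)], 0.8 * exp(-1), tolerance = 1e-5)
  # dead mass appears where the living mass went
  expect_equal(tr$u_h[3, ] + tr$u_d[3, ], rep(0.8, length(tr$times)),
               tolerance = 1e-9)
})

test_that("snapshots cover t = 0 and t_end at the requested cadence", {
  st <- make_initial_state(scenario_config("single_occlusion"))
  tr <- run_simulation(st, p, vessel_pair(0, Inf),
                       integrator_config("stiff", t_end = 5000,
                                         snapshot_interval = 1800))
  expect_equal(tr$times, c(0, 1800, 3600, 5000))
})

test_that("fields stay non-negative through the occlusion scenario", {
  tr <- default_scenario_trajectory(days = 7, seed = 1)
  expect_gte(tr$clip$min_value, -1e-9)
  expect_equal(tr$clip$n_clipped, 0L)
})

test_that("positivity clipping zeroes only sub-tolerance negatives", {
  st <- make_initial_state(scenario_config("single_occlusion", rng_seed = 2))
  tr <- run_simulation(st, p, vessel_pair(0, Inf),
                       integrator_config("stiff", t_end = 3600,
                                         positivity_clip = TRUE))
  expect_true(all(tr$u_n >= 0 & tr$u_h >= 0 & tr$u_d >= 0 & tr$O2 >= 0))
})

test_that("an occlusion inside the horizon is handled as a restart", {
  late <- run_scenario(scenario_config("single_occlusion", rng_seed = 1,
                                       occlude_left_at = 6 * 3600), p,
                       days = 1)
  immediate <- run_scenario(scenario_config("single_occlusion", rng_seed = 1),
                            p, days = 1)
  expect_length(late$times, 25)
  # while the left vessel still feeds, its wall carries more oxygen than
  # under immediate thrombosis; after its occlusion both collapse alike
  expect_gt(late$O2[1, 7], immediate$O2[1, 7] + 1)
  expect_lt(late$O2[1, 25], 7)
})

test_that("trajectory metadata identify the run", {
  tr <- default_scenario_trajectory(days = 7, seed = 1)
  expect_equal(tr$scenario, "single_occlusion")
  expect_equal(tr$seed, 1L)
  expect_match(tr$fingerprint, "^[0-9a-f]{8}$")
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 61 * length(tr$times))
  expect_named(df, c("time_s", "x_um", "u_n", "u_h", "u_d", "O2_mmHg"))
})
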