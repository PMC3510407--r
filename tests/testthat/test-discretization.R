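p <- model_parameters()

test_that("Neumann Laplacian: constants, quadratics, brute-force stencil", {
  expect_equal(laplacian_neumann(rep(3.2, 9), 0.5), rep(0, 9))
  x <- seq(0, 3, by = 0.5)
  expect_equal(laplacian_neumann(x^2, 0.5)[2:6], rep(2, 5))
  set.seed(11)
  f <- runif(7)
  dx <- 0.3
  lap <- laplacian_neumann(f, dx)
  for (i in 1:7) {
    fm <- if (i == 1) f[2] else f[i - 1] # reflecting ghost nodes
    fp <- if (i == 7) f[6] else f[i + 1]
    expect_equal(lap[i], (fm - 2 * f[i] + fp) / dx^2)
  }
  expect_error(laplacian_neumann(c(1, 2), 1), "3 nodes")
})

test_that("Robin oxygen boundary: equilibrium, sign, occlusion", {
  v <- vessel_pair(Inf, Inf)
  dx <- 5e-4
  # uniform field at vessel oxygen: no exchange, zero Laplacian
  expect_equal(laplacian_robin_oxygen(rep(60, 11), dx, v$left, v$right),
               rep(0, 11))
  # tissue below vessel oxygen: boundary term positive (oxygen flows in)
  low <- rep(30, 11)
  lap <- laplacian_robin_oxygen(low, dx, v$left, v$right)
  expect_gt(lap[1], 0)
  expect_gt(lap[11], 0)
  # tissue above vessel oxygen: oxygen flows back into the vessel
  high <- rep(80, 11)
  lap <- laplacian_robin_oxygen(high, dx, v$left, v$right)
  expect_lt(lap[1], 0)
  # occluded (sealed) vessels exchange nothing
  vo <- vessel_pair(0, 0)
  expect_equal(laplacian_robin_oxygen(low, dx, vo$left, vo$right, t = 1),
               rep(0, 11))
  # the sink variant drains toward a zero-oxygen lumen
  vs <- vessel_pair(0, Inf)
  vs$left$occluded_mode <- "sink"
  expect_lt(laplacian_robin_oxygen(low, dx, vs$left, vs$right, t = 1)[1], 0)
})

test_that("steady one-vessel slab with constant consumption matches the
           closed-form profile", {
  # D O2'' = k, Robin wall at x=0, zero-flux wall at x=L:
  # O2(x) = O2v - JkL/D - kLx/D + kx^2/(2D)
  D <- p$D_O2
  k <- 2e-3 # mmHg/s
  g <- grid_1d(300)
  dx <- g$dx * 1e-4
  L <- (g$n - 1) * dx
  v <- vessel_pair(Inf, 0) # right vessel sealed from t=0
  O2 <- rep(60, g$n)
  dt <- 0.2 * dx^2 / D
  for (i in 1:60000) {
    O2 <- O2 + dt * (D * laplacian_robin_oxygen(O2, dx, v$left, v$right, 1) - k)
  }
  x <- (seq_len(g$n) - 1) * dx
  exact <- 60 - v$left$J * k * L / D - k * L * x / D + k * x^2 / (2 * D)
  expect_equal(O2, exact, tolerance = 0.01)
})

test_that("semi-discrete RHS equals the term-by-term brute-force oracle", {
  g <- grid_1d(50) # 11 nodes
  set.seed(3)
  st <- tissue_state(g, u_n = runif(11, 0, 0.5), u_h = runif(11, 0, 0.4),
                     u_d = runif(11, 0, 0.1), O2 = runif(11, 0.1, 60), t = 10)
  for (v in list(vessel_pair(0, Inf), vessel_pair(Inf, Inf),
                 vessel_pair(5, 20))) {
    got <- semidiscrete_rhs(st, p, v)
    want <- oracle_rhs(st, p, v)
    expect_equal(got, want, tolerance = 1e-13)
  }
  # and for the hard-step switching variant
  ps <- model_parameters(switch_form = "step")
  expect_equal(semidiscrete_rhs(st, ps, vessel_pair(0, Inf)),
               oracle_rhs(st, ps, vessel_pair(0, Inf)), tolerance = 1e-13)
})

test_that("sealed domains conserve oxygen and cell mass discretely", {
  g <- grid_1d(100)
  set.seed(5)
  st <- tissue_state(g, u_n = runif(21, 0, 0.4), u_h = runif(21, 0, 0.4),
                     u_d = 0, O2 = runif(21, 10, 40), t = 1)
  # no consumers of oxygen, both vessels occluded: d/dt sum(O2) = 0
  p0 <- model_parameters(A_n = 1e-300)
  st0 <- st; st0$u_n[] <- 0; st0$u_h[] <- 0
  # the reflecting-ghost scheme conserves the trapezoidal sum exactly
  trap <- function(v) sum(v) - (v[1] + v[length(v)]) / 2
  r <- semidiscrete_rhs(st0, p0, vessel_pair(0, 0))
  expect_equal(trap(r$dO2), 0, tolerance = 1e-12)
  # no growth, switching and death off: total cell mass conserved
  pf <- model_parameters(tau_n = Inf, tau_h = Inf, tau_nh = Inf,
                         tau_hn = Inf, tau_hd = Inf)
  r <- semidiscrete_rhs(st, pf, vessel_pair(0, 0))
  expect_equal(trap(r$du_n + r$du_h + r$du_d) * g$dx, 0, tolerance = 1e-18)
})

test_that("grid construction places vessels on the end nodes", {
  g <- grid_1d(300)
  expect_equal(g$n, 61L)
  expect_equal(g$x[1], 0)
  expect_equal(g$x[g$n], 300)
  expect_error(grid_1d(12, dx = 5), "multiple")
  expect_error(grid_1d(10, dx = 5), "5 nodes")
})
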