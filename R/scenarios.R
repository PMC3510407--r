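#' Scenario configuration
#'
#' Describes the initial tissue and the vessel occlusion schedule for the
#' canonical experiments:
#'
#' * `"single_occlusion"`: normoxic cells seeded around the left vessel
#'   (plateau over the left half of the domain), left vessel thrombosed at
#'   t = 0, right vessel functional.  300 um domain by default.
#' * `"two_colony"`: as above on a 400 um domain, plus a small normoxic
#'   colony already established at the functional (right) vessel.
#' * `"control"`: the single-occlusion initial tissue but both vessels stay
#'   functional (the pure random-motion invasion baseline).
#' * `"sweep_member"`: the two-colony layout at an arbitrary inter-vessel
#'   distance, initial data scaled proportionally to the tissue size (used
#'   by [distance_sweep()]).
#' * `"custom"`: whatever you pass.
#'
#' The initial oxygen field is uniform random noise around a healthy-tissue
#' mean of 24 mmHg; cells are seeded as a smoothed plateau of height
#' `seed_fraction` (fraction of capacity).
#'
#' @param name scenario preset name (see above).
#' @param L_x inter-vessel distance, um (preset default if `NULL`).
#' @param seed_fraction height of the seeded normoxic plateau (fraction of
#'   capacity).
#' @param colony_fraction height of the far-vessel colony (two-colony and
#'   sweep presets).
#' @param edge_width smoothing width of the seed edges, um.
#' @param O2_mean,O2_amplitude initial oxygen mean and half-range, mmHg.
#' @param rng_seed integer seed for the initial oxygen noise.
#' @param occlude_left_at,occlude_right_at vessel occlusion times, s
#'   (`NULL` = preset default).
#' @return An object of class `"scenario_config"`.
#' @examples
#' cfg <- scenario_config("single_occlusion", rng_seed = 1)
#' st <- make_initial_state(cfg)
#' @export
scenario_config <- function(name = c("single_occlusion", "two_colony",
                                     "control", "sweep_member", "custom"),
                            L_x = NULL, seed_fraction = 0.7,
                            colony_fraction = 0.05, edge_width = 10,
                            O2_mean = 24, O2_amplitude = 6,
                            rng_seed = 1L,
                            occlude_left_at = NULL, occlude_right_at = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    single_occlusion = list(L_x = 300, colony = 0, left = 0, right = Inf),
    two_colony       = list(L_x = 400, colony = colony_fraction,
                            left = 0, right = Inf),
    control          = list(L_x = 300, colony = 0, left = Inf, right = Inf),
    sweep_member     = list(L_x = 300, colony = colony_fraction,
                            left = 0, right = Inf),
    custom           = list(L_x = 300, colony = colony_fraction,
                            left = 0, right = Inf))
  L_x <- if (is.null(L_x)) defaults$L_x else L_x
  if (name == "sweep_member" && (L_x < 50 || L_x > 700))
    stop("sweep members cover inter-vessel distances of 50 to 700 um")
  if (!(seed_fraction > 0 && seed_fraction <= 1) && seed_fraction != 0)
    stop("seed_fraction must be in (0, 1] (or 0 for empty tissue)")
  if (!(O2_amplitude >= 0 && O2_amplitude < O2_mean))
    stop("O2_amplitude must be in [0, O2_mean) so oxygen stays positive")
  structure(list(
    name = name, L_x = L_x, seed_fraction = seed_fraction,
    colony_fraction = defaults$colony, edge_width = edge_width,
    O2_mean = O2_mean, O2_amplitude = O2_amplitude,
    rng_seed = as.integer(rng_seed),
    occlude_left_at = if (is.null(occlude_left_at)) defaults$left
                      else occlude_left_at,
    occlude_right_at = if (is.null(occlude_right_at)) defaults$right
                       else occlude_right_at),
    class = "scenario_config")
}

#' Randomised initial oxygen field
#'
#' I.i.d. uniform noise on `[O2_mean - a, O2_mean + a]`, reproducible under
#' the seed.  The default mean of 24 mmHg is the healthy brain tissue
#' oxygenation around which measured distributions scatter.
#'
#' @param grid a [grid_1d()].
#' @param O2_mean mean oxygen, mmHg.
#' @param O2_amplitude half-range `a`, mmHg (must be `< O2_mean`).
#' @param rng_seed integer seed.
#' @return Numeric vector of length `grid$n`.
#' @export
randomized_oxygen <- function(grid, O2_mean = 24, O2_amplitude = 6,
                              rng_seed = 1L) {
  if (!(O2_amplitude >= 0 && O2_amplitude < O2_mean))
    stop("O2_amplitude must be in [0, O2_mean) so oxygen stays positive")
  if (O2_amplitude == 0) return(rep(O2_mean, grid$n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(rng_seed))
  runif(grid$n, O2_mean - O2_amplitude, O2_mean + O2_amplitude)
}

#' Build the initial tissue state of a scenario
#'
#' The normoxic seed is a plateau of height `seed_fraction` covering
#' `(0, L_x/2]` with a tanh-smoothed edge of width `edge_width`; the
#' two-colony presets add a Gaussian colony of height `colony_fraction`
#' (taken exactly at the far-vessel node) and width `edge_width` at the
#' functional (right) vessel.  Hypoxic and necrotic densities start at
#' zero; oxygen from [randomized_oxygen()].
#'
#' Scenario constructors are pure: identical configurations give identical
#' states.
#'
#' @param cfg a [scenario_config()].
#' @param grid optional [grid_1d()] (defaults to `cfg$L_x` at 5 um spacing).
#' @return A [tissue_state()] at t = 0.
#' @export
make_initial_state <- function(cfg, grid = grid_1d(cfg$L_x)) {
  x <- grid$x
  u_n <- cfg$seed_fraction * 0.5 * (1 - tanh((x - cfg$L_x / 2) / cfg$edge_width))
  if (cfg$colony_fraction > 0)
    u_n <- u_n + cfg$colony_fraction *
      exp(-((cfg$L_x - x) / cfg$edge_width)^2)
  tissue_state(grid, u_n = pmin(u_n, 1), u_h = 0, u_d = 0,
               O2 = randomized_oxygen(grid, cfg$O2_mean, cfg$O2_amplitude,
                                      cfg$rng_seed),
               t = 0)
}

#' Vessel pair of a scenario
#'
#' @param cfg a [scenario_config()].
#' @return A vessel pair as from [vessel_pair()].
#' @export
scenario_vessels <- function(cfg) {
  vessel_pair(cfg$occlude_left_at, cfg$occlude_right_at)
}

#' Run a scenario end to end
#'
#' Convenience wrapper: builds the initial state and vessels from `cfg` and
#' integrates for `days` simulated days.
#'
#' @param cfg a [scenario_config()].
#' @param params a [model_parameters()].
#' @param days horizon, days.
#' @param integ optional [integrator_config()] (default: stiff mode with
#'   hourly snapshots).
#' @return A `"tissue_trajectory"`.
#' @export
run_scenario <- function(cfg, params = model_parameters(), days = 7,
                         integ = NULL) {
  if (is.null(integ))
    integ <- integrator_config("stiff", t_end = days * 86400)
  run_simulation(make_initial_state(cfg), params, scenario_vessels(cfg),
                 integ, scenario = cfg$name, seed = cfg$rng_seed)
}
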