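#' Oxygen-dependent phenotype switching functions
#'
#' The three step-like switches coupling the compartments: normoxic cells
#' acquire the hypoxic phenotype below the hypoxia threshold (`S_nh`),
#' hypoxic cells recover above it (`S_hn = 1 - S_nh`, exactly complementary),
#' and hypoxic cells under persistent anoxia die (`S_hd`, centred on the
#' anoxia threshold).  With the default smooth form
#' \deqn{S_{nh}(O_2) = \tfrac12\left(1 - \tanh\frac{O_2 - O_2^{(S)}}{\Delta O_2}\right)}
#' and analogously for `S_hd` around \eqn{O_2^{(D)}}.
#'
#' @param O2 oxygen partial pressure(s), mmHg; must be non-negative.
#' @param params a [model_parameters()] object.
#' @return A list with numeric components `S_nh`, `S_hn`, `S_hd`, each in
#'   \[0, 1\] and the same length as `O2`.
#' @examples
#' s <- switching_functions(7, model_parameters())
#' s$S_nh # 0.5 at the hypoxia threshold
#' @export
switching_functions <- function(O2, params) {
  if (any(!is.finite(O2)) || any(O2 < 0))
    stop("O2 must be finite and non-negative (integrator positivity failure?)")
  S_nh <- .s_down(O2, params$O2_S, params$delta_O2, params$switch_form)
  list(S_nh = S_nh,
       S_hn = 1 - S_nh,
       S_hd = .s_down(O2, params$O2_D, params$delta_O2, params$switch_form))
}

.s_down <- function(O2, centre, width, form) {
  if (identical(form, "step")) {
    ifelse(O2 < centre, 1, ifelse(O2 > centre, 0, 0.5))
  } else {
    0.5 * (1 - tanh((O2 - centre) / width))
  }
}

#' Pointwise reaction rates of the cell compartments
#'
#' Logistic growth limited by the total occupied fraction (necrotic debris
#' occupies space), oxygen-driven phenotype exchange and anoxic death:
#' with \eqn{T = u_n + u_h + u_d},
#' \deqn{\dot u_n = u_n(1-T)/\tau_n - S_{nh} u_n/\tau_{nh} + S_{hn} u_h/\tau_{hn}}
#' \deqn{\dot u_h = u_h(1-T)/\tau_h + S_{nh} u_n/\tau_{nh} - S_{hn} u_h/\tau_{hn} - S_{hd} u_h/\tau_{hd}}
#' \deqn{\dot u_d = S_{hd} u_h/\tau_{hd}}
#' Phenotype exchange conserves mass: the three rates sum to the pure
#' logistic part.  Apoptosis is absorbed into the effective proliferation
#' rates; necrotic material neither moves nor clears.
#'
#' @param u_n,u_h,u_d compartment densities as fractions of capacity
#'   (equal-length numeric vectors).
#' @param O2 oxygen, mmHg (same length).
#' @param params a [model_parameters()] object.
#' @return A list of rate vectors `du_n`, `du_h`, `du_d` (1/s).
#' @export
cell_reaction_rhs <- function(u_n, u_h, u_d, O2, params) {
  r <- .recycle(u_n = u_n, u_h = u_h, u_d = u_d, O2 = O2)
  u_n <- r$u_n; u_h <- r$u_h; u_d <- r$u_d; O2 <- r$O2
  s <- switching_functions(O2, params)
  room <- 1 - (u_n + u_h + u_d)
  flow_nh <- s$S_nh * u_n / params$tau_nh
  flow_hn <- s$S_hn * u_h / params$tau_hn
  death <- s$S_hd * u_h / params$tau_hd
  list(du_n = u_n * room / params$tau_n - flow_nh + flow_hn,
       du_h = u_h * room / params$tau_h + flow_nh - flow_hn - death,
       du_d = death)
}

#' Michaelis-Menten oxygen uptake rate
#'
#' Saturable consumption by both viable phenotypes,
#' \deqn{\dot O_2|_{uptake} = -A_n\,(u_n + r\,u_h)\,\frac{O_2}{O_2^{(T)} + O_2}}
#' with \eqn{r} the hypoxic-to-normoxic uptake ratio.  Always non-positive
#' and vanishing as \eqn{O_2 \to 0}, so uptake cannot drive oxygen negative
#' in the continuum limit.
#'
#' @inheritParams cell_reaction_rhs
#' @return Numeric vector of uptake rates (mmHg/s, non-positive).
#' @export
oxygen_uptake_rhs <- function(u_n, u_h, O2, params) {
  r <- .recycle(u_n = u_n, u_h = u_h, O2 = O2)
  -params$A_n * (r$u_n + params$uptake_ratio * r$u_h) * r$O2 /
    (params$O2_T + r$O2)
}

# recycle length-1 arguments to the common length; anything else must match
.recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- !(lengths(args) %in% c(1L, n))
  if (any(bad))
    stop(paste(names(args), collapse = ", "),
         " must have equal length (scalars are recycled)")
  lapply(args, rep_len, n)
}

#' Calibrate the volumetric oxygen uptake scale
#'
#' Finds the uptake `A_n` for which the steady-state oxygen profile in a
#' full-density normoxic slab, fed by a single vessel, first crosses the
#' hypoxia threshold `O2_S` at a prescribed distance from the vessel wall.
#' Hypoxia in vascularised tumour tissue sets in roughly 150 um from a
#' vessel, which is the default anchor.
#'
#' The steady profile solves \eqn{D_{O_2} O_2'' = A_n\,O_2/(O_2^{(T)}+O_2)}
#' on a semi-infinite slab.  With `vessel_bc = "dirichlet"` the wall is held
#' at the perivascular level `vessel_O2`; with `"robin"` the transmural
#' exchange law (gradient `(O2 - O2_v)/J` at the wall) is used instead.  The
#' solve uses the first integral of the steady equation (shooting on the
#' wall value for the Robin case) and bisection on `A_n`; the result is
#' reproducible to well under three significant digits.
#'
#' @param params a [model_parameters()] object (thresholds and `D_O2` used).
#' @param vessel_O2 vessel oxygen, mmHg.
#' @param target_distance desired hypoxia onset distance from the wall, um
#'   (in (0, 1000)).
#' @param vessel_bc `"dirichlet"` (perivascular wall value, default) or
#'   `"robin"` (transmural exchange with length `J`).
#' @param J exchange length for the Robin wall, cm.
#' @return Calibrated `A_n`, mmHg/s.
#' @examples
#' round(calibrate_uptake(model_parameters()), 2) # the packaged default
#' @export
calibrate_uptake <- function(params = model_parameters(), vessel_O2 = 60,
                             target_distance = 150,
                             vessel_bc = c("dirichlet", "robin"), J = 0.1) {
  vessel_bc <- match.arg(vessel_bc)
  if (!(target_distance > 0 && target_distance < 1000))
    stop("target_distance must be in (0, 1000) um")
  target_cm <- target_distance * 1e-4
  D <- params$D_O2
  O2T <- params$O2_T
  O2S <- params$O2_S
  if (vessel_O2 <= O2S)
    stop("vessel oxygen must exceed the hypoxia threshold for a crossing ",
         "to exist (diagnostic: wall O2 = ", vessel_O2, " mmHg <= O2_S)")

  # first integral with O2, O2' -> 0 far from the vessel:
  #   O2'(x) = -sqrt(2 A F(O2) / D),  F(s) = s - O2T log(1 + s/O2T)
  Ffun <- function(s) s - O2T * log1p(s / O2T)
  # distance from a wall value b down to the O2_S crossing, as
  # sqrt(D/(2A)) * integral of F^{-1/2}; the quadrature is A-independent
  quad <- function(a, b) {
    stats::integrate(function(s) 1 / sqrt(Ffun(s)), a, b,
                     rel.tol = 1e-10, subdivisions = 500L)$value
  }
  crossing <- function(A) {
    if (vessel_bc == "dirichlet") {
      wall <- vessel_O2
    } else {
      # wall value solves the Robin flux match: (O2v - b)/J = sqrt(2 A F(b)/D)
      g <- function(b) (vessel_O2 - b) / J - sqrt(2 * A * Ffun(b) / D)
      if (g(O2S) <= 0) return(0) # wall already below the hypoxia threshold
      wall <- stats::uniroot(g, c(O2S, vessel_O2 - 1e-12), tol = 1e-12)$root
    }
    sqrt(D / (2 * A)) * quad(O2S, wall)
  }
  # crossing distance is monotone decreasing in A: bracket and bisect
  lo <- 1e-6; hi <- 1e4
  if (crossing(lo) < target_cm || crossing(hi) > target_cm)
    stop("calibration target unreachable: steady profile crosses O2_S at ",
         signif(crossing(lo) * 1e4, 3), " um (A_n -> 0) to ",
         signif(crossing(hi) * 1e4, 3), " um (A_n -> inf)")
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (crossing(mid) > target_cm) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-10) break
  }
  sqrt(lo * hi)
}
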