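#' Model parameters for the two-phenotype glioblastoma model
#'
#' Builds the validated parameter set of the model.  Defaults are the
#' literature-derived values for human glioma: carrying capacity
#' \eqn{10^6} cell/cm2, hypoxia switch at 7 mmHg, anoxia at 0.7 mmHg,
#' Michaelis-Menten half-saturation at 2.5 mmHg, doubling times of 24 h
#' (normoxic) and 48 h (hypoxic), switch times of 1 h (normoxic to hypoxic)
#' and 96 h (back), 48 h mean survival under anoxia, cell diffusivities
#' \eqn{6.6\times 10^{-12}} and \eqn{6.6\times 10^{-11}} cm2/s and oxygen
#' diffusivity \eqn{10^{-5}} cm2/s.
#'
#' Densities are handled internally as fractions of `C_M`, so `C_M` only
#' matters when absolute cell counts are reported
#' (see [population_totals()]).
#'
#' The volumetric uptake scale `A_n` (mmHg/s consumed by tissue at full
#' normoxic density, before Michaelis-Menten saturation) is the one parameter
#' not printed directly in per-volume units; the default is the output of
#' [calibrate_uptake()] with its defaults (steady oxygen profile of a
#' full-density normoxic slab crossing the hypoxia threshold 150 um from a
#' perivascular boundary held at 60 mmHg), frozen to three significant
#' digits.  Hypoxic cells consume at `uptake_ratio` times the normoxic rate.
#'
#' @param C_M carrying capacity, cell/cm2.
#' @param D_n,D_h normoxic / hypoxic cell diffusivity, cm2/s.
#' @param D_O2 oxygen diffusivity, cm2/s.
#' @param tau_n,tau_h normoxic / hypoxic doubling time, s.
#' @param tau_nh,tau_hn,tau_hd phenotype switch (normoxic to hypoxic, back)
#'   and anoxic death characteristic times, s.  `Inf` disables a channel.
#' @param O2_S,O2_D,O2_T hypoxia switch, anoxia and Michaelis-Menten
#'   thresholds, mmHg.
#' @param delta_O2 transition width of the switching sigmoids, mmHg.
#' @param A_n maximal volumetric oxygen uptake at full normoxic density,
#'   mmHg/s.
#' @param uptake_ratio hypoxic-to-normoxic uptake ratio (dimensionless).
#' @param switch_form `"tanh"` for smooth complementary sigmoids (default)
#'   or `"step"` for hard switches.
#' @return An object of class `"model_parameters"` (a validated named list).
#' @examples
#' p <- model_parameters()
#' p$tau_nh / 3600 # 1 h
#' @export
model_parameters <- function(C_M = 1e6,
                             D_n = 6.6e-12,
                             D_h = 6.6e-11,
                             D_O2 = 1e-5,
                             tau_n = 24 * 3600,
                             tau_h = 48 * 3600,
                             tau_nh = 1 * 3600,
                             tau_hn = 96 * 3600,
                             tau_hd = 48 * 3600,
                             O2_S = 7,
                             O2_D = 0.7,
                             O2_T = 2.5,
                             delta_O2 = 0.1,
                             A_n = 3.14,
                             uptake_ratio = 1 / 5,
                             switch_form = c("tanh", "step")) {
  switch_form <- match.arg(switch_form)
  p <- list(C_M = C_M, D_n = D_n, D_h = D_h, D_O2 = D_O2,
            tau_n = tau_n, tau_h = tau_h, tau_nh = tau_nh,
            tau_hn = tau_hn, tau_hd = tau_hd,
            O2_S = O2_S, O2_D = O2_D, O2_T = O2_T,
            delta_O2 = delta_O2, A_n = A_n, uptake_ratio = uptake_ratio,
            switch_form = switch_form)
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

validate_parameters <- function(p) {
  num <- p[setdiff(names(p), "switch_form")]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && length(v) == 1 && !is.na(v) && v > 0, logical(1))]
  if (length(bad))
    stop("parameters must be positive scalars: ", paste(bad, collapse = ", "))
  if (!(p$O2_D < p$O2_T && p$O2_T < p$O2_S))
    stop("thresholds must satisfy O2_D < O2_T < O2_S")
  if (!(p$D_n < p$D_h))
    stop("hypoxic cells must be the motile phenotype (D_n < D_h)")
  if (is.finite(p$tau_n) && is.finite(p$tau_h) && !(p$tau_n < p$tau_h))
    stop("normoxic cells must be the proliferative phenotype (tau_n < tau_h)")
  if (is.finite(p$tau_nh) && is.finite(p$tau_hn) && !(p$tau_nh < p$tau_hn))
    stop("entry into the hypoxic phenotype must be faster than recovery ",
         "(tau_nh < tau_hn)")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Two-phenotype glioblastoma model parameters\n")
  cat(sprintf("  capacity C_M           %g cell/cm2\n", x$C_M))
  cat(sprintf("  diffusivity D_n, D_h   %g, %g cm2/s\n", x$D_n, x$D_h))
  cat(sprintf("  oxygen D_O2            %g cm2/s\n", x$D_O2))
  cat(sprintf("  doubling tau_n, tau_h  %g, %g h\n",
              x$tau_n / 3600, x$tau_h / 3600))
  cat(sprintf("  switch tau_nh, tau_hn  %g, %g h; death tau_hd %g h\n",
              x$tau_nh / 3600, x$tau_hn / 3600, x$tau_hd / 3600))
  cat(sprintf("  O2 thresholds S/T/D    %g / %g / %g mmHg (width %g)\n",
              x$O2_S, x$O2_T, x$O2_D, x$delta_O2))
  cat(sprintf("  uptake A_n             %g mmHg/s (hypoxic ratio %g)\n",
              x$A_n, x$uptake_ratio))
  cat(sprintf("  switching form         %s\n", x$switch_form))
  invisible(x)
}

# numeric packing consumed by the compiled kernel
.pack_params <- function(p) {
  c(p$D_n, p$D_h, p$D_O2, p$tau_n, p$tau_h, p$tau_nh, p$tau_hn, p$tau_hd,
    p$O2_S, p$O2_D, p$O2_T, p$delta_O2, p$A_n, p$uptake_ratio,
    if (identical(p$switch_form, "step")) 1 else 0)
}

# accepted config keys -> (target name, conversion to internal units)
.config_keys <- function() {
  list(
    C_M          = list("C_M", 1),
    D_n          = list("D_n", 1),
    D_h          = list("D_h", 1),
    D_O2         = list("D_O2", 1),
    tau_n_h      = list("tau_n", 3600),
    tau_h_h      = list("tau_h", 3600),
    tau_nh_h     = list("tau_nh", 3600),
    tau_hn_h     = list("tau_hn", 3600),
    tau_hd_h     = list("tau_hd", 3600),
    O2_S         = list("O2_S", 1),
    O2_D         = list("O2_D", 1),
    O2_T         = list("O2_T", 1),
    delta_O2     = list("delta_O2", 1),
    A_n          = list("A_n", 1),
    uptake_ratio = list("uptake_ratio", 1)
  )
}

#' Read model parameters from a flat key-value config file
#'
#' The format is `key = value` lines (`#` comments allowed).  Time constants
#' are given in hours (`tau_n_h`, `tau_nh_h`, ...), diffusivities in cm2/s
#' and oxygen levels in mmHg; `switch_form` may be `tanh` or `step`.
#' Unknown keys are an error.
#'
#' @param path file to read.
#' @param base parameter set supplying the values not present in the file.
#' @return A [model_parameters()] object.
#' @export
read_parameters <- function(path, base = model_parameters()) {
  kv <- .read_config_lines(path)
  keys <- .config_keys()
  p <- unclass(base)
  for (k in names(kv)) {
    if (k == "switch_form") {
      p$switch_form <- match.arg(kv[[k]], c("tanh", "step"))
    } else if (k %in% names(keys)) {
      v <- suppressWarnings(as.numeric(kv[[k]]))
      if (is.na(v)) stop("non-numeric value for key '", k, "'")
      p[[keys[[k]][[1]]]] <- v * keys[[k]][[2]]
    } else {
      stop("unknown parameter key '", k, "' in ", path)
    }
  }
  validate_parameters(p)
  structure(p, class = "model_parameters")
}

#' Write model parameters to a flat key-value config file
#'
#' Inverse of [read_parameters()]: `read_parameters(write_parameters(p, f))`
#' restores `p` exactly.
#'
#' @param p a [model_parameters()] object.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  keys <- .config_keys()
  lines <- c("# glioxide model parameters",
             vapply(names(keys), function(k) {
               sprintf("%s = %.17g", k, p[[keys[[k]][[1]]]] / keys[[k]][[2]])
             }, character(1)),
             sprintf("switch_form = %s", p$switch_form))
  writeLines(lines, path)
  invisible(path)
}

.read_config_lines <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  out <- list()
  for (i in seq_along(raw)) {
    m <- regmatches(raw[i], regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", raw[i]))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line ", i, ": '", raw[i], "'")
    out[[m[2]]] <- trimws(m[3])
  }
  out
}
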