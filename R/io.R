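#' Write a trajectory as a long-format snapshot table
#'
#' Plain tab-separated text with columns
#' `time_s, x_um, u_n, u_h, u_d, O2_mmHg` (one row per snapshot and node),
#' diffable across runs.
#'
#' @param traj a `"tissue_trajectory"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snapshot_table <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Morphometric summary of a trajectory
#'
#' One row per metric: palisade width (maximal over snapshots), formation
#' time, lifetime, necrotic core width at the final snapshot, invasion time
#' of the functional vessel, switch completion time, and final cell counts.
#'
#' @param traj a `"tissue_trajectory"`.
#' @param thresholds a [metric_thresholds()].
#' @param functional_side,occluded_side boundary roles (defaults match the
#'   canonical scenarios: left vessel occluded, right functional).
#' @param C_M carrying capacity for the counts.
#' @return A `data.frame` with columns `metric`, `value`, `unit`.
#' @export
metrics_summary <- function(traj, thresholds = metric_thresholds(),
                            functional_side = "right",
                            occluded_side = "left", C_M = 1e6) {
  w <- palisade_widths(traj, thresholds, functional_side)
  life <- palisade_lifetime(traj, thresholds, functional_side)
  last <- snapshot(traj, length(traj$times))
  inv <- invasion_time(traj, functional_side, thresholds)
  sw <- switch_completion_time(traj, occluded_side, thresholds)
  tot <- population_totals(last, C_M)
  data.frame(
    metric = c("palisade_width_max", "palisade_width_argmax_time",
               "formation_time", "lifetime", "necrotic_core_width",
               "invasion_time", "switch_completion_time",
               "N_normoxic", "N_hypoxic", "N_necrotic"),
    value = c(max(w), traj$times[which.max(w)] / 3600,
              life$formation_time, life$lifetime,
              necrotic_core_width(last, thresholds, occluded_side),
              inv, sw, tot[["N_n"]], tot[["N_h"]], tot[["N_d"]]),
    unit = c("um", "h", "h", "h", "um", "d", "h",
             "cell", "cell", "cell"),
    stringsAsFactors = FALSE)
}

#' Run manifest
#'
#' Records how a result set was produced: scenario and parameter values
#' (after unit conversion), integrator settings, seed, package version,
#' wall-clock interval and the inventory of output files with checksums.
#'
#' @param traj a `"tissue_trajectory"`.
#' @param params a [model_parameters()].
#' @param files character vector of output paths to inventory.
#' @param started,finished POSIXct wall-clock bounds.
#' @param path optional file to write the manifest to (key-value text).
#' @return The manifest as a named list, invisibly if `path` is given.
#' @export
run_manifest <- function(traj, params, files = character(),
                         started = Sys.time(), finished = Sys.time(),
                         path = NULL) {
  files <- files[file.exists(files)]
  man <- c(
    list(scenario = traj$scenario, rng_seed = traj$seed,
         integrator = traj$method, fingerprint = traj$fingerprint,
         n_snapshots = length(traj$times),
         t_end_s = max(traj$times), L_x_um = traj$grid$L_x,
         dx_um = traj$grid$dx,
         min_state_value = traj$clip$min_value,
         n_clipped = traj$clip$n_clipped,
         version = as.character(packageVersion("glioxide")),
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(finished, "%Y-%m-%dT%H:%M:%S%z")),
    as.list(unlist(unclass(params))),
    if (length(files))
      stats::setNames(as.list(unname(tools::md5sum(files))),
                      paste0("md5_", basename(files))))
  if (!is.null(path)) {
    writeLines(c("# glioxide run manifest",
                 sprintf("%s = %s", names(man),
                         vapply(man, function(v) format(v, digits = 15),
                                character(1)))), path)
    return(invisible(man))
  }
  man
}

#' Command-line entry point
#'
#' Backs the `inst/cli/glioxide` script; also callable directly.
#' Subcommands:
#' \describe{
#'   \item{run}{run one scenario preset and write the snapshot table,
#'     metrics summary and manifest.}
#'   \item{sweep}{run the inter-vessel distance sweep and write its table;
#'     members already present in the output are skipped, so an interrupted
#'     sweep resumes.}
#'   \item{calibrate}{print the calibrated uptake A_n.}
#' }
#' Flags: `--preset name`, `--config file`, `--set key=value` (repeatable;
#' keys `scenario.*`, `integrator.*` or parameter keys), `--seed int`,
#' `--outdir dir`, `--days x`, `--distances a,b,c`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: glioxide <run|sweep|calibrate> [flags]")
    cmd <- args[1]
    fl <- .parse_flags(args[-1])
    switch(cmd,
           run = .cli_run(fl),
           sweep = .cli_sweep(fl),
           calibrate = .cli_calibrate(fl),
           stop("unknown subcommand '", cmd, "'"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  fl <- list(set = character())
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument '", a, "'")
    key <- substring(a, 3)
    if (i == length(args)) stop("flag --", key, " needs a value")
    val <- args[i + 1]
    if (key == "set") fl$set <- c(fl$set, val) else fl[[key]] <- val
    i <- i + 2
  }
  fl
}

.apply_overrides <- function(fl, cfg, integ_opts, params) {
  for (kv in fl$set) {
    m <- regmatches(kv, regexec("^([A-Za-z0-9_.]+)=(.*)$", kv))[[1]]
    if (length(m) != 3) stop("--set expects key=value, got '", kv, "'")
    key <- m[2]; val <- m[3]
    if (startsWith(key, "scenario.")) {
      cfg[[substring(key, 10)]] <- as.numeric(val)
    } else if (startsWith(key, "integrator.")) {
      k <- substring(key, 12)
      integ_opts[[k]] <- if (k == "method") val else as.numeric(val)
    } else {
      keys <- .config_keys()
      if (key == "switch_form") params$switch_form <- val
      else if (key %in% names(keys))
        params[[keys[[key]][[1]]]] <- as.numeric(val) * keys[[key]][[2]]
      else stop("unknown --set key '", key, "'")
    }
  }
  validate_parameters(params)
  list(cfg = cfg, integ_opts = integ_opts, params = params)
}

.cli_setup <- function(fl, default_preset = "single_occlusion") {
  params <- if (!is.null(fl$config)) read_parameters(fl$config)
            else model_parameters()
  seed <- if (!is.null(fl$seed)) as.integer(fl$seed) else 1L
  preset <- if (!is.null(fl$preset)) fl$preset else default_preset
  cfg <- scenario_config(preset, rng_seed = seed)
  integ_opts <- list(method = "stiff",
                     days = if (!is.null(fl$days)) as.numeric(fl$days) else 7)
  ov <- .apply_overrides(fl, cfg, integ_opts, params)
  outdir <- if (!is.null(fl$outdir)) fl$outdir else "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  c(ov, list(seed = seed, outdir = outdir))
}

.cli_run <- function(fl) {
  s <- .cli_setup(fl)
  started <- Sys.time()
  io <- s$integ_opts
  t_end <- if (!is.null(io$t_end)) io$t_end else io$days * 86400
  integ <- integrator_config(io$method, t_end = t_end,
                             dt = if (is.null(io$dt)) 0.01 else io$dt)
  stab <- check_stability(integ$dt, grid_1d(s$cfg$L_x), s$params)
  message(sprintf("stability: dt_max = %.4g s (%s); using %s mode",
                  stab$dt_max, stab$limiting, integ$method))
  traj <- run_simulation(make_initial_state(s$cfg), s$params,
                         scenario_vessels(s$cfg), integ,
                         scenario = s$cfg$name, seed = s$seed)
  if (traj$clip$min_value < 0)
    message(sprintf("negative excursion: min state value %.3e",
                    traj$clip$min_value))
  snap_f <- file.path(s$outdir, "snapshots.tsv")
  met_f <- file.path(s$outdir, "metrics.tsv")
  write_snapshot_table(traj, snap_f)
  write.table(metrics_summary(traj), met_f, sep = "\t",
              row.names = FALSE, quote = FALSE)
  run_manifest(traj, s$params, c(snap_f, met_f), started, Sys.time(),
               path = file.path(s$outdir, "manifest.txt"))
  message("wrote ", snap_f, ", ", met_f)
}

.cli_sweep <- function(fl) {
  s <- .cli_setup(fl, default_preset = "two_colony")
  distances <- if (!is.null(fl$distances))
    as.numeric(strsplit(fl$distances, ",")[[1]])
  else seq(50, 700, by = 50)
  out_f <- file.path(s$outdir, "sweep.tsv")
  done <- if (file.exists(out_f))
    read.table(out_f, header = TRUE, sep = "\t")$distance_um
  else numeric()
  todo <- setdiff(distances, done)
  if (length(todo)) {
    res <- distance_sweep(todo, s$params, days = s$integ_opts$days,
                          rng_seed = s$seed, base_cfg = s$cfg)
    if (file.exists(out_f)) {
      prev <- read.table(out_f, header = TRUE, sep = "\t")
      res <- rbind(prev, res)
      res <- res[order(res$distance_um), ]
    }
    write.table(res, out_f, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res <- read.table(out_f, header = TRUE, sep = "\t")
  if (any(!is.na(res$error))) {
    message("sweep completed with failed members")
    return(invisible(2L))
  }
  message("wrote ", out_f, " (", nrow(res), " rows)")
}

.cli_calibrate <- function(fl) {
  params <- if (!is.null(fl$config)) read_parameters(fl$config)
            else model_parameters()
  target <- if (!is.null(fl$distance)) as.numeric(fl$distance) else 150
  bc <- if (!is.null(fl$bc)) fl$bc else "dirichlet"
  A <- calibrate_uptake(params, target_distance = target, vessel_bc = bc)
  cat(sprintf("A_n = %.6g mmHg/s (hypoxia onset %g um, %s vessel wall)\n",
              A, target, bc))
}
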