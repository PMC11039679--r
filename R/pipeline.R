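# Configuration, orchestration and reporting: the end-to-end pipeline surface.
# A thin command-line wrapper over these functions ships in
# inst/scripts/redoxtf-cli.R.

#' Read a simulation configuration file
#'
#' YAML with sections `condition`, `perturbation`, `params`, `run`; any
#' omitted key falls back to the shipped default. See
#' `system.file("config", "default.yaml", package = "redoxtf")`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config parse error in ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(raw)) stop("config parse error: top level must be a mapping",
                          call. = FALSE)
  cond <- raw$condition %||% list()
  pert <- raw$perturbation %||% list()
  pars <- raw$params %||% list()
  run <- raw$run %||% list()
  unknown <- setdiff(names(pars), names(formals(kinetic_params)))
  if (length(unknown)) {
    stop("unknown parameter(s) in [params]: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  condition <- do.call(exposure_condition, c(
    list(mode = cond$mode %||% "none", dose = cond$dose %||% 0),
    if (!is.null(cond$treatment_start)) {
      list(treatment_start = cond$treatment_start)
    }))
  perturbation <- do.call(perturbation_mode, c(
    list(label = pert$label %||% "control"),
    pert[intersect(names(pert),
                   c("srxn1_multiplier", "prdx_capacity_multiplier"))]))
  params <- do.call(kinetic_params, pars)
  simulation_config(condition = condition, perturbation = perturbation,
                    params = params,
                    n_cells = run$n_cells %||% 100L,
                    t_end = run$t_end %||% 24,
                    dt_sample = run$dt_sample %||% 1 / 3,
                    seed = run$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Print every configuration default
#'
#' @param config Optional [simulation_config()]; defaults to the shipped
#'   default configuration.
#' @return The configuration, invisibly.
#' @export
config_show <- function(config = NULL) {
  if (is.null(config)) config <- simulation_config()
  cat("[condition]\n")
  cat(sprintf("  mode: %s\n  dose: %g\n  treatment_start: %g\n",
              config$condition$mode, config$condition$dose,
              config$condition$treatment_start))
  cat("[perturbation]\n")
  cat(sprintf("  label: %s\n  srxn1_multiplier: %g\n",
              config$perturbation$label, config$perturbation$srxn1_multiplier))
  cat(sprintf("  prdx_capacity_multiplier: %g\n",
              config$perturbation$prdx_capacity_multiplier))
  cat("[params]\n")
  for (nm in names(config$params)) {
    cat(sprintf("  %s: %g\n", nm, config$params[[nm]]))
  }
  cat("[run]\n")
  cat(sprintf("  n_cells: %d\n  t_end: %g\n  dt_sample: %g\n  seed: %d\n",
              config$n_cells, config$t_end, config$dt_sample, config$seed))
  invisible(config)
}

config_hash <- function(config) {
  canon <- utils::capture.output(utils::str(
    list(condition = unclass(config$condition),
         perturbation = unclass(config$perturbation),
         params = unclass(config$params),
         n_cells = config$n_cells, t_end = config$t_end,
         dt_sample = config$dt_sample, seed = config$seed),
    digits.d = 15, vec.len = 100))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(canon, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, config, outputs, extra = list()) {
  man <- c(
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("redoxtf"))),
    sprintf("seed: %d", config$seed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("outputs: %s", paste(outputs, collapse = ", ")),
    vapply(names(extra), function(nm) sprintf("%s: %s", nm, extra[[nm]]),
           character(1))
  )
  path <- file.path(out_dir, "manifest.txt")
  writeLines(man, path)
  invisible(path)
}

#' Simulate a population from a configuration file
#'
#' Writes `traces.csv`, `snapshot.csv` (5-h fixation by default) and a run
#' manifest to `out_dir`.
#'
#' @param config_path YAML configuration path (see [read_config()]), or a
#'   [simulation_config()] object.
#' @param out_dir Output directory (created if absent).
#' @param t_fix Snapshot fixation time in hours.
#' @param verbose Log a summary line to stderr.
#' @return Invisibly, a list with the trace and snapshot tables and paths.
#' @export
run_simulate <- function(config_path, out_dir, t_fix = 5, verbose = FALSE) {
  config <- if (inherits(config_path, "simulation_config")) config_path
            else read_config(config_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- simulate_population(config)
  snap <- simulate_snapshot(config, t_fix = min(t_fix, config$t_end))
  tp <- file.path(out_dir, "traces.csv")
  sp <- file.path(out_dir, "snapshot.csv")
  write_traces(traces, tp)
  write_snapshot(snap, sp)
  df <- death_fraction(traces)
  write_manifest(out_dir, config, c("traces.csv", "snapshot.csv"),
                 list(n_cells = sprintf("%d", config$n_cells),
                      death_fraction = sprintf("%.4f", df)))
  if (verbose) {
    message(sprintf("simulated %d cells (seed %d): death fraction %.3f",
                    config$n_cells, config$seed, df))
  }
  invisible(list(traces = traces, snapshot = snap,
                 paths = c(traces = tp, snapshot = sp)))
}

#' Analyze a trace table end to end
#'
#' Runs the full analysis pipeline on a trace CSV (or in-memory table):
#' validation, event detection, event-aligned aggregation, windowed
#' autocorrelation with fate stratification, snapshot-style quadrant
#' classification of the traces at a fixed frame, and a plain-text report.
#' Writes `events.csv`, `aligned.csv`, `acf.csv`, `quadrant.csv`,
#' `report.txt` to `out_dir`.
#'
#' @param traces_path Trace CSV path or a `trace_table`.
#' @param out_dir Output directory.
#' @param thresholds An [activation_thresholds()] object.
#' @param anchor Alignment anchor (default `"foxo_exit"`, the bolus
#'   convention; use `"foxo_entry"` for continuous exposure).
#' @param channel Aligned channel.
#' @param t_fix Frame (hours) for the quadrant section.
#' @param quantile Control quantile when the table contains untreated cells;
#'   otherwise fixed cuts from `fallback_cuts`.
#' @param fallback_cuts `c(log_p53_cut, foxo_frac_cut)` used when no
#'   untreated cells are present.
#' @return Invisibly, a list of all stage results.
#' @export
run_analyze <- function(traces_path, out_dir,
                        thresholds = activation_thresholds(),
                        anchor = c("foxo_exit", "foxo_entry"),
                        channel = "p53_nuc", t_fix = 5, quantile = 0.95,
                        fallback_cuts = NULL) {
  anchor <- match.arg(anchor)
  traces <- if (is.data.frame(traces_path)) traces_path
            else read_traces(traces_path)
  report <- validate_traces(traces)
  if (any(!report$pass)) {
    bad <- report[!report$pass, , drop = FALSE]
    stop("trace validation failed for cell ", bad$cell_id[1], ": ",
         bad$reason[1], call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  events <- detect_events(traces, thresholds)
  utils::write.csv(events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)

  ens <- tryCatch(align_traces(traces, events, anchor = anchor,
                               channel = channel),
                  warning = function(w) {
                    suppressWarnings(align_traces(traces, events,
                                                  anchor = anchor,
                                                  channel = channel))
                  })
  aligned_df <- data.frame(lag_h = ens$lag, median = ens$median,
                           mad = ens$mad, n = ens$n, flagged = ens$flagged)
  utils::write.csv(aligned_df, file.path(out_dir, "aligned.csv"),
                   row.names = FALSE)

  fates <- suppressWarnings(compare_fates(traces, events))
  acf_rows <- list()
  for (grp in c("dying", "surviving")) {
    g <- fates[[grp]]
    if (!is.null(g)) {
      acf_rows[[grp]] <- data.frame(group = grp, lag_h = g$lags,
                                    median_r = g$median, mad_r = g$mad,
                                    n = g$n)
    }
  }
  acf_df <- if (length(acf_rows)) do.call(rbind, acf_rows) else
    data.frame(group = character(0), lag_h = numeric(0),
               median_r = numeric(0), mad_r = numeric(0), n = integer(0))
  utils::write.csv(acf_df, file.path(out_dir, "acf.csv"), row.names = FALSE)

  # quadrant section from the trace frame nearest t_fix
  tg <- sort(unique(traces$t_h))
  t_snap <- tg[which.min(abs(tg - min(t_fix, max(tg))))]
  rows <- traces[abs(traces$t_h - t_snap) < 1e-9 & !traces$dead &
                   !is.na(traces$foxo1_nuc_frac), , drop = FALSE]
  snap <- data.frame(cell_id = rows$cell_id, mode = rows$mode,
                     dose = rows$dose, perturbation = rows$perturbation,
                     t_fix = t_snap, foxo1_nuc_frac = rows$foxo1_nuc_frac,
                     log_p53 = log(rows$p53_nuc), stringsAsFactors = FALSE)
  ctrl <- snap[snap$dose == 0, , drop = FALSE]
  thr <- if (nrow(ctrl) >= 50) {
    estimate_thresholds(ctrl, quantile = quantile)
  } else if (!is.null(fallback_cuts)) {
    fixed_thresholds(fallback_cuts[1], fallback_cuts[2])
  } else {
    fixed_thresholds(stats::quantile(snap$log_p53, 0.5, na.rm = TRUE),
                     0.5)
  }
  quad <- quadrant_classify(snap, thr)
  utils::write.csv(quad$summary, file.path(out_dir, "quadrant.csv"),
                   row.names = FALSE)

  lag_stat <- lag_statistic(events)
  med_dur <- stats::median(events$nuclear_duration[events$n_episodes > 0])
  death_frac <- mean(events$died)

  rp <- file.path(out_dir, "report.txt")
  lines <- c(
    "redoxtf analysis report",
    sprintf("cells: %d  frames/cell: %d", nrow(events),
            length(tg)),
    "",
    "[quadrants]",
    utils::capture.output(print(quad$summary, row.names = FALSE)),
    "",
    "[foxo1 episodes]",
    sprintf("cells with >=1 episode: %d (%.1f%%)",
            sum(events$n_episodes > 0),
            100 * mean(events$n_episodes > 0)),
    sprintf("median nuclear duration (h): %s",
            ifelse(is.na(med_dur), "NA", sprintf("%.2f", med_dur))),
    "",
    "[exit -> p53 onset lag]",
    sprintf("qualifying cells: %d", lag_stat$n),
    sprintf("median lag (h): %s",
            ifelse(is.na(lag_stat$median), "NA",
                   sprintf("%.2f", lag_stat$median))),
    "",
    "[alignment]",
    sprintf("anchored cells: %d  excluded (no anchor): %d",
            ens$n_cells, ens$n_excluded),
    "",
    "[oscillation]",
    sprintf("dying: %s", if (is.null(fates$dying)) "absent (< n_min)"
            else sprintf("n=%d oscillatory %.1f%%", fates$dying$n,
                         100 * fates$dying$osc_fraction)),
    sprintf("surviving: %s", if (is.null(fates$surviving))
      "absent (< n_min)"
      else sprintf("n=%d oscillatory %.1f%%", fates$surviving$n,
                   100 * fates$surviving$osc_fraction)),
    "",
    "[death]",
    sprintf("death fraction: %.3f", death_frac)
  )
  writeLines(lines, rp)
  invisible(list(events = events, aligned = ens, fates = fates,
                 quadrant = quad, lag = lag_stat, report_path = rp))
}
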