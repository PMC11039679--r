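# Event detection: FOXO1 nuclear entry/exit episodes (hysteresis + persistence),
# p53 accumulation onset (baseline + MAD rule), and the p53 rate series.

#' Activation thresholds for event detection
#'
#' Hysteresis thresholds for FOXO1 episode calling and the onset rule for
#' p53. A FOXO1 episode opens at the first of `persistence` consecutive
#' frames at or above `foxo_hi` and closes at the first of `persistence`
#' consecutive frames at or below `foxo_lo`. p53 onset is the first time the
#' (pre-death) series exceeds `baseline + p53_mad_mult * MAD(baseline)` for
#' `onset_run` consecutive frames.
#'
#' The onset cut has a relative floor: it is never less than
#' `baseline * (1 + onset_floor)`, because a 3-frame MAD estimate can
#' collapse to near zero by chance and would then call onsets on pure
#' measurement noise.
#'
#' @param foxo_hi,foxo_lo Enter/exit thresholds on the nuclear fraction,
#'   `0 < foxo_lo <= foxo_hi < 1`.
#' @param persistence Integer frames (>= 1) both crossings must persist.
#' @param p53_mad_mult MAD multiplier of the onset rule.
#' @param onset_run Integer frames the onset exceedance must persist.
#' @param onset_floor Minimum relative rise above baseline for an onset.
#' @return An `activation_thresholds` object.
#' @export
activation_thresholds <- function(foxo_hi = 0.55, foxo_lo = 0.45,
                                  persistence = 2L, p53_mad_mult = 3,
                                  onset_run = 3L, onset_floor = 0.15) {
  if (!(foxo_lo > 0 && foxo_lo <= foxo_hi && foxo_hi < 1)) {
    stop("need 0 < foxo_lo <= foxo_hi < 1", call. = FALSE)
  }
  if (persistence < 1 || persistence != round(persistence)) {
    stop("`persistence` must be a positive integer", call. = FALSE)
  }
  if (onset_run < 1 || onset_run != round(onset_run)) {
    stop("`onset_run` must be a positive integer", call. = FALSE)
  }
  if (onset_floor < 0) stop("`onset_floor` must be >= 0", call. = FALSE)
  structure(list(foxo_hi = foxo_hi, foxo_lo = foxo_lo,
                 persistence = as.integer(persistence),
                 p53_mad_mult = p53_mad_mult,
                 onset_run = as.integer(onset_run),
                 onset_floor = onset_floor),
            class = "activation_thresholds")
}

#' Centered running-median smoother
#'
#' Running median with an odd window; edges use shrunken (still centered,
#' truncated) windows, so a constant series is unchanged and a monotone
#' series stays monotone. Missing values stay missing and do not contribute
#' to neighboring windows.
#'
#' @param x Numeric series.
#' @param width Odd window width (default 3).
#' @return Smoothed series, same length as `x`.
#' @export
smooth_trace <- function(x, width = 3L) {
  if (width %% 2 == 0) stop("`width` must be odd", call. = FALSE)
  n <- length(x)
  if (n == 0) return(x)
  half <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- stats::median(x[lo:hi], na.rm = TRUE)
  }
  out
}

# First index at which `runs` of TRUE of length >= len starts at/after `from`;
# NA treated as FALSE. Returns NA_integer_ if none.
first_run_start <- function(flag, len, from = 1L) {
  flag[is.na(flag)] <- FALSE
  n <- length(flag)
  run <- 0L
  for (i in seq(from, length.out = max(0L, n - from + 1L))) {
    if (flag[i]) {
      run <- run + 1L
      if (run >= len) return(i - len + 1L)
    } else run <- 0L
  }
  NA_integer_
}

#' Detect FOXO1 nuclear residence episodes
#'
#' Hysteresis episode detection on a (smoothed) nuclear-fraction series.
#' Entry is the first frame of at least `persistence` consecutive frames at
#' or above `foxo_hi`; the episode closes at the first frame of at least
#' `persistence` consecutive frames at or below `foxo_lo`. An episode still
#' open at the last observed (pre-death) frame has `exit_time = NA`.
#' `nuclear_duration` sums `exit - entry` over episodes, counting open
#' episodes up to the last observed frame. The primary episode is the
#' longest.
#'
#' @param foxo Numeric nuclear-fraction series (smoothed; `NA` = missing).
#' @param t_h Time grid in hours.
#' @param thresholds An [activation_thresholds()] object.
#' @return A `foxo_episodes` list: `episodes` (data frame with `entry_time`,
#'   `exit_time`), `nuclear_duration`, `primary` (index or NA),
#'   `all_missing` flag.
#' @export
detect_foxo1_episodes <- function(foxo, t_h,
                                  thresholds = activation_thresholds()) {
  stopifnot(length(foxo) == length(t_h),
            inherits(thresholds, "activation_thresholds"))
  valid <- which(!is.na(foxo))
  if (!length(valid)) {
    return(structure(list(episodes = data.frame(entry_time = numeric(0),
                                                exit_time = numeric(0)),
                          nuclear_duration = 0, primary = NA_integer_,
                          all_missing = TRUE),
                     class = "foxo_episodes"))
  }
  last_obs <- max(valid)
  hi_flag <- foxo >= thresholds$foxo_hi
  lo_flag <- foxo <= thresholds$foxo_lo
  pers <- thresholds$persistence
  entries <- numeric(0); exits <- numeric(0)
  pos <- 1L
  repeat {
    e <- first_run_start(hi_flag, pers, pos)
    if (is.na(e) || e > last_obs) break
    x <- first_run_start(lo_flag, pers, e + 1L)
    entries <- c(entries, t_h[e])
    if (is.na(x) || x > last_obs) {
      exits <- c(exits, NA_real_)
      break
    }
    exits <- c(exits, t_h[x])
    pos <- x + 1L
  }
  ep <- data.frame(entry_time = entries, exit_time = exits)
  closed_end <- ifelse(is.na(ep$exit_time), t_h[last_obs], ep$exit_time)
  durations <- closed_end - ep$entry_time
  structure(list(episodes = ep,
                 nuclear_duration = sum(durations),
                 primary = if (nrow(ep)) which.max(durations) else NA_integer_,
                 all_missing = FALSE),
            class = "foxo_episodes")
}

#' p53 accumulation rate series
#'
#' Derivative of the p53 series in AU per hour: central differences
#' `(x[i+1] - x[i-1]) / (2 dt)` in the interior, one-sided differences at the
#' ends. Any difference touching a missing sample is missing; fewer than 3
#' valid points yields an all-missing series.
#'
#' @param p53 Numeric series on a uniform grid.
#' @param dt_h Grid spacing in hours.
#' @return Numeric rate series, same length.
#' @export
p53_rate <- function(p53, dt_h) {
  n <- length(p53)
  out <- rep(NA_real_, n)
  if (sum(!is.na(p53)) < 3 || n < 2) return(out)
  if (n >= 3) {
    i <- 2:(n - 1)
    out[i] <- (p53[i + 1] - p53[i - 1]) / (2 * dt_h)
  }
  out[1] <- (p53[2] - p53[1]) / dt_h
  out[n] <- (p53[n] - p53[n - 1]) / dt_h
  out
}

#' Detect p53 accumulation onset
#'
#' Baseline is the median of the first three observed frames; its dispersion
#' is their median absolute deviation (unscaled). Onset is the first time at
#' or after `after` where the series exceeds
#' `baseline + max(p53_mad_mult * MAD, onset_floor * baseline)` for
#' `onset_run` consecutive frames; absent (`NA`) if that never happens
#' before death/movie end.
#'
#' @param p53 Numeric p53 series (`NA` = missing).
#' @param t_h Time grid in hours.
#' @param thresholds An [activation_thresholds()] object.
#' @param after Earliest admissible onset time in hours.
#' @return A `p53_onset` list: `onset_time` (or `NA`), `baseline`,
#'   `baseline_mad`.
#' @export
detect_p53_onset <- function(p53, t_h,
                             thresholds = activation_thresholds(),
                             after = 0) {
  stopifnot(length(p53) == length(t_h))
  if (length(p53) < 3 || any(is.na(p53[1:3]))) {
    stop("baseline window (first 3 frames) must be observed", call. = FALSE)
  }
  base <- stats::median(p53[1:3])
  base_mad <- stats::median(abs(p53[1:3] - base))
  cut <- base + max(thresholds$p53_mad_mult * base_mad,
                    thresholds$onset_floor * base)
  flag <- p53 > cut & t_h >= after
  idx <- first_run_start(flag, thresholds$onset_run)
  structure(list(onset_time = if (is.na(idx)) NA_real_ else t_h[idx],
                 baseline = base, baseline_mad = base_mad),
            class = "p53_onset")
}

#' Per-cell event table for a trace population
#'
#' Runs smoothing, FOXO1 episode detection and p53 onset detection on every
#' cell of a trace table. FOXO1 is smoothed with a running median
#' (`smooth_width`) before episode detection; onset is detected on the raw
#' p53 series. Events are detected on pre-death samples only.
#'
#' @param traces A `trace_table`.
#' @param thresholds An [activation_thresholds()] object.
#' @param smooth_width Odd running-median width for the FOXO1 channel.
#' @return Data frame with one row per cell: `cell_id`, `n_episodes`,
#'   `entry_time`, `exit_time` (primary episode; `NA` when absent/open),
#'   `nuclear_duration`, `onset_time`, `baseline`, `baseline_mad`,
#'   `death_time`, `died`.
#' @export
detect_events <- function(traces, thresholds = activation_thresholds(),
                          smooth_width = 3L) {
  stopifnot(is.data.frame(traces))
  cells <- unique(traces$cell_id)
  res <- lapply(cells, function(id) {
    tr <- traces[traces$cell_id == id, , drop = FALSE]
    tr <- tr[order(tr$t_h), , drop = FALSE]
    f_s <- smooth_trace(tr$foxo1_nuc_frac, smooth_width)
    ep <- detect_foxo1_episodes(f_s, tr$t_h, thresholds)
    onset <- if (sum(!is.na(tr$p53_nuc)) >= 3 &&
                 !any(is.na(tr$p53_nuc[1:3]))) {
      detect_p53_onset(tr$p53_nuc, tr$t_h, thresholds)
    } else list(onset_time = NA_real_, baseline = NA_real_,
                baseline_mad = NA_real_)
    died <- any(tr$dead)
    death_time <- if (died) min(tr$t_h[tr$dead]) else NA_real_
    prim <- ep$primary
    data.frame(cell_id = id,
               n_episodes = nrow(ep$episodes),
               entry_time = if (!is.na(prim)) ep$episodes$entry_time[prim]
                            else NA_real_,
               exit_time = if (!is.na(prim)) ep$episodes$exit_time[prim]
                           else NA_real_,
               nuclear_duration = ep$nuclear_duration,
               onset_time = onset$onset_time,
               baseline = onset$baseline,
               baseline_mad = onset$baseline_mad,
               death_time = death_time,
               died = died,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
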