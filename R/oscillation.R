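# Windowed autocorrelation of p53 traces with the FOXO1-conditioned window
# rule, oscillation classification, and fate-stratified comparison.

#' Select the autocorrelation window for one cell
#'
#' Window rule: cells that never accumulated FOXO1 in the nucleus use the
#' first 10 h; cells whose (primary) FOXO1 episode exited at time `T` use
#' `[T, T + 10]`. Windows running past the last observed frame are truncated
#' (flag set); cells with an open episode (no exit) are excluded.
#'
#' @param events_row One row of the [detect_events()] table (or a list with
#'   `n_episodes`, `exit_time`, `death_time`).
#' @param t_end Last nominal frame time in hours.
#' @param window_h Window length in hours (default 10).
#' @return A list: `start`, `end` (NA when excluded), `truncated`,
#'   `excluded`.
#' @export
select_acf_window <- function(events_row, t_end, window_h = 10) {
  n_ep <- events_row$n_episodes
  exit_t <- events_row$exit_time
  death_t <- if (!is.null(events_row$death_time)) events_row$death_time
             else NA_real_
  last_obs <- if (!is.na(death_t)) death_t else t_end
  if (is.na(n_ep) || n_ep == 0) {
    start <- 0
  } else if (is.na(exit_t)) {
    return(list(start = NA_real_, end = NA_real_, truncated = FALSE,
                excluded = TRUE))
  } else {
    start <- exit_t
  }
  end <- start + window_h
  truncated <- end > last_obs
  if (truncated) end <- last_obs
  list(start = start, end = end, truncated = truncated, excluded = FALSE)
}

#' Sample autocorrelation of a window
#'
#' Standard sample ACF with mean removal over the window:
#' `r(k) = sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`,
#' so `r(0) = 1`. An optional linear detrend (default on in the pipeline)
#' removes a least-squares line before correlating, so a monotone
#' post-exit p53 rise is not read as long-lag structure.
#'
#' @param x Numeric series (no missing values).
#' @param max_lag_frames Maximum lag in frames.
#' @param detrend Remove a least-squares linear trend first.
#' @return Numeric vector `r[0..max_lag]`; all-`NA` with a warning when the
#'   series is constant (zero variance).
#' @export
trace_acf <- function(x, max_lag_frames, detrend = FALSE) {
  n <- length(x)
  if (n < 8) stop("need at least 8 valid frames", call. = FALSE)
  if (any(is.na(x))) stop("`x` must not contain missing values",
                          call. = FALSE)
  if (detrend) {
    tt <- seq_len(n)
    x <- stats::residuals(stats::lm.fit(cbind(1, tt), x))
  }
  x <- x - mean(x)
  denom <- sum(x^2)
  max_lag_frames <- min(max_lag_frames, n - 1L)
  if (denom <= .Machine$double.eps * n) {
    warning("zero-variance window: autocorrelation undefined")
    return(rep(NA_real_, max_lag_frames + 1L))
  }
  vapply(0:max_lag_frames, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / denom
  }, numeric(1))
}

#' Windowed ACF of one cell's p53 trace
#'
#' Applies the window rule, extracts the observed (pre-death) p53 samples in
#' the window, and computes the sample ACF. Cells excluded by the window rule
#' or with fewer than 8 valid in-window frames return `NULL`.
#'
#' @param trace One cell's rows of a `trace_table` (sorted by time).
#' @param events_row Matching row of the [detect_events()] table.
#' @param max_lag_h Maximum lag in hours (default 8).
#' @param detrend Linear detrend before correlating (default `TRUE`).
#' @param window_h ACF window length in hours.
#' @return An `acf_result` list (`window`, `lags`, `r`, `n_points`,
#'   `truncated`, `oscillation_score`, `is_oscillatory` are filled by
#'   [classify_oscillation()]), or `NULL` when the cell is excluded.
#' @export
cell_acf <- function(trace, events_row, max_lag_h = 8, detrend = TRUE,
                     window_h = 10) {
  trace <- trace[order(trace$t_h), , drop = FALSE]
  t_end <- max(trace$t_h)
  w <- select_acf_window(events_row, t_end, window_h)
  if (w$excluded) return(NULL)
  dt <- trace$t_h[2] - trace$t_h[1]
  sel <- trace$t_h >= w$start - 1e-9 & trace$t_h <= w$end + 1e-9 &
    !is.na(trace$p53_nuc)
  x <- trace$p53_nuc[sel]
  if (length(x) < 8) return(NULL)
  max_lag_frames <- round(max_lag_h / dt)
  r <- trace_acf(x, max_lag_frames, detrend = detrend)
  structure(list(window = c(w$start, w$end),
                 lags = (seq_along(r) - 1L) * dt,
                 r = r, n_points = length(x), truncated = w$truncated),
            class = "acf_result")
}

#' Classify a windowed ACF as oscillatory
#'
#' The oscillation score is the maximum autocorrelation over the lag band
#' (default 3--8 h, the p53 pulsing band); a window is oscillatory when the
#' score exceeds `max(r_min, 2/sqrt(n_points))`. Windows whose available
#' lags end below the band's upper edge are scored over the available band
#' and flagged.
#'
#' @param acf_result An `acf_result` from [cell_acf()].
#' @param lag_band Numeric `c(lo, hi)` band in hours.
#' @param r_min Minimum score (default 0.2).
#' @return The `acf_result` with `oscillation_score`, `is_oscillatory` and
#'   `band_truncated` filled in (score `NA` for zero-variance windows).
#' @export
classify_oscillation <- function(acf_result, lag_band = c(3, 8),
                                 r_min = 0.2) {
  stopifnot(inherits(acf_result, "acf_result"))
  in_band <- acf_result$lags >= lag_band[1] & acf_result$lags <= lag_band[2]
  band_truncated <- max(acf_result$lags) < lag_band[2]
  r_band <- acf_result$r[in_band]
  score <- if (length(r_band) && any(!is.na(r_band))) {
    max(r_band, na.rm = TRUE)
  } else NA_real_
  acf_result$oscillation_score <- score
  acf_result$band_truncated <- band_truncated
  acf_result$is_oscillatory <- !is.na(score) &&
    score > max(r_min, 2 / sqrt(acf_result$n_points))
  acf_result
}

#' Fate-stratified autocorrelation comparison
#'
#' Computes each cell's windowed p53 ACF (window rule conditioned on its
#' FOXO1 events), classifies oscillation, and summarizes the ACF curves of
#' dying versus surviving cells with per-lag median and MAD. Cells dying
#' before accruing 8 valid in-window frames are excluded and counted.
#'
#' @param traces A `trace_table`.
#' @param events Event table from [detect_events()] (must carry `died`).
#' @param n_min Minimum cells per group; a smaller group is reported absent.
#' @param max_lag_h,detrend,window_h,lag_band,r_min Passed to [cell_acf()] /
#'   [classify_oscillation()].
#' @return A list with per-group (`dying`, `surviving`) entries: `n`,
#'   `lags`, `median`, `mad`, `scores`, `osc_fraction` (NULL when below
#'   `n_min`); plus `n_excluded`.
#' @export
compare_fates <- function(traces, events, n_min = 5L, max_lag_h = 8,
                          detrend = TRUE, window_h = 10,
                          lag_band = c(3, 8), r_min = 0.2) {
  dtg <- sort(unique(traces$t_h))
  dt <- dtg[2] - dtg[1]
  n_lags <- round(max_lag_h / dt) + 1L
  lags <- (seq_len(n_lags) - 1L) * dt
  res <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    tr <- traces[traces$cell_id == events$cell_id[i], , drop = FALSE]
    a <- cell_acf(tr, events[i, ], max_lag_h = max_lag_h, detrend = detrend,
                  window_h = window_h)
    if (!is.null(a)) res[[i]] <- classify_oscillation(a, lag_band, r_min)
  }
  have <- !vapply(res, is.null, logical(1))
  n_excluded <- sum(!have)
  summarize_group <- function(sel) {
    idx <- which(have & sel)
    if (length(idx) < n_min) return(NULL)
    R <- matrix(NA_real_, length(idx), n_lags)
    for (j in seq_along(idx)) {
      r <- res[[idx[j]]]$r
      R[j, seq_len(min(n_lags, length(r)))] <- r[seq_len(min(n_lags,
                                                             length(r)))]
    }
    scores <- vapply(idx, function(i) {
      s <- res[[i]]$oscillation_score
      if (is.null(s)) NA_real_ else s
    }, numeric(1))
    osc <- vapply(idx, function(i) isTRUE(res[[i]]$is_oscillatory),
                  logical(1))
    list(n = length(idx), lags = lags,
         median = apply(R, 2, stats::median, na.rm = TRUE),
         mad = apply(R, 2, function(col) {
           stats::median(abs(col - stats::median(col, na.rm = TRUE)),
                         na.rm = TRUE)
         }),
         scores = scores, osc_fraction = mean(osc))
  }
  dying <- summarize_group(events$died)
  surviving <- summarize_group(!events$died)
  if (is.null(dying) && any(events$died & have)) {
    warning("dying group below n_min; reported absent")
  }
  if (is.null(surviving) && any(!events$died & have)) {
    warning("surviving group below n_min; reported absent")
  }
  list(dying = dying, surviving = surviving, n_excluded = n_excluded)
}
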