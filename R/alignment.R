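# Event-aligned trace aggregation and heat-map sort orders.

#' Heat-map sort order
#'
#' Row order for single-cell heat maps. `key = "duration"` sorts by FOXO1
#' nuclear residence duration, longest first; `key = "entry_time"` sorts by
#' FOXO1 entry time, earliest first. Cells without an episode sort last;
#' ties (and the no-episode block) keep the original cell order (stable).
#'
#' @param events Event table from [detect_events()].
#' @param key `"duration"` or `"entry_time"`.
#' @return Integer permutation of `seq_len(nrow(events))`.
#' @export
sort_order <- function(events, key = c("duration", "entry_time")) {
  key <- match.arg(key)
  has_ep <- events$n_episodes > 0
  val <- if (key == "duration") {
    ifelse(has_ep, -events$nuclear_duration, Inf)
  } else {
    ifelse(has_ep & !is.na(events$entry_time), events$entry_time, Inf)
  }
  order(val, seq_len(nrow(events)))
}

#' Event-aligned trace ensemble
#'
#' Re-indexes each cell's channel to lag = t - anchor time (anchor is the
#' primary episode's entry or exit as detected), then summarizes per lag with
#' the median and median absolute deviation over contributing cells. Cells
#' lacking the anchor event are excluded and counted. Lags with fewer than
#' `n_min` contributing cells keep their summaries but are flagged.
#'
#' @param traces A `trace_table`.
#' @param events Event table from [detect_events()].
#' @param anchor `"foxo_exit"` or `"foxo_entry"`.
#' @param channel Column to align (`"p53_nuc"` or `"foxo1_nuc_frac"`), or
#'   `"p53_rate"` for the derivative series.
#' @param window Half-width of the lag window in hours (default 10).
#' @param n_min Minimum cells per lag for an unflagged summary.
#' @return An `aligned_ensemble` list: `lag` (hours), `median`, `mad`, `n`,
#'   `flagged` (n < n_min), `matrix` (cells x lags), `n_cells`,
#'   `n_excluded`.
#' @export
align_traces <- function(traces, events, anchor = c("foxo_exit", "foxo_entry"),
                         channel = "p53_nuc", window = 10, n_min = 5L) {
  anchor <- match.arg(anchor)
  anchor_time <- if (anchor == "foxo_exit") events$exit_time
                 else events$entry_time
  keep <- !is.na(anchor_time)
  n_excluded <- sum(!keep)
  tg <- sort(unique(traces$t_h))
  dt <- if (length(tg) > 1) tg[2] - tg[1] else 1
  lag <- seq(-window, window, by = dt)
  ids <- events$cell_id[keep]
  if (!length(ids)) {
    warning("no cells with the requested anchor event")
    return(structure(list(lag = lag,
                          median = rep(NA_real_, length(lag)),
                          mad = rep(NA_real_, length(lag)),
                          n = rep(0L, length(lag)),
                          flagged = rep(TRUE, length(lag)),
                          matrix = matrix(NA_real_, 0, length(lag)),
                          n_cells = 0L, n_excluded = n_excluded),
                     class = "aligned_ensemble"))
  }
  at <- anchor_time[keep]
  M <- matrix(NA_real_, length(ids), length(lag),
              dimnames = list(ids, NULL))
  for (j in seq_along(ids)) {
    tr <- traces[traces$cell_id == ids[j], , drop = FALSE]
    tr <- tr[order(tr$t_h), , drop = FALSE]
    vals <- if (channel == "p53_rate") p53_rate(tr$p53_nuc, dt)
            else tr[[channel]]
    cell_lag <- tr$t_h - at[j]
    idx <- round((cell_lag - lag[1]) / dt) + 1L
    ok <- idx >= 1L & idx <= length(lag)
    M[j, idx[ok]] <- vals[ok]
  }
  n_lag <- colSums(!is.na(M))
  med <- apply(M, 2, function(col) {
    if (any(!is.na(col))) stats::median(col, na.rm = TRUE) else NA_real_
  })
  madv <- apply(M, 2, function(col) {
    if (any(!is.na(col))) stats::median(abs(col - stats::median(col,
                                                               na.rm = TRUE)),
                                        na.rm = TRUE)
    else NA_real_
  })
  structure(list(lag = lag, median = med, mad = madv, n = n_lag,
                 flagged = n_lag < n_min, matrix = M,
                 n_cells = length(ids), n_excluded = n_excluded),
            class = "aligned_ensemble")
}

#' Exit-to-onset lag statistic
#'
#' Per-cell lag between p53 accumulation onset and FOXO1 nuclear exit
#' (onset - exit, hours; negative lags permitted), over cells with both
#' events, with the cohort median and MAD.
#'
#' @param events Event table from [detect_events()].
#' @return A list: `per_cell` (data frame `cell_id`, `lag_h`),
#'   `median` and `mad` (NA when no qualifying cells), `n`.
#' @export
lag_statistic <- function(events) {
  ok <- !is.na(events$exit_time) & !is.na(events$onset_time)
  lag_h <- events$onset_time[ok] - events$exit_time[ok]
  list(per_cell = data.frame(cell_id = events$cell_id[ok], lag_h = lag_h,
                             stringsAsFactors = FALSE),
       median = if (length(lag_h)) stats::median(lag_h) else NA_real_,
       mad = if (length(lag_h)) stats::median(abs(lag_h -
                                                    stats::median(lag_h)))
             else NA_real_,
       n = sum(ok))
}
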