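# Fixed-timepoint quadrant classification and dose-response summaries.

#' Estimate activation thresholds from an untreated control snapshot
#'
#' Reproducible stand-in for manually drawn gating lines: the activation cut
#' for each channel is a high quantile (default the 95th percentile) of the
#' untreated control distribution, so the per-channel false-positive rate on
#' control-like cells is about `1 - quantile`.
#'
#' @param control_snapshot A `snapshot_table` of untreated cells (>= 50).
#' @param quantile Control quantile in (0.5, 1).
#' @param level_col,frac_col Channel columns: the level-read TF (log scale)
#'   and the shuttling TF (nuclear fraction). Defaults match the p53/FOXO1
#'   pair; any (level, shuttling) TF pair may be supplied.
#' @return A `quadrant_thresholds` list: `log_p53_cut`, `foxo_frac_cut`,
#'   `source`, `quantile`.
#' @export
estimate_thresholds <- function(control_snapshot, quantile = 0.95,
                                level_col = "log_p53",
                                frac_col = "foxo1_nuc_frac") {
  stopifnot(is.data.frame(control_snapshot))
  if (nrow(control_snapshot) < 50) {
    stop("need at least 50 control cells to estimate thresholds",
         call. = FALSE)
  }
  if (quantile <= 0.5 || quantile >= 1) {
    stop("`quantile` must be in (0.5, 1)", call. = FALSE)
  }
  cuts <- c(stats::quantile(control_snapshot[[level_col]], quantile,
                            na.rm = TRUE, names = FALSE, type = 7),
            stats::quantile(control_snapshot[[frac_col]], quantile,
                            na.rm = TRUE, names = FALSE, type = 7))
  if (any(!is.finite(cuts))) stop("non-finite threshold estimate",
                                  call. = FALSE)
  structure(list(log_p53_cut = cuts[1], foxo_frac_cut = cuts[2],
                 source = "control_quantile", quantile = quantile),
            class = "quadrant_thresholds")
}

#' Fixed quadrant thresholds
#'
#' @param log_p53_cut,foxo_frac_cut Finite cut values.
#' @return A `quadrant_thresholds` list with `source = "fixed"`.
#' @export
fixed_thresholds <- function(log_p53_cut, foxo_frac_cut) {
  if (!is.finite(log_p53_cut) || !is.finite(foxo_frac_cut)) {
    stop("thresholds must be finite", call. = FALSE)
  }
  structure(list(log_p53_cut = log_p53_cut, foxo_frac_cut = foxo_frac_cut,
                 source = "fixed", quantile = NA_real_),
            class = "quadrant_thresholds")
}

#' Quadrant classification of a snapshot
#'
#' Labels every cell by strict threshold exceedance: `both` when both
#' channels exceed their cuts, `foxo1_only` / `p53_only` when exactly one
#' does, `neither` otherwise, and summarizes label fractions per dose.
#'
#' @param snapshot A `snapshot_table`.
#' @param thresholds A `quadrant_thresholds` object.
#' @param level_col,frac_col Channel columns (see [estimate_thresholds()]).
#' @return A list: `cells` (snapshot with a `label` column) and `summary`
#'   (per-dose fractions `both`, `foxo1_only`, `p53_only`, `neither` and
#'   `n`; fractions sum to 1 per dose).
#' @export
quadrant_classify <- function(snapshot, thresholds,
                              level_col = "log_p53",
                              frac_col = "foxo1_nuc_frac") {
  stopifnot(inherits(thresholds, "quadrant_thresholds"))
  p_act <- snapshot[[level_col]] > thresholds$log_p53_cut
  f_act <- snapshot[[frac_col]] > thresholds$foxo_frac_cut
  label <- ifelse(p_act & f_act, "both",
                  ifelse(f_act, "foxo1_only",
                         ifelse(p_act, "p53_only", "neither")))
  cells <- snapshot
  cells$label <- label
  doses <- sort(unique(snapshot$dose))
  summary <- do.call(rbind, lapply(doses, function(d) {
    lab <- label[snapshot$dose == d]
    n <- length(lab)
    data.frame(dose = d,
               both = mean(lab == "both"),
               foxo1_only = mean(lab == "foxo1_only"),
               p53_only = mean(lab == "p53_only"),
               neither = mean(lab == "neither"),
               n = n)
  }))
  list(cells = cells, summary = summary)
}

#' Tidy dose-response table and mutual-exclusivity statistic
#'
#' Long-format table (one row per dose x label) from a quadrant summary,
#' plus the mutual-exclusivity statistic: the maximum both-active fraction
#' over doses. Doses with zero cells are omitted with a warning.
#'
#' @param summary The `summary` component of [quadrant_classify()].
#' @return A list: `table` (columns `dose`, `label`, `fraction`, `n`) and
#'   `max_both_fraction`.
#' @export
dose_response_table <- function(summary) {
  stopifnot(is.data.frame(summary))
  empty <- summary$n == 0
  if (any(empty)) {
    warning("omitting dose group(s) with zero cells: ",
            paste(summary$dose[empty], collapse = ", "))
    summary <- summary[!empty, , drop = FALSE]
  }
  labels <- c("both", "foxo1_only", "p53_only", "neither")
  tab <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    data.frame(dose = summary$dose[i], label = labels,
               fraction = as.numeric(summary[i, labels]),
               n = summary$n[i], stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab,
       max_both_fraction = if (nrow(summary)) max(summary$both) else NA_real_)
}
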