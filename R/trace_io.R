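# Delimited-table readers/writers for trace and snapshot data.
# Layout is tidy/long: one row per cell x timepoint, missing samples written
# as empty fields, floats at 6 significant digits.

TRACE_COLUMNS <- c("cell_id", "mode", "dose", "perturbation", "t_h",
                   "foxo1_nuc_frac", "p53_nuc", "dead")
SNAPSHOT_COLUMNS <- c("cell_id", "mode", "dose", "perturbation", "t_fix",
                      "foxo1_nuc_frac", "log_p53")

fmt6 <- function(x) {
  out <- ifelse(is.na(x), "", formatC(signif(x, 6), format = "g",
                                      digits = 6))
  out
}

#' Write a trace table to CSV
#'
#' Long-format UTF-8 CSV with header
#' `cell_id,mode,dose,perturbation,t_h,foxo1_nuc_frac,p53_nuc,dead`;
#' missing samples (post-death frames) are empty fields, floats carry six
#' significant digits.
#'
#' @param table A `trace_table` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(TRACE_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("trace table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(cell_id = table$cell_id, mode = table$mode,
                    dose = fmt6(table$dose), perturbation = table$perturbation,
                    t_h = fmt6(table$t_h),
                    foxo1_nuc_frac = fmt6(table$foxo1_nuc_frac),
                    p53_nuc = fmt6(table$p53_nuc),
                    dead = ifelse(table$dead, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trace table from CSV
#'
#' Parses and validates a long-format trace CSV (see [write_traces()] for the
#' schema). Validation failures (missing column, nuclear fraction outside
#' \[0, 1\], non-uniform grid, post-death samples present, duplicated rows)
#' raise an error naming the offending cell and time.
#'
#' @param path CSV file path.
#' @param validate If `TRUE` (default), run [validate_traces()] and fail on
#'   any invalid cell.
#' @return A `trace_table` data frame.
#' @export
read_traces <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = "")
  missing_cols <- setdiff(TRACE_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("schema validation: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, TRACE_COLUMNS]
  if (nrow(tab) == 0) {
    tab$dead <- logical(0)
    class(tab) <- c("trace_table", "data.frame")
    return(tab)
  }
  tab$dose <- as.numeric(tab$dose)
  tab$t_h <- as.numeric(tab$t_h)
  tab$foxo1_nuc_frac <- as.numeric(tab$foxo1_nuc_frac)
  tab$p53_nuc <- as.numeric(tab$p53_nuc)
  tab$dead <- as.logical(tab$dead)
  class(tab) <- c("trace_table", "data.frame")
  if (validate) {
    rep <- validate_traces(tab)
    if (any(!rep$pass)) {
      bad <- rep[!rep$pass, , drop = FALSE]
      stop(sprintf("schema validation: cell %s failed: %s",
                   bad$cell_id[1], bad$reason[1]), call. = FALSE)
    }
  }
  tab
}

#' Validate a trace table
#'
#' Report-only per-cell checks: uniform strictly-increasing time grid,
#' channels within range (`foxo1_nuc_frac` in \[0, 1\], `p53_nuc >= 0`),
#' no duplicated `(cell_id, t_h)` rows, and death-truncation consistency
#' (every sample flagged `dead` is missing, and dead frames form a suffix of
#' the trace).
#'
#' @param table A trace table.
#' @return Data frame with columns `cell_id`, `pass`, `reason`.
#' @export
validate_traces <- function(table) {
  stopifnot(is.data.frame(table))
  cells <- unique(table$cell_id)
  res <- lapply(cells, function(id) {
    tr <- table[table$cell_id == id, , drop = FALSE]
    tr <- tr[order(tr$t_h), , drop = FALSE]
    reasons <- character(0)
    if (anyDuplicated(tr$t_h)) {
      reasons <- c(reasons, sprintf("duplicated (cell_id, t) row at t=%g h",
                                    tr$t_h[duplicated(tr$t_h)][1]))
    } else if (nrow(tr) > 1) {
      d <- diff(tr$t_h)
      # tolerance accommodates 6-significant-digit CSV times: the absolute
      # rounding error grows with t, so successive diffs can wobble by
      # ~1e-5 * max(t)
      tol <- max(1e-9, 2e-5 * max(abs(tr$t_h)))
      if (any(d <= 0) || max(abs(d - d[1])) > tol) {
        reasons <- c(reasons, "non-uniform time grid")
      }
    }
    f <- tr$foxo1_nuc_frac
    bad_f <- which(!is.na(f) & (f < 0 | f > 1))
    if (length(bad_f)) {
      reasons <- c(reasons,
                   sprintf("foxo1_nuc_frac outside [0,1] at t=%g h",
                           tr$t_h[bad_f[1]]))
    }
    bad_p <- which(!is.na(tr$p53_nuc) & tr$p53_nuc < 0)
    if (length(bad_p)) {
      reasons <- c(reasons, sprintf("negative p53_nuc at t=%g h",
                                    tr$t_h[bad_p[1]]))
    }
    if (any(tr$dead, na.rm = TRUE)) {
      first_dead <- which(tr$dead)[1]
      if (!all(tr$dead[first_dead:nrow(tr)])) {
        reasons <- c(reasons, "dead frames are not a suffix of the trace")
      }
      if (any(!is.na(tr$foxo1_nuc_frac[tr$dead])) ||
          any(!is.na(tr$p53_nuc[tr$dead]))) {
        reasons <- c(reasons, "post-death samples present")
      }
    }
    data.frame(cell_id = id, pass = length(reasons) == 0,
               reason = if (length(reasons)) paste(reasons, collapse = "; ")
                        else "", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Write / read snapshot tables
#'
#' Fixed-timepoint snapshot CSV with header
#' `cell_id,mode,dose,perturbation,t_fix,foxo1_nuc_frac,log_p53`.
#'
#' @param table A `snapshot_table` data frame.
#' @param path CSV file path.
#' @return `write_snapshot()`: `path` invisibly; `read_snapshot()`: a
#'   `snapshot_table`.
#' @export
write_snapshot <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(SNAPSHOT_COLUMNS, names(table))
  if (length(missing_cols)) {
    stop("snapshot table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(cell_id = table$cell_id, mode = table$mode,
                    dose = fmt6(table$dose), perturbation = table$perturbation,
                    t_fix = fmt6(table$t_fix),
                    foxo1_nuc_frac = fmt6(table$foxo1_nuc_frac),
                    log_p53 = fmt6(table$log_p53), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(SNAPSHOT_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("schema validation: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- tab[, SNAPSHOT_COLUMNS]
  for (nm in c("dose", "t_fix", "foxo1_nuc_frac", "log_p53")) {
    tab[[nm]] <- as.numeric(tab[[nm]])
  }
  bad <- which(!is.na(tab$foxo1_nuc_frac) &
                 (tab$foxo1_nuc_frac < 0 | tab$foxo1_nuc_frac > 1))
  if (length(bad)) {
    stop(sprintf("schema validation: cell %s foxo1_nuc_frac outside [0,1]",
                 tab$cell_id[bad[1]]), call. = FALSE)
  }
  class(tab) <- c("snapshot_table", "data.frame")
  tab
}
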