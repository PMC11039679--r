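# Sort orders, aligned ensembles, equivariance, and the lag statistic.

events_row <- function(cell_id, n_ep, entry, exit, dur, onset = NA_real_) {
  data.frame(cell_id = cell_id, n_episodes = n_ep, entry_time = entry,
             exit_time = exit, nuclear_duration = dur, onset_time = onset,
             baseline = 100, baseline_mad = 1, death_time = NA_real_,
             died = FALSE, stringsAsFactors = FALSE)
}

test_that("sort orders follow duration-descending / entry-ascending rules", {
  ev <- rbind(events_row("a", 1, 1, 6, 5), events_row("b", 1, 1, 3, 2),
              events_row("c", 1, 1, 10, 9))
  expect_equal(sort_order(ev, "duration"), c(3, 1, 2))

  # stable tie-break keeps original order
  ev_tie <- rbind(events_row("a", 1, 1, 4, 3), events_row("b", 1, 2, 5, 3),
                  events_row("c", 1, 3, 6, 3))
  expect_equal(sort_order(ev_tie, "duration"), 1:3)

  # absent entries last
  ev_e <- rbind(events_row("a", 0, NA, NA, 0), events_row("b", 1, 1, 3, 2),
                events_row("c", 1, 0.5, 3, 2.5))
  expect_equal(sort_order(ev_e, "entry_time"), c(3, 2, 1))
})

make_shifted_traces <- function(shifts, curve, dt = 1 / 3) {
  n <- length(curve)
  rows <- lapply(seq_along(shifts), function(i) {
    k <- round(shifts[i] / dt)
    vals <- c(rep(NA_real_, k), curve)[1:n]
    data.frame(cell_id = sprintf("s%02d", i), mode = "bolus", dose = 100,
               perturbation = "control",
               t_h = seq(0, by = dt, length.out = n),
               foxo1_nuc_frac = 0.5, p53_nuc = vals, dead = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("aligning shifted copies of one curve collapses them exactly", {
  dt <- 1 / 3
  curve <- 100 + 10 * sin(seq(0, 4 * pi, length.out = 61))
  shifts <- c(1, 2, 3)
  traces <- make_shifted_traces(shifts, curve)
  ev <- rbind(events_row("s01", 1, 1, 1 + 1, 1),
              events_row("s02", 1, 2, 2 + 1, 1),
              events_row("s03", 1, 3, 3 + 1, 1))
  ens <- align_traces(traces, ev, anchor = "foxo_entry",
                      channel = "p53_nuc", window = 6, n_min = 3)
  full <- which(ens$n == 3)
  expect_true(length(full) > 10)
  expect_true(all(ens$mad[full] == 0))
  # median equals the common curve re-indexed to lag 0 at the anchor
  lag0 <- which(abs(ens$lag) < 1e-9)
  expect_equal(ens$median[lag0], curve[1 + round(0 / dt)])
})

test_that("median and MAD at each lag match direct recomputation", {
  set.seed(12)
  cfg <- simulation_config(exposure_condition("bolus", 100), n_cells = 30,
                           seed = 2)
  tr <- simulate_population(cfg)
  ev <- detect_events(tr)
  ens <- align_traces(tr, ev, anchor = "foxo_exit", channel = "p53_nuc")
  for (j in seq_along(ens$lag)) {
    col <- ens$matrix[, j]
    if (all(is.na(col))) {
      expect_true(is.na(ens$median[j]))
    } else {
      expect_equal(ens$median[j], median(col, na.rm = TRUE))
      expect_equal(ens$mad[j],
                   median(abs(col - median(col, na.rm = TRUE)), na.rm = TRUE))
    }
  }
  expect_equal(ens$n_cells + ens$n_excluded, nrow(ev))
})

test_that("two traces at base +/- c give median base and MAD c", {
  dt <- 1 / 3
  n <- 31
  t_h <- seq(0, by = dt, length.out = n)
  mk <- function(id, val) {
    data.frame(cell_id = id, mode = "bolus", dose = 80,
               perturbation = "control", t_h = t_h, foxo1_nuc_frac = 0.5,
               p53_nuc = val, dead = FALSE, stringsAsFactors = FALSE)
  }
  traces <- rbind(mk("a", 120), mk("b", 80))
  ev <- rbind(events_row("a", 1, 2, 4, 2), events_row("b", 1, 2, 4, 2))
  ens <- align_traces(traces, ev, anchor = "foxo_exit", window = 4,
                      n_min = 2)
  full <- ens$n == 2
  expect_true(all(ens$median[full] == 100))
  expect_true(all(ens$mad[full] == 20))
})

test_that("alignment is equivariant under joint time shifts", {
  dt <- 1 / 3
  curve <- 100 + cumsum(runif(40))
  tr1 <- make_shifted_traces(0, curve)
  tr2 <- make_shifted_traces(2, curve)
  ev1 <- events_row("s01", 1, 3, 5, 2)
  ev2 <- events_row("s01", 1, 5, 7, 2)
  e1 <- align_traces(tr1, ev1, anchor = "foxo_exit", window = 5, n_min = 1)
  e2 <- align_traces(tr2, ev2, anchor = "foxo_exit", window = 5, n_min = 1)
  both <- !is.na(e1$median) & !is.na(e2$median)
  expect_true(any(both))
  expect_equal(e1$median[both], e2$median[both])
})

test_that("lag statistic reports per-cell and cohort values", {
  ev <- rbind(events_row("a", 1, 2, 6, 4, onset = 7),
              events_row("b", 1, 2, 6, 4, onset = 5.5),
              events_row("c", 0, NA, NA, 0, onset = 4))
  ls_ <- lag_statistic(ev)
  expect_equal(ls_$n, 2)
  expect_equal(sort(ls_$per_cell$lag_h), c(-0.5, 1))
  expect_equal(ls_$median, 0.25)

  empty <- lag_statistic(events_row("a", 0, NA, NA, 0))
  expect_true(is.na(empty$median))
  expect_equal(empty$n, 0)
})

test_that("ensemble with zero anchored cells warns and is empty", {
  tr <- make_trace_table(2, 8)
  ev <- rbind(events_row("c001", 0, NA, NA, 0),
              events_row("c002", 0, NA, NA, 0))
  expect_warning(ens <- align_traces(tr, ev, anchor = "foxo_exit"),
                 "no cells")
  expect_equal(ens$n_cells, 0)
})
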