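# ACF window rule, sample autocorrelation vs brute force, oscillation
# classification, and fate-stratified comparison.

test_that("window rule follows the FOXO1-conditioned specification", {
  no_ep <- list(n_episodes = 0, exit_time = NA_real_, death_time = NA_real_)
  w <- select_acf_window(no_ep, t_end = 24)
  expect_equal(c(w$start, w$end), c(0, 10))
  expect_false(w$truncated)

  exited <- list(n_episodes = 1, exit_time = 7, death_time = NA_real_)
  w2 <- select_acf_window(exited, t_end = 24)
  expect_equal(c(w2$start, w2$end), c(7, 17))

  late <- list(n_episodes = 1, exit_time = 20, death_time = NA_real_)
  w3 <- select_acf_window(late, t_end = 24)
  expect_equal(c(w3$start, w3$end), c(20, 24))
  expect_true(w3$truncated)

  open_ep <- list(n_episodes = 1, exit_time = NA_real_,
                  death_time = NA_real_)
  expect_true(select_acf_window(open_ep, t_end = 24)$excluded)

  # death truncates the window
  dying <- list(n_episodes = 1, exit_time = 7, death_time = 12)
  w4 <- select_acf_window(dying, t_end = 24)
  expect_equal(c(w4$start, w4$end), c(7, 12))
  expect_true(w4$truncated)
})

test_that("window rule is a pure function of its inputs (property table)", {
  set.seed(4)
  for (i in 1:100) {
    n_ep <- sample(0:2, 1)
    exit_t <- if (n_ep > 0 && runif(1) < 0.8) runif(1, 0, 23) else NA_real_
    death_t <- if (runif(1) < 0.3) runif(1, 1, 24) else NA_real_
    row <- list(n_episodes = n_ep, exit_time = exit_t, death_time = death_t)
    w <- select_acf_window(row, t_end = 24)
    if (n_ep == 0) {
      expect_equal(w$start, 0)
    } else if (is.na(exit_t)) {
      expect_true(w$excluded)
      next
    } else {
      expect_equal(w$start, exit_t)
    }
    last_obs <- if (!is.na(death_t)) death_t else 24
    expect_equal(w$end, min(w$start + 10, last_obs))
    expect_equal(w$truncated, w$start + 10 > last_obs)
  }
})

test_that("sample ACF equals the brute-force double loop and r(0) = 1", {
  set.seed(55)
  for (i in 1:50) {
    x <- rnorm(sample(10:40, 1), sd = runif(1, 0.5, 3))
    r <- trace_acf(x, max_lag_frames = 8)
    expect_equal(r, bf_acf(x, min(8, length(x) - 1)), tolerance = 1e-12)
    expect_equal(r[1], 1)
    expect_true(all(abs(r) <= 1 + 1e-12))
  }
  expect_error(trace_acf(rnorm(5), 3), "at least 8")
  expect_warning(r0 <- trace_acf(rep(2, 20), 5), "zero-variance")
  expect_true(all(is.na(r0)))
})

test_that("white noise autocorrelation obeys the large-sample bound", {
  set.seed(3)
  x <- rnorm(31)
  r <- trace_acf(x, max_lag_frames = 24)
  frac_inside <- mean(abs(r[-1]) < 2 / sqrt(31))
  expect_gte(frac_inside, 0.9)
})

test_that("a sampled sinusoid peaks at its period in the 3-8 h band", {
  dt <- 1 / 3
  t_h <- seq(0, 10, by = dt)
  x <- sin(2 * pi * t_h / 5)
  r <- trace_acf(x, max_lag_frames = round(8 / dt))
  lags <- (seq_along(r) - 1) * dt
  band <- lags >= 3 & lags <= 8
  peak_lag <- lags[band][which.max(r[band])]
  expect_lte(abs(peak_lag - 5), dt + 1e-9)
})

test_that("classification calls oscillators and rejects monotone ramps", {
  dt <- 1 / 3
  n <- 31
  t_h <- seq(0, by = dt, length.out = n)
  mk_trace <- function(vals) {
    data.frame(cell_id = "x", mode = "bolus", dose = 50,
               perturbation = "control", t_h = t_h, foxo1_nuc_frac = 0.2,
               p53_nuc = vals, dead = FALSE, stringsAsFactors = FALSE)
  }
  ev <- data.frame(cell_id = "x", n_episodes = 0, entry_time = NA_real_,
                   exit_time = NA_real_, nuclear_duration = 0,
                   onset_time = NA_real_, baseline = 100,
                   baseline_mad = 1, death_time = NA_real_, died = FALSE)

  osc <- classify_oscillation(cell_acf(
    mk_trace(100 + 30 * sin(2 * pi * t_h / 5.5)), ev))
  expect_true(osc$is_oscillatory)
  expect_lte(abs(osc$lags[which.max(osc$r[osc$lags >= 3 & osc$lags <= 8])]
                 + 3 - 3), 8)

  set.seed(8)
  ramp <- classify_oscillation(cell_acf(
    mk_trace(100 + 20 * t_h + rnorm(n, 0, 1)), ev))
  expect_false(ramp$is_oscillatory)

  # oscillation call is invariant to positive affine transforms
  a <- classify_oscillation(cell_acf(
    mk_trace(100 + 30 * sin(2 * pi * t_h / 5.5)), ev))
  b <- classify_oscillation(cell_acf(
    mk_trace(40 + 3 * (100 + 30 * sin(2 * pi * t_h / 5.5))), ev))
  expect_equal(a$r, b$r, tolerance = 1e-10)
  expect_equal(a$oscillation_score, b$oscillation_score, tolerance = 1e-10)
})

test_that("fate comparison summarizes groups and handles absent groups", {
  dt <- 1 / 3
  n <- 73
  t_h <- seq(0, by = dt, length.out = n)
  mk <- function(id, vals, died = FALSE) {
    data.frame(cell_id = id, mode = "bolus", dose = 80,
               perturbation = "control", t_h = t_h, foxo1_nuc_frac = 0.2,
               p53_nuc = vals, dead = FALSE, stringsAsFactors = FALSE)
  }
  ev_row <- function(id, died) {
    data.frame(cell_id = id, n_episodes = 0, entry_time = NA_real_,
               exit_time = NA_real_, nuclear_duration = 0,
               onset_time = NA_real_, baseline = 100, baseline_mad = 1,
               death_time = NA_real_, died = died)
  }
  vals <- 100 + 30 * sin(2 * pi * t_h / 5.5)
  traces <- do.call(rbind, lapply(sprintf("c%02d", 1:10),
                                  function(id) mk(id, vals)))
  ev <- do.call(rbind, lapply(sprintf("c%02d", 1:10),
                              function(id) ev_row(id, died = FALSE)))

  # all surviving: dying curve absent
  out <- suppressWarnings(compare_fates(traces, ev))
  expect_null(out$dying)
  expect_equal(out$surviving$n, 10)

  # two identical groups give identical median curves
  ev2 <- ev
  ev2$died[1:5] <- TRUE
  out2 <- compare_fates(traces, ev2)
  expect_equal(out2$dying$median, out2$surviving$median)
})
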