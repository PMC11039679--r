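# Simulator: closed-form oracles for the linear subsystems, determinism,
# order-independence, and the structural invariants of the generated tables.

test_that("H2O2 kinetics match closed forms for constant-input cases", {
  p <- kinetic_params()
  tg <- seq(0, 6, by = 1 / 3)

  expect_equal(simulate_h2o2(exposure_condition("none"), p, tg),
               rep(0, length(tg)))

  # bolus: pure exponential decay
  h <- simulate_h2o2(exposure_condition("bolus", 100), p, tg)
  expect_equal(h, 100 * exp(-p$k_clear * tg), tolerance = 1e-6)
  expect_equal(h[tg == 1], 100 * exp(-2.3), tolerance = 1e-6)

  # continuous: relaxation to v / k_clear
  v <- p$k_gox * 2.5
  h2 <- simulate_h2o2(exposure_condition("continuous", 2.5), p, tg)
  expect_equal(h2, v / p$k_clear * (1 - exp(-p$k_clear * tg)),
               tolerance = 1e-6)
  expect_lt(abs(h2[length(h2)] - v / p$k_clear), v / p$k_clear * 1e-4)
})

test_that("PRDX hyperoxidation matches closed forms under constant H", {
  p <- kinetic_params()
  tg <- seq(0, 10, by = 1 / 3)
  H <- rep(8, length(tg))

  expect_equal(simulate_prdx(rep(0, 10), p, t_grid = seq(0, 3, by = 1 / 3)),
               rep(0, 10))

  # no repair: P = 1 - exp(-k_hyp H t), monotone to 1
  pr <- simulate_prdx(H, p, perturbation_mode("srxn1_inhibited"), tg)
  expect_equal(pr, 1 - exp(-p$k_hyp * 8 * tg), tolerance = 1e-6)
  expect_true(all(diff(pr) > 0))

  # with repair: steady state k_hyp H / (k_hyp H + k_srx)
  rate <- p$k_hyp * 8 + p$k_srx
  pr2 <- simulate_prdx(rep(8, 301), p, t_grid = seq(0, 100, length.out = 301))
  expect_equal(pr2[301], p$k_hyp * 8 / rate, tolerance = 1e-5)
})

test_that("input validation rejects bad conditions and grids", {
  p <- kinetic_params()
  expect_error(exposure_condition("bolus", -5), "non-negative")
  expect_error(exposure_condition("none", 10), "dose = 0")
  expect_error(simulate_h2o2(exposure_condition("bolus", 10), p,
                             c(0, 1, 1.5)), "uniform")
  expect_error(simulate_prdx(c(-1, 0, 1), p,
                             t_grid = c(0, 1, 2)), "non-negative")
  expect_error(simulation_config(n_cells = 0), "positive integer")
  expect_error(simulation_config(t_end = 24, dt_sample = 0.7),
               "integer frame count")
  expect_error(perturbation_mode("control", srxn1_multiplier = 2),
               "multipliers = 1")
})

test_that("identical configurations give bitwise-identical populations", {
  cfg <- simulation_config(exposure_condition("bolus", 80), n_cells = 12,
                           seed = 42)
  t1 <- simulate_population(cfg)
  t2 <- simulate_population(cfg)
  expect_identical(t1, t2)
})

test_that("per-cell streams are order-independent of population size", {
  cfg_big <- simulation_config(exposure_condition("bolus", 100),
                               n_cells = 10, seed = 3)
  cfg_small <- simulation_config(exposure_condition("bolus", 100),
                                 n_cells = 4, seed = 3)
  big <- simulate_population(cfg_big)
  small <- simulate_population(cfg_small)
  for (i in 1:4) {
    id <- sprintf("b100_%04d", i)
    expect_equal(big[big$cell_id == id, -1], small[small$cell_id == id, -1],
                 ignore_attr = TRUE)
  }
  # simulate_cell reproduces the population rows
  one <- simulate_cell(cfg_big, 7L)
  expect_equal(one$foxo1_nuc_frac,
               big$foxo1_nuc_frac[big$cell_id == "b100_0007"])
  expect_equal(one$p53_nuc, big$p53_nuc[big$cell_id == "b100_0007"])
})

test_that("untreated control stays at baseline", {
  cfg <- simulation_config(exposure_condition("none"), n_cells = 20,
                           seed = 9)
  tr <- simulate_population(cfg, keep_state = TRUE)
  st <- attr(tr, "state")
  expect_true(all(st$P == 0))
  expect_true(all(st$F_true <= cfg$params$f_min + 1e-9))
  # p53 stays near its basal fixed point throughout
  p_rel <- st$p53_true / st$p53_true[, 1]
  expect_lt(max(abs(p_rel - 1)), 0.05)
  # only the ~1%/day background hazard applies without treatment
  expect_lte(death_fraction(tr), 0.1)
})

test_that("P stays in [0,1] and post-death samples are missing", {
  cfg <- simulation_config(exposure_condition("bolus", 300), n_cells = 40,
                           seed = 17)
  tr <- simulate_population(cfg, keep_state = TRUE)
  st <- attr(tr, "state")
  expect_true(all(st$P >= 0 & st$P <= 1))
  dt <- attr(tr, "death_time")
  for (id in names(dt)[!is.na(dt)]) {
    rows <- tr[tr$cell_id == id, ]
    post <- rows$t_h >= dt[[id]]
    expect_true(all(is.na(rows$foxo1_nuc_frac[post])))
    expect_true(all(is.na(rows$p53_nuc[post])))
    expect_true(all(rows$dead[post]))
    expect_true(all(!rows$dead[!post]))
  }
})

test_that("snapshot equals the trace frame when measurement noise is off", {
  p <- kinetic_params(sigma_meas = 0)
  cfg <- simulation_config(exposure_condition("bolus", 100), params = p,
                           n_cells = 8, seed = 5)
  tr <- simulate_population(cfg)
  sn <- simulate_snapshot(cfg, t_fix = 5)
  frame <- tr[abs(tr$t_h - 5) < 1e-9 & !tr$dead, ]
  expect_equal(sn$foxo1_nuc_frac, frame$foxo1_nuc_frac)
  expect_equal(sn$log_p53, log(frame$p53_nuc))
  expect_error(simulate_snapshot(cfg, t_fix = 30), "t_fix")
})

test_that("SRXN1 inhibition prolongs FOXO1 residence and delays p53 onset", {
  p <- kinetic_params()
  base <- simulation_config(exposure_condition("bolus", 100), params = p,
                            n_cells = 60, seed = 21)
  inhib <- simulation_config(exposure_condition("bolus", 100),
                             perturbation_mode("srxn1_inhibited"),
                             params = p, n_cells = 60, seed = 21)
  ev_c <- detect_events(simulate_population(base))
  ev_j <- detect_events(simulate_population(inhib))
  act_c <- ev_c$n_episodes > 0
  act_j <- ev_j$n_episodes > 0
  expect_gt(median(ev_j$nuclear_duration[act_j]),
            median(ev_c$nuclear_duration[act_c]))
  # p53 onset later (or absent) under inhibition: compare onset medians
  on_c <- ev_c$onset_time[act_c]
  on_j <- ev_j$onset_time[act_j]
  expect_gt(sum(is.na(on_j)) / length(on_j), sum(is.na(on_c)) / length(on_c))
})
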