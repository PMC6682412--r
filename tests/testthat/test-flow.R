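# Flow pipeline: gating, per-event OxD, subpopulation splitting,
# time/dose courses, dead fractions, the death-line fit and CFU survival.

test_that("roGFP+ gating partitions events by the i405*i488 product", {
  ev <- make_event_fixture()
  g <- gate_rogfp_positive(ev, expr_threshold = 1e4)
  # by construction events 1,2,3,6,7,9 have i405*i488 > 1e4
  expect_equal(g$gated$event_id, c(1, 2, 3, 6, 7, 9))
  expect_equal(nrow(g$gated) + nrow(g$rejected), nrow(ev))
  expect_length(intersect(g$gated$event_id, g$rejected$event_id), 0)
  # all-zero product -> empty
  ev0 <- ev; ev0$i405 <- 0
  expect_equal(nrow(gate_rogfp_positive(ev0, 1e4)$gated), 0)
  # permissive bound keeps every positive product
  expect_equal(nrow(gate_rogfp_positive(ev, 1e-12)$gated), nrow(ev))
  # empty input is fine
  expect_equal(nrow(gate_rogfp_positive(ev[0, ], 1e4)$gated), 0)
})

test_that("per-event OxD hits anchors, flags exclusions, recovers simulated means", {
  calib <- calibration_set(1, 5, 1, 1)  # linear form
  ev <- tibble::tibble(i405 = c(1, 5 * (1 + 4 * 1.2) / 5, 0.5),
                       i488 = c(1, 1, 0))
  out <- oxd_per_event(ev, calib)
  expect_equal(out$oxd[1], 0)
  expect_equal(out$oxd_flag[2], "excluded")
  expect_equal(out$oxd_flag[3], "invalid")
  # simulated events at true OxD 0.35 recover the mean within 3 SE
  cfg <- flow_sim_config(doses = 0, timepoints = 30,
                         n_events_per_sample = 5000, replicates = 1,
                         wt_af_fraction = 0, frac_replicate_sd = 0,
                         frac_oxidized_by_dose = c("0" = 0),
                         reduced_oxd_knots = data.frame(time = c(0, 100),
                                                        oxd = c(0.35, 0.35)),
                         seed = 8)
  sim <- simulate_flow_experiment(cfg)
  out2 <- oxd_per_event(sim$events, sim$calibration)
  ox <- out2$oxd[out2$oxd_flag %in% c("in_range", "over_range")]
  expect_lt(abs(mean(ox) - 0.35), 3 * 0.03 / sqrt(5000) + 0.002)
})

test_that("subpopulation splitting finds the boundary of a bimodal mixture", {
  set.seed(10)
  oxd <- c(rnorm(400, 0.35, 0.03), rnorm(600, 1.00, 0.03))
  for (m in c("mixture", "valley")) {
    sp <- split_subpopulations(oxd, method = m)
    expect_false(sp$unimodal)
    expect_gt(sp$threshold_oxd, 0.5)
    expect_lt(sp$threshold_oxd, 0.9)
    se3 <- 3 * sqrt(0.6 * 0.4 / 1000)
    expect_lt(abs(sp$frac_oxidized - 0.60), se3)
    expect_equal(sp$frac_oxidized + sp$frac_reduced, 1)
  }
})

test_that("unimodal inputs give a flagged degenerate split, not a crash", {
  set.seed(11)
  lo <- split_subpopulations(rnorm(500, 0.30, 0.03))
  expect_true(lo$unimodal)
  expect_equal(lo$frac_oxidized, 0)
  hi <- split_subpopulations(rnorm(500, 1.00, 0.03))
  expect_true(hi$unimodal)
  expect_equal(hi$frac_oxidized, 1)
  expect_error(split_subpopulations(rnorm(50, 0.5, 0.1)), "too few")
  fx <- split_subpopulations(rnorm(500, 0.3, 0.2), method = "fixed",
                             fixed_cutoff = 0.6)
  expect_equal(fx$threshold_oxd, 0.6)
})

test_that("oxidized fractions rise with dose and the null condition stays near zero", {
  cfg <- flow_sim_config(doses = c(0, 50, 80, 100), timepoints = 60,
                         n_events_per_sample = 2500, replicates = 2,
                         frac_replicate_sd = 0, seed = 12)
  sim <- simulate_flow_experiment(cfg)
  tc <- oxidized_fraction_timecourse(sim$events, sim$calibration)
  expect_equal(nrow(tc$samples), 8)  # one row per dose x time x replicate
  means <- tc$summary[order(tc$summary$dose_uM), ]
  expect_true(all(diff(means$mean_frac_oxidized) > 0))
  expect_lt(means$mean_frac_oxidized[1], 0.05)  # 2% true fraction at dose 0
})

test_that("excluded OxD values never enter fractions", {
  set.seed(3)
  ok <- rnorm(300, 0.3, 0.02)
  sp1 <- split_subpopulations(ok, min_events = 100)
  sp2 <- split_subpopulations(c(ok, rep(NA_real_, 50)), min_events = 100)
  expect_identical(sp1$frac_oxidized, sp2$frac_oxidized)
  expect_equal(sp2$n_events, 300)
})

test_that("dead fraction counts Sytox-positive events", {
  s <- c(rep(10, 75), rep(1000, 25))
  expect_equal(dead_fraction(s, 100), 0.25)
  expect_equal(dead_fraction(rep(1, 10), 100), 0)
  expect_equal(dead_fraction(rep(500, 10), 100), 1)
  expect_error(dead_fraction(s, -1), "positive")
  thr <- sytox_threshold_from_control(rlnorm(5000, log(5), 0.5))
  expect_gt(thr, 5)
})

test_that("death-vs-oxidation OLS is exact on a noiseless line and matches the normal equations", {
  x <- c(0.2, 0.4, 0.6, 0.8, 0.9)
  y <- 1.09 * x - 0.16
  # summary.lm warns on an essentially perfect fit; that is the point here
  fit <- suppressWarnings(death_vs_oxidation_fit(x, y))
  expect_equal(fit$slope, 1.09, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.16, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(13)
  x2 <- runif(10); y2 <- 1.09 * x2 - 0.16 + rnorm(10, 0, 0.05)
  fit2 <- death_vs_oxidation_fit(x2, y2)
  oracle <- ols_normal_equations(x2, y2)
  expect_equal(fit2$slope, oracle$slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, oracle$intercept, tolerance = 1e-10)
  expect_equal(fit2$r_squared, oracle$r_squared, tolerance = 1e-10)
  expect_error(death_vs_oxidation_fit(c(0.5, 0.5, 0.5), c(0, 1, 0.5)),
               "degenerate")
  expect_error(death_vs_oxidation_fit(c(0.1, 0.2), c(0, 1)), "3 points")
})

test_that("CFU survival is the colony percentage with count validation", {
  expect_equal(cfu_survival(0, 24), 0)
  expect_equal(cfu_survival(23, 24), 100 * 23 / 24)
  expect_equal(cfu_survival(24, 24), 100)
  expect_error(cfu_survival(25, 24), "exceeds")
  expect_error(cfu_survival(5, 0), "positive")
})
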