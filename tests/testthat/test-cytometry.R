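test_that("SSC threshold inverts the empirical CDF", {
  # order-statistic check on uniform SSC
  set.seed(42)
  ctrl <- data.frame(sample_id = "c", fsc = 1, ssc = runif(10000),
                     dioc = 1, pi = 1)
  thr <- compute_ssc_threshold(ctrl, 0.6)
  expect_lt(abs(thr - 0.6), 2 / sqrt(10000))
  # realized low fraction is exact up to ties on continuous data
  expect_equal(mean(ctrl$ssc <= thr), 0.6)

  expect_error(compute_ssc_threshold(ctrl, 0), "between 0 and 1")
  expect_error(compute_ssc_threshold(ctrl, 1), "between 0 and 1")
  expect_error(compute_ssc_threshold(ctrl[0, ], 0.5), "non-empty")

  ctrl$ssc <- 5
  expect_warning(thr_const <- compute_ssc_threshold(ctrl, 0.7), "constant")
  expect_equal(apply_ssc_gate(ctrl, thr_const)$frac_low, 1)
})

test_that("the SSC gate counts events strictly above the threshold", {
  ev <- data.frame(sample_id = "m", fsc = 1,
                   ssc = c(1, 2, 3, 4, 5, 6, 10, 20, 30, 40),
                   dioc = 1, pi = 1)
  g <- apply_ssc_gate(ev, 6)
  expect_equal(g$frac_high, 0.4)
  expect_equal(g$frac_low + g$frac_high, 1)
  expect_equal(apply_ssc_gate(ev, 100)$frac_high, 0)
})

test_that("gate monotonicity: frac_high never increases with the threshold", {
  gp <- default_generative_params()
  ev <- simulate_events(sample_condition("TiO2", 32), gp, 5000, seed = 8)
  thr <- sort(runif(20, min(ev$ssc), max(ev$ssc)))
  fh <- vapply(thr, function(t) apply_ssc_gate(ev, t)$frac_high, numeric(1))
  expect_true(all(diff(fh) <= 0))
})

test_that("uptake shifts the gated SSC-high fraction dose-dependently", {
  gp <- default_generative_params()
  ctrl <- simulate_events(sample_condition(), gp, 20000, seed = 1)
  thr <- compute_ssc_threshold(ctrl, 0.70)
  fh <- vapply(c(0, 6, 32, 64), function(d) {
    nm <- if (d == 0) "none" else "TiO2"
    ev <- simulate_events(sample_condition(nm, d), gp, 20000, seed = 1 + d)
    apply_ssc_gate(ev, thr)$frac_high
  }, numeric(1))
  expect_true(all(diff(fh) > 0))
  expect_lt(abs(fh[1] - 0.30), 0.02)
})

test_that("fluorescence thresholds: explicit pass-through and valley finding", {
  exp_thr <- derive_fluor_thresholds(
    rule = list(method = "explicit", dioc = 123, pi = 456))
  expect_equal(exp_thr$dioc, 123)
  expect_equal(exp_thr$pi, 456)
  expect_equal(exp_thr$rule, "explicit")

  # bimodal synthetic channels with a known valley between the modes
  gp <- default_generative_params(baseline_mortality = 0.4)
  ev <- simulate_events(sample_condition(nm_type = "none"), gp, 2e4, seed = 2)
  thr <- derive_fluor_thresholds(ev, rule = list(method = "valley"))
  expect_gt(thr$dioc, 40 * 2)      # above the low mode
  expect_lt(thr$dioc, 1500 / 2)    # below the high mode
  expect_gt(thr$pi, 8 * 2)
  expect_lt(thr$pi, 800 / 2)

  # unimodal input has no valley
  uni <- data.frame(sample_id = "u", fsc = 1, ssc = 1,
                    dioc = rlnorm(5000, log(100), 0.2),
                    pi = rlnorm(5000, log(100), 0.2))
  expect_error(derive_fluor_thresholds(uni, rule = list(method = "valley")),
               "unimodal")
})

test_that("death classification partitions events exactly", {
  ev <- manual_events(5, 2, 3)
  d <- classify_death(ev, dioc_threshold = 100, pi_threshold = 100)
  expect_equal(d$live, 0.5)
  expect_equal(d$apoptotic, 0.2)
  expect_equal(d$dead, 0.3)
  expect_equal(d$mortality, 0.5)

  all_live <- manual_events(10, 0, 0)
  d2 <- classify_death(all_live, 100, 100)
  expect_equal(d2$live, 1)
  expect_equal(d2$mortality, 0)

  # partition property on arbitrary random tables
  set.seed(3)
  for (i in 1:10) {
    ev_r <- data.frame(sample_id = "r", fsc = 1, ssc = 1,
                       dioc = rlnorm(200, log(100), 1),
                       pi = rlnorm(200, log(100), 1))
    dr <- classify_death(ev_r, 100, 100)
    expect_identical(dr$live + dr$apoptotic + dr$dead, 1)
    expect_identical(dr$mortality, 1 - dr$live)
  }
})

test_that("PI positivity dominates DiOC in classification", {
  ev <- data.frame(sample_id = "p", fsc = 1, ssc = 1,
                   dioc = c(1000, 1000), pi = c(1000, 10))
  d <- classify_death(ev, 100, 100)
  expect_equal(d$dead, 0.5)   # DiOC-high but PI+ is dead
  expect_equal(d$live, 0.5)
})

test_that("classified mortality recovers the generator truth at large n", {
  gp <- default_generative_params()
  cond <- sample_condition("TiO2", 48, TRUE, 72)
  p <- true_mortality(cond, gp)
  ev <- simulate_events(cond, gp, 1e5, seed = 21)
  thr <- derive_fluor_thresholds(ev, rule = list(method = "valley"))
  d <- classify_death(ev, thr)
  expect_lt(abs(d$mortality - p), 3 * sqrt(p * (1 - p) / 1e5))
})
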