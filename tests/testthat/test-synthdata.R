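test_that("conditions validate their fields", {
  c1 <- sample_condition("TiO2", 64, irradiated = TRUE, timepoint_h = 72)
  expect_equal(c1$dose_gy, 4)
  expect_equal(sample_condition()$dose_gy, 0)
  expect_error(sample_condition("TiO2", -1), "dose")
  expect_error(sample_condition("none", 16), "nanomaterial")
  expect_error(sample_condition("TiO2", 16, timepoint_h = -2), "timepoint")
})

test_that("true mortality follows the generative model", {
  gp <- default_generative_params()
  # dose 0, no irradiation -> baseline asymptote of the NM curve
  expect_equal(true_mortality(sample_condition("TiO2", 0, FALSE, 72), gp),
               gp$nm_ll4$TiO2[["72"]]$lower)
  # null world is exact independent action at every dose and timepoint
  for (tp in c(24, 48, 72, 168)) {
    q <- gp$ir_kill[[as.character(tp)]]
    for (d in nm_dose_grid()[-1]) {
      p_nm <- true_mortality(sample_condition("TiO2", d, FALSE, tp), gp)
      p_comb <- true_mortality(sample_condition("TiO2", d, TRUE, tp), gp)
      expect_equal(p_comb, 1 - (1 - p_nm) * (1 - q))
    }
  }
  # closed-form worked value: p_NM = 0.2795, q = 0.255 -> 0.4632275
  expect_equal(true_mortality(sample_condition("TiO2", 64, TRUE, 72), gp),
               0.4632275, tolerance = 1e-10)
})

test_that("default curves hit their single-agent anchors", {
  gp <- default_generative_params()
  expect_equal(ll4_predict(64, gp$nm_ll4$TiO2[["72"]]), 0.2795)
  expect_equal(ll4_predict(64, gp$nm_ll4$SiO2TiO2[["168"]]), 0.7057)
  expect_equal(ll4_predict(32, gp$nm_ll4$AlSiTiO2[["72"]]), 0.60)
  expect_equal(unname(gp$ir_kill[c("72", "168")]), c(0.255, 0.634))
})

test_that("simulated events carry the intended structure", {
  gp <- default_generative_params()
  # no NM, no irradiation: no uptake, no SSC shift
  ev0 <- simulate_events(sample_condition(), gp, 2000, seed = 4)
  expect_false(any(attr(ev0, "truth")$laden))
  expect_equal(attr(ev0, "truth")$uptake_fraction, 0)

  # zero-mortality world: every event live (DiOC-high, PI-low)
  gp0 <- default_generative_params(baseline_mortality = 0)
  ev_live <- simulate_events(sample_condition(nm_type = "none"), gp0,
                             2000, seed = 4)
  expect_true(all(attr(ev_live, "truth")$state == "live"))
  expect_true(all(ev_live$dioc > 300) && all(ev_live$pi < 300))

  # mortality 0.3: empirical non-live fraction within 3 binomial SD
  gp3 <- default_generative_params(baseline_mortality = 0.3)
  ev <- simulate_events(sample_condition(nm_type = "none"), gp3,
                        1e5, seed = 11)
  frac <- mean(attr(ev, "truth")$state != "live")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))

  # all intensities finite and non-negative
  expect_true(all(is.finite(as.matrix(ev[c("fsc", "ssc", "dioc", "pi")]))))
  expect_true(all(ev$ssc >= 0 & ev$dioc >= 0 & ev$pi >= 0))
})

test_that("equal seeds give bit-identical output", {
  gp <- default_generative_params()
  cond <- sample_condition("SiO2TiO2", 32, TRUE, 48)
  expect_identical(simulate_events(cond, gp, 500, seed = 9),
                   simulate_events(cond, gp, 500, seed = 9))
  expect_identical(simulate_pcr(cond, gp, seed = 9),
                   simulate_pcr(cond, gp, seed = 9))
  g1 <- simulate_growth_images(cond, 2, gp, n_fields = 2, seed = 9)
  g2 <- simulate_growth_images(cond, 2, gp, n_fields = 2, seed = 9)
  expect_identical(g1, g2)
})

test_that("growth image generator tracks its ground truth", {
  gp0 <- default_generative_params(baseline_mortality = 0)
  imgs <- simulate_growth_images(sample_condition(nm_type = "none"), 0, gp0,
                                 n_fields = 5, seed = 2,
                                 plating_per_field = 30)
  counts <- vapply(imgs, function(x) x$truth_count, integer(1))
  # day 0 expectation equals the plating density (Poisson spread)
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 5))
  for (im in imgs) expect_identical(im$truth_count, nrow(im$centers))

  # total mortality drives counts to zero at any day
  gp_dead <- default_generative_params()
  gp_dead$baseline_mortality <- 1
  for (day in c(0, 3, 7)) {
    imgs_d <- simulate_growth_images(sample_condition(nm_type = "none"),
                                     day, gp_dead, n_fields = 3, seed = 5)
    expect_true(all(vapply(imgs_d, function(x) x$truth_count, integer(1)) == 0))
  }
})

test_that("impossible nucleus placement errors out", {
  gp <- default_generative_params()
  expect_error(
    simulate_growth_images(sample_condition(), 0, gp, n_fields = 1,
                           seed = 1, plating_per_field = 500,
                           field_size = 64L, carrying_capacity = Inf),
    "too small")
})

test_that("qPCR generator encodes the stress model", {
  gp <- default_generative_params()
  # noiseless world: control condition gives fold change exactly 1,
  # and one lost cycle doubles expression downstream
  gp$ct_params <- lapply(gp$ct_params, function(cp) {
    cp$noise_sd <- 0
    cp
  })
  ct_ctrl <- simulate_pcr(sample_condition(), gp, seed = 1)
  ct_trt <- simulate_pcr(sample_condition("TiO2", 32, TRUE, 72), gp, seed = 2)
  fc <- fold_change_table(rbind(ct_ctrl, ct_trt), "GAPDH")
  ctrl_rows <- fc[fc$dose_surface == 0, ]
  expect_equal(ctrl_rows$fold_change, rep(1, nrow(ctrl_rows)))
  # HMOX1 induced under co-exposure; NQO1/TXNRD1 flat by default
  trt <- fc[fc$dose_surface == 32, ]
  hm <- trt$fold_change[trt$gene == "HMOX1"]
  stress <- 32 / 64 + 0.5 + 0.5 * 32 / 64
  expect_equal(hm, 2^(gp$ct_params$HMOX1$stress_slope * stress))
  expect_equal(trt$fold_change[trt$gene %in% c("NQO1", "TXNRD1")], c(1, 1))
})

test_that("event tables round-trip through CSV", {
  gp <- default_generative_params()
  ev <- simulate_events(sample_condition("TiO2", 16), gp, 200, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_csv(ev, path)
  back <- read_event_csv(path)
  expect_equal(back$ssc, ev$ssc, tolerance = 1e-12)
  expect_s3_class(back, "event_table")
})
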