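test_that("2^-ddCt matches its closed form", {
  expect_equal(delta_delta_ct(24, 18, 26, 18), 4)
  expect_equal(delta_delta_ct(25, 18, 26, 18), 2)   # ddCt = -1 doubles
  # self-normalization is 1 for any finite Ct pair
  set.seed(1)
  for (i in 1:10) {
    a <- runif(1, 10, 40); b <- runif(1, 10, 40)
    expect_equal(delta_delta_ct(a, b, a, b), 1)
  }
  # shifting the target Ct by -k multiplies the fold change by 2^k
  base <- delta_delta_ct(24, 18, 26, 18)
  for (k in c(0.5, 1, 3))
    expect_equal(delta_delta_ct(24 - k, 18, 26, 18), base * 2^k)
  expect_error(delta_delta_ct(NA, 18, 26, 18), "finite")
})

test_that("fold-change table normalizes against the per-timepoint control", {
  gp <- default_generative_params()
  gp$ct_params <- lapply(gp$ct_params, function(cp) { cp$noise_sd <- 0; cp })
  ct <- rbind(
    simulate_pcr(sample_condition(timepoint_h = 24), gp, seed = 1),
    simulate_pcr(sample_condition("TiO2", 64, FALSE, 24), gp, seed = 2),
    simulate_pcr(sample_condition(timepoint_h = 72), gp, seed = 3),
    simulate_pcr(sample_condition("TiO2", 64, FALSE, 72), gp, seed = 4))
  fc <- fold_change_table(ct, "GAPDH")
  expect_true(all(fc$fold_change[fc$dose_surface == 0] == 1))
  hm <- fc[fc$gene == "HMOX1" & fc$dose_surface == 64, ]
  expect_true(all(hm$fold_change > 1))   # dose-dependent induction
  expect_error(fold_change_table(ct, "ACTB"), "absent")
})

test_that("welch_t agrees with the closed-form statistic to 1e-8", {
  fixtures <- list(
    list(a = c(0.21, 0.25, 0.28), b = c(0.41, 0.47, 0.52)),
    list(a = c(1.2, 3.4, 2.2, 5.1, 0.3), b = c(2.0, 2.1, 2.3)),
    list(a = rnorm(10), b = rnorm(12, 1, 3)))
  set.seed(99)
  for (fx in fixtures) {
    got <- welch_t(fx$a, fx$b)
    want <- welch_oracle(fx$a, fx$b)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$df, want$df, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    # antisymmetric under group exchange
    rev <- welch_t(fx$b, fx$a)
    expect_equal(rev$t, -got$t, tolerance = 1e-12)
    expect_equal(rev$p, got$p, tolerance = 1e-12)
  }
})

test_that("welch_t enforces its preconditions", {
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
  ident <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
})

test_that("p-values fall monotonically with the group shift", {
  a <- c(1, 2, 3)
  ps <- vapply(c(0.5, 1, 2, 4), function(delta)
    welch_t(a, a + delta)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("the comparison suite runs both families with star conventions", {
  make_table <- function(effect) {
    grid <- expand.grid(nm_type = c("none", "TiO2"),
                        dose_surface = c(0, 16, 64),
                        irradiated = c(FALSE, TRUE),
                        replicate = 1:3, stringsAsFactors = FALSE)
    grid <- grid[(grid$nm_type == "none") == (grid$dose_surface == 0), ]
    base <- 0.05 + effect * (grid$dose_surface / 64 +
                               0.3 * grid$irradiated)
    set.seed(17)
    grid$timepoint_h <- 72
    grid$mortality <- pmin(pmax(base + rnorm(nrow(grid), 0, 0.01), 0), 1)
    grid
  }
  strong <- comparison_suite(make_table(0.5))
  expect_setequal(unique(strong$family), c("IR_vs_NI", "dose_vs_IRctrl"))
  top <- strong[strong$family == "dose_vs_IRctrl" & strong$dose_surface == 64, ]
  expect_true(all(grepl("#", top$stars)))
  ir_top <- strong[strong$family == "IR_vs_NI" & strong$dose_surface == 64, ]
  expect_true(all(nchar(ir_top$stars) > 0))

  # no effect: no significant calls at the strictest level
  null_tab <- make_table(0)
  nullr <- comparison_suite(null_tab)
  expect_true(mean(nullr$p < 0.05) < 0.3)
  expect_true(all(nchar(nullr$stars) <= 1))
})

test_that("null-world comparisons hold the nominal type-I error", {
  gp <- default_generative_params(baseline_mortality = 0.3)
  grid <- expand.grid(nm_type = "none", dose_surface = 0,
                      irradiated = c(FALSE, TRUE), replicate = 1:4,
                      timepoint_h = 72, stringsAsFactors = FALSE)
  # identical generative mortality everywhere: IR_vs_NI is a true null
  gp$ir_kill[] <- 0
  ps <- vapply(1:150, function(r) {
    tab <- simulate_mortality_table(grid, gp, n_events = 400,
                                    seed = derive_seed(5, r))
    suite <- comparison_suite(tab)
    suite$p[suite$family == "IR_vs_NI"]
  }, numeric(1))
  rate <- mean(ps < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(ps)) + 0.02)
})

test_that("missing replicates are skipped with a warning", {
  tab <- data.frame(nm_type = c("TiO2", "TiO2", "TiO2"),
                    dose_surface = 16, irradiated = c(TRUE, TRUE, FALSE),
                    timepoint_h = 72, replicate = c(1, 2, 1),
                    mortality = c(0.3, 0.32, 0.1))
  expect_warning(res <- comparison_suite(tab), "skipped")
})
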