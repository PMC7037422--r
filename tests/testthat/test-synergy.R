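test_that("the irradiation impulse is the conditional kill fraction", {
  expect_equal(ir_impulse(0.255, 0), 0.255)
  expect_equal(ir_impulse(0.4, 0.4), 0)
  expect_equal(ir_impulse(0.634, 0.1), 0.534 / 0.9)
  expect_error(ir_impulse(0.1, 0.2), "protective")
  expect_error(ir_impulse(0.5, 1), "\\[0, 1\\)")
})

test_that("independent action combines mortalities like Bliss", {
  expect_equal(transfer_impulse(0.2795, 0.255), 0.4632275)
  expect_equal(transfer_impulse(0.37, 0), 0.37)
  expect_equal(transfer_impulse(0, 0.42), 0.42)
  # commutative, associative, bounded, monotone
  set.seed(10)
  for (i in 1:25) {
    p <- runif(3)
    expect_equal(transfer_impulse(p[1], p[2]), transfer_impulse(p[2], p[1]))
    expect_equal(transfer_impulse(transfer_impulse(p[1], p[2]), p[3]),
                 transfer_impulse(p[1], transfer_impulse(p[2], p[3])))
    comb <- transfer_impulse(p[1], p[2])
    expect_true(comb >= 0 && comb <= 1)
    expect_gte(comb, max(p[1], p[2]) - 1e-12)
  }
})

test_that("the simulated irradiated curve transfers the impulse elementwise", {
  ni <- dose_response_data(c(6, 64), c(0.05, 0.28))
  sim <- simulate_ir_curve(ni, 0.255)
  expect_equal(sim$response, c(0.29225, 0.4636))
  expect_equal(sim$dose, ni$dose)
  expect_equal(simulate_ir_curve(ni, 0)$response, ni$response)
  sat <- dose_response_data(c(6, 64), c(1, 1))
  expect_equal(simulate_ir_curve(sat, 0.3)$response, c(1, 1))
})

test_that("coefficient distance is a scaled Euclidean norm", {
  p1 <- ll4_params(0.05, 0.85, 32, 2)
  expect_equal(coefficient_distance(p1, p1), 0)
  p2 <- ll4_params(0.05, 0.75, 32, 2)
  expect_equal(coefficient_distance(p1, p2), 0.1)
  expect_equal(coefficient_distance(p1, p2), coefficient_distance(p2, p1))
  # log keeps ed50 units from dominating; raw option differs accordingly
  p3 <- ll4_params(0.05, 0.85, 64, 2)
  expect_equal(coefficient_distance(p1, p3), log(2))
  expect_equal(coefficient_distance(p1, p3, log_ed50 = FALSE), 32)
  # coordinate-wise scaling divisors
  expect_equal(coefficient_distance(p1, p2, scaling = c(1, 0.1, 1, 1)), 1)
  expect_error(coefficient_distance(p1, p2, scaling = c(1, 2)), "scaling")
})

test_that("a noise-free null world scores distance 0 with sign 0", {
  truth <- ll4_params(0.05, 0.85, 30, 1.8)
  d <- nm_dose_grid()
  ni <- dose_response_data(d, ll4_predict(d, truth))
  q <- 0.255
  obs <- simulate_ir_curve(ni, q)   # observed == simulated exactly
  res <- synergy_call(obs, ni, controls = list(p_ir_ctrl = transfer_impulse(0.05, q),
                                               p_ni_ctrl = 0.05))
  expect_lt(res$distance, 1e-5)
  expect_identical(res$sign, 0L)
  expect_true(all(abs(res$per_dose_delta) < 1e-12))
})

test_that("generated synergy yields a positive call", {
  gp <- default_generative_params(synergy_coeff = 0.8)
  cu <- sim_curves(gp, n_events = 50000, seed = 31)
  res <- synergy_call(cu$ir, cu$ni)
  expect_identical(res$sign, 1L)
  expect_gt(res$distance, 0)
  expect_gt(res$mean_delta, 0.02)
})

test_that("mismatched dose grids are rejected", {
  ni <- dose_response_data(c(0, 6, 16, 32), c(0.05, 0.1, 0.2, 0.3))
  obs <- dose_response_data(c(0, 6, 16, 64), c(0.3, 0.35, 0.4, 0.6))
  expect_error(synergy_call(obs, ni), "dose grids")
})

test_that("the heatmap collects signed scores by nanomaterial and time", {
  gp0 <- default_generative_params(0)
  gp1 <- default_generative_params(1.2)
  results <- list(); nms <- character(); tps <- numeric()
  for (tp in c(24, 48, 72)) {
    gp <- if (tp == 48) gp1 else gp0   # interaction only at 48 h
    cu <- sim_curves(gp, timepoint_h = tp, n_events = 20000,
                     seed = 100 + tp)
    results[[length(results) + 1L]] <- synergy_call(cu$ir, cu$ni)
    nms <- c(nms, "TiO2"); tps <- c(tps, tp)
  }
  hm <- synergy_heatmap(results, nms, tps)
  expect_equal(dim(hm), c(1L, 3L))
  expect_equal(colnames(hm), c("24", "48", "72"))
  expect_equal(which.max(abs(hm[1, ])), c(`48` = 2L))
  expect_gt(hm[1, "48"], 0)

  # single cell grid
  hm1 <- synergy_heatmap(results[1], "TiO2", 24)
  expect_equal(dim(hm1), c(1L, 1L))
  expect_equal(hm1[1, 1], results[[1]]$sign * results[[1]]$distance)
})
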