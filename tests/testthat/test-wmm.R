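test_that("residual correlations vanish for independent amplicons", {
  cfg <- simulation_config(n_cells = 10000, composition = c("2" = 1),
                           seed = 901, run_id = "ind", residual_corr = 0)
  pan <- simulate_panel(cfg)
  ctrl <- simulate_control_run(cfg, control_cn = 2, panel = pan, seed = 902)
  ms <- fit_model_set(ctrl$run, 2)
  corr <- estimate_residual_correlation(ctrl$run, ms)
  off <- corr$corr[upper.tri(corr$corr)]
  expect_lt(max(abs(off)), 0.05)
  expect_identical(corr$corr, t(corr$corr))
  expect_equal(diag(corr$corr), rep(1, nrow(corr$corr)), ignore_attr = TRUE)
})

test_that("a duplicated amplicon column yields correlation 1 and a PSD repair", {
  fx <- default_fit_fixture()
  run <- fx$ctrl$run
  ids <- names(fx$ms$models)
  # overwrite one vector amplicon with a copy of another
  run$counts[, ids[2]] <- run$counts[, ids[1]]
  ms <- fx$ms
  ms$models[[ids[2]]] <- ms$models[[ids[1]]]
  ms$models[[ids[2]]]$amplicon_id <- ids[2]
  corr <- estimate_residual_correlation(run, ms)
  expect_equal(corr$corr[ids[1], ids[2]], 1, tolerance = 1e-12)
  # the repaired factorization exists and reproduces a PSD matrix
  rebuilt <- corr$cholesky %*% t(corr$cholesky)
  expect_true(all(eigen(rebuilt, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
})

test_that("copula simulation preserves NB marginals and injects correlation", {
  fx <- default_fit_fixture()
  ms <- fx$ms
  ids <- names(ms$models)
  totals <- sample(ms$control_totals, 10000, replace = TRUE)
  # identity mixing: marginal moments match the model to within 5%
  sim <- simulate_cn_reads(ms, identity_corr(ids), totals, cn = 2, seed = 31)
  for (id in ids[c(1, 5, 9)]) {
    m <- ms$models[[id]]
    mu <- predict_mean(m, totals, 2, ms$cn0_floor)
    v <- predict_variance(ms, m, mu, 2)
    expect_equal(mean(sim[, id]), mean(mu), tolerance = 0.05)
    expect_equal(var(sim[, id]), mean(v) + var(mu), tolerance = 0.05)
  }
  # strong pairwise correlation survives the quantile back-transform
  p <- length(ids)
  R <- diag(p); R[1, 2] <- R[2, 1] <- 0.9
  corr_model <- structure(list(amplicon_ids = ids, corr = R,
                               cholesky = t(chol(R))), class = "vcn_corr")
  sim2 <- simulate_cn_reads(ms, corr_model, totals, cn = 2, seed = 32)
  m1 <- ms$models[[ids[1]]]; m2 <- ms$models[[ids[2]]]
  r1 <- (sim2[, 1] - predict_mean(m1, totals, 2, ms$cn0_floor)) /
    sqrt(predict_variance(ms, m1, predict_mean(m1, totals, 2, ms$cn0_floor), 2))
  r2 <- (sim2[, 2] - predict_mean(m2, totals, 2, ms$cn0_floor)) /
    sqrt(predict_variance(ms, m2, predict_mean(m2, totals, 2, ms$cn0_floor), 2))
  expect_gt(cor(r1, r2), 0.8)
  expect_lt(cor(r1, r2), 0.95)
  # determinism: a fixed seed reproduces the matrix bit-exactly
  sim3 <- simulate_cn_reads(ms, corr_model, totals, cn = 2, seed = 32)
  expect_identical(sim2, sim3)
})

test_that("fit_mixture recovers pure and two-component mixtures", {
  fx <- default_fit_fixture()
  expected <- expected_call_dists(fx$ms, fx$corr, n_per_state = 3000,
                                  max_cn = 9, seed = 41)
  # observed equal to one state's distribution: all weight there, SAD 0
  est <- fit_mixture(expected[, "2"], expected, n_cells = 3000)
  expect_equal(unname(est$weights["2"]), 1, tolerance = 1e-9)
  expect_equal(est$sad, 0, tolerance = 1e-9)
  # analytic 0.6/0.4 mix of CN1 and CN4
  obs <- 0.6 * expected[, "1"] + 0.4 * expected[, "4"]
  est2 <- fit_mixture(obs, expected, n_cells = 5000)
  expect_equal(unname(est2$weights["1"]), 0.6, tolerance = 0.02)
  expect_equal(unname(est2$weights["4"]), 0.4, tolerance = 0.02)
  expect_equal(sum(est2$weights), 1, tolerance = 1e-9)
  # matches the exhaustive 0.01-grid simplex oracle
  oracle <- grid_search_mixture(obs, expected, active = c(2, 5))  # CN1, CN4
  expect_lte(est2$sad, oracle$sad + 0.01)
})

test_that("identical states resolve deterministically to the lower index", {
  bins <- 5
  d1 <- c(0.1, 0.6, 0.2, 0.1, 0)
  expected <- cbind("0" = d1, "1" = d1, "2" = c(0, 0.05, 0.15, 0.6, 0.2))
  est <- fit_mixture(d1, expected, n_cells = 1000)
  expect_equal(unname(est$weights["0"]), 1, tolerance = 1e-9)
  expect_equal(est$sad, 0, tolerance = 1e-12)
})

test_that("mixture weights are invariant to permuting the observed cells", {
  fx <- default_fit_fixture()
  expected <- expected_call_dists(fx$ms, fx$corr, n_per_state = 2000,
                                  max_cn = 9, seed = 42)
  calls <- c(rep(1L, 700), rep(4L, 200), rep(0L, 100))
  est_a <- fit_mixture(calls, expected)
  est_b <- fit_mixture(sample(calls), expected)
  expect_identical(est_a$weights, est_b$weights)
})

test_that("the correction concentrates a noisy single-CN run back on its state", {
  # a noisier-than-default operating point where raw calls leak off CN 1
  cfg <- simulation_config(n_cells = 2000, composition = c("1" = 1),
                           seed = 911, run_id = "noisy",
                           residual_corr = 0.15, alpha_base = 0.10)
  pan <- simulate_panel(cfg)
  ctrl <- simulate_control_run(cfg, control_cn = 1, panel = pan, seed = 912)
  test <- simulate_run(cfg, panel = pan)
  ms <- fit_model_set(ctrl$run, 1)
  calls <- call_cells(test$run, ms)
  raw_off <- mean(calls$cn != 1L, na.rm = TRUE)
  expect_gt(raw_off, 0.02)  # the scenario produces visible fall-off
  corr <- estimate_residual_correlation(ctrl$run, ms)
  mix <- run_wmm(calls, ms, corr, sim_factor = 5, seed = 913)
  expect_gte(unname(mix$weights["1"]), 0.98)
})

test_that("a bimodal composition is recovered with small per-state error", {
  truth <- c("0" = 0.10, "1" = 0.65, "2" = 0.05, "3" = 0.05, "4" = 0.15)
  cfg <- simulation_config(n_cells = 8000, composition = truth,
                           seed = 921, run_id = "mix3")
  pan <- simulate_panel(cfg)
  ctrl <- simulate_control_run(cfg, control_cn = 4, panel = pan, seed = 922)
  test <- simulate_run(cfg, panel = pan)
  ms <- fit_model_set(ctrl$run, 4)
  calls <- call_cells(test$run, ms)
  corr <- estimate_residual_correlation(ctrl$run, ms)
  mix <- run_wmm(calls, ms, corr, sim_factor = 5, seed = 923)
  emp <- table(factor(test$truth$true_cn, levels = 0:9)) / 8000
  for (s in names(truth)) {
    expect_lte(abs(unname(mix$weights[s]) - emp[s]), 0.03)
  }
})
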