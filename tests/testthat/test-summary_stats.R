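test_that("transduction summaries obey the closed-form identities", {
  s <- summarize_transduction(c("0" = 0.5, "2" = 0.5))
  expect_equal(s$pct_transduced, 50)
  expect_equal(s$avg_vcn_all, 1.0)
  expect_equal(s$avg_vcn_per_transduced, 2.0)
  s1 <- summarize_transduction(c("1" = 1.0))
  expect_equal(s1$pct_transduced, 100)
  expect_equal(s1$avg_vcn_per_transduced, 1.0)
  s0 <- summarize_transduction(c("0" = 1.0))
  expect_equal(s0$pct_transduced, 0)
  expect_true(is.na(s0$avg_vcn_per_transduced))
  # identity avg_all = avg_per_transduced * fraction, over random weights
  withr::local_seed(7)
  for (i in 1:20) {
    w <- runif(10); w <- w / sum(w); names(w) <- 0:9
    s <- summarize_transduction(w)
    expect_equal(s$avg_vcn_all,
                 s$avg_vcn_per_transduced * s$pct_transduced / 100,
                 tolerance = 1e-9)
  }
  # call vectors and weight vectors agree
  calls <- c(rep(0L, 50), rep(2L, 50))
  expect_equal(summarize_transduction(calls)$avg_vcn_all, 1.0)
})

test_that("sensitivity and specificity are plain class-conditional rates", {
  perfect <- sensitivity_specificity(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  called <- c(rep(FALSE, 999), TRUE)
  truth <- rep(FALSE, 1000)
  expect_equal(sensitivity_specificity(called, truth)$specificity, 99.9)
  expect_true(is.na(sensitivity_specificity(called, truth)$sensitivity))
  inverted <- sensitivity_specificity(!c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(inverted$sensitivity, 0)
  expect_equal(inverted$specificity, 0)
})

test_that("Poisson comparison evaluates the PMF and its correlation", {
  dist <- dpois(0:9, 1.62); dist[10] <- 1 - ppois(8, 1.62)
  pf <- poisson_compare(dist, 1.62)
  expect_equal(pf$predicted_pmf[1], 0.19790, tolerance = 1e-4)
  expect_equal(pf$predicted_pmf[2], 0.32060, tolerance = 1e-4)
  expect_equal(pf$r2, 1, tolerance = 1e-12)
  # invariant to rescaling the observed counts
  pf2 <- poisson_compare(dist * 1234, 1.62)
  expect_equal(pf2$r2, pf$r2, tolerance = 1e-12)
  # mu = 0 boundary: degenerate pmf at 0
  pf0 <- poisson_compare(c(1, 0, 0), 0)
  expect_equal(pf0$predicted_pmf, c(1, 0, 0))
  expect_error(poisson_compare(dist, -1), "mu")
})

test_that("linearity reports slope, CI and curvature diagnostics", {
  x <- c(0, 1, 2, 4)
  rep0 <- linearity(x, x)
  expect_equal(rep0$slope, 1, tolerance = 1e-12)
  expect_equal(rep0$r2, 1, tolerance = 1e-12)
  expect_equal(rep0$residual_corr, 0)
  withr::local_seed(12)
  x7 <- seq(0, 4, length.out = 7)
  y7 <- x7 + rnorm(7, 0, 0.05)
  rep1 <- linearity(x7, y7)
  expect_gt(rep1$slope, 0.9); expect_lt(rep1$slope, 1.1)
  expect_gt(rep1$r2, 0.98)
  expect_true(rep1$slope_ci_95[1] < rep1$slope &&
                rep1$slope < rep1$slope_ci_95[2])
  # a pure quadratic triggers the curvature test; p agrees with the
  # nested-model F test oracle
  x10 <- seq(0.5, 5, length.out = 10)
  y10 <- x10^2
  rep2 <- linearity(x10, y10)
  expect_lt(rep2$quad_term_p, 0.05)
  f_oracle <- anova(lm(y10 ~ x10), lm(y10 ~ x10 + I(x10^2)))[2, "Pr(>F)"]
  expect_equal(rep2$quad_term_p, f_oracle, tolerance = 1e-10)
  expect_error(linearity(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("cv_percent uses the population standard deviation", {
  expect_equal(cv_percent(c(2, 2, 2)), 0)
  expect_equal(cv_percent(c(1, 3)), 50)
  expect_equal(cv_percent(c(0.96, 1.0, 1.04)), 3.266, tolerance = 1e-3)
  expect_gt(cv_percent(c(1, 3), sample_sd = TRUE), 50)
  expect_error(cv_percent(c(0, 0)), "mean")
})

test_that("read normalisation is depth-compositional with a median anchor", {
  panel <- data.frame(amplicon_id = c("H1", "H2", "V1"),
                      class = c("human", "human", "vector"))
  uni <- matrix(5L, 4, 3, dimnames = list(letters[1:4], panel$amplicon_id))
  run <- new_vcn_run(uni, panel)
  norm <- normalize_reads(run)
  expect_true(all(norm == 1))
  # doubling every count of one cell leaves its normalized row unchanged
  m <- uni; m["a", ] <- 10L
  norm2 <- normalize_reads(new_vcn_run(m, panel))
  expect_equal(norm2["a", ], norm["a", ], tolerance = 1e-12)
  # doubling only the vector reads at equal human totals doubles the
  # vector entries
  m3 <- uni; m3["a", "V1"] <- 10L
  norm3 <- normalize_reads(new_vcn_run(m3, panel), mode = "human")
  expect_equal(unname(norm3["a", "V1"]), 2)
  expect_equal(unname(norm3["b", "V1"]), 1)
})

test_that("outlier groups separate on vector but not human reads", {
  fx <- default_fit_fixture()
  cfg <- fx$cfg
  cfg$composition <- c("1" = 0.1, "2" = 0.9)  # a true low-VCN subclone
  cfg$n_cells <- 3000
  cfg$seed <- 931
  test <- simulate_run(cfg, panel = fx$panel)
  calls <- call_cells(test$run, fx$ms)
  rep <- outlier_read_comparison(test$run, calls, expected_cn = 2)
  expect_lt(rep$lower$vector_p, 0.001)
  expect_gt(rep$lower$human_p_two_sided, 0.05)
  # identical groups: construct a lower group from copies of expected cells
  counts <- test$run$counts[1:40, ]
  rownames(counts) <- sprintf("dup%02d", 1:40)
  run_dup <- new_vcn_run(rbind(test$run$counts[1:40, ], counts),
                         test$run$panel)
  calls_dup <- data.frame(barcode = rownames(run_dup$counts),
                          cn = rep(c(2L, 1L), each = 40),
                          quality = 1, transduced = TRUE)
  class(calls_dup) <- c("vcn_calls", "data.frame")
  rep_dup <- outlier_read_comparison(run_dup, calls_dup, expected_cn = 2)
  expect_equal(rep_dup$lower$vector_p, 0.5, tolerance = 1e-9)
  # a tiny group comes back NA
  calls_small <- calls_dup
  calls_small$cn <- c(rep(2L, 78), 1L, 1L)
  expect_true(is.na(outlier_read_comparison(run_dup, calls_small,
                                            2)$lower$vector_p))
})

test_that("shuffled outlier labels give calibrated null p-values", {
  fx <- default_fit_fixture()
  cfg <- fx$cfg; cfg$n_cells <- 500; cfg$seed <- 941
  test <- simulate_run(cfg, panel = fx$panel)  # pure CN 2
  withr::local_seed(942)
  pvals <- replicate(200, {
    fake_cn <- rep(2L, 500)
    fake_cn[sample.int(500, 100)] <- 1L  # random "lower" labels
    calls <- data.frame(barcode = rownames(test$run$counts), cn = fake_cn,
                        quality = 1, transduced = TRUE)
    class(calls) <- c("vcn_calls", "data.frame")
    outlier_read_comparison(test$run, calls, 2)$lower$vector_p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the distribution permutation test behaves at its boundaries", {
  a <- rep(c(1L, 2L, 4L), times = c(30, 50, 20))
  same <- compare_vcn_distributions(a, a, n_perm = 199, seed = 1)
  expect_equal(same$p, 1)
  # maximal separation attains the minimal attainable p
  sep <- compare_vcn_distributions(rep(1L, 100), rep(4L, 100),
                                   n_perm = 999, seed = 2)
  expect_equal(sep$p, 1 / 1000)
  # symmetric in its arguments
  b <- rep(c(1L, 3L), times = c(60, 40))
  p_ab <- compare_vcn_distributions(a, b, n_perm = 499, seed = 3)$p
  p_ba <- compare_vcn_distributions(b, a, n_perm = 499, seed = 3)$p
  expect_equal(p_ab, p_ba)
  expect_error(compare_vcn_distributions(integer(0), a), "empty")
})

test_that("the permutation test holds its nominal type-I error", {
  withr::local_seed(55)
  law <- c(0.2, 0.5, 0.2, 0.1)
  rejections <- replicate(500, {
    a <- sample(0:3, 50, replace = TRUE, prob = law)
    b <- sample(0:3, 50, replace = TRUE, prob = law)
    compare_vcn_distributions(a, b, n_perm = 199)$p <= 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("median VAF tracks mutated copies per total copies", {
  withr::local_seed(77)
  # one mutated copy of four, depth 40, 500 cells
  depth <- rpois(500, 40)
  alt <- rbinom(500, depth, 0.25)
  out <- vaf_summary(alt, depth - alt, rep(4L, 500))
  expect_gte(out$median_vaf[out$cn == 4], 0.22)
  expect_lte(out$median_vaf[out$cn == 4], 0.28)
  # all-alt reads give VAF 1; zero-depth cells are excluded
  out2 <- vaf_summary(c(10L, 0L), c(0L, 0L), c(2L, 2L))
  expect_equal(out2$median_vaf, 1)
  expect_equal(out2$n_cells, 1)
})
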