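#' Transduction and average-VCN summary
#'
#' From either a per-cell call set or a weighted-mixture weight vector,
#' computes the percent of transduced cells (`100 * (1 - w0)`), the
#' sample average copy number, and the average copy number per transduced
#' cell (`avg_all / (1 - w0)`), the quantity release assays express
#' relative to the vector-positive fraction.
#'
#' @param x A `vcn_calls` data.frame, an integer vector of per-cell
#'   calls, a `mixture_estimate`, or a named proportion vector over copy
#'   numbers `0..max_cn`.
#' @param max_cn Top copy-number bin when `x` is a call vector
#'   (default 9).
#' @return A list of class `transduction_summary`: `pct_transduced`,
#'   `avg_vcn_all`, `avg_vcn_per_transduced` (NA-flagged when no cell is
#'   transduced), `cn_distribution`.
#' @export
summarize_transduction <- function(x, max_cn = 9L) {
  if (inherits(x, "mixture_estimate")) {
    w <- x$weights
  } else if (inherits(x, "vcn_calls") || is.integer(x) ||
             (is.numeric(x) && is.null(names(x)) && any(x > 1))) {
    cn <- if (inherits(x, "vcn_calls")) x$cn else as.integer(x)
    w <- cn_histogram(cn, max_cn)
  } else {
    w <- x / sum(x)
    if (is.null(names(w))) names(w) <- seq_along(w) - 1L
  }
  states <- as.numeric(names(w))
  w0 <- if ("0" %in% names(w)) unname(w["0"]) else 0
  pct <- 100 * (1 - w0)
  avg_all <- sum(states * w)
  avg_per <- if (w0 < 1) avg_all / (1 - w0) else NA_real_
  structure(list(pct_transduced = pct,
                 avg_vcn_all = avg_all,
                 avg_vcn_per_transduced = avg_per,
                 cn_distribution = w),
            class = "transduction_summary")
}

#' @export
print.transduction_summary <- function(x, ...) {
  cat(sprintf("transduced: %.1f%%  avg VCN: %.3f  avg VCN/transduced: %.3f\n",
              x$pct_transduced, x$avg_vcn_all, x$avg_vcn_per_transduced))
  invisible(x)
}

#' Sensitivity and specificity of transduction calls
#'
#' @param called_transduced Logical vector of per-cell calls (`NA`
#'   dropped pairwise).
#' @param truth_transduced Logical vector of ground-truth status.
#' @return List with `sensitivity` and `specificity` in percent; a metric
#'   whose truth class is empty is `NA`.
#' @export
sensitivity_specificity <- function(called_transduced, truth_transduced) {
  keep <- !is.na(called_transduced) & !is.na(truth_transduced)
  called <- called_transduced[keep]
  truth <- truth_transduced[keep]
  pos <- sum(truth)
  neg <- sum(!truth)
  list(sensitivity = if (pos > 0) 100 * sum(called & truth) / pos else NA_real_,
       specificity = if (neg > 0) 100 * sum(!called & !truth) / neg else NA_real_)
}

#' Compare a copy-number distribution to a Poisson model
#'
#' Under independent transduction events per cell, copy number follows a
#' Poisson law in the multiplicity of infection. The theoretical PMF over
#' bins `0..max_cn` (upper tail folded into the top bin) is compared with
#' the observed proportions by squared Pearson correlation.
#'
#' @param cn_distribution Proportion vector over copy numbers `0..max_cn`.
#' @param mu Poisson mean (>= 0).
#' @return A list of class `poisson_fit`: `mu`, `r2`, `predicted_pmf`.
#' @export
poisson_compare <- function(cn_distribution, mu) {
  if (mu < 0) stop("mu must be >= 0")
  k <- length(cn_distribution) - 1L
  pmf <- stats::dpois(0:k, lambda = mu)
  pmf[k + 1L] <- 1 - stats::ppois(k - 1L, lambda = mu)  # fold the tail
  obs <- cn_distribution / sum(cn_distribution)
  r2 <- if (stats::sd(pmf) == 0 || stats::sd(obs) == 0) NA_real_ else
    stats::cor(obs, pmf)^2
  structure(list(mu = mu, r2 = r2, predicted_pmf = pmf),
            class = "poisson_fit")
}

#' Assess linearity of estimated versus expected average VCN
#'
#' Standard unweighted least-squares regression of estimated on expected
#' values, with the diagnostics used to establish an unbiased
#' quantitative response: the 95% confidence interval of the slope, the
#' correlation between residuals and fitted values (with p-value), and
#' the p-value of a quadratic term in a degree-2 refit (curvature check).
#'
#' @param expected Numeric vector of expected (true) average VCN.
#' @param estimated Numeric vector of estimated average VCN.
#' @return A list of class `linearity_report`: `slope`, `intercept`,
#'   `r2`, `slope_ci_95`, `residual_corr`, `residual_p`, `quad_term_p`.
#' @export
linearity <- function(expected, estimated) {
  stopifnot(length(expected) == length(estimated))
  if (length(expected) < 3L) stop("need >= 3 points")
  if (stats::sd(expected) == 0) stop("zero variance in expected values")
  fit <- stats::lm(estimated ~ expected)
  ci <- suppressWarnings(stats::confint(fit, "expected", level = 0.95))
  res <- stats::residuals(fit)
  fitted <- stats::fitted(fit)
  if (stats::sd(res) < 1e-12) {
    rc <- 0; rp <- 1
  } else {
    ct <- stats::cor.test(res, fitted)
    rc <- unname(ct$estimate); rp <- ct$p.value
  }
  qfit <- stats::lm(estimated ~ expected + I(expected^2))
  # summary.lm warns on an exactly collinear/perfect fit; the p-value is
  # still well-defined for our use
  qc <- suppressWarnings(stats::coef(summary(qfit)))
  quad_p <- if ("I(expected^2)" %in% rownames(qc))
    qc["I(expected^2)", "Pr(>|t|)"] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 slope_ci_95 = c(ci[1], ci[2]),
                 residual_corr = rc,
                 residual_p = rp,
                 quad_term_p = quad_p),
            class = "linearity_report")
}

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the population standard deviation (divisor n)
#' by default; set `sample_sd = TRUE` for the n-1 divisor.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @param sample_sd Use the sample standard deviation (default `FALSE`).
#' @return CV in percent.
#' @export
cv_percent <- function(values, sample_sd = FALSE) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  s <- if (sample_sd) stats::sd(values) else
    sqrt(mean((values - m)^2))
  100 * s / m
}

#' Depth- and amplicon-normalised read counts
#'
#' Each count is first normalised to the cell's total read depth, then
#' each amplicon's column is normalised to its median across cells:
#' `n_ij = (c_ij / total_i) / median_j(c_.j / total_.)`. Amplicons whose
#' median is zero cannot be scaled and come back as `NA` columns, listed
#' in the `"zero_median"` attribute.
#'
#' @param run A `vcn_run`.
#' @param mode Which amplicons define the per-cell total (`"all"`,
#'   matching depth normalisation of the whole panel, or `"human"`).
#' @return Numeric matrix of normalised reads with attribute
#'   `"zero_median"`.
#' @export
normalize_reads <- function(run, mode = c("all", "human")) {
  mode <- match.arg(mode)
  totals <- total_reads(run, mode = mode)
  safe <- ifelse(totals > 0, totals, NA_real_)
  frac <- run$counts / safe
  med <- apply(frac, 2, stats::median, na.rm = TRUE)
  zero <- colnames(run$counts)[!is.na(med) & med == 0]
  med[med == 0] <- NA_real_
  out <- sweep(frac, 2, med, "/")
  attr(out, "zero_median") <- zero
  out
}

#' Compare outlier call groups by normalised read counts
#'
#' Splits cells into expected (`cn == expected_cn`), lower and higher
#' call groups and, for each outlier group, runs Welch t-tests of the
#' per-cell mean normalised reads against the expected group: human
#' amplicons (the genomic-input control; one-tailed in the group's
#' direction, two-sided also reported) and vector amplicons (one-tailed
#' in the group's direction: lower group tests "less", higher tests
#' "greater"). A true outlier subclone shifts vector reads but not human
#' reads; a doublet-like artifact shifts both.
#'
#' @param run A `vcn_run`.
#' @param calls A `vcn_calls` data.frame aligned to `run`.
#' @param expected_cn The run's expected copy number.
#' @return A list with one element per outlier group (`lower`, `higher`),
#'   each containing group size and p-values (`NA` when the group has
#'   fewer than 3 cells), plus `n_expected`.
#' @export
outlier_read_comparison <- function(run, calls, expected_cn) {
  # normalise against human-only totals: a whole-panel total is itself
  # CN-dependent and would couple the human comparison to the vector signal
  norm <- normalize_reads(run, mode = "human")
  is_hum <- run$panel$class == "human"
  hum <- rowMeans(norm[, is_hum, drop = FALSE], na.rm = TRUE)
  vec <- rowMeans(norm[, !is_hum, drop = FALSE], na.rm = TRUE)
  cn <- calls$cn
  grp_idx <- list(expected = which(!is.na(cn) & cn == expected_cn),
                  lower = which(!is.na(cn) & cn < expected_cn),
                  higher = which(!is.na(cn) & cn > expected_cn))
  test_group <- function(idx, direction) {
    if (length(idx) < 3L || length(grp_idx$expected) < 3L) {
      return(list(n = length(idx), vector_p = NA_real_,
                  human_p = NA_real_, human_p_two_sided = NA_real_))
    }
    e <- grp_idx$expected
    list(n = length(idx),
         vector_p = stats::t.test(vec[idx], vec[e],
                                  alternative = direction)$p.value,
         human_p = stats::t.test(hum[idx], hum[e],
                                 alternative = direction)$p.value,
         human_p_two_sided = stats::t.test(hum[idx], hum[e])$p.value)
  }
  list(lower = test_group(grp_idx$lower, "less"),
       higher = test_group(grp_idx$higher, "greater"),
       n_expected = length(grp_idx$expected))
}

#' Permutation test for a difference between two VCN distributions
#'
#' Test statistic: total variation distance between the two normalised
#' copy-number histograms (chi-square distance available via
#' `statistic`). The null is generated by permuting group labels;
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`.
#'
#' @param calls_a,calls_b Integer vectors of per-cell copy-number calls
#'   (or `vcn_calls` data.frames).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param statistic `"tvd"` (default) or `"chisq"`.
#' @return List with `p`, `statistic`, `observed`.
#' @export
compare_vcn_distributions <- function(calls_a, calls_b, n_perm = 10000L,
                                      seed = NULL,
                                      statistic = c("tvd", "chisq")) {
  statistic <- match.arg(statistic)
  a <- if (inherits(calls_a, "vcn_calls")) calls_a$cn else as.integer(calls_a)
  b <- if (inherits(calls_b, "vcn_calls")) calls_b$cn else as.integer(calls_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty call group")
  max_cn <- max(a, b)
  stat_fun <- function(x, y) {
    px <- cn_histogram(x, max_cn)
    py <- cn_histogram(y, max_cn)
    if (statistic == "tvd") {
      0.5 * sum(abs(px - py))
    } else {
      m <- (px + py) / 2
      ok <- m > 0
      sum((px[ok] - py[ok])^2 / m[ok])
    }
  }
  obs <- stat_fun(a, b)
  pool <- c(a, b)
  na <- length(a)
  with_local_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (stat_fun(pool[idx], pool[-idx]) >= obs - 1e-12) hits <- hits + 1L
    }
    list(p = (1 + hits) / (1 + n_perm), statistic = statistic,
         observed = obs)
  })
}

#' Median variant allele frequency by called copy number
#'
#' Per-cell VAF is `alt / (alt + ref)`; cells with zero depth are
#' excluded. For a vector mutation present on `m` of `c` integrated
#' copies the expected VAF is `m / c` (e.g. 25% for one mutated copy of
#' four).
#'
#' @param alt_reads,ref_reads Integer vectors of per-cell allele depths.
#' @param calls Integer vector of per-cell copy-number calls (or a
#'   `vcn_calls` data.frame).
#' @return A data.frame with columns `cn`, `n_cells`, `median_vaf`.
#' @export
vaf_summary <- function(alt_reads, ref_reads, calls) {
  cn <- if (inherits(calls, "vcn_calls")) calls$cn else as.integer(calls)
  depth <- alt_reads + ref_reads
  keep <- depth > 0 & !is.na(cn)
  vaf <- alt_reads[keep] / depth[keep]
  grp <- cn[keep]
  agg <- stats::aggregate(vaf, by = list(cn = grp),
                          FUN = function(v) c(n = length(v),
                                              med = stats::median(v)))
  data.frame(cn = agg$cn,
             n_cells = agg$x[, "n"],
             median_vaf = agg$x[, "med"])
}
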