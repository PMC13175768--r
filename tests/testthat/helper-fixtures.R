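# Shared fixtures, built in code. Expensive simulation-based fixtures are
# memoised so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny hand-built panel + run for io tests.
tiny_panel_df <- function() {
  data.frame(amplicon_id = c("H1", "H2", "V1", "V2"),
             class = c("human", "human", "vector", "vector"),
             target = c("chr1", "chr2", "vec_a", "vec_b"),
             stringsAsFactors = FALSE)
}

tiny_counts <- function() {
  m <- matrix(c(10L, 12L, 5L, 3L,
                8L,  9L,  4L, 2L,
                0L,  0L,  0L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("AAA", "CCC", "GGG"),
                              c("H1", "H2", "V1", "V2")))
  m
}

write_tiny_run_files <- function(dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  panel_path <- file.path(dir, "panel.tsv")
  counts_path <- file.path(dir, "counts.tsv")
  utils::write.table(tiny_panel_df(), panel_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  df <- data.frame(barcode = rownames(tiny_counts()), tiny_counts(),
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(counts = counts_path, panel = panel_path)
}

# A hand-parameterised model set (no fitting) for caller unit tests:
# per-copy mean at total = 1e4 is `per_copy`, dispersion `alpha`.
toy_model_set <- function(per_copy = c(30, 40, 25), alpha = c(0.05, 0.08, 0.04),
                          control_cn = 1L, cn0_floor = 0.05) {
  ids <- sprintf("V%d", seq_along(per_copy))
  models <- mapply(function(id, pc, a) {
    structure(list(amplicon_id = id,
                   const = log(pc * control_cn) - log(1e4),
                   x1 = 1,
                   alpha = a,
                   control_cn = control_cn,
                   mean_reads = pc * control_cn,
                   loglik = NA_real_, n_cells = NA_integer_),
              class = "amplicon_model")
  }, ids, per_copy, alpha, SIMPLIFY = FALSE)
  names(models) <- ids
  structure(list(models = models,
                 extrapolator = NULL,
                 control_cn = as.integer(control_cn),
                 cn0_floor = cn0_floor,
                 total_mode = "human",
                 excluded = character(0),
                 control_totals = rep(1e4, 100)),
            class = "vcn_model_set")
}

# A moderate default-conditions simulation: CN-4 control + fitted models +
# residual correlation, shared across caller/wmm tests.
default_fit_fixture <- function() {
  memoise_fixture("default_fit", function() {
    cfg <- simulation_config(n_cells = 1500, composition = c("2" = 1),
                             seed = 701, run_id = "fx")
    pan <- simulate_panel(cfg)
    ctrl <- simulate_control_run(cfg, control_cn = 4, panel = pan, seed = 702)
    ms <- fit_model_set(ctrl$run, 4)
    corr <- estimate_residual_correlation(ctrl$run, ms)
    list(cfg = cfg, panel = pan, ctrl = ctrl, ms = ms, corr = corr)
  })
}

# Brute-force two-sided Fisher p by hypergeometric enumeration over all
# tables with the observed margins; numerically tied probabilities are
# included with the conventional (1 + 1e-7) relative tolerance.
fisher_p_enum <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- r1 + r2
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive simplex grid search at `step` resolution over the given
# active states: the independent oracle for the weighted mixture fit.
grid_search_mixture <- function(obs, expected, active, step = 0.01) {
  k <- length(active)
  n_units <- round(1 / step)
  combos <- compositions_of(n_units, k)
  best_sad <- Inf
  best_w <- NULL
  sub <- expected[, active, drop = FALSE]
  for (i in seq_len(nrow(combos))) {
    w <- combos[i, ] * step
    sad <- sum(abs(obs - drop(sub %*% w)))
    if (sad < best_sad) {
      best_sad <- sad
      best_w <- w
    }
  }
  full <- numeric(ncol(expected))
  full[active] <- best_w
  list(weights = full, sad = best_sad)
}

# All length-k vectors of non-negative integers summing to n.
compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    rest <- compositions_of(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, rest)
  }
  do.call(rbind, out)
}
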