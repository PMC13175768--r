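#' Estimate inter-amplicon residual correlation from control cells
#'
#' Closely tiled vector amplicons co-vary beyond what independent NB
#' sampling predicts (e.g., polymerase run-on). Deviations from the
#' modelled mean are standardised per cell/amplicon,
#' `r = (count - mean) / sd`, and their pairwise Pearson correlations are
#' computed over the control cells. The matrix is repaired to positive
#' semi-definiteness by eigenvalue clipping (at 1e-6) and renormalised to
#' unit diagonal before taking its Cholesky factor.
#'
#' @param control_run A `vcn_run` of control cells.
#' @param model_set A `vcn_model_set` fitted on the same control data.
#' @return A list of class `vcn_corr` with `amplicon_ids`, `corr`,
#'   `cholesky` (lower triangular).
#' @export
estimate_residual_correlation <- function(control_run, model_set) {
  ids <- names(model_set$models)
  if (length(ids) < 2L) stop("need >= 2 retained vector amplicons")
  totals <- total_reads(control_run, mode = model_set$total_mode)
  ok <- totals > 0
  if (sum(ok) < 30L) stop("need >= 30 control cells with positive totals")
  cn <- model_set$control_cn
  resid <- sapply(ids, function(id) {
    m <- model_set$models[[id]]
    mu <- predict_mean(m, totals[ok], cn, cn0_floor = model_set$cn0_floor)
    s <- sqrt(predict_variance(model_set, m, mu, cn))
    (control_run$counts[ok, id] - mu) / s
  })
  sds <- apply(resid, 2, stats::sd)
  corr <- suppressWarnings(stats::cor(resid))
  if (any(sds == 0) || any(!is.finite(corr))) {
    warning("constant residual column; its correlations set to 0")
    corr[!is.finite(corr)] <- 0
    diag(corr) <- 1
  }
  corr <- (corr + t(corr)) / 2
  repaired <- repair_psd(corr)
  structure(list(amplicon_ids = ids, corr = corr,
                 cholesky = t(chol(repaired + diag(1e-10, nrow(repaired))))),
            class = "vcn_corr")
}

# Clip eigenvalues at eps, reconstruct, renormalize to unit diagonal.
repair_psd <- function(mat, eps = 1e-6) {
  e <- eigen(mat, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / outer(d, d)
  (out + t(out)) / 2
}

#' Identity correlation model
#'
#' Convenience constructor for independent amplicons (used when no control
#' run is available or for sensitivity checks).
#'
#' @param amplicon_ids Character vector of amplicon ids.
#' @return A `vcn_corr` with identity correlation.
#' @export
identity_corr <- function(amplicon_ids) {
  p <- length(amplicon_ids)
  structure(list(amplicon_ids = amplicon_ids, corr = diag(p),
                 cholesky = diag(p)),
            class = "vcn_corr")
}

#' Simulate correlated amplicon read counts for one copy-number state
#'
#' Gaussian-copula construction: independent standard normal scores per
#' amplicon are mixed by the Cholesky factor of the repaired correlation
#' matrix, mapped to uniforms, and pushed through each amplicon's NB
#' quantile function at the mean/dispersion predicted for `cn` and the
#' given per-cell totals. The copula preserves the NB marginals exactly
#' while injecting the empirically observed inter-amplicon correlation.
#'
#' @param model_set A `vcn_model_set`.
#' @param corr_model A `vcn_corr` (e.g. [estimate_residual_correlation()]).
#' @param totals Per-cell total read depths for the simulated cells
#'   (typically resampled from the control run's empirical totals).
#' @param cn Copy-number state to simulate.
#' @param seed Optional integer seed (local to this call).
#' @return Integer matrix `length(totals)` x amplicons with amplicon ids
#'   as column names.
#' @export
simulate_cn_reads <- function(model_set, corr_model, totals, cn,
                              seed = NULL) {
  with_local_seed(seed, {
    ids <- names(model_set$models)
    stopifnot(identical(ids, corr_model$amplicon_ids))
    n <- length(totals)
    p <- length(ids)
    z <- matrix(stats::rnorm(n * p), n, p) %*% t(corr_model$cholesky)
    u <- stats::pnorm(z)
    # guard exact 0/1 uniforms
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    counts <- matrix(0L, n, p, dimnames = list(NULL, ids))
    for (j in seq_len(p)) {
      m <- model_set$models[[ids[j]]]
      mu <- predict_mean(m, totals, cn, cn0_floor = model_set$cn0_floor)
      a <- alpha_for_cn(model_set, m, cn)
      counts[, j] <- as.integer(stats::qnbinom(u[, j], size = 1 / a, mu = mu))
    }
    counts
  })
}

#' Per-state reference distributions of called copy number
#'
#' For every state on the caller grid, simulates reads with
#' [simulate_cn_reads()] at totals resampled from the control run and runs
#' the caller on them, yielding the distribution of called copy number a
#' pure population of that state would produce. These are the "expected"
#' distributions mixed by [fit_mixture()].
#'
#' @param model_set A `vcn_model_set`.
#' @param corr_model A `vcn_corr`.
#' @param n_per_state Simulated cells per state.
#' @param max_cn Top of the copy-number grid (default 9).
#' @param seed Optional integer seed.
#' @return Matrix `(max_cn + 1)` bins x `(max_cn + 1)` states of called-CN
#'   proportions; column `s` is the call distribution of true state `s`.
#' @export
expected_call_dists <- function(model_set, corr_model, n_per_state,
                                max_cn = 9L, seed = NULL) {
  with_local_seed(seed, {
    states <- 0:max_cn
    out <- matrix(0, max_cn + 1L, max_cn + 1L,
                  dimnames = list(as.character(states), as.character(states)))
    for (s in states) {
      totals <- sample(model_set$control_totals, n_per_state, replace = TRUE)
      reads <- simulate_cn_reads(model_set, corr_model, totals, s)
      res <- call_matrix(model_set, reads, totals, max_cn)
      out[, as.character(s)] <- cn_histogram(res$cn, max_cn)
    }
    out
  })
}

#' Histogram of copy-number calls over bins 0..max_cn
#'
#' Calls above `max_cn` (impossible on the default grid, possible for
#' externally supplied calls) are merged into the top bin; `NA` calls are
#' dropped.
#'
#' @param cn Integer vector of calls.
#' @param max_cn Top bin.
#' @return Normalised proportions, length `max_cn + 1`.
#' @export
cn_histogram <- function(cn, max_cn = 9L) {
  cn <- cn[!is.na(cn)]
  cn <- pmin(cn, max_cn)
  h <- tabulate(cn + 1L, nbins = max_cn + 1L)
  names(h) <- as.character(0:max_cn)
  if (sum(h) == 0) stop("no callable cells")
  h / sum(h)
}

#' Fit population copy-number proportions by SAD minimisation
#'
#' The weighted mixture method: find simplex weights over copy-number
#' states such that the weight-mixed expected call distributions match the
#' observed call distribution, minimising the sum of absolute differences
#' (SAD) over copy-number bins. Optimisation is deterministic projected
#' pairwise descent on the simplex: starting from all weight on the single
#' state that best explains the data, each iteration moves mass between
#' the pair of states giving the largest SAD decrease at the current step
#' size, which is halved when no move improves. Iteration stops after
#' `max_iter` rounds or when `SAD <= 1 / (10 * n_cells)`.
#'
#' @param observed Either an integer vector of per-cell copy-number calls
#'   or a pre-binned proportion vector of length `nrow(expected)`.
#' @param expected Matrix of per-state call distributions, bins x states
#'   (see [expected_call_dists()]).
#' @param n_cells Number of observed cells (sets the stopping tolerance).
#' @param max_iter Maximum iterations (default 1000).
#' @return A list of class `mixture_estimate` with `weights` (named, sums
#'   to 1), `sad`, `n_iter`, `converged`.
#' @export
fit_mixture <- function(observed, expected, n_cells = NULL,
                        max_iter = 1000L) {
  n_bins <- nrow(expected)
  if (length(observed) == 0L) stop("empty observed calls")
  if (length(observed) == n_bins && !is.integer(observed) &&
      abs(sum(observed) - 1) < 1e-6) {
    obs <- as.numeric(observed)
    if (is.null(n_cells)) stop("n_cells required when observed is pre-binned")
  } else {
    if (is.null(n_cells)) n_cells <- sum(!is.na(observed))
    obs <- cn_histogram(observed, max_cn = n_bins - 1L)
  }
  tol <- 1 / (10 * n_cells)
  n_states <- ncol(expected)
  sad_of <- function(w) sum(abs(obs - drop(expected %*% w)))

  # start on the vertex with smallest SAD (ties -> lowest state index)
  vertex_sad <- vapply(seq_len(n_states), function(s) {
    sum(abs(obs - expected[, s]))
  }, numeric(1))
  w <- numeric(n_states)
  w[which.min(vertex_sad)] <- 1
  sad <- sad_of(w)

  step <- 0.5
  iter <- 0L
  converged <- sad <= tol
  while (iter < max_iter && sad > tol && step > 1e-8) {
    iter <- iter + 1L
    best <- NULL
    best_sad <- sad - 1e-14
    for (from in seq_len(n_states)) {
      if (w[from] <= 0) next
      delta <- min(step, w[from])
      for (to in seq_len(n_states)) {
        if (to == from) next
        w2 <- w
        w2[from] <- w2[from] - delta
        w2[to] <- w2[to] + delta
        s2 <- sad_of(w2)
        if (s2 < best_sad) {
          best_sad <- s2
          best <- w2
        }
      }
    }
    if (is.null(best)) {
      step <- step / 2
    } else {
      w <- best
      sad <- best_sad
    }
  }
  if (sad <= tol) converged <- TRUE else converged <- step <= 1e-8
  names(w) <- colnames(expected)
  structure(list(weights = w, sad = sad, n_iter = iter,
                 converged = converged),
            class = "mixture_estimate")
}

#' Run the full weighted-mixture correction for a set of calls
#'
#' Convenience wrapper: builds the per-state expected call distributions
#' (simulated reference of `sim_factor` times the observed cell count per
#' state) and fits the mixture weights.
#'
#' @param calls A `vcn_calls` data.frame (or integer call vector).
#' @param model_set A `vcn_model_set`.
#' @param corr_model A `vcn_corr`.
#' @param max_cn Top of the copy-number grid (default 9).
#' @param sim_factor Simulated reference cells per state as a multiple of
#'   the observed cell count (default 10).
#' @param seed Optional integer seed for the reference simulation.
#' @param max_iter Maximum mixture iterations.
#' @return A `mixture_estimate`.
#' @export
run_wmm <- function(calls, model_set, corr_model, max_cn = 9L,
                    sim_factor = 10, seed = NULL, max_iter = 1000L) {
  cn <- if (inherits(calls, "vcn_calls")) calls$cn else as.integer(calls)
  cn <- cn[!is.na(cn)]
  n_cells <- length(cn)
  expected <- expected_call_dists(model_set, corr_model,
                                  n_per_state = ceiling(sim_factor * n_cells),
                                  max_cn = max_cn, seed = seed)
  fit_mixture(cn, expected, n_cells = n_cells, max_iter = max_iter)
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("mixture_estimate (weighted mixture method)\n")
  cat(sprintf("  SAD %.3g after %d iteration(s), converged: %s\n",
              x$sad, x$n_iter, x$converged))
  top <- x$weights[x$weights > 0.001]
  cat("  weights:", paste(sprintf("CN%s=%.3f", names(top), top),
                          collapse = ", "), "\n")
  invisible(x)
}

# Evaluate `code` under a locally set RNG seed, restoring the caller's
# RNG state afterwards; with seed = NULL the code runs on the current RNG.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
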