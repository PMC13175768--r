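#' Caller configuration
#'
#' @param max_cn Top of the copy-number grid (default 9, giving reporting
#'   bins CN 0 through CN 9; cells called at the top of the grid are
#'   flagged `saturated`).
#' @param min_quality Minimum log-likelihood gap required to keep a call;
#'   calls below it get `cn = NA`. Defaults to 0 (no quality filtering).
#' @param per_amplicon Also compute diagnostic per-amplicon copy-number
#'   calls (default `FALSE`). The cell-level call is authoritative.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(max_cn = 9L, min_quality = 0, per_amplicon = FALSE) {
  max_cn <- as.integer(max_cn)
  if (max_cn < 1L) stop("max_cn must be >= 1")
  structure(list(max_cn = max_cn, min_quality = min_quality,
                 per_amplicon = per_amplicon),
            class = "caller_config")
}

#' Log-likelihood of a count under one copy-number state
#'
#' Log NB probability mass of `count` for one vector amplicon under the
#' mean and variance predicted for copy number `cn` at the cell's total
#' read depth. Underflow is floored at a large negative finite value so
#' sums over amplicons stay finite.
#'
#' @param model_set A `vcn_model_set`.
#' @param model The `amplicon_model` for this amplicon.
#' @param count Observed read count(s) (integer >= 0).
#' @param total_reads Per-cell total read depth(s) (> 0).
#' @param cn Copy-number state.
#' @return Log-likelihood value(s).
#' @export
amplicon_loglik <- function(model_set, model, count, total_reads, cn) {
  mu <- predict_mean(model, total_reads, cn, cn0_floor = model_set$cn0_floor)
  a <- alpha_for_cn(model_set, model, cn)
  ll <- stats::dnbinom(count, size = 1 / a, mu = mu, log = TRUE)
  pmax(ll, -1e12)
}

# Vectorized caller over a cells x amplicons matrix of vector counts.
# Returns cn (NA where totals == 0), quality, and the loglik matrix.
call_matrix <- function(model_set, vec_counts, totals, max_cn) {
  n <- length(totals)
  states <- 0:max_cn
  ok <- totals > 0
  loglik <- matrix(-Inf, n, length(states),
                   dimnames = list(NULL, as.character(states)))
  if (any(ok)) {
    t_ok <- totals[ok]
    for (s in seq_along(states)) {
      ll <- 0
      for (m in model_set$models) {
        ll <- ll + amplicon_loglik(model_set, m,
                                   vec_counts[ok, m$amplicon_id],
                                   t_ok, states[s])
      }
      loglik[ok, s] <- ll
    }
  }
  cn <- rep(NA_integer_, n)
  quality <- rep(0, n)
  if (any(ok)) {
    sub <- loglik[ok, , drop = FALSE]
    best <- max.col(sub, ties.method = "first")  # ties -> lower cn
    top <- sub[cbind(seq_len(nrow(sub)), best)]
    sub[cbind(seq_len(nrow(sub)), best)] <- -Inf
    second <- do.call(pmax, as.data.frame(sub))
    cn[ok] <- states[best]
    quality[ok] <- top - second
  }
  list(cn = cn, quality = quality, loglik = loglik)
}

#' Call per-cell copy number for every cell of a run
#'
#' For each cell, per-amplicon NB log-likelihoods are summed across all
#' retained vector amplicons for each copy-number state on the grid
#' `0..max_cn`; the called copy number is the state with the highest
#' summed log-likelihood, and call quality is the gap between the highest
#' and second-highest state. Ties are broken toward the lower copy number
#' (conservative with respect to insertional load) with quality 0. Cells
#' with zero total reads are uncallable (`cn = NA`, quality 0).
#'
#' @param run A `vcn_run` (test cells).
#' @param model_set A `vcn_model_set` from [fit_model_set()].
#' @param config A [caller_config()].
#' @return A data.frame of class `vcn_calls` with columns `barcode`, `cn`,
#'   `quality`, `transduced`, `saturated`; the summed log-likelihood
#'   matrix is attached as attribute `"loglik"` and, when requested,
#'   per-amplicon calls as attribute `"per_amplicon_cn"`.
#' @export
call_cells <- function(run, model_set, config = caller_config()) {
  ids <- names(model_set$models)
  missing <- setdiff(ids, colnames(run$counts))
  if (length(missing) > 0L) {
    stop("run lacks modelled amplicon(s): ", paste(missing, collapse = ", "))
  }
  totals <- total_reads(run, mode = model_set$total_mode)
  vec_counts <- run$counts[, ids, drop = FALSE]
  res <- call_matrix(model_set, vec_counts, totals, config$max_cn)
  cn <- res$cn
  if (config$min_quality > 0) {
    cn[!is.na(cn) & res$quality < config$min_quality] <- NA_integer_
  }
  calls <- data.frame(barcode = rownames(run$counts),
                      cn = cn,
                      quality = res$quality,
                      transduced = call_transduction(cn),
                      saturated = !is.na(cn) & cn == config$max_cn,
                      stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  attr(calls, "loglik") <- res$loglik
  if (isTRUE(config$per_amplicon)) {
    pa <- sapply(ids, function(id) {
      one <- call_matrix(model_set_subset(model_set, id),
                         vec_counts[, id, drop = FALSE], totals,
                         config$max_cn)
      one$cn
    })
    attr(calls, "per_amplicon_cn") <- pa
  }
  class(calls) <- c("vcn_calls", "data.frame")
  calls
}

# Restrict a model set to a single amplicon (diagnostic per-amplicon calls).
model_set_subset <- function(model_set, ids) {
  model_set$models <- model_set$models[ids]
  model_set
}

#' Call one cell
#'
#' Convenience wrapper around the vectorized caller for a single cell.
#'
#' @param model_set A `vcn_model_set`.
#' @param cell_counts Named integer vector of vector-amplicon counts.
#' @param total_reads The cell's total read depth.
#' @param config A [caller_config()].
#' @return A list with `cn`, `quality`, `loglik_by_cn`.
#' @export
call_cell <- function(model_set, cell_counts, total_reads,
                      config = caller_config()) {
  m <- matrix(cell_counts, nrow = 1,
              dimnames = list("cell", names(cell_counts)))
  res <- call_matrix(model_set, m, total_reads, config$max_cn)
  list(cn = res$cn[1], quality = res$quality[1],
       loglik_by_cn = res$loglik[1, ])
}

#' Transduction status from a copy-number call
#'
#' A cell is transduced iff its called copy number is greater than 0.
#' `NA` calls propagate.
#'
#' @param cn Integer copy-number call(s), or a `vcn_calls` data.frame.
#' @return Logical vector.
#' @export
call_transduction <- function(cn) {
  if (inherits(cn, "vcn_calls")) cn <- cn$cn
  cn > 0L
}
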