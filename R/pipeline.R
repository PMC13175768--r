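#' Run the full copy-number pipeline on a test run
#'
#' Convenience wrapper chaining the standard analysis: fit the amplicon
#' models on the control cells, call per-cell copy number on the test
#' cells, estimate the residual correlation, correct the population
#' proportions with the weighted mixture method, and summarise.
#'
#' @param run Test `vcn_run`.
#' @param control_run Control `vcn_run` (cells of known copy number).
#' @param control_cn Known copy number of the control cells.
#' @param max_cn Top of the copy-number grid (default 9).
#' @param wmm Apply the weighted-mixture correction (default `TRUE`).
#' @param sim_factor Simulated reference size per state, as a multiple of
#'   the test cell count (default 10).
#' @param seed Optional integer seed for the reference simulation.
#' @param ... Passed to [fit_model_set()].
#' @return List with `model_set`, `calls`, `corr`, `mixture` (or `NULL`),
#'   `summary` (a `transduction_summary` from the corrected weights when
#'   available, else from the raw calls).
#' @export
vcn_pipeline <- function(run, control_run, control_cn, max_cn = 9L,
                         wmm = TRUE, sim_factor = 10, seed = NULL, ...) {
  model_set <- fit_model_set(control_run, control_cn, ...)
  calls <- call_cells(run, model_set, caller_config(max_cn = max_cn))
  corr <- estimate_residual_correlation(control_run, model_set)
  mixture <- NULL
  if (isTRUE(wmm)) {
    mixture <- run_wmm(calls, model_set, corr, max_cn = max_cn,
                       sim_factor = sim_factor, seed = seed)
  }
  summary <- summarize_transduction(if (is.null(mixture)) calls else mixture,
                                    max_cn = max_cn)
  list(model_set = model_set, calls = calls, corr = corr,
       mixture = mixture, summary = summary)
}
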