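#' Fit the three-parameter negative-binomial model for one vector amplicon
#'
#' Control cells with a known integer vector copy number anchor the model.
#' The amplicon's read count in a cell is modelled as negative binomial
#' with
#' \deqn{\log(\mathrm{mean}) = const + x1 \cdot \log(\mathrm{total\ reads})}
#' \deqn{\mathrm{variance} = \mathrm{mean} + \alpha \cdot \mathrm{mean}^2}
#' `const` captures the amplicon's overall efficiency, `x1` the strength of
#' its dependence on the cell's total read depth, and `alpha` the
#' cell-to-cell overdispersion. Fitting is by profile maximum likelihood:
#' at fixed `alpha`, `(const, x1)` are obtained by iteratively reweighted
#' least squares with a log link; `alpha` is maximised by bounded 1-D
#' optimisation of the profile log-likelihood, started from a
#' method-of-moments estimate.
#'
#' @param counts Integer vector of per-cell read counts for this amplicon.
#' @param totals Numeric vector of per-cell total read depths (same order).
#'   Cells with `totals == 0` are excluded from fitting.
#' @param control_cn Known copy number of the control cells (>= 1).
#' @param amplicon_id Identifier stored on the model.
#' @param alpha_bounds Search interval for `alpha` (default `c(1e-8, 10)`).
#' @return An object of class `amplicon_model`: a list with elements
#'   `amplicon_id`, `const`, `x1`, `alpha`, `control_cn`, `mean_reads`,
#'   `loglik`, `n_cells`.
#' @export
fit_amplicon_model <- function(counts, totals, control_cn,
                               amplicon_id = "amplicon",
                               alpha_bounds = c(1e-8, 10)) {
  stopifnot(length(counts) == length(totals))
  keep <- totals > 0
  y <- as.numeric(counts[keep])
  t <- as.numeric(totals[keep])
  if (length(y) < 30L) {
    stop("need >= 30 control cells with positive totals to fit amplicon '",
         amplicon_id, "'")
  }
  if (all(y == 0)) {
    stop("all counts zero for amplicon '", amplicon_id,
         "' (should have been removed by the depth filter)")
  }
  control_cn <- as.integer(control_cn)
  if (control_cn < 1L) stop("control_cn must be >= 1")

  X <- cbind(1, log(t))
  # method-of-moments start for alpha from Poisson-fit Pearson residuals
  beta0 <- nb_irls(X, y, alpha = 0)
  mu0 <- exp(pmin(X %*% beta0, 700))
  alpha_mom <- max((mean((y - mu0)^2 / mu0) - 1) / mean(mu0), alpha_bounds[1])
  alpha_mom <- min(alpha_mom, alpha_bounds[2])

  profile_ll <- function(log_alpha) {
    a <- exp(log_alpha)
    beta <- nb_irls(X, y, alpha = a)
    nb_loglik(y, exp(pmin(X %*% beta, 700)), a)
  }
  opt <- stats::optimize(profile_ll, interval = log(alpha_bounds),
                         maximum = TRUE, tol = 1e-6)
  # seed the line search near the moment estimate as well; keep the better
  ll_mom <- profile_ll(log(alpha_mom))
  if (ll_mom > opt$objective) {
    opt <- list(maximum = log(alpha_mom), objective = ll_mom)
  }
  # the Poisson submodel (alpha at the lower bound) must never win
  ll_lo <- profile_ll(log(alpha_bounds[1]))
  if (ll_lo >= opt$objective) {
    opt <- list(maximum = log(alpha_bounds[1]), objective = ll_lo)
  }
  alpha_hat <- exp(opt$maximum)
  beta_hat <- nb_irls(X, y, alpha = alpha_hat)

  structure(list(amplicon_id = amplicon_id,
                 const = unname(beta_hat[1]),
                 x1 = unname(beta_hat[2]),
                 alpha = alpha_hat,
                 control_cn = control_cn,
                 mean_reads = mean(y),
                 loglik = opt$objective,
                 n_cells = length(y)),
            class = "amplicon_model")
}

# IRLS for a log-link NB mean model with fixed dispersion alpha.
# Weights mu/(1 + alpha*mu) are the inverse variance on the link scale.
nb_irls <- function(X, y, alpha, max_iter = 50L, tol = 1e-10) {
  beta <- stats::coef(stats::lm.fit(X, log(y + 0.5)))
  for (i in seq_len(max_iter)) {
    eta <- pmin(X %*% beta, 700)
    mu <- pmax(exp(eta), 1e-12)
    w <- as.vector(mu / (1 + alpha * mu))
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  drop(beta)
}

# NB log-likelihood in the mean/dispersion parameterization
# (size = 1/alpha, variance = mu + alpha mu^2); Poisson at alpha -> 0.
nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-10) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  }
}

#' Fit amplicon models for all retained vector amplicons of a run
#'
#' Applies the vector-amplicon depth filter to the control cells, fits one
#' [fit_amplicon_model()] per retained vector amplicon, and fits the
#' cross-amplicon dispersion extrapolator. The per-cell total-read
#' covariate is computed over human amplicons only by default, so that the
#' covariate does not itself depend on vector copy number.
#'
#' @param run A `vcn_run` containing the control cells (and possibly test
#'   cells).
#' @param control A `vcn_control_spec`, or an integer copy number when
#'   every cell of `run` is a control cell.
#' @param cn0_floor Background fraction used for the copy-number-0 state:
#'   the CN-0 mean is `cn0_floor / control_cn` of the control-level mean,
#'   representing ambient reads / barcode hopping (default 0.05).
#' @param total_mode `"human"` (default) or `"all"`: which amplicons enter
#'   the per-cell total.
#' @param min_mean Vector-amplicon depth filter threshold passed to
#'   [filter_vector_amplicons()] (computed over the control cells).
#' @param extrapolator_degree Polynomial degree of the dispersion
#'   extrapolator (default 1).
#' @return An object of class `vcn_model_set`: list with `models` (named
#'   list of `amplicon_model`), `extrapolator`, `control_cn`, `cn0_floor`,
#'   `total_mode`, `excluded`, `control_totals`.
#' @export
fit_model_set <- function(run, control, cn0_floor = 0.05,
                          total_mode = c("human", "all"),
                          min_mean = 5.0, extrapolator_degree = 1L) {
  total_mode <- match.arg(total_mode)
  if (is.numeric(control)) control <- control_spec(control_cn = control)
  if (!inherits(control, "vcn_control_spec")) {
    stop("control must be a vcn_control_spec or an integer copy number")
  }
  ctrl_run <- resolve_control_run(run, control)
  flt <- filter_vector_amplicons(ctrl_run, min_mean = min_mean)
  ctrl_run <- flt$run
  totals <- total_reads(ctrl_run, mode = total_mode)
  vec_ids <- ctrl_run$panel$amplicon_id[ctrl_run$panel$class == "vector"]
  models <- lapply(vec_ids, function(id) {
    fit_amplicon_model(ctrl_run$counts[, id], totals,
                       control_cn = control$control_cn, amplicon_id = id)
  })
  names(models) <- vec_ids
  extrap <- fit_alpha_extrapolator(models, degree = extrapolator_degree)
  structure(list(models = models,
                 extrapolator = extrap,
                 control_cn = control$control_cn,
                 cn0_floor = cn0_floor,
                 total_mode = total_mode,
                 excluded = flt$excluded,
                 control_totals = unname(totals[totals > 0])),
            class = "vcn_model_set")
}

# Subset the run (or a referenced external run) to the control cells.
resolve_control_run <- function(run, control) {
  if (!is.null(control$control_run)) {
    cr <- control$control_run
    if (is.character(cr)) stop("control_run paths must be loaded before fitting; ",
                               "pass the vcn_run object")
    if (!inherits(cr, "vcn_run")) stop("control_run must be a vcn_run")
    run <- cr
  }
  if (!is.null(control$control_cells)) {
    missing <- setdiff(control$control_cells, rownames(run$counts))
    if (length(missing) > 0L) {
      stop("control cells absent from run: ", paste(utils::head(missing, 3),
                                                    collapse = ", "))
    }
    run$counts <- run$counts[control$control_cells, , drop = FALSE]
  }
  run
}

#' Fit the cross-amplicon dispersion extrapolator
#'
#' Dispersion for copy-number states other than the control state is
#' extrapolated from the trend of fitted `alpha` against average amplicon
#' read depth across all retained vector amplicons: a least-squares
#' polynomial (default degree 1) of `log(alpha)` on `log(mean_reads)`.
#' Amplicons with higher mean reads tend to have lower dispersion, so the
#' fitted slope is typically negative.
#'
#' @param models List of `amplicon_model` objects.
#' @param degree Polynomial degree (default 1).
#' @return List with `degree`, `coef` (intercept-first polynomial
#'   coefficients on the log-log scale) and `residual_sd`, or `NULL` with a
#'   warning when fewer than 3 models are available (each amplicon then
#'   falls back to its own fitted `alpha`).
#' @export
fit_alpha_extrapolator <- function(models, degree = 1L) {
  if (length(models) < 3L) {
    warning("fewer than 3 amplicon models; falling back to per-amplicon ",
            "constant alpha")
    return(NULL)
  }
  x <- log(vapply(models, function(m) m$mean_reads, numeric(1)))
  y <- log(pmax(vapply(models, function(m) m$alpha, numeric(1)), 1e-8))
  degree <- min(degree, length(models) - 1L)
  fit <- stats::lm(y ~ stats::poly(x, degree = degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  list(degree = degree, coef = coefs,
       residual_sd = stats::sd(stats::residuals(fit)))
}

# Evaluate an intercept-first polynomial.
polyval <- function(coef, x) {
  out <- 0
  for (k in rev(seq_along(coef))) out <- out * x + coef[k]
  out
}

#' Predicted mean read count for a copy-number state
#'
#' The control-anchored mean `exp(const + x1 log(total))` is scaled
#' linearly by copy number relative to the control copy number. Copy
#' number 0 uses the background floor `cn0_floor` in place of 0, so that
#' untransduced cells are modelled as carrying a small ambient fraction of
#' the per-copy signal rather than an impossible zero-mean distribution.
#'
#' @param model An `amplicon_model`.
#' @param total_reads Per-cell total read depth(s), > 0.
#' @param cn Copy-number state (integer >= 0).
#' @param cn0_floor Background fraction substituted for `cn = 0`
#'   (default 0.05).
#' @return Predicted mean(s), same length as `total_reads`.
#' @export
predict_mean <- function(model, total_reads, cn, cn0_floor = 0.05) {
  if (any(total_reads <= 0)) stop("total_reads must be > 0")
  if (cn < 0 || cn != round(cn)) stop("cn must be a non-negative integer")
  base <- exp(model$const + model$x1 * log(total_reads))
  base * max(cn, cn0_floor) / model$control_cn
}

#' Dispersion for a copy-number state
#'
#' At the control copy number the amplicon's own fitted `alpha` is used.
#' For other states `alpha` is taken from the cross-amplicon extrapolator
#' evaluated at the amplicon's mean read depth, scaled by
#' `control_cn / max(cn, cn0_floor)` so that relative cell-to-cell
#' variability shrinks as copy number grows, and clipped below at 1e-8.
#'
#' @param model_set A `vcn_model_set` (carries the extrapolator).
#' @param model The `amplicon_model` being evaluated.
#' @param cn Copy-number state (integer >= 0).
#' @return Scalar dispersion `alpha_cn >= 1e-8`.
#' @export
alpha_for_cn <- function(model_set, model, cn) {
  if (cn == model$control_cn) return(max(model$alpha, 1e-8))
  base <- if (is.null(model_set$extrapolator)) {
    model$alpha
  } else {
    exp(polyval(model_set$extrapolator$coef, log(model$mean_reads)))
  }
  scale <- model$control_cn / max(cn, model_set$cn0_floor)
  min(max(base * scale, 1e-8), 1e8)
}

#' Predicted variance for a copy-number state
#'
#' `variance = mean + alpha_cn * mean^2` with `alpha_cn` from
#' [alpha_for_cn()].
#'
#' @param model_set A `vcn_model_set`.
#' @param model An `amplicon_model`.
#' @param mean Predicted mean(s) (> 0).
#' @param cn Copy-number state.
#' @return Predicted variance(s).
#' @export
predict_variance <- function(model_set, model, mean, cn) {
  a <- alpha_for_cn(model_set, model, cn)
  mean + a * mean^2
}

#' Serialize a model set to JSON
#'
#' Per-amplicon `{amplicon_id, const, x1, alpha, control_cn, mean_reads}`
#' plus the extrapolator coefficients, with stable field order.
#'
#' @param model_set A `vcn_model_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(model_set, path) {
  payload <- list(
    control_cn = model_set$control_cn,
    cn0_floor = model_set$cn0_floor,
    total_mode = model_set$total_mode,
    excluded = model_set$excluded,
    models = lapply(unname(model_set$models), function(m) {
      m[c("amplicon_id", "const", "x1", "alpha", "control_cn",
          "mean_reads", "n_cells")]
    }),
    extrapolator = model_set$extrapolator,
    control_totals = model_set$control_totals
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model set written by [write_models()]
#'
#' @param path Path to a models JSON file.
#' @return A `vcn_model_set`.
#' @export
read_models <- function(path) {
  payload <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- lapply(payload$models, function(m) {
    m$control_cn <- as.integer(m$control_cn)
    structure(m, class = "amplicon_model")
  })
  names(models) <- vapply(models, function(m) m$amplicon_id, character(1))
  extrap <- payload$extrapolator
  if (!is.null(extrap)) extrap$coef <- as.numeric(unlist(extrap$coef))
  structure(list(models = models,
                 extrapolator = extrap,
                 control_cn = as.integer(payload$control_cn),
                 cn0_floor = payload$cn0_floor,
                 total_mode = payload$total_mode,
                 excluded = as.character(unlist(payload$excluded)),
                 control_totals = as.numeric(unlist(payload$control_totals))),
            class = "vcn_model_set")
}

#' @export
print.vcn_model_set <- function(x, ...) {
  cat(sprintf("vcn_model_set: %d vector amplicon model(s), control CN %d\n",
              length(x$models), x$control_cn))
  invisible(x)
}
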