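#' Simulation configuration
#'
#' Builds the configuration for the synthetic-run generator. Numeric
#' defaults live in the packaged defaults file
#' (`extdata/sim_defaults.yaml`) and describe a typical targeted
#' single-cell DNA run: 99 human + 11 vector amplicons at a median
#' per-amplicon coverage of 58 reads per cell, lognormal per-cell total
#' depth, amplicon efficiency spread, dispersion decreasing with amplicon
#' depth, and residual inter-amplicon correlation.
#'
#' Exactly one of `composition` (named fractions over integer copy
#' numbers, summing to 1) or `poisson_mu` (independent-transduction
#' Poisson mean) defines the copy-number law.
#'
#' @param n_cells Number of cells to simulate.
#' @param composition Named numeric vector, e.g. `c("0" = .1, "1" = .9)`.
#' @param poisson_mu Poisson mean for the copy-number law.
#' @param seed Integer seed; all outputs are bit-reproducible given the
#'   full configuration.
#' @param run_id Run identifier.
#' @param ... Overrides for any defaults-file field (`coverage_median`,
#'   `n_human_amplicons`, `n_vector_amplicons`, `total_cv`,
#'   `efficiency_sd`, `x1_range`, `alpha_base`, `alpha_slope`,
#'   `alpha_jitter_sd`, `alpha_range`, `residual_corr`,
#'   `cn0_background`, `doublet_rate`).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_cells = 4000L, composition = NULL,
                              poisson_mu = NULL, seed = 1L,
                              run_id = "sim", ...) {
  cfg <- sim_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (is.null(composition) == is.null(poisson_mu)) {
    stop("give exactly one of composition or poisson_mu")
  }
  if (!is.null(composition)) {
    if (is.null(names(composition))) {
      stop("composition must be named by copy number")
    }
    if (abs(sum(composition) - 1) > 1e-6) {
      stop("composition fractions must sum to 1")
    }
  } else if (poisson_mu < 0) {
    stop("poisson_mu must be >= 0")
  }
  if (cfg$coverage_median <= 0) stop("coverage_median must be > 0")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    stop("doublet_rate must be in [0, 1)")
  }
  cfg$n_cells <- as.integer(n_cells)
  cfg$composition <- composition
  cfg$poisson_mu <- poisson_mu
  cfg$seed <- as.integer(seed)
  cfg$run_id <- run_id
  structure(cfg, class = "sim_config")
}

sim_defaults <- function() {
  path <- system.file("extdata", "sim_defaults.yaml", package = "scvcn")
  if (path == "") stop("packaged simulation defaults not found")
  yaml::read_yaml(path)
}

#' Simulate the amplicon panel and its generative parameters
#'
#' Draws per-amplicon efficiency weights (lognormal), depth slopes `x1`
#' (uniform on `x1_range`), and dispersions `alpha` coupled to efficiency
#' so that deeper amplicons are less overdispersed, then anchors the
#' intercepts `const` so that the panel-wide expected total equals the
#' cell's total depth at the median coverage (human amplicons at the
#' diploid level, vector amplicons per copy). The same panel object is
#' shared between control and test runs so they obey one generative law.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_panel` with elements `panel`
#'   (a `vcn_panel`) and `params` (per-amplicon data.frame with `w`,
#'   `x1`, `alpha`, `const`).
#' @export
simulate_panel <- function(config) {
  with_local_seed(config$seed, {
    n_h <- config$n_human_amplicons
    n_v <- config$n_vector_amplicons
    n_amp <- n_h + n_v
    t0 <- config$coverage_median * n_amp
    ids <- c(sprintf("HUM_%03d", seq_len(n_h)),
             sprintf("VEC_%03d", seq_len(n_v)))
    cls <- c(rep("human", n_h), rep("vector", n_v))
    w <- stats::rlnorm(n_amp, 0, config$efficiency_sd)
    w <- w / sum(w)
    x1 <- stats::runif(n_amp, config$x1_range[1], config$x1_range[2])
    la <- log(config$alpha_base) +
      config$alpha_slope * (log(w) - mean(log(w))) +
      stats::rnorm(n_amp, 0, config$alpha_jitter_sd)
    alpha <- pmin(pmax(exp(la), config$alpha_range[1]),
                  config$alpha_range[2])
    # human amplicons carry the diploid level; vector consts are per copy
    level <- ifelse(cls == "human", w * t0, w * t0 / 2)
    const <- log(level) - x1 * log(t0)
    panel <- as_vcn_panel(data.frame(amplicon_id = ids, class = cls,
                                     target = ids,
                                     stringsAsFactors = FALSE))
    params <- data.frame(amplicon_id = ids, class = cls, w = w, x1 = x1,
                         alpha = alpha, const = const,
                         stringsAsFactors = FALSE)
    structure(list(panel = panel, params = params, t0 = t0),
              class = "sim_panel")
  })
}

# Draw counts for a set of cells given their true copy numbers.
# Vector amplicons share an exchangeable Gaussian-copula correlation.
sim_draw_cells <- function(sim_panel, cn, config) {
  n <- length(cn)
  p <- sim_panel$params
  t0 <- sim_panel$t0
  sdlog <- sqrt(log(1 + config$total_cv^2))
  totals <- stats::rlnorm(n, log(t0), sdlog)
  counts <- matrix(0L, n, nrow(p),
                   dimnames = list(NULL, p$amplicon_id))
  is_h <- p$class == "human"
  for (j in which(is_h)) {
    mu <- exp(p$const[j] + p$x1[j] * log(totals))
    counts[, j] <- stats::rnbinom(n, size = 1 / p$alpha[j], mu = mu)
  }
  vj <- which(!is_h)
  pv <- length(vj)
  rho <- config$residual_corr
  R <- matrix(rho, pv, pv); diag(R) <- 1
  z <- matrix(stats::rnorm(n * pv), n, pv) %*% chol(R)
  u <- pmin(pmax(stats::pnorm(z), 1e-12), 1 - 1e-12)
  cn_factor <- pmax(cn, config$cn0_background)
  # dispersion anchored at the diploid-equivalent level, shrinking with CN
  alpha_scale <- ifelse(cn >= 1, 2 / cn, 1)
  for (k in seq_len(pv)) {
    j <- vj[k]
    mu <- exp(p$const[j] + p$x1[j] * log(totals)) * cn_factor
    counts[, j] <- as.integer(stats::qnbinom(u[, k],
                                             size = 1 / (p$alpha[j] * alpha_scale),
                                             mu = mu))
  }
  list(counts = counts, totals = totals)
}

# Draw true copy numbers from the configured law.
sim_draw_cn <- function(n, config) {
  if (!is.null(config$composition)) {
    states <- as.integer(names(config$composition))
    states[sample.int(length(states), n, replace = TRUE,
                      prob = config$composition)]
  } else {
    stats::rpois(n, config$poisson_mu)
  }
}

#' Simulate a single-cell run with known ground truth
#'
#' Generates a cell x amplicon count matrix with the statistical
#' structure the copy-number model assumes: per-cell total depth is
#' lognormal around the configured median coverage; human amplicon counts
#' are NB at the diploid level with log mean linear in log total; vector
#' amplicon counts are NB with mean proportional to the cell's true copy
#' number (untransduced cells carry a small ambient background fraction)
#' and with exchangeable residual correlation injected through a Gaussian
#' copula; optional doublets are formed by summing the counts of two
#' independently drawn cells.
#'
#' @param config A [simulation_config()].
#' @param panel Optional [simulate_panel()] output; pass the same object
#'   to control and test runs so they share one generative law. When
#'   `NULL` a panel is derived from the config.
#' @return A list of class `sim_run` with `run` (a `vcn_run`), `truth`
#'   (data.frame: `barcode`, `true_cn`, `is_doublet`, `parent_cn1`,
#'   `parent_cn2`, `transduced`) and `panel` (the `sim_panel`).
#' @export
simulate_run <- function(config, panel = NULL) {
  if (is.null(panel)) panel <- simulate_panel(config)
  with_local_seed(config$seed + 1L, {
    n <- config$n_cells
    cn <- sim_draw_cn(n, config)
    cells <- sim_draw_cells(panel, cn, config)
    true_cn <- as.numeric(cn)
    is_doublet <- rep(FALSE, n)
    parent1 <- rep(NA_integer_, n)
    parent2 <- rep(NA_integer_, n)
    n_d <- round(n * config$doublet_rate)
    if (n_d > 0) {
      idx <- sample.int(n, n_d)
      cn_partner <- sim_draw_cn(n_d, config)
      partners <- sim_draw_cells(panel, cn_partner, config)
      cells$counts[idx, ] <- cells$counts[idx, , drop = FALSE] +
        partners$counts
      cells$totals[idx] <- cells$totals[idx] + partners$totals
      is_doublet[idx] <- TRUE
      parent1[idx] <- cn[idx]
      parent2[idx] <- cn_partner
      true_cn[idx] <- (cn[idx] + cn_partner) / 2
    }
    barcodes <- sprintf("%s_cell_%06d", config$run_id, seq_len(n))
    rownames(cells$counts) <- barcodes
    run <- new_vcn_run(cells$counts, panel$panel, run_id = config$run_id)
    truth <- data.frame(barcode = barcodes,
                        true_cn = true_cn,
                        is_doublet = is_doublet,
                        parent_cn1 = parent1,
                        parent_cn2 = parent2,
                        transduced = true_cn > 0,
                        stringsAsFactors = FALSE)
    structure(list(run = run, truth = truth, panel = panel),
              class = "sim_run")
  })
}

#' Simulate a single-copy-number control run
#'
#' Same generative law as [simulate_run()] restricted to one copy-number
#' state, suitable as the control input of [fit_model_set()].
#'
#' @param config A [simulation_config()] (its composition/poisson fields
#'   are ignored).
#' @param control_cn Copy number of every control cell (>= 1).
#' @param panel A [simulate_panel()] object shared with the test run.
#' @param seed Optional seed override for the control run's cells.
#' @return A `sim_run` list.
#' @export
simulate_control_run <- function(config, control_cn, panel = NULL,
                                 seed = NULL) {
  control_cn <- as.integer(control_cn)
  if (control_cn < 1L) stop("control_cn must be >= 1")
  cfg <- config
  cfg$composition <- stats::setNames(1, as.character(control_cn))
  cfg$poisson_mu <- NULL
  cfg$doublet_rate <- 0
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$run_id <- sprintf("%s_ctrl_cn%d", config$run_id, control_cn)
  simulate_run(cfg, panel = panel)
}

#' Inject a vector variant and simulate per-cell allele depths
#'
#' For a vector mutation carried on `m` of the integrated copies, each
#' transduced cell's variant allele fraction is `m / true_cn`; allele
#' depths are binomial at that fraction with Poisson-distributed total
#' depth. Untransduced cells get zero depth.
#'
#' @param truth Truth data.frame from [simulate_run()].
#' @param m Number of mutated copies (must not exceed any transduced
#'   cell's `true_cn`).
#' @param mean_depth Mean per-cell depth at the variant site (default 40).
#' @param seed Optional integer seed.
#' @return A data.frame with `barcode`, `ref`, `alt`.
#' @export
inject_vector_variant <- function(truth, m, mean_depth = 40, seed = NULL) {
  with_local_seed(seed, {
    cn <- truth$true_cn
    pos <- !is.na(cn) & cn >= 1
    if (m < 0) stop("m must be >= 0")
    if (m > 0 && any(cn[pos] < m)) {
      stop("m exceeds true_cn for some transduced cells")
    }
    depth <- integer(length(cn))
    depth[pos] <- stats::rpois(sum(pos), mean_depth)
    vaf <- ifelse(pos, ifelse(cn > 0, m / cn, 0), 0)
    alt <- integer(length(cn))
    alt[pos] <- stats::rbinom(sum(pos), depth[pos], vaf[pos])
    data.frame(barcode = truth$barcode,
               ref = depth - alt,
               alt = alt,
               stringsAsFactors = FALSE)
  })
}

#' Simulate germline genotype data for cell-line demultiplexing
#'
#' Each line carries a block of `n_variants_per_line` biallelic sites at
#' which it is homozygous-alt while the other lines are homozygous-ref
#' (mimicking a panel of discriminating common SNPs). Per-cell allele
#' depths are Poisson with binomial allele sampling; a small genotype
#' error rate flips the generating genotype and a dropout rate zeroes a
#' site's depth. Doublet cells mix the allele fractions of two lines.
#'
#' @param n_cells Number of cells.
#' @param line_fractions Named fractions over lines (summing to 1).
#' @param n_variants_per_line Discriminating sites per line (default 50).
#' @param mean_depth Mean site depth (default 20).
#' @param error_rate Genotype error rate (default 0.01).
#' @param dropout_rate Per-site missing rate (default 0.10).
#' @param doublet_rate Fraction of cross-line doublets (default 0).
#' @param seed Integer seed.
#' @return List with `ref`, `alt` (cells x variants matrices), `db`
#'   (reference genotype database for [demultiplex()]), `line` (truth
#'   labels; doublets are `"doublet:A+B"`).
#' @export
simulate_germline <- function(n_cells, line_fractions,
                              n_variants_per_line = 50L, mean_depth = 20,
                              error_rate = 0.01, dropout_rate = 0.10,
                              doublet_rate = 0, seed = 1L) {
  with_local_seed(seed, {
    lines <- names(line_fractions)
    n_lines <- length(lines)
    nv <- n_variants_per_line * n_lines
    var_ids <- sprintf("var_%03d", seq_len(nv))
    block <- rep(seq_len(n_lines), each = n_variants_per_line)
    db <- lapply(seq_len(n_lines), function(l) {
      stats::setNames(ifelse(block == l, "1/1", "0/0"), var_ids)
    })
    names(db) <- lines
    line <- sample(lines, n_cells, replace = TRUE, prob = line_fractions)
    frac_of <- function(ln) ifelse(db[[ln]][var_ids] == "1/1", 0.99, 0.01)
    f <- t(vapply(line, frac_of, numeric(nv)))
    n_d <- round(n_cells * doublet_rate)
    if (n_d > 0 && n_lines > 1) {
      idx <- sample.int(n_cells, n_d)
      other <- vapply(line[idx], function(ln) {
        sample(setdiff(lines, ln), 1)
      }, character(1))
      f[idx, ] <- (f[idx, , drop = FALSE] +
                     t(vapply(other, frac_of, numeric(nv)))) / 2
      line[idx] <- paste0("doublet:", line[idx], "+", other)
    }
    # genotype errors flip the generating allele fraction at random sites
    err <- matrix(stats::runif(n_cells * nv) < error_rate, n_cells, nv)
    f[err] <- 1 - f[err]
    depth <- matrix(stats::rpois(n_cells * nv, mean_depth), n_cells, nv)
    depth[matrix(stats::runif(n_cells * nv) < dropout_rate,
                 n_cells, nv)] <- 0L
    alt <- matrix(stats::rbinom(n_cells * nv, depth, f), n_cells, nv)
    ref <- depth - alt
    dimnames(ref) <- dimnames(alt) <-
      list(sprintf("cell_%05d", seq_len(n_cells)), var_ids)
    list(ref = ref, alt = alt, db = db, line = line)
  })
}

#' Simulate an antibody-tag count matrix
#'
#' Marker-positive populations express at `positive_fold` times the
#' background tag level; counts are NB. Includes lineage markers (CD4,
#' CD8), the phenotype markers (CD45RO, CD62L, CD69, HLA-DR) and isotype
#' controls (IgG1/IgG2a/IgG2b) plus unstructured filler antibodies.
#'
#' @param lineage Character vector per cell: `"CD4+ T"`, `"CD8+ T"` or
#'   `"other"`.
#' @param positive_markers Optional named list: marker -> logical vector
#'   of cells positive for it (overrides/augments lineage defaults).
#' @param sticky_rate Fraction of cells with high isotype background
#'   (default 0.02).
#' @param background_mean Mean background tag count (default 2).
#' @param positive_fold Expression fold over background (default 10).
#' @param n_filler Unstructured antibodies to pad the panel (default 34).
#' @param seed Integer seed.
#' @return Integer matrix cells x antibodies with a `"sticky"` attribute
#'   (truth labels).
#' @export
simulate_protein <- function(lineage, positive_markers = list(),
                             sticky_rate = 0.02, background_mean = 2,
                             positive_fold = 10, n_filler = 34L,
                             seed = 1L) {
  with_local_seed(seed, {
    n <- length(lineage)
    core <- c("CD4", "CD8", "CD45RO", "CD62L", "CD69", "HLA-DR",
              "IgG1", "IgG2a", "IgG2b")
    filler <- sprintf("AB_%02d", seq_len(n_filler))
    abs_all <- c(core, filler)
    pos <- matrix(FALSE, n, length(abs_all),
                  dimnames = list(NULL, abs_all))
    pos[, "CD4"] <- lineage == "CD4+ T"
    pos[, "CD8"] <- lineage == "CD8+ T"
    for (mk in names(positive_markers)) pos[, mk] <- positive_markers[[mk]]
    sticky <- stats::runif(n) < sticky_rate
    for (ig in c("IgG1", "IgG2a", "IgG2b")) pos[sticky, ig] <- TRUE
    base <- stats::rlnorm(length(abs_all), log(background_mean), 0.3)
    mu <- matrix(base, n, length(abs_all), byrow = TRUE)
    mu[pos] <- mu[pos] * positive_fold
    counts <- matrix(stats::rnbinom(n * length(abs_all),
                                    size = 1 / 0.3, mu = mu),
                     n, length(abs_all),
                     dimnames = list(sprintf("cell_%05d", seq_len(n)),
                                     abs_all))
    attr(counts, "sticky") <- sticky
    counts
  })
}
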