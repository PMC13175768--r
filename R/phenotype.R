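#' Genotype cells from allele depths
#'
#' Plumbing step upstream of demultiplexing: per-cell, per-variant ref/alt
#' allele depths are turned into diploid genotypes by alt-allele fraction
#' `f = alt / (ref + alt)`: `f < het_lo` gives `0/0`, `f > het_hi` gives
#' `1/1`, otherwise `0/1`; sites with depth below `min_depth` are missing.
#'
#' @param ref_counts,alt_counts Integer matrices, cells x variants.
#' @param min_depth Minimum total depth to call a genotype (default 5).
#' @param het_lo,het_hi Alt-fraction thresholds (defaults 0.2 and 0.8).
#' @return Character matrix of genotypes (`"0/0"`, `"0/1"`, `"1/1"`,
#'   `NA`).
#' @export
genotype_cells <- function(ref_counts, alt_counts, min_depth = 5,
                           het_lo = 0.2, het_hi = 0.8) {
  stopifnot(identical(dim(ref_counts), dim(alt_counts)))
  depth <- ref_counts + alt_counts
  f <- alt_counts / ifelse(depth > 0, depth, 1)
  gt <- matrix("0/1", nrow(ref_counts), ncol(ref_counts),
               dimnames = dimnames(ref_counts))
  gt[f < het_lo] <- "0/0"
  gt[f > het_hi] <- "1/1"
  gt[depth < min_depth] <- NA_character_
  gt
}

#' Assign cells to cell lines by germline genotype matching
#'
#' Each cell's non-missing genotypes are compared against a reference
#' database of known germline genotypes per cell line. A cell is assigned
#' to the line with the highest match fraction, provided that fraction is
#' strictly greater than `min_match`; ties between lines, or best matches
#' at or below the threshold, leave the cell unassigned.
#'
#' @param genotypes Character matrix cells x variants from
#'   [genotype_cells()] (variant ids as column names).
#' @param db Named list: line id -> named character vector of genotypes
#'   by variant id.
#' @param min_match Match-fraction threshold, strict (default 0.60).
#' @return A data.frame with columns `barcode`, `line`, `match_fraction`,
#'   `tie`.
#' @export
demultiplex <- function(genotypes, db, min_match = 0.60) {
  if (length(db) == 0L) stop("empty germline database")
  lines <- names(db)
  frac <- sapply(lines, function(ln) {
    prof <- db[[ln]]
    vars <- intersect(colnames(genotypes), names(prof))
    if (length(vars) == 0L) return(rep(NA_real_, nrow(genotypes)))
    gt <- genotypes[, vars, drop = FALSE]
    ref <- matrix(prof[vars], nrow(genotypes), length(vars), byrow = TRUE)
    hits <- rowSums(gt == ref, na.rm = TRUE)
    tried <- rowSums(!is.na(gt))
    ifelse(tried > 0, hits / tried, NA_real_)
  })
  frac <- matrix(frac, nrow = nrow(genotypes),
                 dimnames = list(rownames(genotypes), lines))
  best <- apply(frac, 1, function(r) {
    if (all(is.na(r))) return(c(NA_integer_, NA_real_, 0))
    m <- max(r, na.rm = TRUE)
    idx <- which(r == m)
    c(idx[1], m, as.numeric(length(idx) > 1))
  })
  assigned <- lines[best[1, ]]
  match_fraction <- best[2, ]
  tie <- best[3, ] > 0
  assigned[is.na(match_fraction) | match_fraction <= min_match | tie] <-
    "unassigned"
  data.frame(barcode = rownames(genotypes) %||% seq_len(nrow(genotypes)),
             line = assigned,
             match_fraction = match_fraction,
             tie = tie,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise antibody-tag counts
#'
#' Surrogate for the vendor's proprietary noise-corrected scaled protein
#' normalisation, with a documented contract: monotone in count,
#' compositionally scaled per cell, and comparable to the 0.7 positivity
#' threshold after background centering. Per cell,
#' `x = log1p(count / cell total * 1e4)`; per run, the background level is
#' the mode of the pooled distribution of the isotype-control antibodies
#' and is subtracted from every antibody, clipping at 0. Cells with zero
#' total tag counts come back as all-zero rows and are flagged.
#'
#' @param protein_matrix Integer matrix cells x antibodies (antibody names
#'   as column names).
#' @param isotype Names of the isotype-control antibodies used for the
#'   background estimate (default IgG1/IgG2a/IgG2b).
#' @return Numeric matrix of normalised values with attributes
#'   `"background"` (estimated background level) and `"flagged_cells"`
#'   (row indices of zero-total cells).
#' @export
normalize_protein <- function(protein_matrix,
                              isotype = c("IgG1", "IgG2a", "IgG2b")) {
  if (any(protein_matrix < 0)) stop("tag counts must be >= 0")
  totals <- rowSums(protein_matrix)
  flagged <- which(totals == 0)
  safe_tot <- ifelse(totals > 0, totals, 1)
  x <- log1p(protein_matrix / safe_tot * 1e4)
  iso <- intersect(isotype, colnames(protein_matrix))
  if (length(iso) == 0L) {
    warning("no isotype-control antibodies found; background set to 0")
    bg <- 0
  } else {
    pooled <- as.vector(x[totals > 0, iso])
    bg <- density_mode(pooled)
  }
  out <- pmax(x - bg, 0)
  out[flagged, ] <- 0
  attr(out, "background") <- bg
  attr(out, "flagged_cells") <- flagged
  out
}

# Mode of a sample via kernel density (fallback to median for tiny n).
density_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 10L || stats::sd(x) == 0) return(stats::median(x))
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Default lineage marker rules
#'
#' Ordered rules; the first matching rule wins. Sticky cells (any isotype
#' control positive) are labelled first and are meant to be excluded from
#' downstream phenotype statistics.
#'
#' @return Named list of rules, each with `positive` and `negative`
#'   marker character vectors.
#' @export
default_lineage_rules <- function() {
  list(
    "sticky" = list(positive_any = c("IgG1", "IgG2a", "IgG2b"),
                    positive = character(0), negative = character(0)),
    "CD4+ T" = list(positive = "CD4", negative = "CD8"),
    "CD8+ T" = list(positive = "CD8", negative = "CD4")
  )
}

#' Assign cell lineages by marker rules
#'
#' Markers are binarised at a strict positivity threshold on the
#' normalised scale (`value > threshold` is positive); a rule matches when
#' all its `positive` markers are positive, all its `negative` markers are
#' negative, and (if present) at least one of `positive_any` is positive.
#' Rules are evaluated in declared order; unmatched cells get `"other"`.
#'
#' @param normalized Matrix from [normalize_protein()].
#' @param rules Rule list (default [default_lineage_rules()]).
#' @param threshold Positivity threshold (default 0.7, strict).
#' @return A data.frame with columns `barcode`, `lineage`, `sticky`.
#' @export
assign_lineage <- function(normalized, rules = default_lineage_rules(),
                           threshold = 0.7) {
  used <- unique(unlist(lapply(rules, function(r) {
    c(r$positive, r$negative, r$positive_any)
  })))
  unknown <- setdiff(used, colnames(normalized))
  if (length(unknown) > 0L) {
    stop("rule references unknown antibody: ", paste(unknown, collapse = ", "))
  }
  pos <- normalized > threshold
  lineage <- rep("other", nrow(normalized))
  unset <- rep(TRUE, nrow(normalized))
  for (nm in names(rules)) {
    r <- rules[[nm]]
    hit <- rep(TRUE, nrow(normalized))
    for (mk in r$positive) hit <- hit & pos[, mk]
    for (mk in r$negative) hit <- hit & !pos[, mk]
    if (!is.null(r$positive_any) && length(r$positive_any) > 0L) {
      hit <- hit & rowSums(pos[, r$positive_any, drop = FALSE]) > 0
    }
    lineage[unset & hit] <- nm
    unset <- unset & !hit
  }
  sticky <- lineage == "sticky"
  data.frame(barcode = rownames(normalized) %||% seq_len(nrow(normalized)),
             lineage = lineage, sticky = sticky, stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 table with sample odds ratio
#'
#' Two-sided exact p (hypergeometric) via [stats::fisher.test()], plus the
#' sample odds ratio `(a d) / (b c)` with the Haldane 0.5 correction
#' applied to every cell when any cell is 0. A table with an empty margin
#' is degenerate: `p = 1` and the odds ratio is flagged undefined.
#'
#' @param tab 2x2 integer matrix (or vector `c(a, b, c, d)` filled by row).
#' @return List with `p`, `odds_ratio`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  p <- stats::fisher.test(tab)$p.value
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(p = p, odds_ratio = or, degenerate = FALSE)
}

#' Test enrichment of an exhaustion-like phenotype by transduction status
#'
#' The exhaustion-like phenotype is defined on normalised protein values
#' as effector-memory (CD45RO positive, CD62L negative) cells
#' co-expressing CD69 and HLA-DR, binarised at the strict positivity
#' threshold. Cells are stratified by CAR status (transduced = copy
#' number > 0) and frequencies compared with Fisher's exact test; the
#' sample odds ratio is reported with Haldane correction for zero cells.
#'
#' @param normalized Matrix from [normalize_protein()].
#' @param transduced Logical vector, one per cell (e.g.
#'   [call_transduction()] output); `NA` cells are dropped.
#' @param threshold Positivity threshold (default 0.7).
#' @param markers Named list mapping the four roles to antibody column
#'   names.
#' @param exclude Optional logical vector of cells to exclude (e.g.
#'   sticky cells).
#' @return List with `freq_car_pos`, `freq_car_neg` (percent),
#'   `odds_ratio`, `fisher_p`, `table`, `degenerate`, and the
#'   `exhaustion_like` logical vector.
#' @export
exhaustion_test <- function(normalized, transduced, threshold = 0.7,
                            markers = list(CD45RO = "CD45RO",
                                           CD62L = "CD62L",
                                           CD69 = "CD69",
                                           HLADR = "HLA-DR"),
                            exclude = NULL) {
  need <- unlist(markers)
  unknown <- setdiff(need, colnames(normalized))
  if (length(unknown) > 0L) {
    stop("marker not in protein matrix: ", paste(unknown, collapse = ", "))
  }
  ex_like <- normalized[, markers$CD45RO] > threshold &
    !(normalized[, markers$CD62L] > threshold) &
    normalized[, markers$CD69] > threshold &
    normalized[, markers$HLADR] > threshold
  keep <- !is.na(transduced)
  if (!is.null(exclude)) keep <- keep & !exclude
  tab <- matrix(c(sum(ex_like[keep] & transduced[keep]),
                  sum(!ex_like[keep] & transduced[keep]),
                  sum(ex_like[keep] & !transduced[keep]),
                  sum(!ex_like[keep] & !transduced[keep])),
                2, 2, byrow = TRUE,
                dimnames = list(c("CAR+", "CAR-"),
                                c("exhaustion_like", "not")))
  ft <- fisher_exact_2x2(tab)
  n_pos <- sum(tab[1, ])
  n_neg <- sum(tab[2, ])
  list(freq_car_pos = if (n_pos > 0) 100 * tab[1, 1] / n_pos else NA_real_,
       freq_car_neg = if (n_neg > 0) 100 * tab[2, 1] / n_neg else NA_real_,
       odds_ratio = ft$odds_ratio,
       fisher_p = ft$p,
       table = tab,
       degenerate = ft$degenerate,
       exhaustion_like = ex_like)
}
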