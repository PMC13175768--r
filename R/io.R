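#' Read an amplicon panel specification
#'
#' A panel file is a delimited table (TSV, or CSV detected by sniffing the
#' header line) with columns `amplicon_id`, `class` and optionally `target`.
#' `class` labels every amplicon as `"human"` (endogenous genomic control)
#' or `"vector"` (target on the integrated vector whose read count scales
#' with copy number).
#'
#' @param path Path to the panel file.
#' @return A `data.frame` of class `vcn_panel` with columns `amplicon_id`,
#'   `class`, `target`.
#' @export
read_panel <- function(path) {
  sep <- sniff_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  required <- c("amplicon_id", "class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("panel file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"target" %in% names(df)) df$target <- NA_character_
  as_vcn_panel(df[, c("amplicon_id", "class", "target")])
}

#' Construct a validated panel
#'
#' @param df A data.frame with columns `amplicon_id`, `class` and
#'   optionally `target`.
#' @return A `vcn_panel` data.frame.
#' @export
as_vcn_panel <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"target" %in% names(df)) df$target <- NA_character_
  df$amplicon_id <- as.character(df$amplicon_id)
  df$class <- as.character(df$class)
  if (anyDuplicated(df$amplicon_id)) {
    stop("duplicate amplicon_id in panel")
  }
  bad <- setdiff(unique(df$class), c("human", "vector"))
  if (length(bad) > 0L) {
    stop("unknown amplicon class: ", paste(bad, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("vcn_panel", "data.frame")
  df
}

#' Construct a validated read-count run
#'
#' The universal input of the pipeline: a cells x amplicons matrix of
#' non-negative integer read counts, with an attached panel describing
#' each amplicon.
#'
#' @param counts Integer matrix, cells in rows (rownames = cell barcodes),
#'   amplicons in columns (colnames = amplicon ids, in panel order).
#' @param panel A `vcn_panel`.
#' @param run_id Character run identifier.
#' @return A list of class `vcn_run` with elements `counts`, `panel`,
#'   `run_id`.
#' @export
new_vcn_run <- function(counts, panel, run_id = "run") {
  panel <- as_vcn_panel(panel)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("counts must have cell barcodes as rownames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate barcode")
  if (is.null(colnames(counts))) stop("counts must have amplicon ids as colnames")
  unknown <- setdiff(colnames(counts), panel$amplicon_id)
  if (length(unknown) > 0L) {
    stop("unknown amplicon: ", paste(unknown, collapse = ", "))
  }
  absent <- setdiff(panel$amplicon_id, colnames(counts))
  if (length(absent) > 0L) {
    stop("panel amplicon missing from counts: ", paste(absent, collapse = ", "))
  }
  # enforce panel column order
  counts <- counts[, panel$amplicon_id, drop = FALSE]
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, panel = panel, run_id = run_id),
            class = "vcn_run")
}

#' Read a count matrix and its panel into a run object
#'
#' The counts file is a delimited table whose first column (`barcode`)
#' holds the cell barcode and whose remaining columns are amplicons.
#'
#' @param counts_path Path to the counts table (TSV or CSV).
#' @param panel_path Path to the panel file (see [read_panel()]).
#' @param run_id Run identifier stored on the object.
#' @return A `vcn_run`.
#' @export
read_run <- function(counts_path, panel_path, run_id = basename(counts_path)) {
  panel <- read_panel(panel_path)
  sep <- sniff_delim(counts_path)
  df <- utils::read.table(counts_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (names(df)[1L] != "barcode") {
    stop("first column of counts file must be 'barcode'")
  }
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- as.character(df$barcode)
  run <- new_vcn_run(counts, panel, run_id = run_id)
  message(sprintf("read run '%s': %d cells x %d amplicons (%d vector)",
                  run_id, nrow(run$counts), ncol(run$counts),
                  sum(panel$class == "vector")))
  run
}

#' Write a run's count matrix back to TSV
#'
#' @param run A `vcn_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  df <- data.frame(barcode = rownames(run$counts), run$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop low-depth vector amplicons
#'
#' Vector amplicons whose average read depth across all cells is at or
#' below `min_mean` are removed from the run before model fitting, to
#' avoid low-confidence copy-number estimates. Human amplicons are always
#' retained.
#'
#' @param run A `vcn_run`.
#' @param min_mean Depth threshold; a vector amplicon with mean count
#'   `<= min_mean` is excluded (default 5).
#' @return A list with elements `run` (filtered) and `excluded`
#'   (character vector of removed amplicon ids).
#' @export
filter_vector_amplicons <- function(run, min_mean = 5.0) {
  is_vec <- run$panel$class == "vector"
  if (!any(is_vec)) stop("run has no vector amplicons")
  means <- colMeans(run$counts)
  drop <- is_vec & means <= min_mean
  if (sum(is_vec & !drop) == 0L) stop("no usable vector amplicons")
  excluded <- run$panel$amplicon_id[drop]
  keep <- !drop
  run$panel <- as_vcn_panel(run$panel[keep, , drop = FALSE])
  run$counts <- run$counts[, keep, drop = FALSE]
  list(run = run, excluded = excluded)
}

#' Per-cell total read depth
#'
#' The depth covariate of the amplicon model. By default totals are
#' computed over human amplicons only, so that the covariate is not
#' itself a function of vector copy number.
#'
#' @param run A `vcn_run`.
#' @param mode `"human"` (default) or `"all"`.
#' @return Named numeric vector of totals, one per cell.
#' @export
total_reads <- function(run, mode = c("human", "all")) {
  mode <- match.arg(mode)
  cols <- if (mode == "human") run$panel$class == "human" else
    rep(TRUE, nrow(run$panel))
  rowSums(run$counts[, cols, drop = FALSE])
}

#' @export
print.vcn_run <- function(x, ...) {
  cat(sprintf("vcn_run '%s': %d cells x %d amplicons (%d human, %d vector)\n",
              x$run_id, nrow(x$counts), ncol(x$counts),
              sum(x$panel$class == "human"), sum(x$panel$class == "vector")))
  invisible(x)
}

#' Read a control specification (YAML or JSON)
#'
#' The control spec names the cells with known integer vector copy number
#' that anchor the amplicon models. Fields: `control_cn` (integer >= 1)
#' and either `control_cells` (barcodes within the test run) or
#' `control_run` (path of a separate control run whose cells are all
#' controls).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of class `vcn_control_spec`.
#' @export
read_control_spec <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$control_cn)) stop("control spec lacks control_cn")
  control_spec(control_cn = spec$control_cn,
               control_cells = spec$control_cells,
               control_run = spec$control_run)
}

#' Construct a control specification
#'
#' @param control_cn Known integer copy number of the control cells
#'   (must be >= 1; a zero-copy control cannot anchor the mean model).
#' @param control_cells Optional character vector of control barcodes.
#' @param control_run Optional path or `vcn_run` holding the control cells.
#' @return A list of class `vcn_control_spec`.
#' @export
control_spec <- function(control_cn, control_cells = NULL, control_run = NULL) {
  control_cn <- as.integer(control_cn)
  if (is.na(control_cn) || control_cn < 1L) {
    stop("control_cn must be an integer >= 1")
  }
  structure(list(control_cn = control_cn,
                 control_cells = control_cells,
                 control_run = control_run),
            class = "vcn_control_spec")
}

#' Write per-cell copy-number calls to TSV
#'
#' @param calls A `vcn_calls` data.frame (see [call_cells()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  df <- data.frame(barcode = calls$barcode,
                   cn = calls$cn,
                   quality = formatC(calls$quality, digits = 15, format = "g"),
                   transduced = calls$transduced,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell calls written by [write_calls()]
#'
#' @param path Path to a calls TSV.
#' @return A `vcn_calls` data.frame with columns `barcode`, `cn`,
#'   `quality`, `transduced`.
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer",
                                         "numeric", "logical"))
  class(df) <- c("vcn_calls", "data.frame")
  df
}

# Decide between tab and comma from the header line.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
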