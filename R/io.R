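#' Read an element-by-condition matrix from disk
#'
#' TSV/CSV files carry a header row of condition ids and a first column of
#' element ids; all cells must be 0 or 1. MatrixMarket (`mtx`) files use the
#' 1-based coordinate format with two sidecar label files (one label per
#' line): `<path>.rows.txt` for elements and `<path>.cols.txt` for
#' conditions, unless overridden.
#'
#' Orientation is fixed: rows are elements, columns are conditions. Files
#' stored transposed must be read with `transpose = TRUE`; the orientation is
#' never guessed.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`; default inferred from the
#'   file extension.
#' @param transpose transpose after reading (for files stored
#'   conditions-by-elements).
#' @param element_file,condition_file label sidecar paths for `mtx`.
#' @return a [condition_matrix()].
#' @export
read_matrix <- function(path, format = NULL, transpose = FALSE,
                        element_file = paste0(path, ".rows.txt"),
                        condition_file = paste0(path, ".cols.txt")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pbbr_io_error")
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(element_file)
    cn <- readLines(condition_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m)) {
      abort("label sidecar length does not match matrix dimensions",
            class = "pbbr_io_error")
    }
    dimnames(m) <- list(rn, cn)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     colClasses = "character", row.names = NULL)
    rn <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    rownames(m) <- rn
  }
  if (transpose) m <- t(m)
  condition_matrix(m)
}

#' Write an element-by-condition matrix to disk
#'
#' Inverse of [read_matrix()]: a round trip preserves entries and labels
#' bit-exactly.
#'
#' @inheritParams read_matrix
#' @param matrix a [condition_matrix()].
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, format = NULL,
                         element_file = paste0(path, ".rows.txt"),
                         condition_file = paste0(path, ".cols.txt")) {
  format <- format %||% tolower(tools::file_ext(path))
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    m <- unclass(matrix)
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE, doDiag = FALSE), path)
    writeLines(rownames(matrix), element_file)
    writeLines(colnames(matrix), condition_file)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(element = rownames(matrix), unclass(matrix),
                     check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Binarize a continuous expression matrix
#'
#' Two presence rules are supported:
#' \describe{
#'   \item{`ct_threshold`}{qRT-PCR cycle-threshold data: an element is present
#'     in a condition iff its Ct value is non-missing and strictly below
#'     `threshold` (default 35 cycles); a reading at or above the cap, or a
#'     missing reading, counts as not detected.}
#'   \item{`count_positive`}{count data (e.g. expressed sequence tags): an
#'     element is present iff at least one tag/count was observed.}
#' }
#'
#' @param values numeric matrix (rows = elements, columns = conditions),
#'   possibly with missing entries.
#' @param rule `"ct_threshold"` or `"count_positive"`.
#' @param threshold detection cap in PCR cycles for `ct_threshold`; must be
#'   positive.
#' @param strict use strict inequality `value < threshold` (default); set
#'   `FALSE` for `value <= threshold`.
#' @return a [condition_matrix()].
#' @export
binarize_expression <- function(values, rule = c("ct_threshold", "count_positive"),
                                threshold = 35, strict = TRUE) {
  rule <- match.arg(rule)
  values <- as.matrix(values)
  if (rule == "ct_threshold") {
    if (!is.numeric(threshold) || threshold <= 0) {
      abort("`threshold` must be positive", class = "pbbr_validation_error")
    }
    present <- if (strict) values < threshold else values <= threshold
    present[is.na(present)] <- FALSE
  } else {
    if (any(values < 0, na.rm = TRUE)) {
      abort("negative counts are not allowed under count_positive",
            class = "pbbr_validation_error")
    }
    present <- values >= 1
    present[is.na(present)] <- FALSE
  }
  out <- matrix(as.integer(present), nrow = nrow(values),
                dimnames = dimnames(values))
  condition_matrix(out)
}
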