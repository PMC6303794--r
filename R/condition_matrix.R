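#' Binary element-by-condition matrices
#'
#' A `condition_matrix` is an integer matrix with entries in \{0, 1\}, rows
#' labeled by element ids (e.g. proteins, miRNAs) and columns by condition
#' ids (e.g. tissues, experimental conditions). Entry `[e, j] == 1` records
#' that element `e` is present in condition `j`. The column support
#' `supp(C_j)` is the set of elements present in condition `j`; the element
#' usage (expression breadth) of an element is its row sum; the density is
#' the fraction of ones.
#'
#' @param x a numeric/integer/logical matrix with entries in \{0, 1\}, or a
#'   data frame whose first column holds element ids and remaining columns
#'   hold binary entries.
#' @param elements,conditions optional character vectors of unique labels;
#'   default to the dimnames of `x` (or `e1..em` / `c1..cn`).
#' @return a `condition_matrix` object.
#' @examples
#' m <- condition_matrix(rbind(a = c(1, 1, 0), b = c(1, 1, 0),
#'                             c = c(0, 1, 1), d = c(0, 0, 1)),
#'                       conditions = c("c1", "c2", "c3"))
#' element_usage(m)
#' @export
condition_matrix <- function(x, elements = NULL, conditions = NULL) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      elements <- elements %||% as.character(first)
      x <- as.matrix(x[, -1, drop = FALSE])
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x)) abort("`x` must be a matrix or data frame", class = "pbbr_validation_error")
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("condition matrix must have at least one row and one column",
          class = "pbbr_validation_error")
  }
  storage.mode(x) <- "integer"
  rownames(x) <- elements %||% rownames(x) %||% paste0("e", seq_len(nrow(x)))
  colnames(x) <- conditions %||% colnames(x) %||% paste0("c", seq_len(ncol(x)))
  validate_condition_matrix(x)
  structure(x, class = c("condition_matrix", "matrix", "array"))
}

validate_condition_matrix <- function(x) {
  if (nrow(x) < 1L || ncol(x) < 1L) {
    abort("condition matrix must have at least one row and one column",
          class = "pbbr_validation_error")
  }
  bad <- which(is.na(x) | (x != 0L & x != 1L), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    e <- rownames(x)[bad[1, 1]]
    j <- colnames(x)[bad[1, 2]]
    abort(sprintf("non-binary entry %s at element '%s', condition '%s'",
                  format(x[bad[1, 1], bad[1, 2]]), e, j),
          class = "pbbr_validation_error")
  }
  for (lab in list(rownames(x), colnames(x))) {
    if (anyDuplicated(lab)) {
      abort(sprintf("duplicate label '%s'", lab[duplicated(lab)][1]),
            class = "pbbr_validation_error")
    }
    if (any(!nzchar(lab)) || anyNA(lab)) {
      abort("labels must be non-empty strings", class = "pbbr_validation_error")
    }
  }
  invisible(x)
}

#' @export
print.condition_matrix <- function(x, ...) {
  cat(sprintf("<condition_matrix> %d elements x %d conditions, density %.3f\n",
              nrow(x), ncol(x), mean(x == 1L)))
  print(unclass(x)[seq_len(min(10L, nrow(x))), , drop = FALSE])
  if (nrow(x) > 10L) cat(sprintf("... %d more elements\n", nrow(x) - 10L))
  invisible(x)
}

# Column supports as a list of integer element-index vectors (sorted).
column_supports <- function(matrix) {
  lapply(seq_len(ncol(matrix)), function(j) which(matrix[, j] == 1L))
}

#' Drop elements never present in any condition
#'
#' Elements with zero usage cannot belong to any used building block; this
#' removes them before decomposition. Removed element ids are attached as the
#' `"removed"` attribute (and reported via a message).
#'
#' @param matrix a [condition_matrix()].
#' @param quiet suppress the message.
#' @return the reduced `condition_matrix` with attribute `removed` (character
#'   vector of dropped element ids). An all-zero matrix returns a 0-row matrix
#'   with a warning; downstream solvers reject it.
#' @export
drop_unused_elements <- function(matrix, quiet = FALSE) {
  keep <- rowSums(matrix == 1L) >= 1L
  removed <- rownames(matrix)[!keep]
  out <- unclass(matrix)[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    out <- structure(out, class = c("condition_matrix", "matrix", "array"))
  } else {
    warn("all elements have zero usage; returning an empty matrix")
    out <- structure(out, class = c("condition_matrix", "matrix", "array"))
  }
  if (!quiet && length(removed) > 0L) {
    message(sprintf("dropped %d unused element(s): %s", length(removed),
                    paste(head(removed, 5L), collapse = ", ")))
  }
  attr(out, "removed") <- removed
  out
}
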