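#' Building-block decompositions
#'
#' A decomposition of a condition matrix `C` is a list of `k` pairwise
#' distinct, non-empty building blocks (element sets) together with a `k x n`
#' binary usage matrix `U`. It is *valid* when, for every condition `j`, the
#' union of the blocks with `U[i, j] == 1` equals the column support
#' `supp(C_j)` exactly (empty columns receive no blocks), and every block is
#' used in at least one condition. The reusability of block `i` is
#' `r_i = sum(U[i, ])`; the objective tracked throughout is the total
#' reusability `sum(U)` (equivalently `k *` mean reusability).
#'
#' `new_decomposition()` assembles the object; use [is_valid()] to check it
#' against a matrix, and [tidy()]/[glance()] to extract per-block and
#' whole-decomposition summaries.
#'
#' @param blocks list of character vectors of element ids (each sorted
#'   internally).
#' @param usage `k x n` binary matrix; rows align with `blocks`, columns with
#'   `conditions`.
#' @param elements,conditions label vectors of the parent matrix.
#' @param method provenance tag (`"exact"`, `"heuristic"`,
#'   `"trivial_columns"`, `"singletons"`, `"sampled"`, `"planted"`).
#' @param seed integer seed used to produce the object, or `NULL`.
#' @return an object of class `pbb_decomposition`.
#' @export
new_decomposition <- function(blocks, usage, elements, conditions,
                              method = "unknown", seed = NULL) {
  blocks <- lapply(blocks, function(b) sort(as.character(b)))
  usage <- matrix(as.integer(usage), nrow = length(blocks),
                  dimnames = list(NULL, conditions))
  structure(
    list(blocks = blocks, usage = usage, elements = elements,
         conditions = conditions, k = length(blocks),
         total_reusability = sum(usage), method = method, seed = seed),
    class = "pbb_decomposition"
  )
}

#' @export
print.pbb_decomposition <- function(x, ...) {
  cat(sprintf("<pbb_decomposition> k = %d blocks over %d elements x %d conditions\n",
              x$k, length(x$elements), length(x$conditions)))
  cat(sprintf("  total reusability %d (mean %.3f), method = %s%s\n",
              x$total_reusability, x$total_reusability / x$k, x$method,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Reusability-maximal usage for fixed blocks
#'
#' Marks each block as used in every condition whose support contains it:
#' `U[i, j] = 1` iff block `i` is a subset of `supp(C_j)`. Among all valid
#' usage assignments of the same blocks this maximizes every row sum, hence
#' the total reusability (saturated-usage dominance). A block contained in no
#' support gets reusability 0; optimizing callers must reject such blocks.
#'
#' @param matrix a [condition_matrix()].
#' @param blocks list of character vectors of element ids.
#' @return a `k x n` binary usage matrix.
#' @export
saturate_usage <- function(matrix, blocks) {
  idx <- blocks_to_indices(blocks, rownames(matrix))
  m <- unclass(matrix)
  u <- vapply(idx, function(b) {
    as.integer(colSums(m[b, , drop = FALSE]) == length(b))
  }, integer(ncol(m)))
  # vapply gives n x k; transpose to k x n
  u <- matrix(t(u), nrow = length(blocks), dimnames = list(NULL, colnames(m)))
  u
}

blocks_to_indices <- function(blocks, elements) {
  lapply(blocks, function(b) {
    i <- match(b, elements)
    if (anyNA(i)) {
      abort(sprintf("block member '%s' is not an element of the matrix",
                    b[is.na(i)][1]), class = "pbbr_validation_error")
    }
    sort(i)
  })
}

#' Validate a decomposition against its matrix
#'
#' Checks every decomposition invariant: blocks non-empty, pairwise distinct,
#' drawn from the matrix elements; usage dimensions consistent; every block
#' used at least once; and exact union reconstruction — for every condition,
#' the union of its assigned blocks equals the column support (so empty
#' columns carry no blocks).
#'
#' @param matrix a [condition_matrix()].
#' @param decomposition a `pbb_decomposition`.
#' @param tiling additionally require that the blocks used within each
#'   condition are pairwise disjoint (the stricter contract satisfied by
#'   every decomposition the optimizers emit; blocks still overlap freely
#'   across conditions).
#' @return `TRUE`, or `FALSE` with attribute `"violation"` describing the
#'   first violated invariant.
#' @export
is_valid <- function(matrix, decomposition, tiling = FALSE) {
  d <- decomposition
  fail <- function(msg) structure(FALSE, violation = msg)
  if (length(d$blocks) == 0L) return(fail("decomposition has no blocks"))
  if (any(lengths(d$blocks) == 0L)) return(fail("empty block"))
  keys <- vapply(d$blocks, block_key, "")
  if (anyDuplicated(keys)) return(fail("blocks are not pairwise distinct"))
  if (!all(unlist(d$blocks) %in% rownames(matrix))) {
    return(fail("block member outside matrix elements"))
  }
  if (nrow(d$usage) != length(d$blocks) || ncol(d$usage) != ncol(matrix)) {
    return(fail("usage dimensions inconsistent with blocks/conditions"))
  }
  if (any(rowSums(d$usage) < 1L)) {
    return(fail(sprintf("block %d is used in no condition",
                        which(rowSums(d$usage) < 1L)[1])))
  }
  m <- unclass(matrix)
  for (j in seq_len(ncol(m))) {
    supp <- rownames(m)[m[, j] == 1L]
    used <- which(d$usage[, j] == 1L)
    members <- as.character(unlist(d$blocks[used]))
    un <- sort(unique(members))
    if (!identical(un, sort(supp))) {
      return(fail(sprintf(
        "condition %s: union of %d assigned block(s) {%s} != support {%s}",
        colnames(m)[j], length(used), paste(un, collapse = ","),
        paste(sort(supp), collapse = ","))))
    }
    if (tiling && length(members) != length(un)) {
      return(fail(sprintf("condition %s: used blocks overlap", colnames(m)[j])))
    }
  }
  TRUE
}

#' Baseline decompositions
#'
#' `trivial_column_decomposition()` uses one block per distinct non-empty
#' column support (the shortest description with zero modular structure);
#' `singleton_decomposition()` uses one block per element, so block
#' reusabilities equal element usages and the total reusability equals the
#' number of ones in the matrix. Both carry saturated usage.
#'
#' @param matrix a [condition_matrix()].
#' @return a `pbb_decomposition`.
#' @export
trivial_column_decomposition <- function(matrix) {
  supports <- column_supports(matrix)
  nz <- supports[lengths(supports) > 0L]
  if (length(nz) == 0L) abort("matrix has no non-empty column", class = "pbbr_validation_error")
  blocks <- unique(lapply(nz, function(s) rownames(matrix)[s]))
  new_decomposition(blocks, saturate_usage(matrix, blocks),
                    rownames(matrix), colnames(matrix),
                    method = "trivial_columns")
}

#' @rdname trivial_column_decomposition
#' @export
singleton_decomposition <- function(matrix) {
  usage <- rowSums(matrix == 1L)
  if (any(usage == 0L)) {
    abort(sprintf("element '%s' has zero usage; run drop_unused_elements() first",
                  rownames(matrix)[usage == 0L][1]),
          class = "pbbr_validation_error")
  }
  blocks <- as.list(rownames(matrix))
  new_decomposition(blocks, saturate_usage(matrix, blocks),
                    rownames(matrix), colnames(matrix),
                    method = "singletons")
}

#' Write / read a decomposition as JSON
#'
#' The on-disk form records elements, conditions, blocks (as lists of element
#' ids), the usage matrix, the objective name and value, method and seed.
#' A round trip is bit-exact.
#'
#' @param decomposition a `pbb_decomposition`.
#' @param path file path.
#' @export
write_decomposition <- function(decomposition, path) {
  d <- decomposition
  obj <- list(
    elements = d$elements, conditions = d$conditions,
    blocks = d$blocks,
    usage = lapply(seq_len(nrow(d$usage)), function(i) unname(d$usage[i, ])),
    objective = "total_reusability", value = d$total_reusability,
    method = d$method, seed = d$seed, k = d$k
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- obj$blocks
  if (!is.list(blocks)) blocks <- as.list(blocks)
  usage <- obj$usage
  if (is.list(usage)) usage <- do.call(rbind, usage)
  new_decomposition(lapply(blocks, as.character),
                    matrix(as.integer(usage), nrow = length(blocks)),
                    as.character(obj$elements), as.character(obj$conditions),
                    method = obj$method,
                    seed = if (is.null(obj$seed)) NULL else as.integer(obj$seed))
}
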