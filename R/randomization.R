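#' Constrained random equivalents of a condition matrix
#'
#' Two single-margin null models:
#' \describe{
#'   \item{`dp_rand()`}{*density-preserving*: each condition keeps exactly
#'     its number of present elements (column sum), but the identity of
#'     those elements is drawn uniformly at random without replacement,
#'     independently per column. Column sums are conserved exactly; row sums
#'     float.}
#'   \item{`rss_rand()`}{*row-sum-sequence-preserving*: the multiset of
#'     element usages is conserved exactly — the row sums are randomly
#'     permuted across elements, then each element's presences are placed
#'     uniformly at random without replacement among the conditions,
#'     independently per row. Row-sum multiset conserved; column sums
#'     float.}
#' }
#' Randomized matrices may contain empty rows or columns and duplicate
#' columns; all downstream operations accept them.
#'
#' @param matrix a [condition_matrix()].
#' @param seed integer seed (required); output is bit-reproducible.
#' @return a `condition_matrix` with the same dimensions and labels.
#' @export
dp_rand <- function(matrix, seed) {
  m <- unclass(matrix)
  nr <- nrow(m)
  out <- local_seed(seed, {
    o <- matrix(0L, nr, ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      s <- sum(m[, j] == 1L)
      if (s > 0L) o[sample.int(nr, s), j] <- 1L
    }
    o
  })
  structure(out, class = c("condition_matrix", "matrix", "array"))
}

#' @rdname dp_rand
#' @export
rss_rand <- function(matrix, seed) {
  m <- unclass(matrix)
  nc <- ncol(m)
  out <- local_seed(seed, {
    rs <- sample(rowSums(m == 1L))
    o <- matrix(0L, nrow(m), nc, dimnames = dimnames(m))
    for (i in seq_len(nrow(m))) {
      if (rs[i] > 0L) o[i, sample.int(nc, rs[i])] <- 1L
    }
    o
  })
  structure(out, class = c("condition_matrix", "matrix", "array"))
}

#' Seeded ensemble of random equivalents
#'
#' Member `i` is generated with a seed derived deterministically from
#' `(base_seed, i)`, so the whole ensemble is reproducible end-to-end and
#' individual members can be regenerated in isolation.
#'
#' @inheritParams dp_rand
#' @param kind `"dp_rand"` or `"rss_rand"`.
#' @param size number of members (`>= 1`).
#' @param base_seed integer seed for the ensemble.
#' @return an object of class `pbb_ensemble`: list with `matrices`, `kind`,
#'   `base_seed`, `seeds`, `size`.
#' @export
pbb_ensemble <- function(matrix, kind = c("dp_rand", "rss_rand"), size,
                         base_seed) {
  kind <- match.arg(kind)
  if (size < 1L) abort("`size` must be >= 1", class = "pbbr_validation_error")
  seeds <- vapply(seq_len(size), function(i) derive_seed(base_seed, i), integer(1))
  f <- if (kind == "dp_rand") dp_rand else rss_rand
  structure(
    list(matrices = lapply(seeds, function(s) f(matrix, s)),
         kind = kind, base_seed = base_seed, seeds = seeds, size = size),
    class = "pbb_ensemble"
  )
}

#' @export
print.pbb_ensemble <- function(x, ...) {
  cat(sprintf("<pbb_ensemble> %d %s matrices (base seed %d)\n",
              x$size, x$kind, x$base_seed))
  invisible(x)
}
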