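#' Candidate building-block universe
#'
#' Enumerates the deduplicated candidate blocks a solver may choose from,
#' together with each block's containment count
#' `cnt(B) = #\{j : B subset of supp(C_j)\}` — the reusability it would earn
#' under saturated usage.
#'
#' Two constructions are available:
#' \describe{
#'   \item{`closed`}{all distinct non-empty intersections of subsets of
#'     column supports (the fixed point of iterated pairwise intersection),
#'     plus all column supports and all singletons of used elements. Every
#'     closed block equals the intersection of the supports containing it;
#'     replacing any block by this closure preserves its containment count
#'     and can only extend its coverage, which is why closed blocks suffice
#'     for greedy covering.}
#'   \item{`all_subsets`}{every distinct non-empty subset of some column
#'     support. Exhaustive; guarded to `m <= 12`, `n <= 6` and used by the
#'     exact solver only.}
#' }
#'
#' @param matrix a [condition_matrix()].
#' @param construction `"closed"` or `"all_subsets"`.
#' @param cap maximum number of blocks kept; if exceeded, the highest-`cnt`
#'   blocks are kept but column supports and singletons are never evicted.
#' @return an object of class `pbb_universe`; `tidy()` gives one row per
#'   block with its size and containment count.
#' @export
build_universe <- function(matrix, construction = c("closed", "all_subsets"),
                           cap = Inf) {
  construction <- match.arg(construction)
  m <- unclass(matrix)
  if (sum(m) == 0L) abort("matrix has no present entries", class = "pbbr_validation_error")
  supports <- column_supports(matrix)
  nz <- unique(supports[lengths(supports) > 0L])

  if (construction == "all_subsets") {
    if (nrow(m) > 12L || ncol(m) > 6L) {
      abort("all_subsets universe is guarded to m <= 12, n <= 6",
            class = "pbbr_validation_error")
    }
    seen <- new.env(parent = emptyenv())
    blocks <- list()
    for (s in nz) {
      for (sz in seq_along(s)) {
        subs <- combn(s, sz, simplify = FALSE)
        for (b in subs) {
          key <- paste(b, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            blocks[[length(blocks) + 1L]] <- b
          }
        }
      }
    }
  } else {
    blocks <- closed_intersections(m, nz)
    # guarantee singletons of every used element
    have1 <- unlist(blocks[lengths(blocks) == 1L])
    used <- which(rowSums(m == 1L) >= 1L)
    for (e in setdiff(used, have1)) blocks[[length(blocks) + 1L]] <- e
  }

  cnt <- vapply(blocks, function(b) {
    sum(colSums(m[b, , drop = FALSE]) == length(b))
  }, integer(1))
  keep <- cnt >= 1L
  blocks <- blocks[keep]
  cnt <- cnt[keep]

  if (is.finite(cap) && length(blocks) > cap) {
    prot <- vapply(blocks, function(b) {
      length(b) == 1L || any(vapply(nz, function(s) identical(s, b), TRUE))
    }, TRUE)
    ord <- order(-cnt, -lengths(blocks))
    keep_idx <- sort(unique(c(which(prot), setdiff(ord, which(prot))[
      seq_len(max(0L, cap - sum(prot)))])))
    blocks <- blocks[keep_idx]
    cnt <- cnt[keep_idx]
  }

  structure(
    list(blocks = lapply(blocks, function(b) rownames(m)[b]),
         idx = blocks, cnt = cnt, construction = construction,
         elements = rownames(m), conditions = colnames(m)),
    class = "pbb_universe"
  )
}

# All distinct non-empty intersections of subsets of the given supports.
# For small n this enumerates column subsets directly (identical to the
# pairwise-intersection fixed point); otherwise it iterates pairwise
# intersections until closure.
closed_intersections <- function(m, nz_supports) {
  n <- ncol(m)
  if (n <= 12L) {
    seen <- new.env(parent = emptyenv())
    out <- list()
    for (j in seq_len(n)) {
      s <- which(m[, j] == 1L)
      if (length(s) == 0L) next
      key <- paste(s, collapse = ",")
      if (is.null(seen[[key]])) { seen[[key]] <- TRUE; out[[length(out) + 1L]] <- s }
    }
    # intersections over all subsets of columns, built incrementally
    frontier <- out
    repeat {
      new_blocks <- list()
      for (b in frontier) {
        for (j in seq_len(n)) {
          i <- b[m[b, j] == 1L]
          if (length(i) == 0L) next
          key <- paste(i, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            new_blocks[[length(new_blocks) + 1L]] <- i
          }
        }
      }
      if (length(new_blocks) == 0L) break
      out <- c(out, new_blocks)
      frontier <- new_blocks
    }
    out
  } else {
    out <- nz_supports
    seen <- new.env(parent = emptyenv())
    for (b in out) seen[[paste(b, collapse = ",")]] <- TRUE
    frontier <- out
    repeat {
      new_blocks <- list()
      for (a in frontier) {
        for (b in out) {
          i <- intersect(a, b)
          if (length(i) == 0L) next
          key <- paste(i, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            new_blocks[[length(new_blocks) + 1L]] <- i
          }
        }
      }
      if (length(new_blocks) == 0L) break
      out <- c(out, new_blocks)
      frontier <- new_blocks
    }
    out
  }
}

#' @export
print.pbb_universe <- function(x, ...) {
  cat(sprintf("<pbb_universe> %d candidate blocks (%s) over %d elements x %d conditions\n",
              length(x$blocks), x$construction, length(x$elements),
              length(x$conditions)))
  invisible(x)
}

#' @method tidy pbb_universe
#' @export
tidy.pbb_universe <- function(x, ...) {
  tibble(
    block_id = seq_along(x$blocks),
    size = lengths(x$blocks),
    cnt = x$cnt,
    members = x$blocks
  )
}
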