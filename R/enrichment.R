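#' Element-to-term annotation maps
#'
#' `annotation_map()` builds the map from a two-column data frame
#' (element id, term id); `read_annotations()` reads either a two-column TSV
#' or a GAF 2.x file (columns 2 and 5, comment lines starting with `!`
#' skipped).
#'
#' @param x data frame whose first two columns are element id and term id.
#' @return an object of class `pbb_annotation_map`: a tibble with columns
#'   `element`, `term` (deduplicated).
#' @export
annotation_map <- function(x) {
  out <- tibble(element = as.character(x[[1]]), term = as.character(x[[2]]))
  if (any(!nzchar(out$term)) || anyNA(out$term) || anyNA(out$element)) {
    abort("annotation elements/terms must be non-empty strings",
          class = "pbbr_validation_error")
  }
  out <- dplyr::distinct(out)
  class(out) <- c("pbb_annotation_map", class(out))
  out
}

#' @rdname annotation_map
#' @param path file path.
#' @param format `"tsv"` or `"gaf"`.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "pbbr_io_error")
  if (format == "gaf") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    df <- data.frame(
      element = vapply(parts, function(p) p[2], ""),
      term = vapply(parts, function(p) p[5], "")
    )
  } else {
    df <- read.delim(path, sep = "\t", header = FALSE, colClasses = "character")
  }
  annotation_map(df)
}

#' Per-block term enrichment (one-sided hypergeometric test)
#'
#' For each block and each term, tests over-representation of the term among
#' the block's members with the one-sided hypergeometric upper-tail
#' probability of the 2x2 table (in-block & term, in-block & not-term,
#' out-of-block & term, out-of-block & not-term) — the one-sided Fisher
#' exact test. Each block is assigned its most-enriched term (minimum raw p;
#' ties broken by lexicographic term id). The Bonferroni correction
#' multiplies the raw p by both the number of terms and the number of
#' blocks, capped at 1.
#'
#' @param blocks list of character vectors of element ids.
#' @param annotations a [annotation_map()].
#' @param universe character vector of element ids forming the testing
#'   background; all blocks must lie inside it.
#' @param alpha significance threshold on the corrected p (default 0.01).
#' @param correct apply the Bonferroni correction (default `TRUE`; when
#'   `FALSE`, `p_corrected` equals `p_raw`).
#' @param n_blocks_correction number of blocks entering the correction
#'   factor; defaults to `length(blocks)`, override when comparing grouping
#'   methods under an identical factor.
#' @return a tibble with one row per block: `block_id`, `size`, `best_term`,
#'   `p_raw`, `p_corrected`, `significant`.
#' @export
fisher_enrichment <- function(blocks, annotations, universe, alpha = 0.01,
                              correct = TRUE,
                              n_blocks_correction = length(blocks)) {
  if (length(universe) == 0L) abort("empty universe", class = "pbbr_validation_error")
  universe <- unique(as.character(universe))
  out_of_universe <- setdiff(unique(unlist(blocks)), universe)
  if (length(out_of_universe) > 0L) {
    abort(sprintf("block member '%s' is outside the universe", out_of_universe[1]),
          class = "pbbr_validation_error")
  }
  ann <- annotations[annotations$element %in% universe, ]
  terms <- sort(unique(ann$term))
  n_terms <- length(terms)
  N <- length(universe)
  term_members <- split(ann$element, factor(ann$term, levels = terms))
  factor_mult <- if (correct) n_terms * n_blocks_correction else 1
  rows <- purrr::imap(blocks, function(b, i) {
    b <- unique(b)
    nb <- length(b)
    if (n_terms == 0L) {
      return(tibble(block_id = i, size = nb, best_term = NA_character_,
                    p_raw = 1, p_corrected = 1, significant = FALSE))
    }
    p <- unname(vapply(terms, function(t) {
      members <- term_members[[t]]
      x <- sum(b %in% members)
      K <- length(members)
      phyper(x - 1, K, N - K, nb, lower.tail = FALSE)
    }, numeric(1)))
    best <- which(p == min(p))[1]  # terms sorted: lexicographic tie-break
    p_corr <- min(1, p[best] * factor_mult)
    tibble(block_id = i, size = nb, best_term = terms[best],
           p_raw = p[best], p_corrected = p_corr,
           significant = p_corr < alpha)
  })
  dplyr::bind_rows(rows)
}

#' Agglomerative Jaccard clustering of elements
#'
#' Represents each element by its set of conditions (its matrix row),
#' computes pairwise Jaccard distances (1 - |intersection| / |union|; two
#' all-zero rows are at distance 0), and cuts an agglomerative dendrogram
#' ([stats::hclust()]) at `k` clusters. In binary expression data this
#' groups together elements co-present in the greatest possible number of
#' conditions. Unlike building blocks, the result is a partition: disjoint
#' groups covering all elements.
#'
#' @param matrix a [condition_matrix()].
#' @param k number of clusters (`1 <= k <= m`).
#' @param linkage `"average"` (default), `"single"`, or `"complete"`.
#' @return a list of `k` character vectors (element ids).
#' @export
jaccard_agglomerative_blocks <- function(matrix, k,
                                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- unclass(matrix)
  if (k < 1L || k > nrow(m)) abort("`k` must be in 1..m", class = "pbbr_validation_error")
  inter <- m %*% t(m)
  rs <- rowSums(m == 1L)
  uni <- outer(rs, rs, "+") - inter
  jac <- ifelse(uni == 0, 1, inter / uni)
  d <- as.dist(1 - jac)
  if (k == nrow(m)) {
    groups <- seq_len(nrow(m))
  } else {
    hc <- hclust(d, method = linkage)
    groups <- cutree(hc, k = k)
  }
  unname(split(rownames(m), groups))
}

#' Random size-matched element groupings
#'
#' Draws each block independently and uniformly among element subsets of the
#' prescribed size, so the returned size multiset matches `sizes` exactly.
#' Overlaps between blocks are permitted by default, matching the overlap
#' semantics of building blocks; `disjoint = TRUE` instead draws a partition
#' without replacement (requires `sum(sizes) <= |universe|`).
#'
#' @param universe character vector of element ids.
#' @param sizes integer vector of block sizes (each in `1..|universe|`).
#' @param seed integer seed (required).
#' @param disjoint draw disjoint groups instead.
#' @return a list of character vectors.
#' @export
random_size_matched_blocks <- function(universe, sizes, seed, disjoint = FALSE) {
  universe <- unique(as.character(universe))
  if (any(sizes < 1L | sizes > length(universe))) {
    abort("every size must be in 1..|universe|", class = "pbbr_validation_error")
  }
  local_seed(seed, {
    if (disjoint) {
      if (sum(sizes) > length(universe)) {
        abort("disjoint groups need sum(sizes) <= |universe|",
              class = "pbbr_validation_error")
      }
      pool <- sample(universe)
      ends <- cumsum(sizes)
      starts <- c(1L, head(ends, -1) + 1L)
      purrr::map2(starts, ends, function(s, e) sort(pool[s:e]))
    } else {
      lapply(sizes, function(s) sort(sample(universe, s)))
    }
  })
}

#' Compare enrichment across three grouping methods
#'
#' Evaluates term enrichment for (i) the blocks of a heuristic
#' k-maximally-reusable decomposition, (ii) a k-group Jaccard agglomerative
#' clustering, and (iii) random groupings size-matched to the decomposition
#' blocks — all against the identical universe, term list, significance
#' threshold and Bonferroni factor (number of terms x k).
#'
#' @param matrix a [condition_matrix()].
#' @param k number of blocks/groups.
#' @param annotations a [annotation_map()].
#' @param alpha corrected-p significance threshold (default 0.01).
#' @param seed integer seed (required; drives the solver and the random
#'   grouping).
#' @param ... passed to [heuristic_kmrd()].
#' @return an object of class `pbb_enrichment_comparison`; `glance()` gives
#'   the per-method counts of significantly enriched blocks, `tidy()` the
#'   per-block results of all three methods.
#' @export
enrichment_comparison <- function(matrix, k, annotations, alpha = 0.01,
                                  seed, ...) {
  universe <- rownames(matrix)
  kmrd <- heuristic_kmrd(matrix, k, seed = seed, ...)
  groupings <- list(
    kmrd = kmrd$blocks,
    jaccard_clustering = jaccard_agglomerative_blocks(matrix, k),
    random_size_matched = random_size_matched_blocks(
      universe, lengths(kmrd$blocks), seed = derive_seed(seed, 104729L))
  )
  details <- purrr::imap(groupings, function(blocks, method) {
    dplyr::mutate(
      fisher_enrichment(blocks, annotations, universe, alpha = alpha,
                        n_blocks_correction = k),
      method = method, .before = 1L)
  })
  details <- dplyr::bind_rows(details)
  counts <- dplyr::summarise(dplyr::group_by(details, .data$method),
                             n_blocks = dplyr::n(),
                             n_significant = sum(.data$significant),
                             .groups = "drop")
  structure(list(counts = counts, details = details, k = k, alpha = alpha,
                 seed = seed),
            class = "pbb_enrichment_comparison")
}

#' @export
print.pbb_enrichment_comparison <- function(x, ...) {
  cat(sprintf("<pbb_enrichment_comparison> k = %d, alpha = %g\n", x$k, x$alpha))
  print(x$counts)
  invisible(x)
}

#' @method tidy pbb_enrichment_comparison
#' @export
tidy.pbb_enrichment_comparison <- function(x, ...) x$details

#' @method glance pbb_enrichment_comparison
#' @export
glance.pbb_enrichment_comparison <- function(x, ...) x$counts
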