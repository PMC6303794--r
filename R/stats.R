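#' Summary statistics of a decomposition
#'
#' Extracts the three headline quantities tracked per decomposition — mean
#' block size, maximum block size, and the Shannon entropy of the block
#' reusability distribution — together with mean and total reusability.
#'
#' @param decomposition a valid `pbb_decomposition`.
#' @return a one-row tibble with columns `k`, `mean_block_size`,
#'   `max_block_size`, `reusability_entropy` (bits), `mean_reusability`,
#'   `total_reusability`.
#' @export
decomposition_summary <- function(decomposition) {
  sizes <- lengths(decomposition$blocks)
  r <- rowSums(decomposition$usage)
  tibble(
    k = decomposition$k,
    mean_block_size = mean(sizes),
    max_block_size = as.numeric(max(sizes)),
    reusability_entropy = reusability_entropy(r),
    mean_reusability = mean(r),
    total_reusability = sum(r)
  )
}

#' @method glance pbb_decomposition
#' @export
glance.pbb_decomposition <- function(x, ...) {
  dplyr::mutate(decomposition_summary(x), method = x$method,
                seed = x$seed %||% NA_integer_)
}

#' @method tidy pbb_decomposition
#' @export
tidy.pbb_decomposition <- function(x, ...) {
  tibble(
    block_id = seq_along(x$blocks),
    size = lengths(x$blocks),
    reusability = as.integer(rowSums(x$usage)),
    members = x$blocks
  )
}

#' Shannon entropy of a reusability distribution
#'
#' `H = -sum_v p_v log2 p_v`, where `p_v` is the fraction of blocks whose
#' reusability equals the distinct value `v`. Zero iff all blocks share one
#' reusability; maximal (`log2 k`) when all `k` reusabilities are distinct.
#' Reported in bits; the base cancels in the ratio comparisons used to
#' contrast real and randomized systems.
#'
#' @param reusabilities vector of per-block reusabilities (all `>= 1`).
#' @return entropy in bits.
#' @export
reusability_entropy <- function(reusabilities) {
  if (length(reusabilities) == 0L) {
    abort("empty reusability vector", class = "pbbr_validation_error")
  }
  if (any(reusabilities < 1)) {
    abort("reusabilities must be >= 1 (every block must be used)",
          class = "pbbr_validation_error")
  }
  p <- as.numeric(table(reusabilities)) / length(reusabilities)
  -sum(p * log2(p))
}

#' Element usage (expression breadth) histogram
#'
#' Counts, for each usage value `u`, the elements present in exactly `u`
#' conditions (row sums of the matrix). Elements used nowhere are excluded
#' by default, so the counts plus the number of zero-usage elements equal
#' `m`.
#'
#' @param matrix a [condition_matrix()].
#' @param include_zero include the `u = 0` class.
#' @return a tibble with columns `usage` and `n_elements`.
#' @export
element_usage <- function(matrix, include_zero = FALSE) {
  u <- rowSums(unclass(matrix) == 1L)
  tb <- table(factor(u, levels = 0:ncol(matrix)))
  out <- tibble(usage = 0:ncol(matrix), n_elements = as.integer(tb))
  if (!include_zero) out <- out[out$usage >= 1L, ]
  out
}

#' Binomial element-usage expectation at matched density
#'
#' Expected usage histogram if each of the `m` elements were present in each
#' of the `n` conditions independently with probability equal to the matrix
#' density `d` (the null that DP-Rand ensembles of constant-column-sum
#' matrices converge to): expected count at usage `u` is
#' `m * choose(n, u) * d^u * (1 - d)^(n - u)`. Counts sum to `m`.
#'
#' @param matrix a [condition_matrix()].
#' @return a tibble with columns `usage` (0..n) and `expected`.
#' @export
binomial_usage_expectation <- function(matrix) {
  m <- nrow(matrix)
  n <- ncol(matrix)
  d <- mean(unclass(matrix) == 1L)
  tibble(usage = 0:n, expected = m * dbinom(0:n, n, d))
}

#' Trapezoidal area under a per-k curve
#'
#' Standard trapezoid rule over the raw `k` grid (no interpolation). On an
#' equal-width grid the ratio of two AUCs equals the ratio of the two
#' averages of the quantity over `k`.
#'
#' @param k_values strictly increasing numeric vector (length >= 2).
#' @param q_values quantity values aligned with `k_values`.
#' @return the area, a single number.
#' @export
pbb_auc <- function(k_values, q_values) {
  if (length(k_values) < 2L) abort("need at least two points", class = "pbbr_validation_error")
  if (length(k_values) != length(q_values)) {
    abort("`k_values` and `q_values` must be the same length", class = "pbbr_validation_error")
  }
  if (any(diff(k_values) <= 0)) {
    abort("`k_values` must be strictly increasing", class = "pbbr_validation_error")
  }
  sum(diff(k_values) * (head(q_values, -1) + q_values[-1]) / 2)
}

#' Compare a real system's k-curve against an ensemble of null curves
#'
#' Restricts all curves to the common grid of k values feasible everywhere,
#' then computes the per-member AUC ratio (ensemble member / real) of the
#' chosen quantity, the mean/min/max of those ratios, and the z-score of the
#' real mean-over-k against the ensemble's means-over-k.
#'
#' @param real_curve a [kmrd_curve()] result for the observed matrix.
#' @param ensemble_curves list of `pbb_kcurve` objects for the randomized
#'   matrices.
#' @param quantity one of `"mean_block_size"`, `"max_block_size"`,
#'   `"reusability_entropy"`, `"mean_reusability"`.
#' @return an object of class `pbb_comparison`; `tidy()` gives per-member
#'   ratios, `glance()` the summary (ratio mean/min/max, z-score, grid used).
#' @export
ensemble_comparison <- function(real_curve, ensemble_curves,
                                quantity = c("mean_block_size", "max_block_size",
                                             "reusability_entropy", "mean_reusability")) {
  quantity <- match.arg(quantity)
  feas <- function(cv) cv$k[cv$feasible]
  grid <- Reduce(intersect, c(list(feas(real_curve)), lapply(ensemble_curves, feas)))
  if (length(grid) < 2L) {
    abort("common feasible k grid has fewer than two points", class = "pbbr_validation_error")
  }
  grid <- sort(grid)
  pull_q <- function(cv) cv[[quantity]][match(grid, cv$k)]
  q_real <- pull_q(real_curve)
  auc_real <- pbb_auc(grid, q_real)
  members <- purrr::imap(ensemble_curves, function(cv, i) {
    q <- pull_q(cv)
    tibble(member = i,
           auc = pbb_auc(grid, q),
           auc_ratio = pbb_auc(grid, q) / auc_real,
           mean_over_k = mean(q))
  })
  members <- dplyr::bind_rows(members)
  real_mean <- mean(q_real)
  ens_mean <- mean(members$mean_over_k)
  ens_sd <- sd(members$mean_over_k)
  z <- if (isTRUE(all.equal(real_mean, ens_mean))) 0
       else (real_mean - ens_mean) / ens_sd
  structure(
    list(quantity = quantity, grid = grid, members = members,
         real_auc = auc_real, real_mean_over_k = real_mean,
         ratio_mean = mean(members$auc_ratio),
         ratio_min = min(members$auc_ratio),
         ratio_max = max(members$auc_ratio),
         z_score = z),
    class = "pbb_comparison"
  )
}

#' @export
print.pbb_comparison <- function(x, ...) {
  cat(sprintf("<pbb_comparison> %s over common k grid {%s}\n", x$quantity,
              paste(x$grid, collapse = ", ")))
  cat(sprintf("  AUC ratio (ensemble/real): mean %.3f [%.3f, %.3f], z = %.3f (%d members)\n",
              x$ratio_mean, x$ratio_min, x$ratio_max, x$z_score,
              nrow(x$members)))
  invisible(x)
}

#' @method tidy pbb_comparison
#' @export
tidy.pbb_comparison <- function(x, ...) x$members

#' @method glance pbb_comparison
#' @export
glance.pbb_comparison <- function(x, ...) {
  tibble(quantity = x$quantity, n_members = nrow(x$members),
         n_k = length(x$grid), real_auc = x$real_auc,
         real_mean_over_k = x$real_mean_over_k,
         ratio_mean = x$ratio_mean, ratio_min = x$ratio_min,
         ratio_max = x$ratio_max, z_score = x$z_score)
}

#' Joint histogram of block size and reusability
#'
#' Tabulates (block size, reusability) pairs over one or more decompositions
#' of the same matrix, optionally binning sizes. Used to examine how much
#' blocks of different sizes are reused across decompositions of different
#' mean reusabilities.
#'
#' @param decompositions list of `pbb_decomposition` objects.
#' @param size_breaks optional numeric break points passed to [cut()] for
#'   size binning; by default raw sizes are used (recorded in the
#'   `"size_breaks"` attribute).
#' @return a tibble with columns `size` (or `size_bin`), `reusability`, `n`.
#' @export
size_reusability_table <- function(decompositions, size_breaks = NULL) {
  if (length(decompositions) == 0L) {
    return(tibble(size = integer(), reusability = integer(), n = integer()))
  }
  df <- dplyr::bind_rows(purrr::imap(decompositions, function(d, i) {
    dplyr::mutate(tidy(d), decomposition = i)
  }))
  if (is.null(size_breaks)) {
    out <- dplyr::count(df, .data$size, .data$reusability)
  } else {
    df$size_bin <- cut(df$size, breaks = size_breaks, include.lowest = TRUE)
    out <- dplyr::count(df, .data$size_bin, .data$reusability)
  }
  attr(out, "size_breaks") <- size_breaks
  out
}
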