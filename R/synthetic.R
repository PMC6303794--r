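#' Worked micro-example matrix
#'
#' A pinned 4-element, 3-condition matrix used throughout the documentation
#' and tests: elements `a, b, c, d`; condition supports
#' `c1 = {a, b}`, `c2 = {a, b, c}`, `c3 = {c, d}`. Its density is 7/12, its
#' row-sum multiset \{2, 2, 2, 1\}, and its exact 3-block reusability
#' optimum has total reusability 5 (e.g. blocks `{a,b}, {c}, {c,d}`).
#'
#' @return a [condition_matrix()].
#' @export
fixture_m1 <- function() {
  condition_matrix(
    rbind(a = c(1L, 1L, 0L),
          b = c(1L, 1L, 0L),
          c = c(0L, 1L, 1L),
          d = c(0L, 0L, 1L)),
    conditions = c("c1", "c2", "c3")
  )
}

#' Synthetic system with a planted decomposition
#'
#' Samples `k_star` distinct random building blocks and a usage pattern,
#' then assembles the matrix whose column supports are the unions of the
#' blocks used in each condition. By default the planted blocks are
#' disjoint (the modules partition their elements), so the planted
#' decomposition is a tiling of its own matrix and its total reusability is
#' a feasibility lower bound for any solver run at `k = k_star`; with
#' `disjoint = FALSE` blocks are independent random subsets and may
#' overlap.
#'
#' The default usage sampler mirrors the usage extremes seen in biological
#' systems: roughly 20% of blocks constitutive (used in every condition),
#' 30% condition-specific (used in exactly one), the rest used in each
#' condition independently with probability 0.5 (at least once). The
#' default size sampler draws block sizes uniformly from
#' `1..max(1, floor(m / k_star))`, so disjoint placement always fits.
#'
#' @param m,n numbers of elements and conditions.
#' @param k_star number of planted blocks.
#' @param block_size_sampler function(k) returning k sizes in `1..m` (their
#'   sum must be at most `m` when `disjoint = TRUE`).
#' @param usage_sampler function(k, n) returning a k x n binary matrix with
#'   every row sum `>= 1`.
#' @param seed integer seed (required).
#' @param disjoint plant pairwise disjoint blocks (default).
#' @param max_retries retries to achieve pairwise distinct blocks.
#' @return an object of class `pbb_planted_system`: list with `matrix`
#'   (a [condition_matrix()]), `decomposition` (the planted
#'   `pbb_decomposition`, saturated usage), `true_usage` (the usage as
#'   planted, before saturation), and `params`.
#' @export
planted_system <- function(m, n, k_star, block_size_sampler = NULL,
                           usage_sampler = NULL, seed, disjoint = TRUE,
                           max_retries = 100L) {
  if (k_star < 1L) abort("`k_star` must be >= 1", class = "pbbr_validation_error")
  block_size_sampler <- block_size_sampler %||%
    function(k) sample.int(max(1L, floor(m / k_star)), k, replace = TRUE)
  usage_sampler <- usage_sampler %||% default_usage_sampler
  local_seed(seed, {
    elements <- paste0("e", seq_len(m))
    conditions <- paste0("c", seq_len(n))
    blocks <- NULL
    for (try in seq_len(max_retries)) {
      sizes <- block_size_sampler(k_star)
      if (any(sizes < 1L | sizes > m)) {
        abort("block_size_sampler returned sizes outside 1..m",
              class = "pbbr_validation_error")
      }
      if (disjoint) {
        if (sum(sizes) > m) {
          abort("disjoint planted blocks need sum(sizes) <= m",
                class = "pbbr_validation_error")
        }
        pool <- sample.int(m, sum(sizes))
        ends <- cumsum(sizes)
        starts <- c(1L, head(ends, -1) + 1L)
        cand <- lapply(seq_len(k_star), function(i) sort(pool[starts[i]:ends[i]]))
      } else {
        cand <- lapply(sizes, function(s) sort(sample.int(m, s)))
      }
      if (!anyDuplicated(vapply(cand, paste, "", collapse = ","))) {
        blocks <- cand
        break
      }
    }
    if (is.null(blocks)) {
      abort("could not sample pairwise distinct blocks", class = "pbbr_validation_error")
    }
    usage <- usage_sampler(k_star, n)
    if (!all(dim(usage) == c(k_star, n)) || any(rowSums(usage) < 1L)) {
      abort("usage_sampler must return a k x n binary matrix with row sums >= 1",
            class = "pbbr_validation_error")
    }
    mat <- matrix(0L, m, n, dimnames = list(elements, conditions))
    for (j in seq_len(n)) {
      used <- which(usage[, j] == 1L)
      if (length(used) > 0L) mat[unique(unlist(blocks[used])), j] <- 1L
    }
    cm <- condition_matrix(mat)
    block_ids <- lapply(blocks, function(b) elements[b])
    planted <- new_decomposition(block_ids, saturate_usage(cm, block_ids),
                                 elements, conditions, method = "planted",
                                 seed = seed)
    structure(
      list(matrix = cm, decomposition = planted, true_usage = usage,
           params = list(m = m, n = n, k_star = k_star, seed = seed,
                         disjoint = disjoint)),
      class = "pbb_planted_system"
    )
  })
}

default_usage_sampler <- function(k, n) {
  n_const <- ceiling(0.2 * k)
  n_spec <- min(k - n_const, ceiling(0.3 * k))
  u <- matrix(0L, k, n)
  rows <- sample.int(k)  # which blocks get which role
  const_rows <- rows[seq_len(n_const)]
  spec_rows <- rows[n_const + seq_len(n_spec)]
  other_rows <- setdiff(rows, c(const_rows, spec_rows))
  u[const_rows, ] <- 1L
  for (i in spec_rows) u[i, sample.int(n, 1L)] <- 1L
  for (i in other_rows) {
    draw <- rbinom(n, 1L, 0.5)
    if (sum(draw) == 0L) draw[sample.int(n, 1L)] <- 1L
    u[i, ] <- draw
  }
  u
}

#' @export
print.pbb_planted_system <- function(x, ...) {
  cat(sprintf("<pbb_planted_system> %d x %d matrix with %d planted blocks (seed %d)\n",
              x$params$m, x$params$n, x$params$k_star, x$params$seed))
  invisible(x)
}

#' U-shaped element-usage synthetic matrix
#'
#' Beta-binomial generator emulating the element-usage (expression-breadth)
#' distribution characteristic of biological presence/absence data: each
#' element draws a presence probability `p_e ~ Beta(alpha, beta)` and is then
#' present in each of the `n` conditions independently with probability
#' `p_e`. With `alpha = beta = 0.3` (the defaults) most mass sits near
#' `p_e = 0` or `p_e = 1`, producing an excess of rarely used and of
#' constitutive elements relative to the binomial expectation at matched
#' density; `alpha = beta -> Inf` recovers a binomial(n, 1/2) usage profile.
#'
#' @param m,n numbers of elements and conditions.
#' @param alpha,beta positive Beta shape parameters.
#' @param seed integer seed (required).
#' @return a [condition_matrix()].
#' @export
ushaped_matrix <- function(m, n, alpha = 0.3, beta = 0.3, seed) {
  if (alpha <= 0 || beta <= 0) {
    abort("`alpha` and `beta` must be positive", class = "pbbr_validation_error")
  }
  local_seed(seed, {
    p <- rbeta(m, alpha, beta)
    mat <- matrix(rbinom(m * n, 1L, rep(p, times = n)), nrow = m,
                  dimnames = list(paste0("e", seq_len(m)),
                                  paste0("c", seq_len(n))))
    condition_matrix(mat)
  })
}
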