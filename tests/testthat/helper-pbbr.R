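# Shared test fixtures and independent oracles.

# seeded random tiny matrix (m <= 7, n <= 4) with at least one present entry
random_tiny_matrix <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(3:7, 1)
    n <- sample(2:4, 1)
    x <- matrix(rbinom(m * n, 1, runif(1, 0.3, 0.7)), m, n)
    if (sum(x) == 0) x[1, 1] <- 1
    condition_matrix(x)
  })
}

# seeded random small matrix (for validity sweeps)
random_small_matrix <- function(seed, m_max = 40, n_max = 10) {
  withr::with_seed(seed, {
    m <- sample(5:m_max, 1)
    n <- sample(3:n_max, 1)
    x <- matrix(rbinom(m * n, 1, runif(1, 0.2, 0.7)), m, n)
    if (sum(x) == 0) x[1, 1] <- 1
    condition_matrix(x)
  })
}

# tiny random matrix for the naive-oracle comparison (kept very small: the
# oracle enumerates the full cartesian product of column set-partitions)
random_micro_matrix <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(3:4, 1)
    n <- sample(2:3, 1)
    x <- matrix(rbinom(m * n, 1, runif(1, 0.4, 0.7)), m, n)
    if (sum(x) == 0) x[1, 1] <- 1
    condition_matrix(x)
  })
}

# Independent naive oracle for the k-MRD optimum under tiling semantics:
# enumerate every combination of set-partitions of the column supports,
# count the distinct blocks in use, and return the maximal total
# reusability over combinations using exactly k blocks (-Inf if none).
# Completely separate code path from the branch-and-bound solver.
naive_kmrd_total <- function(mat, k) {
  m <- unclass(mat)
  supports <- lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L))
  supports <- Filter(function(s) length(s) > 0L, supports)
  all_partitions <- function(s) {
    if (length(s) == 0L) return(list(list()))
    x <- s[1]
    rest <- s[-1]
    out <- list()
    for (mask in 0:(2^length(rest) - 1)) {
      blk <- sort(c(x, rest[bitwAnd(mask, 2^(seq_along(rest) - 1)) > 0]))
      for (p in all_partitions(setdiff(rest, blk))) {
        out[[length(out) + 1L]] <- c(list(blk), p)
      }
    }
    out
  }
  parts <- lapply(supports, all_partitions)
  best <- -Inf
  rec <- function(ci, counter) {
    if (ci > length(parts)) {
      if (length(counter) == k) {
        tot <- sum(unlist(counter))
        if (tot > best) best <<- tot
      }
      return(invisible())
    }
    for (p in parts[[ci]]) {
      cnt2 <- counter
      for (blk in p) {
        key <- paste(blk, collapse = ",")
        cnt2[[key]] <- (if (is.null(cnt2[[key]])) 0L else cnt2[[key]]) + 1L
      }
      rec(ci + 1L, cnt2)
    }
    invisible()
  }
  rec(1L, list())
  best
}

# minimal feasible k by brute force probing
min_feasible_k <- function(mat) {
  e <- tryCatch(brute_force_kmrd(mat, 1), error = function(e) e)
  if (inherits(e, "error")) e$k_min else 1L
}

# planted U-shaped system: small reusable modules with constitutive and
# condition-specific usage extremes (the synthetic study condition for the
# real-vs-null directional comparisons)
planted_ushaped <- function(seed, m = 200, n = 8, k_star = 25) {
  planted_system(m, n, k_star = k_star,
                 block_size_sampler = function(k) sample.int(20, k, replace = TRUE),
                 seed = seed)
}

# annotation map assigning one private term to each given block
private_term_annotations <- function(blocks) {
  annotation_map(data.frame(
    element = unlist(blocks),
    term = rep(sprintf("T%03d", seq_along(blocks)), lengths(blocks))
  ))
}
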