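# k-MRD solvers.
#
# The optimizers work over TILING decompositions: within every condition the
# blocks used there are pairwise disjoint and their union is exactly the
# condition's support. Blocks overlap freely ACROSS conditions — reuse is
# the point — but within one condition each present element is contributed
# by exactly one block. The constraint pins the objective down: every
# tiling satisfies sum_i size_i * r_i = #ones, so maximizing total
# reusability sum_i r_i rewards carving shared sub-blocks (a constitutive
# core, co-expression classes) out once and reusing them everywhere, and
# the finest useful blocks are the classes of elements with identical
# presence rows. Without it, arbitrarily many high-containment sub-blocks
# of already-reconstructed regions could be stacked to inflate reusability
# without contributing anything to reconstruction.
#
# Internal state: a palette of distinct blocks (sorted element-index
# vectors, stable ids, a `live` flag) plus, per condition, the ids tiling
# it. Total reusability = sum over live blocks of the number of conditions
# they tile.

# ---- tiling state --------------------------------------------------------

new_tiling_state <- function(m) {
  nc <- ncol(m)
  st <- list(m = m, blocks = list(), keys = character(0), cols = list(),
             live = logical(0), tiles = rep(list(integer(0)), nc))
  for (j in seq_len(nc)) {
    s <- which(m[, j] == 1L)
    if (length(s) == 0L) next
    st <- st_place(st, s, j)
  }
  st
}

# make `block` a tile of column j (adding it to the palette if new)
st_place <- function(st, block, j) {
  key <- paste(block, collapse = ",")
  id <- match(key, st$keys)
  if (is.na(id) || !st$live[id]) {
    if (is.na(id)) {
      st$blocks[[length(st$blocks) + 1L]] <- block
      st$keys[length(st$blocks)] <- key
      st$cols[[length(st$blocks)]] <- integer(0)
      st$live[length(st$blocks)] <- TRUE
      id <- length(st$blocks)
    } else {
      st$live[id] <- TRUE
      st$cols[[id]] <- integer(0)
    }
  }
  st$cols[[id]] <- c(st$cols[[id]], j)
  st$tiles[[j]] <- c(st$tiles[[j]], id)
  st
}

st_k <- function(st) sum(st$live)
st_total <- function(st) sum(lengths(st$cols[st$live]))

# replace live block `id` by the bipartition (piece, rest = block \ piece)
# in every condition it tiles; either part may already be live — it then
# gains those conditions (it cannot already tile them, being a proper
# subset of the outgoing tile there)
st_split <- function(st, id, piece) {
  block <- st$blocks[[id]]
  rest <- setdiff(block, piece)
  jj <- st$cols[[id]]
  st$live[id] <- FALSE
  st$cols[[id]] <- integer(0)
  for (j in jj) st$tiles[[j]] <- setdiff(st$tiles[[j]], id)
  for (j in jj) {
    st <- st_place(st, piece, j)
    st <- st_place(st, rest, j)
  }
  st
}

# palette-size change a split would cause
st_split_dk <- function(st, id, piece, rest) {
  pk <- paste(piece, collapse = ",")
  rk <- paste(rest, collapse = ",")
  others <- st$keys[st$live]
  others <- others[others != st$keys[id]]
  1L - sum(c(pk, rk) %in% others)
}

# merge two live blocks tiling exactly the same conditions
st_merge <- function(st, i, j) {
  u <- sort(c(st$blocks[[i]], st$blocks[[j]]))
  jj <- st$cols[[i]]
  for (cc in jj) st$tiles[[cc]] <- setdiff(st$tiles[[cc]], c(i, j))
  st$live[c(i, j)] <- FALSE
  st$cols[[i]] <- integer(0)
  st$cols[[j]] <- integer(0)
  for (cc in jj) st <- st_place(st, u, cc)
  st
}

# ---- shared helpers ------------------------------------------------------

abort_infeasible <- function(k, k_min, k_max = NA_integer_) {
  abort(sprintf("no valid tiling decomposition with k = %d blocks (minimum feasible k is %s)",
                k, format(k_min)),
        class = "pbbr_infeasible", k = k, k_min = k_min, k_max = k_max)
}

tiling_to_decomposition <- function(matrix, st, method, seed = NULL) {
  ids <- which(st$live)
  # canonical order: reusability desc, size desc, lexicographic members
  r <- lengths(st$cols[ids])
  ord <- order(-r, -lengths(st$blocks[ids]), st$keys[ids], method = "radix")
  ids <- ids[ord]
  usage <- matrix(0L, length(ids), ncol(st$m))
  for (i in seq_along(ids)) usage[i, st$cols[[ids[i]]]] <- 1L
  blocks <- lapply(st$blocks[ids], function(b) rownames(matrix)[b])
  d <- new_decomposition(blocks, usage, rownames(matrix), colnames(matrix),
                         method = method, seed = seed)
  stopifnot(isTRUE(is_valid(matrix, d, tiling = TRUE)))
  d
}

# element classes by identical presence rows, ordered by usage desc then
# first-member index: carving the highest-usage class out of a block is the
# move that creates maximally reusable pieces
row_class_list <- function(m) {
  used <- which(rowSums(m == 1L) >= 1L)
  if (length(used) == 0L) return(list())
  pat <- apply(m[used, , drop = FALSE], 1L, paste, collapse = "")
  cl <- split(used, pat)
  u <- vapply(cl, function(e) sum(m[e[1], ]), numeric(1))
  first <- vapply(cl, min, numeric(1))
  cl[order(-u, first)]
}

# ---- exact solver --------------------------------------------------------

#' Exact k-maximally-reusable decomposition (tiny instances)
#'
#' Exhaustive branch-and-bound over all ways to partition every condition's
#' support into blocks, maximizing total reusability with exactly `k`
#' distinct blocks. Blocks used within one condition are disjoint (a
#' tiling); blocks are reused freely across conditions. Guarded to
#' `m <= 12`, `n <= 6`; intended as the oracle for tiny instances. Ties
#' between equal-objective solutions are broken deterministically in favor
#' of the lexicographically smallest sorted block list.
#'
#' @param matrix a [condition_matrix()].
#' @param k number of blocks.
#' @return a `pbb_decomposition` with `method = "exact"`. If no valid
#'   k-decomposition exists, an error of class `pbbr_infeasible` is thrown
#'   whose `k_min` field reports the minimum feasible k.
#' @export
brute_force_kmrd <- function(matrix, k) {
  m <- unclass(matrix)
  if (nrow(m) > 12L || ncol(m) > 6L) {
    abort("exact search is guarded to m <= 12, n <= 6", class = "pbbr_validation_error")
  }
  if (sum(m) == 0L) abort("matrix has no present entries", class = "pbbr_validation_error")
  supports <- lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L))
  nz <- which(lengths(supports) > 0L)
  # process small supports first (fewest partition choices)
  nz <- nz[order(lengths(supports[nz]))]
  sup_sizes <- lengths(supports[nz])
  n_cols <- length(nz)
  max_pieces_after <- rev(cumsum(rev(pmin(sup_sizes, k))))

  k_min <- Inf
  best_total <- -1L
  best_sol <- NULL
  best_key <- ""

  # palette as an environment keyed by block key -> r (reuse count)
  pal <- new.env(parent = emptyenv())
  pal_n <- 0L
  sol_cols <- vector("list", n_cols)  # per processed column: list of blocks

  score <- function() {
    keys <- ls(pal)
    total <- sum(vapply(keys, function(kk) pal[[kk]], integer(1)))
    k_min <<- min(k_min, pal_n)
    if (pal_n != k) return(invisible())
    key <- paste(sort(keys), collapse = "\x1e")
    if (total > best_total || (total == best_total && key < best_key)) {
      best_total <<- total
      best_key <<- key
      best_sol <<- lapply(sol_cols, function(x) x)
    }
    invisible()
  }

  # enumerate partitions of `rem` (sorted int vector) for column ci,
  # then recurse to the next column
  part <- function(ci, rem, used) {
    if (pal_n > k) return(invisible())
    if (length(rem) == 0L) {
      sol_cols[[ci]] <<- used
      col_rec(ci + 1L)
      return(invisible())
    }
    x <- rem[1]
    others <- rem[-1]
    # every subset of `others` combined with x forms the block containing x
    nsub <- length(others)
    for (mask in 0:(2^nsub - 1)) {
      blk <- sort(c(x, others[bitwAnd(mask, 2^(seq_len(nsub) - 1)) > 0]))
      key <- paste(blk, collapse = ",")
      existed <- !is.null(pal[[key]])
      if (!existed && pal_n + 1L > k) next
      if (existed) pal[[key]] <- pal[[key]] + 1L else { pal[[key]] <- 1L; pal_n <<- pal_n + 1L }
      part(ci, setdiff(others, blk), c(used, list(blk)))
      if (pal[[key]] == 1L) { rm(list = key, envir = pal); pal_n <<- pal_n - 1L }
      else pal[[key]] <- pal[[key]] - 1L
    }
    invisible()
  }

  col_rec <- function(ci) {
    if (ci > n_cols) { score(); return(invisible()) }
    # bound: every remaining column contributes at most min(|supp|, k) uses
    cur_total <- sum(vapply(ls(pal), function(kk) pal[[kk]], integer(1)))
    if (cur_total + max_pieces_after[ci] < best_total) return(invisible())
    part(ci, supports[[nz[ci]]], list())
    invisible()
  }

  col_rec(1L)
  if (is.null(best_sol)) {
    km <- if (is.finite(k_min)) as.integer(k_min) else tiling_min_k(m)
    abort_infeasible(k, km)
  }
  # assemble usage from the stored per-column tilings
  keys <- unique(unlist(lapply(best_sol, function(tl)
    vapply(tl, paste, "", collapse = ","))))
  blocks_idx <- lapply(strsplit(keys, ",", fixed = TRUE), as.integer)
  usage <- matrix(0L, length(keys), ncol(m))
  for (ci in seq_len(n_cols)) {
    for (blk in best_sol[[ci]]) {
      usage[match(paste(blk, collapse = ","), keys), nz[ci]] <- 1L
    }
  }
  r <- rowSums(usage)
  ord <- order(-r, -lengths(blocks_idx), keys, method = "radix")
  blocks <- lapply(blocks_idx[ord], function(b) rownames(matrix)[b])
  d <- new_decomposition(blocks, usage[ord, , drop = FALSE],
                         rownames(matrix), colnames(matrix), method = "exact")
  stopifnot(isTRUE(is_valid(matrix, d, tiling = TRUE)))
  d
}

# exact minimum palette size over all tilings (branch and bound; tiny
# instances only — same guard as the exact solver)
tiling_min_k <- function(m) {
  supports <- lapply(seq_len(ncol(m)), function(j) which(m[, j] == 1L))
  nz <- which(lengths(supports) > 0L)
  nz <- nz[order(lengths(supports[nz]))]
  n_cols <- length(nz)
  best <- length(unique(supports[nz]))  # support tiling upper bound
  pal <- new.env(parent = emptyenv())
  pal_n <- 0L
  part <- function(ci, rem) {
    if (pal_n >= best) return(invisible())
    if (length(rem) == 0L) { col_rec(ci + 1L); return(invisible()) }
    x <- rem[1]
    others <- rem[-1]
    nsub <- length(others)
    for (mask in 0:(2^nsub - 1)) {
      blk <- sort(c(x, others[bitwAnd(mask, 2^(seq_len(nsub) - 1)) > 0]))
      key <- paste(blk, collapse = ",")
      existed <- !is.null(pal[[key]])
      if (existed) pal[[key]] <- pal[[key]] + 1L else { pal[[key]] <- 1L; pal_n <<- pal_n + 1L }
      if (pal_n < best) part(ci, setdiff(others, blk))
      if (pal[[key]] == 1L) { rm(list = key, envir = pal); pal_n <<- pal_n - 1L }
      else pal[[key]] <- pal[[key]] - 1L
    }
    invisible()
  }
  col_rec <- function(ci) {
    if (ci > n_cols) { best <<- min(best, pal_n); return(invisible()) }
    part(ci, supports[[nz[ci]]])
    invisible()
  }
  col_rec(1L)
  as.integer(best)
}

# ---- heuristic -----------------------------------------------------------

# all (block id, piece id) pairs where a live palette block is a proper
# subset of another live block: splitting along such a piece reuses it and
# never increases the palette size ("free" improvement)
free_moves <- function(st) {
  ids <- which(st$live)
  sizes <- lengths(st$blocks)
  out <- NULL
  for (b in ids) {
    if (sizes[b] < 2L) next
    memb <- logical(nrow(st$m))
    memb[st$blocks[[b]]] <- TRUE
    for (p in ids) {
      if (p == b || sizes[p] >= sizes[b]) next
      if (all(memb[st$blocks[[p]]])) out <- rbind(out, c(b, p))
    }
  }
  out
}

# deterministic carve piece for a block: its intersection with the highest-
# usage element class (the maximally reusable sub-block); a single-class
# block peels its first element
carve_piece <- function(st, id, classes) {
  B <- st$blocks[[id]]
  for (cl in classes) {
    p <- intersect(B, cl)
    if (length(p) > 0L && length(p) < length(B)) return(sort(p))
  }
  B[1]
}

#' Heuristic k-maximally-reusable decomposition
#'
#' Seeded solver for realistic instances, optimizing total reusability over
#' tiling decompositions. It starts from the distinct-support tiling (one
#' block per distinct non-empty column support) and improves it with two
#' kinds of moves:
#' \describe{
#'   \item{reuse carving}{when one palette block is a proper subset of
#'     another, the larger is split along the smaller wherever it is used —
#'     the shared piece is reused, total reusability rises by the larger
#'     block's reusability, and the number of blocks never grows;}
#'   \item{class splits}{to reach larger `k`, a block is bisected along its
#'     intersection with the highest-usage class of elements with identical
#'     presence rows (both pieces inherit every use of the parent, so every
#'     split strictly increases total reusability).}
#' }
#' For `k` below the number of distinct supports, blocks tiling identical
#' condition sets are merged. The first restart is fully deterministic;
#' later restarts randomize move order, and the best result is returned.
#' Results are bit-reproducible for fixed
#' `(matrix, k, seed, restarts, max_iters)`.
#'
#' @inheritParams brute_force_kmrd
#' @param seed integer seed (required).
#' @param restarts number of independent restarts.
#' @param max_iters cap on reuse-carving (improvement) moves per restart;
#'   splits and merges needed to reach `k` are always performed.
#' @return a `pbb_decomposition` with `method = "heuristic"`, or an error of
#'   class `pbbr_infeasible` reporting the minimum k the greedy reaches.
#' @export
heuristic_kmrd <- function(matrix, k, seed, restarts = 3L, max_iters = 10000L) {
  if (k < 1L) abort("`k` must be >= 1", class = "pbbr_validation_error")
  m <- unclass(matrix)
  if (sum(m) == 0L) abort("matrix has no present entries", class = "pbbr_validation_error")
  classes <- row_class_list(m)
  best <- NULL
  best_total <- -1L
  best_key <- ""
  k0_report <- NA_integer_
  for (r in seq_len(max(1L, restarts))) {
    st <- local_seed(derive_seed(seed, r), {
      run_tiling_greedy(m, k, classes, randomized = r > 1L, max_iters = max_iters)
    })
    if (is.null(st)) next
    if (is.na(k0_report)) k0_report <- attr(st, "k_reached") %||% NA_integer_
    if (!isTRUE(attr(st, "feasible"))) {
      k0_report <- min(k0_report, attr(st, "k_reached"), na.rm = TRUE)
      next
    }
    total <- st_total(st)
    key <- paste(sort(st$keys[st$live]), collapse = "\x1e")
    if (total > best_total || (total == best_total && key < best_key)) {
      best <- st
      best_total <- total
      best_key <- key
    }
  }
  if (is.null(best)) abort_infeasible(k, k0_report)
  tiling_to_decomposition(matrix, best, "heuristic", seed)
}

# tile every column directly by the element classes present in it (each
# class is either inside or disjoint from every support)
class_tiling_state <- function(m, classes) {
  nc <- ncol(m)
  st <- list(m = m, blocks = list(), keys = character(0), cols = list(),
             live = logical(0), tiles = rep(list(integer(0)), nc))
  for (j in seq_len(nc)) {
    for (cl in classes) {
      if (m[cl[1], j] == 1L) st <- st_place(st, sort(cl), j)
    }
  }
  st
}

run_tiling_greedy <- function(m, k, classes, randomized = FALSE,
                              max_iters = 10000L) {
  # when the budget allows at least one block per element class, the class
  # tiling (every column tiled by its classes) is the natural high-reuse
  # start: reaching k only needs singleton peels
  if (k >= length(classes) && length(classes) > 0L) {
    st <- class_tiling_state(m, classes)
    while (st_k(st) < k) {
      ids <- which(st$live & lengths(st$blocks) >= 2L)
      if (length(ids) == 0L) break
      rb <- lengths(st$cols[ids])
      ord <- if (randomized) {
        sample.int(length(ids), prob = rb + 1)
      } else {
        order(-rb, -lengths(st$blocks[ids]), st$keys[ids], method = "radix")
      }
      id <- ids[ord[1]]
      piece <- if (randomized) {
        B <- st$blocks[[id]]
        sort(sample(B, sample.int(length(B) - 1L, 1L)))
      } else {
        st$blocks[[id]][1]
      }
      if (st_k(st) + st_split_dk(st, id, piece,
                                 setdiff(st$blocks[[id]], piece)) > k) break
      st <- st_split(st, id, piece)
    }
    if (st_k(st) == k) {
      attr(st, "feasible") <- TRUE
      attr(st, "k_reached") <- k
      return(st)
    }
  }
  st <- new_tiling_state(m)
  carves <- 0L
  apply_free_moves <- function(st) {
    repeat {
      if (carves >= max_iters) break
      fm <- free_moves(st)
      if (is.null(fm)) break
      rb <- lengths(st$cols[fm[, 1]])
      ord <- if (randomized) {
        sample.int(nrow(fm), prob = rb)
      } else {
        order(-rb, st$keys[fm[, 1]], st$keys[fm[, 2]], method = "radix")
      }
      mv <- fm[ord[1], ]
      st <- st_split(st, mv[1], st$blocks[[mv[2]]])
      carves <<- carves + 1L
    }
    st
  }
  st <- apply_free_moves(st)
  # merge down when below the support-tiling size
  while (st_k(st) > k) {
    ids <- which(st$live)
    colkey <- vapply(st$cols[ids], paste, "", collapse = ",")
    dup <- split(ids, colkey)
    dup <- dup[lengths(dup) >= 2L]
    if (length(dup) == 0L) {
      out <- st
      attr(out, "feasible") <- FALSE
      attr(out, "k_reached") <- st_k(st)
      return(out)
    }
    grp <- dup[[order(vapply(dup, function(g) min(lengths(st$cols[g])), numeric(1)))[1]]]
    st <- st_merge(st, grp[1], grp[2])
    st <- apply_free_moves(st)
  }
  # split up: bisect the most reused splittable block along its highest-
  # usage class
  while (st_k(st) < k) {
    ids <- which(st$live & lengths(st$blocks) >= 2L)
    if (length(ids) == 0L) {
      out <- st
      attr(out, "feasible") <- FALSE
      attr(out, "k_reached") <- st_k(st)
      return(out)
    }
    rb <- lengths(st$cols[ids])
    ord <- if (randomized) {
      sample.int(length(ids), prob = rb + 1)
    } else {
      order(-rb, -lengths(st$blocks[ids]), st$keys[ids], method = "radix")
    }
    applied <- FALSE
    for (i in ord) {
      id <- ids[i]
      piece <- if (randomized && runif(1) < 0.5) {
        B <- st$blocks[[id]]
        sort(sample(B, sample.int(length(B) - 1L, 1L)))
      } else {
        carve_piece(st, id, classes)
      }
      rest <- setdiff(st$blocks[[id]], piece)
      dk <- st_split_dk(st, id, piece, rest)
      k2 <- st_k(st) + dk
      if (k2 > k) next
      st <- st_split(st, id, piece)
      st <- apply_free_moves(st)
      applied <- TRUE
      break
    }
    if (!applied) {
      out <- st
      attr(out, "feasible") <- FALSE
      attr(out, "k_reached") <- st_k(st)
      return(out)
    }
  }
  attr(st, "feasible") <- TRUE
  attr(st, "k_reached") <- st_k(st)
  st
}

#' Per-k decomposition summaries over a range of k
#'
#' Runs a solver for each requested `k` and tabulates the summary statistics
#' of each optimum: mean and maximum block size, reusability entropy, mean
#' and total reusability. Infeasible `k` values are flagged
#' (`feasible = FALSE`), never silently dropped.
#'
#' @inheritParams heuristic_kmrd
#' @param k_values sorted vector of block counts.
#' @param method `"heuristic"` or `"exact"`.
#' @return a tibble of class `pbb_kcurve`, one row per `k`.
#' @export
kmrd_curve <- function(matrix, k_values, method = c("heuristic", "exact"),
                       seed = NULL, restarts = 3L, max_iters = 10000L) {
  method <- match.arg(method)
  if (length(k_values) == 0L) abort("`k_values` must be non-empty", class = "pbbr_validation_error")
  k_values <- sort(unique(as.integer(k_values)))
  rows <- purrr::map(k_values, function(k) {
    d <- tryCatch(
      if (method == "exact") brute_force_kmrd(matrix, k)
      else heuristic_kmrd(matrix, k, seed = seed, restarts = restarts,
                          max_iters = max_iters),
      pbbr_infeasible = function(e) NULL
    )
    if (is.null(d)) {
      tibble(k = k, feasible = FALSE, mean_block_size = NA_real_,
             max_block_size = NA_real_, reusability_entropy = NA_real_,
             mean_reusability = NA_real_, total_reusability = NA_real_)
    } else {
      dplyr::mutate(decomposition_summary(d), feasible = TRUE, .after = "k")
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- list(method = method, seed = seed,
                                  restarts = restarts, max_iters = max_iters,
                                  m = nrow(matrix), n = ncol(matrix))
  class(out) <- c("pbb_kcurve", class(out))
  out
}

#' Sample valid (generally suboptimal) decompositions
#'
#' Draws tiling decompositions by a randomized walk: starting from the
#' distinct-support tiling, blocks are bisected along random pieces until
#' exactly `k` blocks are in use, and a random number of reuse-carving
#' moves (which increase reusability without changing `k`) is applied. The
#' resulting decompositions are valid but span a range of total
#' reusabilities below the optimum.
#'
#' @inheritParams heuristic_kmrd
#' @param n_samples number of decompositions to draw (duplicates allowed).
#' @param max_retries bounded retries per sample.
#' @return a list of `pbb_decomposition` objects with `method = "sampled"`.
#' @export
sample_decompositions <- function(matrix, k, n_samples, seed,
                                  max_retries = 100L) {
  if (n_samples == 0L) return(list())
  m <- unclass(matrix)
  if (sum(m) == 0L) abort("matrix has no present entries", class = "pbbr_validation_error")
  purrr::map(seq_len(n_samples), function(i) {
    local_seed(derive_seed(seed, i), {
      for (try in seq_len(max_retries)) {
        st <- random_tiling(m, k)
        if (is.null(st)) next
        return(tiling_to_decomposition(matrix, st, "sampled",
                                       derive_seed(seed, i)))
      }
      abort(sprintf("could not construct a valid %d-block sample after %d retries",
                    k, max_retries), class = "pbbr_infeasible", k = k,
            k_min = NA_integer_, k_max = NA_integer_)
    })
  })
}

random_tiling <- function(m, k, max_steps = 20L * (k + 5L)) {
  st <- new_tiling_state(m)
  steps <- 0L
  while (st_k(st) > k) {
    ids <- which(st$live)
    colkey <- vapply(st$cols[ids], paste, "", collapse = ",")
    dup <- split(ids, colkey)
    dup <- dup[lengths(dup) >= 2L]
    if (length(dup) == 0L) return(NULL)
    grp <- dup[[sample.int(length(dup), 1L)]]
    st <- st_merge(st, grp[1], grp[2])
  }
  while (st_k(st) < k) {
    steps <- steps + 1L
    if (steps > max_steps) return(NULL)
    ids <- which(st$live & lengths(st$blocks) >= 2L)
    if (length(ids) == 0L) return(NULL)
    id <- ids[sample.int(length(ids), 1L)]
    B <- st$blocks[[id]]
    piece <- sort(sample(B, sample.int(length(B) - 1L, 1L)))
    if (st_k(st) + st_split_dk(st, id, piece, setdiff(B, piece)) > k) next
    st <- st_split(st, id, piece)
  }
  # a random amount of reuse carving leaves a spread of reusabilities
  n_carve <- sample.int(k + 2L, 1L) - 1L
  for (i in seq_len(n_carve)) {
    fm <- free_moves(st)
    if (is.null(fm)) break
    mv <- fm[sample.int(nrow(fm), 1L), ]
    st <- st_split(st, mv[1], st$blocks[[mv[2]]])
  }
  st
}
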