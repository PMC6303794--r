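m1 <- fixture_m1()

test_that("is_valid accepts exact union reconstruction and names violations", {
  blocks <- list(c("a", "b"), "c", c("c", "d"))
  usage <- rbind(c(1, 1, 0), c(0, 1, 1), c(0, 0, 1))
  d <- new_decomposition(blocks, usage, rownames(m1), colnames(m1))
  expect_true(is_valid(m1, d))
  # dropping {c} from c2 leaves the union short of the support
  bad_usage <- usage
  bad_usage[2, 2] <- 0
  d_bad <- new_decomposition(blocks, bad_usage, rownames(m1), colnames(m1))
  v <- is_valid(m1, d_bad)
  expect_false(v)
  expect_match(attr(v, "violation"), "c2")
  # a block used nowhere violates the usage invariant
  d_unused <- new_decomposition(c(blocks, list("a")),
                                rbind(usage, c(0, 0, 0)),
                                rownames(m1), colnames(m1))
  expect_false(is_valid(m1, d_unused))
  # duplicated blocks are rejected
  d_dup <- new_decomposition(list(c("a", "b"), c("b", "a")),
                             rbind(c(1, 1, 0), c(1, 1, 0)),
                             rownames(m1), colnames(m1))
  expect_false(is_valid(m1, d_dup))
})

test_that("singleton decomposition of any matrix is valid under saturation", {
  for (s in 1:5) {
    mat <- random_tiny_matrix(300 + s)
    mat <- drop_unused_elements(mat, quiet = TRUE)
    expect_true(is_valid(mat, singleton_decomposition(mat)))
  }
})

test_that("saturate_usage marks exactly the containing conditions", {
  u <- saturate_usage(m1, list(c("a", "b"), c("a", "b", "c"), c("c", "d")))
  expect_equal(rowSums(u), c(2, 1, 1))
  u2 <- saturate_usage(m1, list(c("a", "b"), "c", c("c", "d")))
  expect_equal(rowSums(u2), c(2, 2, 1))
  expect_equal(sum(u2), 5)
  # a block contained in no support gets zero reusability
  u3 <- saturate_usage(m1, list(c("a", "d")))
  expect_equal(sum(u3), 0)
})

test_that("saturated usage dominates any valid usage of the same blocks", {
  for (s in 1:10) {
    ps <- planted_system(m = 12, n = 5, k_star = 4, seed = 400 + s)
    sat <- saturate_usage(ps$matrix, ps$decomposition$blocks)
    expect_true(all(sat >= ps$true_usage))
  }
})

test_that("trivial column decomposition uses one block per distinct support", {
  d <- trivial_column_decomposition(m1)
  expect_equal(d$k, 3)
  expect_equal(sort(rowSums(d$usage)), c(1, 1, 2))
  expect_equal(d$total_reusability, 4)
  expect_true(is_valid(m1, d))
  # all columns identical: a single block reused n times
  same <- condition_matrix(matrix(1, 3, 4,
                                  dimnames = list(letters[1:3], paste0("c", 1:4))))
  ds <- trivial_column_decomposition(same)
  expect_equal(ds$k, 1)
  expect_equal(rowSums(ds$usage), 4)
  # duplicate columns fold into one block with reusability >= 2
  dup <- condition_matrix(cbind(c1 = c(1, 1, 0), c2 = c(1, 1, 0), c3 = c(0, 1, 1)),
                          elements = letters[1:3])
  dd <- trivial_column_decomposition(dup)
  expect_equal(dd$k, 2)
  expect_true(max(rowSums(dd$usage)) >= 2)
})

test_that("singleton decomposition reusabilities equal element usages", {
  d <- singleton_decomposition(m1)
  expect_equal(d$k, 4)
  expect_equal(sort(rowSums(d$usage)), c(1, 2, 2, 2))
  expect_equal(d$total_reusability, 7)  # number of ones in the matrix
  id <- condition_matrix(diag(3), elements = letters[1:3],
                         conditions = paste0("c", 1:3))
  expect_equal(rowSums(singleton_decomposition(id)$usage), rep(1, 3))
  z <- condition_matrix(rbind(a = c(1, 0), b = c(0, 0)), conditions = c("x", "y"))
  expect_error(singleton_decomposition(z), "zero usage")
})

test_that("closed universe of the micro-example matches hand enumeration", {
  u <- build_universe(m1, "closed")
  got <- lapply(u$blocks, paste, collapse = ",")
  expect_setequal(unlist(got), c("a,b,c", "c,d", "a,b", "c", "a", "b", "d"))
  cnt <- setNames(u$cnt, unlist(got))
  expect_equal(cnt[["a,b"]], 2)
  expect_equal(cnt[["c"]], 2)
  expect_equal(cnt[["a,b,c"]], 1)
  expect_equal(cnt[["c,d"]], 1)
  expect_equal(cnt[["d"]], 1)
})

test_that("closed blocks equal the intersection of the supports containing them", {
  for (s in 1:8) {
    mat <- random_tiny_matrix(500 + s)
    u <- build_universe(mat, "closed")
    m <- unclass(mat)
    for (i in seq_along(u$idx)) {
      b <- u$idx[[i]]
      cols <- which(colSums(m[b, , drop = FALSE]) == length(b))
      closure <- which(rowSums(m[, cols, drop = FALSE] == 1L) == length(cols))
      if (length(b) > 1L) expect_identical(b, closure)
      expect_gte(u$cnt[i], 1)
    }
  }
})

test_that("disjoint column supports close to supports plus singletons", {
  mat <- condition_matrix(cbind(c1 = c(1, 1, 0, 0), c2 = c(0, 0, 1, 1)),
                          elements = letters[1:4])
  u <- build_universe(mat, "closed")
  expect_setequal(vapply(u$blocks, paste, "", collapse = ","),
                  c("a,b", "c,d", "a", "b", "c", "d"))
})

test_that("all_subsets universe is guarded and exhaustive", {
  expect_error(build_universe(condition_matrix(matrix(1, 13, 2)), "all_subsets"),
               "guarded")
  u <- build_universe(m1, "all_subsets")
  # distinct non-empty subsets of {a,b}, {a,b,c}, {c,d}: 7 plus {d}, {c,d}
  expect_equal(length(u$blocks), 9)
  expect_true(all(u$cnt >= 1))
})

test_that("decomposition JSON round trip is exact", {
  d <- brute_force_kmrd(m1, 3)
  path <- file.path(withr::local_tempdir(), "d.json")
  write_decomposition(d, path)
  back <- read_decomposition(path)
  expect_identical(back$blocks, d$blocks)
  expect_equal(unname(back$usage), unname(d$usage))
  expect_identical(back$total_reusability, d$total_reusability)
  expect_identical(back$method, d$method)
})
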