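test_that("condition_matrix validates entries and labels", {
  m <- condition_matrix(rbind(a = c(1, 0), b = c(0, 1)), conditions = c("x", "y"))
  expect_s3_class(m, "condition_matrix")
  expect_error(condition_matrix(rbind(a = c(1, 2), b = c(0, 1))),
               "non-binary entry 2 at element 'a'")
  expect_error(condition_matrix(matrix(1, 2, 1, dimnames = list(c("a", "a"), "x"))),
               "duplicate label")
  expect_error(condition_matrix(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("tsv/csv/mtx round trips preserve entries and labels", {
  m1 <- fixture_m1()
  for (fmt in c("tsv", "csv", "mtx")) {
    path <- file.path(withr::local_tempdir(), paste0("m.", fmt))
    write_matrix(m1, path)
    back <- read_matrix(path)
    expect_identical(unclass(back), unclass(m1), label = fmt)
  }
  # identity matrix: supports are singletons
  id <- condition_matrix(diag(2), elements = c("e1", "e2"),
                         conditions = c("c1", "c2"))
  p <- file.path(withr::local_tempdir(), "id.tsv")
  write_matrix(id, p)
  expect_identical(unclass(read_matrix(p)), unclass(id))
  # 1x1 and empty-column matrices survive
  one <- condition_matrix(matrix(1, 1, 1, dimnames = list("e", "c")))
  p1 <- file.path(withr::local_tempdir(), "one.mtx")
  write_matrix(one, p1)
  expect_identical(unclass(read_matrix(p1)), unclass(one))
  ec <- condition_matrix(cbind(c1 = c(1, 0), c2 = c(0, 0)),
                         elements = c("a", "b"))
  p2 <- file.path(withr::local_tempdir(), "ec.csv")
  write_matrix(ec, p2)
  expect_identical(unclass(read_matrix(p2)), unclass(ec))
})

test_that("non-binary file entries are rejected with the offending cell named", {
  path <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines(c("element\tc1\tc2", "e1\t1\t0", "e2\t2\t1"), path)
  expect_error(read_matrix(path), "element 'e2', condition 'c1'")
})

test_that("transpose flag restores the fixed orientation", {
  m1 <- fixture_m1()
  path <- file.path(withr::local_tempdir(), "t.tsv")
  tm <- condition_matrix(t(unclass(m1)))
  write_matrix(tm, path)
  expect_identical(unclass(read_matrix(path, transpose = TRUE)), unclass(m1))
})

test_that("ct_threshold binarization follows the 35-cycle detection rule", {
  vals <- matrix(c(34.2, 35, NA, 20), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  b <- binarize_expression(vals, "ct_threshold", threshold = 35)
  expect_equal(unname(unclass(b)), rbind(c(1, 0), c(0, 1)))
  # all missing -> all absent
  allna <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_true(all(binarize_expression(allna, "ct_threshold") == 0))
  expect_error(binarize_expression(vals, "ct_threshold", threshold = -1), "positive")
})

test_that("count_positive binarization equates one observed tag with presence", {
  counts <- matrix(c(1, 0, 7, 0), 2, 2,
                   dimnames = list(c("g1", "g2"), c("c1", "c2")))
  b <- binarize_expression(counts, "count_positive")
  expect_equal(unname(unclass(b)), rbind(c(1, 1), c(0, 0)))
  counts[1, 1] <- -2
  expect_error(binarize_expression(counts, "count_positive"), "negative")
})

test_that("binarization is monotone in the Ct threshold", {
  withr::with_seed(11, {
    vals <- matrix(runif(60, 15, 45), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("c", 1:6)))
    vals[sample(60, 8)] <- NA
  })
  prev <- binarize_expression(vals, "ct_threshold", threshold = 20)
  for (t in c(25, 30, 35, 40)) {
    cur <- binarize_expression(vals, "ct_threshold", threshold = t)
    expect_true(all(cur >= prev))  # raising t can only switch 0 -> 1
    prev <- cur
  }
})

test_that("threshold choice is immaterial when no value falls between 25 and 35", {
  withr::with_seed(12, {
    vals <- matrix(sample(c(runif(30, 10, 24.9), runif(30, 35, 45))), 12, 5,
                   dimnames = list(paste0("g", 1:12), paste0("c", 1:5)))
  })
  ref <- binarize_expression(vals, "ct_threshold", threshold = 25)
  for (t in c(28, 30, 33, 35)) {
    expect_identical(unclass(binarize_expression(vals, "ct_threshold", threshold = t)),
                     unclass(ref))
  }
})

test_that("drop_unused_elements removes exactly the zero-usage rows", {
  m <- condition_matrix(rbind(a = c(1, 0), b = c(0, 0), c = c(0, 1)),
                        conditions = c("x", "y"))
  out <- drop_unused_elements(m, quiet = TRUE)
  expect_identical(rownames(out), c("a", "c"))
  expect_identical(attr(out, "removed"), "b")
  # no zero rows: unchanged, empty report
  m1 <- fixture_m1()
  out1 <- drop_unused_elements(m1, quiet = TRUE)
  expect_identical(unclass(out1)[, ], unclass(m1)[, ])
  expect_length(attr(out1, "removed"), 0)
  # all rows zero: warning, everything removed
  z <- condition_matrix(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  expect_warning(outz <- drop_unused_elements(z, quiet = TRUE), "zero usage")
  expect_identical(nrow(outz), 0L)
  expect_identical(attr(outz, "removed"), c("a", "b"))
})
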