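test_that("hypergeometric enrichment matches the closed-form tail sum", {
  # block of 5 with 3 annotated to T, universe of 20 with 4 annotated
  universe <- paste0("g", 1:20)
  ann <- annotation_map(data.frame(element = paste0("g", 1:4), term = "T"))
  block <- c("g1", "g2", "g3", "g10", "g11")
  res <- fisher_enrichment(list(block), ann, universe, correct = FALSE)
  expect_equal(res$p_raw, 496 / 15504, tolerance = 1e-12)
  # agrees with the one-sided Fisher exact test
  ft <- fisher.test(matrix(c(3, 2, 1, 14), 2), alternative = "greater")
  expect_equal(res$p_raw, ft$p.value, tolerance = 1e-10)
})

test_that("hypergeometric p matches exhaustive enumeration on tiny universes", {
  universe <- paste0("g", 1:10)
  K <- 4
  ann <- annotation_map(data.frame(element = paste0("g", 1:K), term = "T"))
  nb <- 4
  for (x_obs in 1:3) {
    block <- c(paste0("g", seq_len(x_obs)), paste0("g", K + seq_len(nb - x_obs)))
    p_pkg <- fisher_enrichment(list(block), ann, universe, correct = FALSE)$p_raw
    # oracle: fraction of all size-nb subsets with overlap >= x_obs
    combs <- utils::combn(10, nb)
    overlaps <- colSums(combs <= K)
    expect_equal(p_pkg, mean(overlaps >= x_obs), tolerance = 1e-12)
  }
})

test_that("blocks with no annotated members get p = 1; correction caps at 1", {
  universe <- paste0("g", 1:12)
  ann <- annotation_map(data.frame(element = c("g1", "g2"), term = c("A", "B")))
  res <- fisher_enrichment(list(c("g5", "g6")), ann, universe)
  expect_equal(res$p_raw, 1)
  expect_equal(res$p_corrected, 1)
  # factor = #terms x #blocks, capped
  ann10 <- annotation_map(data.frame(element = rep(paste0("g", 1:6), 10),
                                     term = rep(sprintf("T%02d", 1:10), each = 6)))
  blocks <- replicate(5, c("g1", "g2"), simplify = FALSE)
  res5 <- fisher_enrichment(blocks, ann10, universe)
  expect_equal(res5$p_corrected, pmin(1, res5$p_raw * 10 * 5))
  # corrected p is monotone in the correction factor and within [raw, 1]
  res1 <- fisher_enrichment(blocks[1], ann10, universe, n_blocks_correction = 1)
  expect_lte(res1$p_corrected[1], res5$p_corrected[1])
  expect_gte(res5$p_corrected[1], res5$p_raw[1])
})

test_that("ties among best terms break lexicographically", {
  universe <- paste0("g", 1:10)
  ann <- annotation_map(data.frame(element = c("g1", "g2", "g1", "g2"),
                                   term = c("Zeta", "Zeta", "Alpha", "Alpha")))
  res <- fisher_enrichment(list(c("g1", "g2")), ann, universe, correct = FALSE)
  expect_equal(res$best_term, "Alpha")
})

test_that("Jaccard agglomerative clustering groups co-expressed elements", {
  m1 <- fixture_m1()
  cl <- jaccard_agglomerative_blocks(m1, 3)
  keys <- sort(vapply(cl, function(b) paste(sort(b), collapse = ","), ""))
  expect_identical(keys, c("a,b", "c", "d"))
  # k = m: all singletons; k = 1: everything together
  expect_length(jaccard_agglomerative_blocks(m1, 4), 4)
  expect_identical(sort(jaccard_agglomerative_blocks(m1, 1)[[1]]),
                   c("a", "b", "c", "d"))
  expect_error(jaccard_agglomerative_blocks(m1, 0), "1..m")
  # always a partition
  for (s in 1:5) {
    mat <- random_small_matrix(600 + s, m_max = 20, n_max = 6)
    k <- sample(2:min(10, nrow(mat)), 1)
    cl <- jaccard_agglomerative_blocks(mat, k)
    expect_length(cl, k)
    expect_setequal(unlist(cl), rownames(mat))
    expect_equal(sum(lengths(cl)), nrow(mat))
  }
})

test_that("random size-matched groupings conserve sizes and respect the seed", {
  universe <- paste0("g", 1:15)
  blocks <- random_size_matched_blocks(universe, c(2, 1, 1), seed = 4)
  expect_equal(lengths(blocks), c(2, 1, 1))
  expect_true(all(unlist(blocks) %in% universe))
  expect_identical(blocks, random_size_matched_blocks(universe, c(2, 1, 1), seed = 4))
  expect_identical(random_size_matched_blocks(universe, 15, seed = 1)[[1]],
                   sort(universe))
  expect_error(random_size_matched_blocks(universe, 16, seed = 1), "1..|universe|")
  # disjoint variant partitions
  dj <- random_size_matched_blocks(universe, c(5, 5, 5), seed = 2, disjoint = TRUE)
  expect_setequal(unlist(dj), universe)
  expect_error(random_size_matched_blocks(universe, c(9, 9), seed = 2, disjoint = TRUE),
               "sum")
})

test_that("threshold saturation counts every block when correction is off", {
  universe <- paste0("g", 1:10)
  ann <- annotation_map(data.frame(element = universe, term = "T"))
  blocks <- list(c("g1", "g2"), c("g3", "g4", "g5"))
  res <- fisher_enrichment(blocks, ann, universe, alpha = 1.01, correct = FALSE)
  expect_true(all(res$significant))
})

test_that("planted private-term structure favors the decomposition blocks", {
  ps <- planted_system(m = 60, n = 6, k_star = 6,
                       block_size_sampler = function(k) rep(8L, k),
                       seed = 99)
  h <- heuristic_kmrd(ps$matrix, 6, seed = 5)
  ann <- private_term_annotations(h$blocks)
  cmp <- enrichment_comparison(ps$matrix, 6, ann, alpha = 0.01, seed = 5)
  counts <- glance(cmp)
  kmrd_n <- counts$n_significant[counts$method == "kmrd"]
  rand_n <- counts$n_significant[counts$method == "random_size_matched"]
  expect_gte(kmrd_n, rand_n)
  expect_equal(nrow(tidy(cmp)), 3 * 6)
  # empty annotation map: nothing significant anywhere
  empty <- annotation_map(data.frame(element = character(0), term = character(0)))
  cmp0 <- enrichment_comparison(ps$matrix, 6, empty, seed = 5)
  expect_true(all(glance(cmp0)$n_significant == 0))
})

test_that("annotation readers accept two-column TSV and GAF", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "ann.tsv")
  writeLines(c("g1\tT1", "g2\tT1", "g3\tT2"), tsv)
  a <- read_annotations(tsv)
  expect_equal(nrow(a), 3)
  expect_setequal(a$term, c("T1", "T2"))
  gaf <- file.path(dir, "ann.gaf")
  writeLines(c("!gaf-version: 2.2",
               paste("DB", "g1", "SYM", "", "GO:0001", "REF", "IEA",
                     "", "P", "", "", "protein", "taxon:9606", "20200101",
                     "DB", sep = "\t"),
               paste("DB", "g2", "SYM", "", "GO:0002", "REF", "IEA",
                     "", "P", "", "", "protein", "taxon:9606", "20200101",
                     "DB", sep = "\t")), gaf)
  g <- read_annotations(gaf, format = "gaf")
  expect_equal(g$element, c("g1", "g2"))
  expect_equal(g$term, c("GO:0001", "GO:0002"))
  expect_error(read_annotations(file.path(dir, "missing.tsv")), "not found")
})
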