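Package: pbbr
Title: Reusable Building-Block Decompositions of Binary Condition Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes binary element-by-condition presence/absence matrices
    into k possibly overlapping building blocks whose unions exactly
    reconstruct the element set of every condition, maximizing the total
    (equivalently, at fixed k, the average) reusability of the blocks.
    Provides exact optimization for tiny instances and a seeded greedy plus
    local-search heuristic for realistic ones; two constrained null models
    (column-sum preserving and row-sum-multiset preserving randomizations)
    with seeded ensembles; decomposition statistics (block sizes, reusability
    entropy, element-usage distributions, binomial usage expectations,
    AUC-over-k ratio comparisons); synthetic generators with planted
    decompositions and U-shaped usage distributions; and hypergeometric
    term-enrichment comparisons against Jaccard agglomerative clustering and
    size-matched random groupings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
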