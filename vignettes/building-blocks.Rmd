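---
title: "Reusable building blocks: model, solvers, and null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reusable building blocks: model, solvers, and null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbbr)
```

## The question

Biological systems deploy a fixed repertoire of elements — proteins across
tissues, miRNAs across conditions — in different combinations, and the
combinations are widely believed to be assembled from *modules*: sets of
elements redeployed as a whole. `pbbr` quantifies that intuition. Given a
binary element-by-condition matrix $C$ ($m$ elements, $n$ conditions, entry
1 = present), it decomposes the observed condition supports into $k$
building blocks whose unions reconstruct every condition exactly, chooses
the decomposition whose blocks are maximally *reusable*, and asks whether
the reusability structure of the real system differs from that of
randomized matrices with the same margins.

## Decompositions and the reusability objective

A decomposition is a list of $k$ pairwise-distinct non-empty blocks
$B_1,\dots,B_k \subseteq \{1..m\}$ plus a $k \times n$ binary usage matrix
$U$; it is valid when, for every condition $j$, the union of the blocks
with $U_{ij}=1$ equals the support $\mathrm{supp}(C_j)$ exactly, and every
block is used somewhere. The reusability of block $i$ is
$r_i = \sum_j U_{ij}$, and a $k$-MRD (maximally reusable decomposition)
maximizes the total $\sum_i r_i$ — equivalent to maximizing the mean at
fixed $k$.

**The tiling constraint.** The optimizers search over decompositions in
which the blocks used within one condition are pairwise *disjoint* — each
condition's support is tiled, while blocks overlap and are reused freely
across conditions. This is a deliberate and load-bearing design choice:

* Without it the objective is degenerate. Under unconstrained unions a
  block may be marked "used" in any condition that merely contains it, so
  arbitrarily many sub-blocks of an already-reconstructed region (for
  instance any subset of a constitutive core) can be appended, inflating
  total reusability without contributing anything to reconstruction. Block
  counts and block sizes then reflect that bookkeeping freedom, not the
  system.
* Under tiling, every decomposition satisfies the accounting identity
  $\sum_i \mathrm{size}_i \cdot r_i = \#\text{ones}(C)$. Maximizing
  $\sum_i r_i$ therefore *forces* structure discovery: the only way to gain
  reusability is to carve out sub-blocks shared across conditions (a
  constitutive core, co-expressed classes) and reuse them, and the finest
  useful blocks are the *classes* of elements with identical presence rows.
* The two notions agree exactly on the package's pinned micro-example
  (`fixture_m1()`): the optimal totals are 5 at $k=3$, 7 at $k=4$, and no
  valid 2-block decomposition exists.

`is_valid()` checks the permissive exact-union contract by default (any
valid usage, overlaps allowed, as produced e.g. by `saturate_usage()` or a
planted overlap-permitting generator); `is_valid(..., tiling = TRUE)`
checks the stricter contract that every solver output satisfies.

Two consequences worth knowing. First, total reusability is non-decreasing
in $k$ throughout the practically relevant range: any block of size
$\ge 2$ can be bisected, both pieces inherit every use of the parent, and
the total grows by the parent's reusability. The natural upper anchor of
the range is the singleton decomposition ($k$ = number of used elements,
total = number of ones — the maximum possible). Beyond that anchor,
decompositions exist only by giving different conditions different
partitions of the same sets, and optimal totals can *decrease*; the
package reports such $k$ as feasible when they are but treats the
singleton anchor as the end of the meaningful curve. Second, the *mean*
reusability (total/$k$) typically declines with $k$; both totals and means
are reported so either convention can be examined.

## Solvers

**Exact (tiny instances).** `brute_force_kmrd()` enumerates, by
depth-first branch-and-bound, all combinations of set-partitions of the
condition supports, pruning on the block budget $k$ and an optimistic
total bound, and returns the maximal-total solution (ties broken toward
the lexicographically smallest block list). It is guarded to
$m \le 12,\ n \le 6$ and exists to be the oracle: the test suite compares
it against an independent naive enumerator on micro matrices, and the
heuristic against it on hundreds of (matrix, $k$) pairs.

**Heuristic (realistic instances).** `heuristic_kmrd()` starts from the
distinct-support tiling (one block per distinct non-empty column support)
and improves it with two moves:

1. *Reuse carving*: whenever one palette block is a proper subset of
   another, the larger is split along the smaller everywhere it is used.
   The shared piece gains all those uses, the total grows by the larger
   block's reusability, and the number of blocks never increases. This is
   the move that extracts a constitutive core: after the first carve the
   core exists as a block, and every other support sheds it in one move.
2. *Class splits*: to reach a larger $k$, the most-reused splittable block
   is bisected along its intersection with the highest-usage class of
   identically-expressed elements (single-class blocks peel one element).
   Both pieces inherit the parent's uses, so the total strictly grows.

For $k$ at or above the number of element classes, the solver instead
starts directly from the *class tiling* (every column tiled by its
classes) and peels singletons — at that point the class tiling is the
high-reuse backbone and only the budget needs adjusting. For $k$ below the
number of distinct supports, blocks tiling identical condition sets are
merged. The first restart is deterministic; later restarts randomize move
order (block choice weighted by reusability, random bipartitions), and the
best result is returned. Everything is bit-reproducible for fixed
`(matrix, k, seed, restarts, max_iters)`; `max_iters` caps only the
optional carving moves, never the repairs needed to reach $k$.

On 50 seeded random matrices ($m \le 7$, $n \le 4$), across every feasible
$k$ up to the singleton anchor, the heuristic reproduces the exact optimum
in about 98% of (matrix, $k$) pairs and never exceeds it; the remaining
gaps are instances whose optima interleave classes across blocks in ways
single bisections cannot reach.

`sample_decompositions()` deliberately does *not* optimize: it applies
random bisections and a random number of carving moves, producing valid
tilings whose totals spread over a range below the optimum — useful for
studying how block-size structure varies with reusability away from the
optimum.

## Null models

Two single-margin randomizations, both exactly conservative and seeded:

* `dp_rand()` — *density preserving*: each condition keeps its number of
  present elements; which elements are present is drawn uniformly without
  replacement, independently per condition. Column sums are conserved
  exactly; row sums float.
* `rss_rand()` — *row-sum-sequence preserving*: the multiset of element
  usages is conserved exactly — row sums are permuted across elements and
  each element's presences are placed uniformly among the conditions. Row
  sums conserved; column sums float.

Rows (respectively columns) are randomized independently; no dual-margin
(swap-based) null is provided, since the two single-margin models bracket
the questions the package asks: what part of the structure is explained by
how many elements each condition uses, and what part by how broadly each
element is used. Randomized matrices may contain empty rows, empty columns
and duplicate columns; every downstream operation accepts them.
`pbb_ensemble()` derives one sub-seed per member from `(base_seed, index)`
with a fixed multiplicative hash, so ensembles are reproducible end-to-end
and single members can be regenerated in isolation. Over a
constant-column-sum matrix, the element-usage histogram of a large
`dp_rand` ensemble converges to the binomial expectation at matched
density (`binomial_usage_expectation()`); the acceptance suite verifies
this with a chi-square goodness-of-fit over 10,000 replicates.

## Statistics and comparisons

For each decomposition: mean and maximum block size, mean and total
reusability, and the Shannon entropy of the reusability distribution,
$H = -\sum_v p_v \log_2 p_v$ over the empirical distribution of distinct
reusability values — zero when all blocks are equally reused, up to
$\log_2 k$ when all values differ. Entropy is reported in bits; the base
cancels in every ratio comparison. `kmrd_curve()` tabulates these per $k$
and flags infeasible $k$ rather than dropping them.

`ensemble_comparison()` compares a real system's curve with an ensemble of
null curves on the intersection of their feasible grids: per-member
AUC ratios (trapezoid rule on the raw grid; on an equal-width grid the
AUC ratio equals the ratio of means), their mean/min/max, and the z-score
of the real mean-over-$k$ against the ensemble's. The directional result
the package reproduces on synthetic data, and the reason the tiling
objective matters, is:

* *mean block size*: ratios (null/real) above 1 — a system with a shared
  core and structured co-usage decomposes into smaller, less overlapping
  blocks than density-matched noise, because the core is carved out once
  and reused while the null must tile each condition with mostly private
  material;
* *reusability entropy*: ratios below 1 — the real system's blocks span
  condition-specific to constitutive reusabilities, while the null's
  concentrate near the low end.

## Synthetic study systems

`ushaped_matrix(m, n, alpha, beta, seed)` draws a presence probability
$p_e \sim \mathrm{Beta}(\alpha, \beta)$ per element and fills each row
i.i.d. Bernoulli($p_e$). The defaults $\alpha = \beta = 0.3$ put most mass
near 0 and 1, reproducing the U-shaped expression-breadth histogram of
real presence/absence data — many rarely-used and many constitutive
elements, in excess of the matched-density binomial at both extremes. This
is the study condition for the directional comparisons: 10 matrices with
$m = 200$, $n = 8$ against 20 `dp_rand` equivalents each, over the $k$
grid $\{15, 45, 75, 105, 135\}$ spanning the feasible range from near the
minimum to near the singleton anchor (about 140 used elements at these
settings). The generator emulates the usage *distribution* only: elements
are independent, so it contains no planted co-expression modules beyond
the classes its tails create, and passing the directional checks on it
says the contrasts follow from the usage distribution alone — it does not
certify behavior on real data with correlated elements.

`planted_system()` plants $k^\ast$ blocks with a usage mix chosen to echo
the observed extremes (by default ~20% constitutive blocks, ~30%
condition-specific, the rest Bernoulli(0.5) per condition with at least
one use) and assembles the matrix from their unions. By default the
planted blocks are *disjoint*, so the planted decomposition is itself a
tiling and its total reusability is a hard feasibility bound any solver
run at $k = k^\ast$ must match or beat — the package's recovery test
demands 20/20 seeded systems. With `disjoint = FALSE` blocks may overlap;
the planted decomposition is then still union-valid but no longer a
tiling bound.

`fixture_m1()` pins the 4-element, 3-condition worked example used
throughout the documentation and tests (supports $\{a,b\}$,
$\{a,b,c\}$, $\{c,d\}$; density $7/12$; optimal totals 5 and 7 at
$k = 3, 4$).

## Term enrichment baselines

`fisher_enrichment()` scores each block against each term with the
one-sided hypergeometric upper tail (the one-sided Fisher exact test) over
a fixed element universe, assigns each block its most-enriched term
(minimum raw $p$; ties broken lexicographically), and applies a Bonferroni
factor of (number of terms) × (number of blocks), capped at 1, with
significance called at corrected $p < 0.01$ by default.
`enrichment_comparison()` evaluates three groupings under identical
universe, terms and correction factor: the heuristic $k$-MRD blocks, a
$k$-cluster Jaccard agglomerative clustering of the element rows
(`stats::hclust`, average linkage by default — the linkage is configurable
since the choice is conventional), and random groupings size-matched to
the decomposition blocks (overlap permitted to match block semantics; a
disjoint variant is available). The random baseline's blocks are drawn
uniformly per size, so with informative annotations the decomposition
should dominate it — the property the tests assert on planted systems
with private per-block terms.

## Numerical and interface conventions

* Binarization: `ct_threshold` calls presence iff the Ct value is
  non-missing and strictly below the cap (default 35 cycles; missing =
  not detected = absent; the strictness is configurable). For data whose
  values avoid the 25–35 band entirely, any threshold in that band gives
  identical matrices — the robustness check the tests replay.
  `count_positive` calls presence from one observed count.
* Orientation is fixed (rows = elements); transposed files must be read
  with `transpose = TRUE`, never guessed. Duplicate condition columns are
  retained — they genuinely raise reusability.
* All tie-breaks are total-order deterministic (reusability, size,
  lexicographic block keys), so fixed seeds give bit-identical outputs;
  every stochastic entry point takes an explicit seed and restores the
  caller's RNG state.
* Problem sizes in the test and acceptance studies (50 tiny oracle
  matrices; 1,000 conservation replicates; 10,000 binomial-law
  replicates; 20 planted systems up to $m = 30$; 10 × 21 curves at
  $m = 200$) were chosen once as the smallest sets that exercise each
  claim with comfortable statistical margins.

## Known limitations

* The heuristic explores only bisection/carve/merge moves; optima that
  require re-partitioning several conditions at once can be missed
  (observed in ~2% of tiny-instance pairs). Restarts mitigate but do not
  eliminate this.
* Exact minimum-$k$ computation is exponential and therefore guarded to
  tiny instances; elsewhere the greedy minimum is reported.
* No claim is made that individual maximally-reusable blocks are
  biologically meaningful units; the decomposition maximizes reusability
  and nothing else, and its value is as an upper bound and a comparison
  instrument against null ensembles.
* Annotations are consumed as flat element-to-term maps; no ontology
  graph propagation is performed.
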