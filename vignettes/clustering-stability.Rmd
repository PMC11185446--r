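---
title: "Clustering stability diagnostics: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering stability diagnostics: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Graph-based clustering of single-cell RNA-seq data is controlled by
parameters — chiefly the modularity resolution and the dimensionality of the
embedding — whose values are routinely chosen by looking at projections.
`scstability` makes that choice quantitative with two per-cell statistics, a
flow representation of cluster rearrangements, and the downstream
interpretation steps (differential expression, over-representation) that a
clustering feeds. This vignette explains the models behind each piece, the
parameters that matter, what the built-in simulators do and do not emulate,
and the numerical decisions taken where the design was genuinely open.

```{r setup}
library(scstability)
```

## Co-clustering conservation

Two clusterings of the same cells at adjacent parameter values, step
*x−1* and step *x*, are compared cell by cell. Conceptually each run defines
a co-clustering matrix `CCM[i, j] = 1` iff cells *i* and *j* share a
cluster; the conservation of cell *i* is the fraction of its mates (the
*j ≠ i* with `CCM[j, i] = 1` at step *x−1*) that are still mates at step
*x*:

```{r}
prev <- cell_partition(as.character(1:6), c(1, 1, 1, 1, 2, 2),
                       param_value = 0.4)
curr <- cell_partition(as.character(1:6), c(1, 1, 1, 3, 2, 2),
                       param_value = 0.5)
coclustering_conservation(prev, curr)
```

Cell 4 was excised from its cluster of four: its three former mates are all
lost (CC = 0), while each remaining member keeps two of three (CC = 2/3).
Values are in [0, 1] by construction and invariant to relabeling clusters.

Three decisions fix the corner cases:

* **Diagonal.** `CCM[i, i] = 1` formally, but every consumer quantifies over
  *j ≠ i*; a cell is never its own mate.
* **Singletons.** A cell that was a singleton at step *x−1* has denominator
  0. Its CC is *missing*, not 0 or 1 — any imputation would bias the
  conservation distribution — and it is excluded from the boxplot summary
  quantiles (`conservation_profile()` reports `n_missing` per pair).
* **One axis per sweep.** "Adjacent" is defined along a single strictly
  increasing parameter axis. Sweeping resolution and the number of principal
  components at once has no well-defined adjacency; use two sweeps
  (`sweep_clustering()`, `sweep_npcs()`).

The quadratic co-clustering matrix is a definitional device only:
`coclustering_conservation()` works from label contingency counts, so the
cost is linear in cells per pair. `build_coclustering()` materializes the
sparse matrix when the object itself is wanted.

## Clustering Uncertainty Score

At fixed parameters, stochastic modularity optimizers return different
partitions for different seeds. Over N seeded runs, let J_i be the set of
cells co-clustered with cell *i* in **at least one** run (the union of
mates — not the intersection, and not all cells). The score is one minus the
mean pairwise co-membership agreement:

CUS_i = 1 − (1/(|J_i|·N)) Σ_{j∈J_i} Σ_n 1[i, j share a cluster in run n].

Orientation matters: 0 means perfectly stable (the name is *uncertainty*,
and profiles are scanned for *minima*). Two degenerate cases are fixed by
convention: a cell that is a singleton in every run has empty J_i and scores
0 (consistently isolated is consistently clustered), and N ≥ 2 is required.

The score's characteristic behavior, and the reason it is more informative
than a global agreement index, is its asymmetry:

* a *small* group of cells inconsistently excised from a large cluster
  penalizes the large cluster's members heavily — each stable member's J_i
  is dominated by mates it keeps, so the few runs in which partners
  disappear weigh on a small union set — producing high scores from
  *infrequent* losses;
* an unstable border between clusters of similar size yields moderate
  scores spread over many cells.

`cus()` computes scores from per-run sparse co-membership cross-products
(never a dense cell-by-cell loop); the test suite holds it exactly equal to
a literal triple-loop enumeration on hundreds of random ensembles.

### The ambiguous-subpopulation model

The simulator reproduces the benchmark used to characterize the score: two
stable clusters that never change, plus ambiguous cells that each join
cluster 1 with probability p, independently per cell and per run. The
population totals 250 cells — 220 consistently clustered and 30 ambiguous —
and three configurations are studied: ambiguity toward the larger of
disparate clusters (200/20), between balanced clusters (110/110), and toward
the smaller cluster (20/200). The disparate splits are this package's
convention; only the 220/30 totals are fixed by the benchmark.
Independent per-cell draws are the minimal model consistent with that
design; a correlated variant (one shared draw per run) would be a different,
stronger model and is not provided.

Under this model the expected class means have closed forms (stable–ambiguous
pairs agree with probability p or 1−p, ambiguous–ambiguous pairs with
p² + (1−p)²). With D the mate-universe size s1 + s2 + a − 1:

* stable cluster 1: E[CUS] = a(1−p) / (s1 − 1 + a),
* stable cluster 2: E[CUS] = a·p / (s2 − 1 + a),
* ambiguous: E[CUS] = 1 − [s1·p + s2(1−p) + (a−1)(p² + (1−p)²)] / D.

`cus_expected()` also returns the Monte-Carlo standard error of each class
mean: the stable-class mean is a linear function of a·N Bernoulli draws, and
the ambiguous-class mean is an i.i.d. average over runs of a quadratic in
the per-run cluster-1 occupancy S ~ Binomial(a, p), whose moments are summed
exactly over `dbinom`. These formulas take every potential mate to be in
J_i, which fails only with probability of order (1−p)^N + p^N — negligible
on the interior of the p-axis at N = 200. At p ∈ {0, 1} all runs are
identical and CUS is exactly 0 for every cell; `cus_expected()` returns that
limit explicitly rather than the interior formula.

```{r}
sc <- ambiguity_scenario(110, 110, 30, p_assign = 0.5, n_runs = 200,
                         master_seed = 1)
cus_expected(sc)
```

One subtlety uncovered by the closed form: "disparate cluster sizes stretch
the CUS range" is a statement about the *configuration*, not about one
orientation of it. With ambiguity directed at the larger cluster only, the
balanced configuration actually has the wider dataset-range on part of the
p-axis (e.g. 200/20 toward-larger at p = 0.7: balanced spread ≈ 0.43 versus
disparate ≈ 0.39, closed form). The 200/20 family is symmetric under
p ↔ 1−p with the two orientations swapping, so the package's tests compare
the wider of the two orientations against the balanced case at each matched
p — which holds everywhere.

### Profiles and minima

`cus_profile()` stacks per-resolution CUS distributions;
`find_local_minima()` flags parameter values whose mean (or median) is
strictly smaller than both neighbors. Endpoints are never minima — nothing
is known beyond the grid — and a flat valley (exact ties strictly below
both flanks) is reported once at its left-most value. The tie rule is this
package's convention; minima detectors are not standardized in the field.

### How many seeds

`N = 20` is the working default for real data (the CLI's `--n-seeds`):
class-mean standard errors scale as 1/√N, and 20 runs resolve the
stable/transition contrast that parameter selection needs. The benchmark
simulations use N = 200 so that Monte-Carlo error is small against the
closed form. Seeds are derived deterministically from one master seed.

## The clustering backend

The metrics are clusterer-agnostic — `read_assignments()` ingests label
tables from any tool — but a standard backend is included so the pipeline is
self-contained: PCA embedding (`reduce_pca()`, genes centered, component
signs canonicalized), exact k-nearest-neighbor search on the embedding,
shared-nearest-neighbor Jaccard edge weights pruned below 1/15 with k = 20,
and Louvain modularity optimization with a resolution parameter
(`igraph::cluster_louvain`), seeded per run. These constants mirror the
common defaults of the ecosystem this package sits in. Neighbor search uses
the full distance matrix: exact, deterministic, and quadratic in cells —
appropriate up to tens of thousands of cells, not hundreds of thousands.

Labels are canonicalized to consecutive integers from 0 ordered by
decreasing cluster size, so exports are stable across sessions. At
resolution 0 the null-model penalty vanishes and a single community attains
the maximal objective; that limit is returned directly, since on
*disconnected* graphs an optimizer may legitimately stall on
objective-neutral merges and return one community per component. For a
sweep, the first seed's partition represents each parameter value in
conservation and flow displays — an explicit convention, since adjacent-step
comparisons need one partition per step.

## Differential expression

`de_test()` is the two-sided Wilcoxon rank-sum test per gene, with the
conventional pre-filters: a gene is tested when detected in at least
`min_pct` (default 0.1) of either group *and* |log2 fold change| ≥
`min_lfc` (default 0.25). Fold changes are computed before filtering, as
log2((mean₁ + 1)/(mean₂ + 1)) on the normalized scale — the pseudocount-1
convention. Exact enumeration is used when both groups have ≤ 25 cells and
the gene has no tied values (zero-inflated counts usually tie); otherwise
the tie-corrected normal approximation with continuity correction. The two
paths agree within |Δp| ≤ 0.02 at group sizes 15–25, and on null data the
test is calibrated (type-I rate within binomial error of 0.05) — both are
asserted in the test suite.

`run_de()` enumerates comparisons from cell metadata: `one_vs_rest` (each
level against all other cells — the marker-gene contrast), `one_vs_one`
(every unordered level pair), and `conditional` (every pair of
primary-variable levels within each level of a second variable, e.g.
treatment pairs within each cluster). BH correction is applied within each
comparison, not across comparisons — each contrast is its own family of
hypotheses. Groups under 3 cells are skipped with a warning rather than
producing meaningless rank statistics.

## Over-representation

`fisher_enrich()` cross-classifies the background universe by DE status and
gene-set membership and reports the literal odds ratio
(DE_path / nonDE_path) / (DE_nonpath / nonDE_nonpath) with no continuity
correction: boundary tables yield 0 or +Inf exactly, and the exact p-value
handles zero cells natively. This is deliberately *not* the conditional
maximum-likelihood estimate that `fisher.test()` prints; the p-value is the
standard two-sided Fisher exact probability. Sidedness is a package
decision (two-sided detects depletion as well as enrichment), as is the
background universe: "consistently expressed" is operationalized by
`make_universe()` as detection in ≥ 10% of cells, configurable. Both
choices move the contingency table, so results should always be read
against the reported universe. BH correction is applied across all sets of
one collection. Gene-set collections travel as GMT files; none are bundled
— licensing of the common pathway databases belongs to their providers.

## The count simulator

`simulate_counts()` generates negative-binomial counts with three planted
features chosen to reproduce, in miniature, the behaviors the diagnostics
exist to detect:

* **private markers** per cluster (default 25 genes at fold 2.5) — the
  recoverable structure;
* a **shared program** between clusters 1 and 2 (25 genes at fold 2.5) —
  two related subtypes beside one distinct population, the hierarchy that
  makes low resolutions merge and intermediate resolutions separate;
* a **continuous activity gradient** across all cells (40 genes scaled up
  to fold 4 by a uniform latent state) — smooth heterogeneity, like
  activation or cell-cycle state, that high resolutions cut at arbitrary,
  seed-dependent places.

Signal genes draw baseline means from a moderately expressed regime
(log-normal, median 0.6), as canonical markers do; background genes follow a
broader log-normal (median 0.3, σ = 1). Dispersion (NB size 2) and mild
log-normal depth variation (σ = 0.3) are typical of UMI data after QC. With
the default 600 cells (250/200/150) this yields the full diagnostic
signature: a stable 2-cluster regime at resolution ≈ 0.1, a noisy
transition, a 3-cluster plateau with median CUS below 0.02 across seeds,
and gradient-driven instability from resolution ≈ 0.9.

What the simulator does **not** emulate: doublets, ambient RNA, batch
effects, gene–gene correlation beyond the planted programs, and realistic
library-size tails. Passing tests therefore demonstrate that the metrics
behave as designed on data with known structure — not that any particular
real dataset has a resolution this clean. On real data the same profile
shapes appear, but plateaus are shorter and minima shallower.

Problem sizes used throughout the checks — 250-cell ensembles at N = 200
runs, 600-cell end-to-end sweeps over ten resolutions and ten seeds,
2000-gene null calibrations, exhaustive 2×2 enumeration over a 30-gene
universe — were chosen so the whole suite documents the package's behavior
at desk scale while every brute-force oracle stays literal.

## QC and normalization plumbing

`qc_filter()` removes cells failing *any* threshold — fewer than 1000
detected features **or** fewer than 4000 total counts by default, both
strict inequalities, optionally a mitochondrial-percent ceiling — and
reports per-criterion removal counts. `mito_ribo_fractions()` computes the
mitochondrial and ribosomal count percentages from configurable gene-name
patterns; they are exported as metadata but **not** regressed out —
variance-stabilizing normalization with covariate regression is upstream
scope, and `normalize_counts()` (median-library scaling + log1p) is
deliberately simple plumbing. Supply an externally normalized matrix to any
function that takes one when a stronger normalization is wanted.

## Known limitations

* O(cells²) neighbor search and per-pair conservation; fine to ~20k cells.
* CC/CUS are label-co-membership statistics: they see *that* assignments
  change, not *how far* cells move in expression space.
* The minima detector is a pointwise rule on a user-chosen grid; a
  too-coarse grid can hide a transition between grid points.
* Closed-form ambiguity expectations assume the full union-mate set and are
  inaccurate within O((1−p)^N + p^N) of the endpoints; use the exact 0
  limit at p ∈ {0, 1}.
* The Wilcoxon exact path refuses tied data rather than falling back
  silently when forced with `method = "exact"`.
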