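# scstability

Quantitative selection of clustering parameters for single-cell RNA-seq.

Graph-based clustering of cells depends on tuning knobs — above all the
modularity **resolution** and the number of principal components — that are
usually chosen by eyeballing UMAPs. `scstability` replaces that visual
inspection with per-cell stability diagnostics:

* **Co-clustering conservation (CC).** For two clusterings at adjacent
  parameter values (step *x−1* to *x*), each cell's CC is the fraction of its
  cluster mates that it keeps:

  CC_i = |{ j ≠ i : j mate of i at x−1 and at x }| / |{ j ≠ i : j mate of i at x−1 }|

  CC = 1 means the cell's neighborhood survived the parameter change intact;
  a cell that was a singleton at x−1 has no mates and is reported missing.

* **Clustering Uncertainty Score (CUS).** Re-run the clusterer N times at
  *fixed* parameters with different seeds. With J_i the set of cells that were
  co-clustered with cell i in *any* run,

  CUS_i = 1 − (1 / (|J_i| · N)) Σ_{j ∈ J_i} Σ_{n=1..N} 1[cell i and j share a cluster in run n]

  CUS = 0 for a perfectly stable cell; infrequent losses of cluster partners
  are penalized heavily, unstable borders between similar-sized clusters
  moderately. Local minima of the CUS-vs-resolution profile mark resolutions
  whose clusterings match the structure of the data.

* **Cluster-flow (Sankey) tables** counting cells that move between clusters
  of adjacent parameter values, with exact weight conservation.

* **Wilcoxon rank-sum differential expression** in three modes
  (one-vs-rest, one-vs-one, and conditional: pairs of one variable within
  each level of a second), with detection- and fold-change pre-filters and
  per-comparison BH correction.

* **Gene-set over-representation** of DEG lists by Fisher's exact test over
  GMT collections, with the literal odds ratio
  OR = (DE_path / nonDE_path) / (DE_nonpath / nonDE_nonpath).

A Louvain/SNN clustering backend, 10x MTX / TSV / GMT readers and writers, QC
filtering, and simulators (partition ensembles with a planted ambiguous
subpopulation; negative-binomial counts with planted clusters, markers and a
pathway) make every stage runnable end to end without external data. All
stability metrics also accept assignment tables produced by any external
clusterer.

## Worked example

```r
library(scstability)

# 600 simulated cells: three clusters, two of them related subtypes,
# plus a continuous activity gradient
sim  <- simulate_counts(planted_count_model(master_seed = 7))
norm <- normalize_counts(sim$counts)
g    <- snn_graph(reduce_pca(norm, n_pcs = 10), k = 20)

sw   <- sweep_clustering(g, resolutions = seq(0.1, 1, 0.1), seeds = 1:10)
prof <- cus_profile(sw$ensembles)
print(prof)
find_local_minima(prof, "median")
```

```
uncertainty_profile over 10 values of resolution
 param_value n_runs   mean median ...
         0.1     10 0.0028 0.0020
         0.2     10 0.2994 0.3433
         0.3     10 0.0151 0.0071
         ...
         0.8     10 0.0247 0.0155
         0.9     10 0.1982 0.0179
         1.0     10 0.0898 0.0272
[1] 0.4 0.6 0.8
```

Reading: at resolution 0.1 the two related subtypes are merged (stable, CUS
near 0); 0.2 is a transition (median CUS 0.34 — seeds disagree); 0.3–0.8 is a
stable three-cluster plateau (median CUS < 0.02, all ten seeds agree on three
clusters); from 0.9 the gradient is cut into seed-dependent pieces. The
flagged minima lie inside the plateau — those resolutions fit the data.
Downstream, `run_de(norm, sim$metadata, "cluster")` recovers the planted
markers and `fisher_enrich()` ranks the planted gene set first
(FDR ≈ 3e-55 in this run).

The same pipeline is available from a shell:

```sh
scstability sweep --input counts_dir --resolutions 0.1,0.5,1 --n-seeds 10 --out out/
scstability cus --assignments out/assignments.tsv --out out/
scstability minima --assignments out/assignments.tsv --statistic median --out out/
```

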