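Package: scstability
Title: Clustering Stability Diagnostics for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative selection of graph-clustering parameters for
    single-cell RNA-seq. Implements per-cell co-clustering conservation
    between adjacent parameter values, a per-cell Clustering Uncertainty
    Score (CUS) over ensembles of seeded runs, cluster-flow (Sankey) edge
    tables, Wilcoxon rank-sum differential expression in one-vs-rest,
    one-vs-one and conditional modes, and Fisher's exact test gene-set
    over-representation with a literal odds ratio. Includes a Louvain-based
    resolution sweep over a shared-nearest-neighbor graph, readers and
    writers for 10x triplet matrices, assignment tables and GMT
    collections, quality-control filtering, and simulators for partition
    ensembles with a planted ambiguous subpopulation and for count
    matrices with planted clusters, markers and pathways.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
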