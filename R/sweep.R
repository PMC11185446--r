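#' Principal-component embedding of a normalized expression matrix
#'
#' Centers genes and projects cells onto the top principal components.
#' Component signs are canonicalized (the loading of largest magnitude is
#' made positive) so repeated invocations, and different LAPACK builds,
#' agree. The decomposition itself is deterministic; `seed` is accepted for
#' interface symmetry with the stochastic steps.
#'
#' @param normalized Numeric matrix, genes x cells (normalized expression).
#' @param n_pcs Number of principal components to keep
#'   (1 <= n_pcs <= min(cells, genes)).
#' @param seed Unused; kept so every pipeline stage takes a seed.
#' @return An object of class `reduced_matrix`: list with `cell_ids`,
#'   `coordinates` (cells x n_pcs, columns ordered by decreasing explained
#'   variance), `sdev`.
#' @export
reduce_pca <- function(normalized, n_pcs, seed = NULL) {
  normalized <- as.matrix(normalized)
  if (!all(is.finite(normalized)))
    stop("expression matrix must be finite", call. = FALSE)
  if (n_pcs < 1L || n_pcs > min(dim(normalized)))
    stop("n_pcs must be in [1, min(cells, genes)]", call. = FALSE)
  if (is.null(colnames(normalized)))
    colnames(normalized) <- paste0("cell", seq_len(ncol(normalized)))
  pc <- stats::prcomp(t(normalized), center = TRUE, scale. = FALSE,
                      rank. = n_pcs)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(k) {
    w <- rot[which.max(abs(rot[, k])), k]
    if (w < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(n_pcs), drop = FALSE], 2, flip, `*`)
  structure(list(cell_ids = colnames(normalized), coordinates = coords,
                 sdev = pc$sdev[seq_len(n_pcs)]),
            class = "reduced_matrix")
}

#' Shared-nearest-neighbor graph of an embedding
#'
#' Builds the k-nearest-neighbor graph (Euclidean distance on the embedding,
#' neighborhoods include the cell itself) and weights each candidate edge by
#' the Jaccard overlap of the two neighborhoods; edges below `prune` are
#' dropped. Defaults (k = 20, prune = 1/15) follow the common graph-clustering
#' convention for single-cell data. Neighbors are found exactly from the full
#' distance matrix, which is quadratic in cells and intended for datasets up
#' to a few tens of thousands of cells.
#'
#' @param reduced A [reduce_pca()] result, or a plain cells x d coordinate
#'   matrix with rownames as cell ids.
#' @param k Neighborhood size (including the cell itself).
#' @param prune Minimum Jaccard weight for an edge to be kept.
#' @return An `igraph` undirected weighted graph whose vertex names are cell
#'   ids, with attribute `k`.
#' @export
snn_graph <- function(reduced, k = 20, prune = 1 / 15) {
  if (inherits(reduced, "reduced_matrix")) {
    coords <- reduced$coordinates
    ids <- reduced$cell_ids
  } else {
    coords <- as.matrix(reduced)
    ids <- rownames(coords) %||% paste0("cell", seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (k < 2 || k > n) stop("k must be in [2, n_cells]", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  ## k nearest including self; ties broken by index for determinism
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                               j = as.vector(t(nn)), x = 1,
                               dims = c(n, n))
  shared <- Matrix::tcrossprod(memb)          # |N_i intersect N_j|
  jac <- methods::as(shared, "TsparseMatrix")
  keep <- jac@i < jac@j
  i <- jac@i[keep] + 1L
  j <- jac@j[keep] + 1L
  w <- jac@x[keep] / (2 * k - jac@x[keep])    # Jaccard: s / (|A|+|B|-s)
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[i[ok]], to = ids[j[ok]], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  g$k <- as.integer(k)
  g
}

## Canonical labels: consecutive integers from 0 by decreasing cluster size;
## ties broken by first appearance so output is stable across sessions.
.canonical_labels <- function(membership) {
  tab <- table(membership)
  ord <- order(-as.vector(tab), match(names(tab), as.character(membership)))
  map <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  unname(map[as.character(membership)])
}

#' Cluster a cell graph by modularity optimization
#'
#' Runs Louvain community detection with a resolution parameter on a
#' (shared-)nearest-neighbor graph. The run is deterministic given `seed`.
#' Labels are canonicalized to consecutive integers from 0, ordered by
#' decreasing cluster size.
#'
#' @param graph An `igraph` graph with vertex names (cell ids), e.g. from
#'   [snn_graph()].
#' @param resolution Non-negative resolution parameter; larger values yield
#'   more, smaller clusters. At resolution 0 the null-model penalty
#'   vanishes, so a single community attains the maximal objective; that
#'   limit is returned deterministically (optimizers may otherwise stall on
#'   objective-neutral merges in disconnected graphs).
#' @param seed Integer seed for the stochastic optimizer.
#' @param param_name Recorded on the returned partition (default
#'   `"resolution"`).
#' @param param_value Recorded parameter value; defaults to `resolution`.
#' @return A [cell_partition()].
#' @export
cluster_graph <- function(graph, resolution, seed,
                          param_name = "resolution",
                          param_value = resolution) {
  stopifnot(igraph::is_igraph(graph))
  if (resolution < 0) stop("resolution must be >= 0", call. = FALSE)
  if (resolution == 0)
    return(cell_partition(igraph::V(graph)$name,
                          rep(0L, igraph::vcount(graph)),
                          param_name = param_name, param_value = param_value,
                          seed = as.integer(seed)))
  w <- igraph::E(graph)$weight
  memb <- withr::with_seed(as.integer(seed), {
    cl <- igraph::cluster_louvain(graph, weights = w,
                                  resolution = resolution)
    igraph::membership(cl)
  })
  cell_partition(igraph::V(graph)$name, .canonical_labels(memb),
                 param_name = param_name, param_value = param_value,
                 seed = as.integer(seed))
}

#' Sweep clustering over a resolution grid and seed ensemble
#'
#' Clusters the graph once per (resolution, seed) pair. The grid is sorted
#' ascending; the first seed's partitions form the [partition_sweep()] used
#' for conservation and flow, and all seeds at each value form a
#' [partition_ensemble()] for CUS.
#'
#' @param graph An `igraph` cell graph, e.g. from [snn_graph()].
#' @param resolutions Numeric vector of distinct resolution values.
#' @param seeds Integer vector of seeds (the first is the representative run).
#' @return List with `sweep` (a `partition_sweep`) and `ensembles` (list of
#'   `partition_ensemble`, one per resolution; `NULL`s when
#'   `length(seeds) < 2`).
#' @export
sweep_clustering <- function(graph, resolutions, seeds) {
  if (length(resolutions) == 0L) stop("empty resolution grid", call. = FALSE)
  if (length(seeds) == 0L) stop("at least one seed is required", call. = FALSE)
  if (anyDuplicated(resolutions)) stop("resolutions must be distinct", call. = FALSE)
  resolutions <- sort(resolutions)
  runs <- lapply(resolutions, function(r)
    lapply(seeds, function(s) cluster_graph(graph, r, s)))
  sweep <- partition_sweep(lapply(runs, `[[`, 1L))
  ensembles <- if (length(seeds) >= 2L) lapply(runs, partition_ensemble)
               else NULL
  list(sweep = sweep, ensembles = ensembles)
}

#' Sweep the number of principal components at fixed resolution
#'
#' Convenience wrapper re-embedding and re-building the graph for each value
#' of `n_pcs`; one sweep may vary only one parameter, so the resolution is
#' held fixed here.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param n_pcs_grid Integer vector of embedding dimensions.
#' @param seeds Integer vector of seeds.
#' @param resolution Fixed clustering resolution.
#' @param k Neighborhood size for [snn_graph()].
#' @return Same shape as [sweep_clustering()].
#' @export
sweep_npcs <- function(normalized, n_pcs_grid, seeds, resolution = 0.8,
                       k = 20) {
  if (length(n_pcs_grid) == 0L) stop("empty n_pcs grid", call. = FALSE)
  if (anyDuplicated(n_pcs_grid)) stop("n_pcs values must be distinct", call. = FALSE)
  n_pcs_grid <- sort(n_pcs_grid)
  runs <- lapply(n_pcs_grid, function(d) {
    g <- snn_graph(reduce_pca(normalized, d), k = k)
    lapply(seeds, function(s)
      cluster_graph(g, resolution, s, param_name = "n_pcs", param_value = d))
  })
  sweep <- partition_sweep(lapply(runs, `[[`, 1L))
  ensembles <- if (length(seeds) >= 2L) lapply(runs, partition_ensemble)
               else NULL
  list(sweep = sweep, ensembles = ensembles)
}
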