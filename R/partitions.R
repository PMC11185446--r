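#' Create a cell partition
#'
#' A `cell_partition` is one cluster-label vector over all cells produced by a
#' single clustering run at one parameter value (and, for stochastic
#' algorithms, one seed). Cluster ids are arbitrary: every operation in this
#' package is invariant to relabeling them.
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param labels Atomic vector of cluster labels, one per cell, aligned with
#'   `cell_ids`. Any atomic type is accepted; labels are compared by equality
#'   only.
#' @param param_name Name of the swept parameter, e.g. `"resolution"` or
#'   `"n_pcs"`.
#' @param param_value Numeric value of the swept parameter for this run.
#' @param seed Integer seed of the run, or `NULL` when not applicable.
#'
#' @return An object of class `cell_partition`: a list with fields
#'   `cell_ids`, `labels`, `param_name`, `param_value`, `seed`.
#' @examples
#' p <- cell_partition(c("c1", "c2", "c3"), c(1, 1, 2),
#'                     param_name = "resolution", param_value = 0.4)
#' cluster_sizes(p)
#' @export
cell_partition <- function(cell_ids, labels, param_name = "resolution",
                           param_value = NA_real_, seed = NULL) {
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) == 0L)
    stop("a cell partition must contain at least one cell", call. = FALSE)
  if (length(labels) != length(cell_ids))
    stop("`labels` and `cell_ids` must have equal length", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("`cell_ids` must be unique", call. = FALSE)
  if (anyNA(labels))
    stop("`labels` must not contain missing values", call. = FALSE)
  structure(
    list(cell_ids = cell_ids, labels = labels,
         param_name = as.character(param_name),
         param_value = as.numeric(param_value),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("cell_partition: %d cells, %d clusters (%s = %s%s)\n",
              length(x$cell_ids), length(unique(x$labels)),
              x$param_name, format(x$param_value),
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Cluster sizes of a partition
#'
#' @param partition A [cell_partition()].
#' @return Named integer vector of cluster sizes, sorted by decreasing size.
#' @export
cluster_sizes <- function(partition) {
  stopifnot(inherits(partition, "cell_partition"))
  sort(table(partition$labels), decreasing = TRUE)
}

.check_same_cells <- function(a, b) {
  if (!identical(a$cell_ids, b$cell_ids))
    stop("partitions must share identical cell_ids in identical order",
         call. = FALSE)
}

#' Create a partition sweep
#'
#' An ordered series of partitions of the same cells along one strictly
#' increasing parameter axis (e.g. clustering resolution). "Adjacent" always
#' means consecutive in this order; only one parameter may vary per sweep —
#' sweeping both resolution and the number of principal components requires
#' two separate sweeps.
#'
#' @param partitions List of [cell_partition()] objects sharing identical
#'   `cell_ids` and `param_name`, in any order of `param_value`.
#' @return An object of class `partition_sweep` (list of partitions sorted by
#'   ascending `param_value`).
#' @export
partition_sweep <- function(partitions) {
  if (length(partitions) == 0L)
    stop("a sweep needs at least one partition", call. = FALSE)
  lapply(partitions, function(p) stopifnot(inherits(p, "cell_partition")))
  for (p in partitions[-1]) .check_same_cells(partitions[[1]], p)
  pn <- unique(vapply(partitions, `[[`, character(1), "param_name"))
  if (length(pn) != 1L)
    stop("all partitions in a sweep must share one param_name; got: ",
         paste(pn, collapse = ", "), call. = FALSE)
  pv <- vapply(partitions, `[[`, numeric(1), "param_value")
  if (anyNA(pv)) stop("sweep partitions need numeric param_value", call. = FALSE)
  partitions <- partitions[order(pv)]
  pv <- sort(pv)
  if (any(diff(pv) <= 0))
    stop("param_value must be strictly increasing across a sweep",
         call. = FALSE)
  structure(partitions, class = "partition_sweep")
}

#' @export
print.partition_sweep <- function(x, ...) {
  pv <- vapply(x, `[[`, numeric(1), "param_value")
  cat(sprintf("partition_sweep: %d steps of %s in [%s, %s], %d cells\n",
              length(x), x[[1]]$param_name, format(min(pv)), format(max(pv)),
              length(x[[1]]$cell_ids)))
  invisible(x)
}

#' Co-clustering matrix of one partition
#'
#' The co-clustering matrix CCM is the boolean cell-by-cell indicator of
#' shared cluster membership in a single run: `CCM[i, j] = 1` iff cells i and
#' j carry the same cluster label (so the diagonal is 1). It is returned as a
#' sparse symmetric pattern matrix; downstream statistics (conservation, CUS)
#' exclude the diagonal and are computed directly from label vectors, so the
#' dense quadratic object is never required.
#'
#' @param partition A [cell_partition()].
#' @return A sparse logical symmetric matrix (cells x cells) with cell ids as
#'   dimnames.
#' @examples
#' p <- cell_partition(c("a", "b", "c"), c("A", "A", "B"))
#' build_coclustering(p)
#' @export
build_coclustering <- function(partition) {
  stopifnot(inherits(partition, "cell_partition"))
  f <- factor(partition$labels)
  z <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                            dims = c(length(f), nlevels(f)))
  ccm <- Matrix::tcrossprod(z) > 0
  dimnames(ccm) <- list(partition$cell_ids, partition$cell_ids)
  ccm
}

## Joint contingency of two aligned label vectors: for each cell, the size of
## its cluster in `prev` and the number of cells sharing BOTH its prev and
## curr labels. All CC/flow math reduces to these counts.
.pair_counts <- function(prev_labels, curr_labels) {
  fp <- factor(prev_labels)
  fc <- factor(curr_labels)
  joint <- table(fp, fc)
  prev_sizes <- table(fp)
  ip <- as.integer(fp)
  ic <- as.integer(fc)
  list(prev_size = as.vector(prev_sizes)[ip],
       joint_size = joint[cbind(ip, ic)])
}

#' Per-cell co-clustering conservation between two adjacent runs
#'
#' For each cell, the fraction of its cluster mates at the previous parameter
#' value that are still its cluster mates at the current one:
#' `CC_i = |mates kept| / |mates at prev|`, mates excluding the cell itself.
#' A cell that was a singleton in `prev` has no mates (denominator 0) and
#' gets `NA`; such cells are excluded from the summary quantiles rather than
#' imputed, since any imputed value would bias the conservation distribution.
#'
#' @param prev,curr [cell_partition()] objects over identical cells, `prev`
#'   at the lower parameter value.
#' @return Named numeric vector of CC values in `[0, 1]` (names = cell ids),
#'   `NA` for cells that were singletons in `prev`.
#' @examples
#' prev <- cell_partition(as.character(1:6), c(1, 1, 1, 1, 2, 2))
#' curr <- cell_partition(as.character(1:6), c(1, 1, 1, 3, 2, 2))
#' coclustering_conservation(prev, curr)  # 2/3 2/3 2/3 0 1 1
#' @export
coclustering_conservation <- function(prev, curr) {
  stopifnot(inherits(prev, "cell_partition"), inherits(curr, "cell_partition"))
  .check_same_cells(prev, curr)
  ct <- .pair_counts(prev$labels, curr$labels)
  denom <- ct$prev_size - 1L
  cc <- ifelse(denom > 0L, (ct$joint_size - 1L) / denom, NA_real_)
  names(cc) <- prev$cell_ids
  cc
}

#' Conservation profile across a sweep
#'
#' Applies [coclustering_conservation()] to every consecutive pair of a sweep
#' and summarizes each pair's CC distribution with boxplot quantiles
#' (singleton `NA`s excluded).
#'
#' @param sweep A [partition_sweep()] with at least two partitions.
#' @return An object of class `conservation_profile`: list with
#'   `per_cell` (list of named CC vectors, one per adjacent pair),
#'   `pairs` (data.frame `from`, `to` of param values) and
#'   `summary` (data.frame with `from`, `to`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`, `n_missing`).
#' @export
conservation_profile <- function(sweep) {
  stopifnot(inherits(sweep, "partition_sweep"))
  if (length(sweep) < 2L)
    stop("a conservation profile needs a sweep of at least two partitions",
         call. = FALSE)
  pv <- vapply(sweep, `[[`, numeric(1), "param_value")
  n_pairs <- length(sweep) - 1L
  per_cell <- vector("list", n_pairs)
  summ <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    cc <- coclustering_conservation(sweep[[k]], sweep[[k + 1L]])
    per_cell[[k]] <- cc
    ok <- cc[!is.na(cc)]
    q <- if (length(ok)) stats::quantile(ok, c(0, .25, .5, .75, 1), names = FALSE)
         else rep(NA_real_, 5)
    summ[[k]] <- data.frame(from = pv[k], to = pv[k + 1L],
                            min = q[1], q1 = q[2], median = q[3],
                            q3 = q[4], max = q[5],
                            n = length(ok), n_missing = sum(is.na(cc)))
  }
  names(per_cell) <- sprintf("%s->%s", format(pv[-length(pv)]), format(pv[-1]))
  structure(list(per_cell = per_cell,
                 pairs = data.frame(from = pv[-length(pv)], to = pv[-1]),
                 param_name = sweep[[1]]$param_name,
                 summary = do.call(rbind, summ)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("conservation_profile over %d adjacent pairs of %s\n",
              nrow(x$pairs), x$param_name))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Cluster-flow (Sankey) edge table between two adjacent runs
#'
#' Counts cells moving between clusters of two partitions of the same cells:
#' one edge `(from, to, n_cells)` per observed label pair. Out-going edge
#' weights of each source cluster sum to its size in `prev`; incoming weights
#' of each target cluster sum to its size in `curr`. Node ids are prefixed
#' with the parameter value (`"0.4:3"`) so steps stay distinct in exports.
#'
#' @inheritParams coclustering_conservation
#' @return An object of class `flow_table`: data.frame with columns `from`,
#'   `to` (cluster labels), `from_id`, `to_id` (param-value-prefixed node
#'   ids) and `n_cells` (>= 1).
#' @export
flow_table <- function(prev, curr) {
  stopifnot(inherits(prev, "cell_partition"), inherits(curr, "cell_partition"))
  .check_same_cells(prev, curr)
  tab <- as.data.frame(table(from = as.character(prev$labels),
                             to = as.character(curr$labels)),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  tab <- tab[order(tab$from, tab$to), , drop = FALSE]
  out <- data.frame(from = tab$from, to = tab$to,
                    from_id = sprintf("%s:%s", format(prev$param_value), tab$from),
                    to_id = sprintf("%s:%s", format(curr$param_value), tab$to),
                    n_cells = as.integer(tab$Freq))
  rownames(out) <- NULL
  structure(out, class = c("flow_table", "data.frame"),
            param_values = c(prev$param_value, curr$param_value))
}

#' Flow tables for every adjacent pair of a sweep
#'
#' @param sweep A [partition_sweep()] with at least two partitions.
#' @return List of [flow_table()] objects, one per adjacent pair.
#' @export
sweep_flow <- function(sweep) {
  stopifnot(inherits(sweep, "partition_sweep"))
  if (length(sweep) < 2L)
    stop("flow needs a sweep of at least two partitions", call. = FALSE)
  lapply(seq_len(length(sweep) - 1L),
         function(k) flow_table(sweep[[k]], sweep[[k + 1L]]))
}
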