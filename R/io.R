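#' Read a 10x-style triplet count matrix
#'
#' Reads `matrix.mtx` (genes x cells, MatrixMarket), `barcodes.tsv` (one
#' cell barcode per line) and `features.tsv` (gene id, and optionally symbol
#' and type columns) from a directory. Uncompressed files are expected.
#'
#' @param dir Directory holding the three files.
#' @return Sparse integer matrix (dgCMatrix), genes x cells, with feature
#'   ids as rownames and barcodes as colnames.
#' @export
read_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bc <- file.path(dir, "barcodes.tsv")
  ft <- file.path(dir, "features.tsv")
  if (!file.exists(ft)) ft <- file.path(dir, "genes.tsv")
  for (f in c(mtx, bc, ft))
    if (!file.exists(f)) stop("missing file: ", f, call. = FALSE)
  m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- readLines(bc)
  features <- utils::read.delim(ft, header = FALSE,
                                stringsAsFactors = FALSE)
  if (nrow(features) != nrow(m) || length(barcodes) != ncol(m))
    stop("matrix dimensions do not match barcodes/features", call. = FALSE)
  dimnames(m) <- list(features[[1]], barcodes)
  m
}

#' Write a 10x-style triplet count matrix
#'
#' @param counts Matrix (dense or sparse), genes x cells, with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_10x <- function(counts, dir) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs gene rownames and cell colnames", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(id = rownames(counts), symbol = rownames(counts),
               type = "Gene Expression"),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Read a dense expression matrix from TSV
#'
#' Tab-separated, header row of cell ids, first column gene ids.
#'
#' @param path Input path.
#' @return Numeric matrix, genes x cells.
#' @export
read_dense_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

## Column-name dialect of assignment tables: "res=0.4;seed=7" (seed part
## optional). param_name "res" is read back as "resolution" for brevity in
## files written by hand.
.parse_run_name <- function(nm) {
  parts <- strsplit(nm, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) x[2], character(1))
  pn <- keys[1]
  if (pn == "res") pn <- "resolution"
  list(param_name = pn, param_value = as.numeric(vals[1]),
       seed = if ("seed" %in% keys) as.integer(vals[keys == "seed"][1])
              else NULL)
}

#' Read a cluster-assignment table
#'
#' TSV with a header: column 1 the cell id, each further column one
#' clustering run, named `"res=<value>;seed=<seed>"` (or any
#' `<param>=<value>` first token; the seed part is optional). Any external
#' clusterer can produce this file; every stability metric in the package
#' operates on it directly.
#'
#' @param path Input path.
#' @return List of [cell_partition()] objects, one per run column.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("assignment table needs a cell column plus at least one run",
         call. = FALSE)
  cells <- as.character(df[[1]])
  lapply(names(df)[-1], function(nm) {
    meta <- .parse_run_name(nm)
    cell_partition(cells, df[[nm]], param_name = meta$param_name,
                   param_value = meta$param_value, seed = meta$seed)
  })
}

#' Write a cluster-assignment table
#'
#' @param partitions List of [cell_partition()] objects over identical
#'   cells.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(partitions, path) {
  if (inherits(partitions, "cell_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) > 0L)
  for (p in partitions[-1]) .check_same_cells(partitions[[1]], p)
  cols <- lapply(partitions, `[[`, "labels")
  names(cols) <- vapply(partitions, function(p) {
    pn <- if (p$param_name == "resolution") "res" else p$param_name
    nm <- sprintf("%s=%s", pn, format(p$param_value))
    if (!is.null(p$seed)) nm <- sprintf("%s;seed=%d", nm, p$seed)
    nm
  }, character(1))
  df <- cbind(data.frame(cell = partitions[[1]]$cell_ids), cols)
  names(df) <- c("cell", names(cols))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group run partitions into ensembles and a representative sweep
#'
#' Partitions (e.g. from [read_assignments()]) are grouped by
#' `param_value`; each group with at least two runs becomes a
#' [partition_ensemble()], and the first run of each value forms the
#' [partition_sweep()].
#'
#' @param partitions List of [cell_partition()] objects.
#' @return List with `sweep` and `ensembles` (possibly empty list).
#' @export
group_runs <- function(partitions) {
  stopifnot(length(partitions) > 0L)
  pv <- vapply(partitions, `[[`, numeric(1), "param_value")
  groups <- split(partitions, pv)
  groups <- groups[order(as.numeric(names(groups)))]
  sweep <- partition_sweep(lapply(groups, `[[`, 1L))
  ensembles <- Filter(Negate(is.null),
                      lapply(groups, function(g)
                        if (length(g) >= 2L) partition_ensemble(g) else NULL))
  list(sweep = sweep, ensembles = unname(ensembles))
}

#' Export a conservation profile to TSV
#'
#' Writes the long table (`pair`, `from`, `to`, `cell_id`, `cc`) and the
#' boxplot quantile summary.
#'
#' @param profile A [conservation_profile()].
#' @param long_path,summary_path Output paths (either may be `NULL` to
#'   skip).
#' @export
write_conservation_tsv <- function(profile, long_path = NULL,
                                   summary_path = NULL) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (!is.null(long_path)) {
    long <- do.call(rbind, lapply(seq_along(profile$per_cell), function(k) {
      cc <- profile$per_cell[[k]]
      data.frame(pair = names(profile$per_cell)[k],
                 from = profile$pairs$from[k], to = profile$pairs$to[k],
                 cell_id = names(cc), cc = unname(cc))
    }))
    utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(summary_path))
    utils::write.table(profile$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Export a flow table as Sankey-ready JSON (and optionally TSV)
#'
#' The JSON has `nodes` (`id`, `step`, `label`, `size`) and `links`
#' (`source`, `target`, `value`) and suits any Sankey renderer.
#'
#' @param flow A [flow_table()].
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @export
write_flow_json <- function(flow, json_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(flow, "flow_table"))
  pv <- attr(flow, "param_values")
  src <- stats::aggregate(n_cells ~ from_id + from, flow, sum)
  tgt <- stats::aggregate(n_cells ~ to_id + to, flow, sum)
  nodes <- rbind(
    data.frame(id = src$from_id, step = pv[1], label = src$from,
               size = src$n_cells),
    data.frame(id = tgt$to_id, step = pv[2], label = tgt$to,
               size = tgt$n_cells))
  nodes <- nodes[order(nodes$step, nodes$id), ]
  if (!is.null(json_path))
    jsonlite::write_json(
      list(nodes = nodes,
           links = data.frame(source = flow$from_id, target = flow$to_id,
                              value = flow$n_cells)),
      json_path, dataframe = "rows", auto_unbox = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(flow), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Export CUS scores and profiles to TSV
#'
#' @param x An `uncertainty_scores` or `uncertainty_profile` object.
#' @param path Output path for the per-cell table (long format for
#'   profiles).
#' @param summary_path For profiles, optional path of the violin-summary
#'   table (`param_value`, `mean`, `median`, `q1`, `q3`).
#' @export
write_cus_tsv <- function(x, path, summary_path = NULL) {
  if (inherits(x, "uncertainty_scores")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (inherits(x, "uncertainty_profile")) {
    utils::write.table(x$scores, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(summary_path))
      utils::write.table(x$summary, summary_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
  } else stop("unsupported object", call. = FALSE)
  invisible(NULL)
}
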