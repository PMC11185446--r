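#' Per-cell mitochondrial and ribosomal count fractions
#'
#' Percent of each cell's counts carried by mitochondrial and ribosomal
#' genes, matched by configurable rowname patterns. Used in QC tables and
#' available as metadata columns for differential expression.
#'
#' @param counts Matrix (dense or sparse), genes x cells, gene rownames.
#' @param mito_pattern,ribo_pattern Regular expressions on gene names
#'   (defaults match human/mouse `MT-`/`mt-` and `RPS/RPL/Rps/Rpl`
#'   prefixes).
#' @return Data.frame with columns `cell`, `pct_mito`, `pct_ribo` (each in
#'   `[0, 100]`; zeros with a warning when no gene matches a pattern).
#' @export
mito_ribo_fractions <- function(counts, mito_pattern = "^(MT-|mt-)",
                                ribo_pattern = "^(RPS|RPL|Rps|Rpl)") {
  if (is.null(rownames(counts)))
    stop("`counts` needs gene rownames", call. = FALSE)
  totals <- Matrix::colSums(counts)
  pct_of <- function(pattern, what) {
    hit <- grepl(pattern, rownames(counts))
    if (!any(hit)) {
      warning("no ", what, " gene matches '", pattern, "'; returning zeros")
      return(rep(0, ncol(counts)))
    }
    sub <- Matrix::colSums(counts[hit, , drop = FALSE])
    ifelse(totals > 0, 100 * sub / totals, 0)
  }
  data.frame(cell = colnames(counts) %||% paste0("cell", seq_len(ncol(counts))),
             pct_mito = pct_of(mito_pattern, "mitochondrial"),
             pct_ribo = pct_of(ribo_pattern, "ribosomal"))
}

#' Quality-control filtering of cells
#'
#' Removes low-quality cells failing any threshold: fewer than
#' `min_features` detected genes OR fewer than `min_counts` total counts
#' (strict "less than" on both), and optionally more than `max_pct_mito`
#' percent mitochondrial counts. The defaults (1000 features, 4000 counts)
#' are the pre-processing rule used for the PBMC demonstration data this
#' package's diagnostics were developed on.
#'
#' @param counts Raw integer count matrix, genes x cells.
#' @param min_features,min_counts Lower thresholds (cells strictly below
#'   either are removed).
#' @param max_pct_mito Optional upper threshold on mitochondrial percent.
#' @return List with `counts` (filtered matrix), `qc` (per-cell data.frame:
#'   `cell`, `n_features`, `n_counts`, `pct_mito`, `pct_ribo`, `keep`) and
#'   `removed` (named counts of cells failing each criterion). Errors if no
#'   cell survives.
#' @export
qc_filter <- function(counts, min_features = 1000, min_counts = 4000,
                      max_pct_mito = NULL) {
  if (min_features < 0 || min_counts < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  n_features <- Matrix::colSums(counts > 0)
  n_counts <- Matrix::colSums(counts)
  fr <- suppressWarnings(mito_ribo_fractions(counts))
  fail_features <- n_features < min_features
  fail_counts <- n_counts < min_counts
  fail_mito <- if (is.null(max_pct_mito)) rep(FALSE, ncol(counts))
               else fr$pct_mito > max_pct_mito
  keep <- !(fail_features | fail_counts | fail_mito)
  qc <- data.frame(cell = fr$cell, n_features = as.integer(n_features),
                   n_counts = as.numeric(n_counts),
                   pct_mito = fr$pct_mito, pct_ribo = fr$pct_ribo,
                   keep = keep)
  if (!any(keep)) {
    stop("all ", ncol(counts), " cells removed by QC (",
         sum(fail_features), " below ", min_features, " features, ",
         sum(fail_counts), " below ", min_counts, " counts)",
         call. = FALSE)
  }
  list(counts = counts[, keep, drop = FALSE], qc = qc,
       removed = c(low_features = sum(fail_features),
                   low_counts = sum(fail_counts),
                   high_mito = sum(fail_mito),
                   total = sum(!keep)))
}

#' Library-size normalization
#'
#' Scales each cell's counts to the median library size of the dataset and
#' applies `log(1 + x)`. This is deliberately simple plumbing so that the
#' stability metrics and DE have a normalized input; variance-stabilizing
#' methods can be substituted upstream by supplying an already-normalized
#' matrix.
#'
#' @param counts Count matrix (dense or sparse), genes x cells.
#' @return Dense numeric matrix of the same shape, log-normalized.
#' @export
normalize_counts <- function(counts) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop(sum(totals == 0), " cell(s) with zero total counts; ",
         "run qc_filter() first", call. = FALSE)
  target <- stats::median(totals)
  m <- as.matrix(counts)
  log1p(sweep(m, 2, target / totals, `*`))
}
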