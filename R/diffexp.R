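#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Tests each gene for a shift in normalized expression between two disjoint
#' cell groups with the two-sided Wilcoxon rank-sum test: exact enumeration
#' when both groups have at most 25 cells and the gene has no tied values,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. Genes are pre-filtered to those detected in at least
#' `min_pct` of the cells of either group and with `|log2 fold change| >=
#' min_lfc`; fold changes are computed before filtering. P-values are
#' BH-adjusted across the genes tested within this comparison.
#'
#' @param normalized Numeric matrix, genes x cells, normalized expression
#'   (zeros mean "not detected").
#' @param cells1,cells2 Disjoint, non-empty character vectors of cell ids
#'   (columns of `normalized`).
#' @param min_pct Minimum detection fraction in at least one group
#'   (default 0.1).
#' @param min_lfc Minimum absolute log2 fold change (default 0.25). The fold
#'   change is `log2((mean1 + 1) / (mean2 + 1))` on the normalized scale.
#' @param comparison Label stored in the `comparison` column.
#' @param method `"auto"` (default, exact when both groups <= 25 cells and
#'   no ties), `"exact"` or `"approx"` to force one path.
#' @return A `de_result` data.frame with columns `comparison`, `gene`,
#'   `n_cells_group1`, `n_cells_group2`, `pct_expressing_1`,
#'   `pct_expressing_2` (percent, 0-100), `log2_fold_change`, `statistic`
#'   (rank-sum W), `p_value`, `fdr`, ordered by increasing p.
#' @export
de_test <- function(normalized, cells1, cells2, min_pct = 0.1,
                    min_lfc = 0.25, comparison = "group1_vs_group2",
                    method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  normalized <- as.matrix(normalized)
  if (is.null(rownames(normalized)))
    rownames(normalized) <- paste0("gene", seq_len(nrow(normalized)))
  cells1 <- as.character(cells1); cells2 <- as.character(cells2)
  if (length(cells1) == 0L || length(cells2) == 0L)
    stop("both cell groups must be non-empty", call. = FALSE)
  if (length(intersect(cells1, cells2)) > 0L)
    stop("cell groups must be disjoint", call. = FALSE)
  missing <- setdiff(c(cells1, cells2), colnames(normalized))
  if (length(missing) > 0L)
    stop("cells absent from the matrix: ", paste(utils::head(missing, 5),
         collapse = ", "), call. = FALSE)
  x1 <- normalized[, cells1, drop = FALSE]
  x2 <- normalized[, cells2, drop = FALSE]
  n1 <- length(cells1); n2 <- length(cells2)

  pct1 <- rowMeans(x1 > 0)
  pct2 <- rowMeans(x2 > 0)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  lfc <- log2((m1 + 1) / (m2 + 1))
  keep <- (pct1 >= min_pct | pct2 >= min_pct) & abs(lfc) >= min_lfc
  genes <- rownames(normalized)[keep]

  stat <- p <- numeric(length(genes))
  for (g in seq_along(genes)) {
    a <- x1[genes[g], ]; b <- x2[genes[g], ]
    if (min(a, b) == max(a, b)) {
      # constant gene: every rank split is tied, no evidence either way
      # (the tie-corrected variance is 0/0 there)
      stat[g] <- n1 * n2 / 2
      p[g] <- 1
      next
    }
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- switch(method,
                    auto = n1 <= 25 && n2 <= 25 && !ties,
                    exact = TRUE,
                    approx = FALSE)
    if (exact && ties)
      stop("exact Wilcoxon enumeration is unavailable with tied values",
           call. = FALSE)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    stat[g] <- unname(wt$statistic)
    p[g] <- wt$p.value
  }
  out <- data.frame(comparison = comparison, gene = genes,
                    n_cells_group1 = n1, n_cells_group2 = n2,
                    pct_expressing_1 = 100 * pct1[keep],
                    pct_expressing_2 = 100 * pct2[keep],
                    log2_fold_change = lfc[keep],
                    statistic = stat, p_value = p,
                    fdr = stats::p.adjust(p, method = "BH"))
  out <- out[order(out$p_value, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"))
}

## Enumerate the comparisons of one grouping mode. Each element: list(id,
## cells1, cells2).
.de_comparisons <- function(metadata, primary_var, secondary_var, mode) {
  cells <- rownames(metadata)
  prim <- as.character(metadata[[primary_var]])
  levels1 <- sort(unique(prim))
  cmp <- list()
  if (mode == "one_vs_rest") {
    for (lv in levels1)
      cmp[[length(cmp) + 1L]] <- list(
        id = sprintf("%s=%s_vs_rest", primary_var, lv),
        cells1 = cells[prim == lv], cells2 = cells[prim != lv])
  } else if (mode == "one_vs_one") {
    for (a in seq_along(levels1)) for (b in seq_along(levels1))
      if (a < b)
        cmp[[length(cmp) + 1L]] <- list(
          id = sprintf("%s=%s_vs_%s", primary_var, levels1[a], levels1[b]),
          cells1 = cells[prim == levels1[a]],
          cells2 = cells[prim == levels1[b]])
  } else {                                   # conditional
    sec <- as.character(metadata[[secondary_var]])
    for (sv in sort(unique(sec)))
      for (a in seq_along(levels1)) for (b in seq_along(levels1))
        if (a < b) {
          in_sec <- sec == sv
          cmp[[length(cmp) + 1L]] <- list(
            id = sprintf("%s=%s_vs_%s|%s=%s", primary_var, levels1[a],
                         levels1[b], secondary_var, sv),
            cells1 = cells[in_sec & prim == levels1[a]],
            cells2 = cells[in_sec & prim == levels1[b]])
        }
  }
  cmp
}

#' Differential expression over metadata groupings
#'
#' Runs [de_test()] for every comparison implied by a grouping mode:
#' * `one_vs_rest` — each level of `primary_var` against all other cells
#'   (the conventional cluster-marker contrast);
#' * `one_vs_one` — every unordered pair of levels of `primary_var`;
#' * `conditional` — every unordered pair of `primary_var` levels within
#'   each level of `secondary_var` (e.g. treatment pairs within each
#'   cluster).
#'
#' Comparisons in which either group has fewer than 3 cells are skipped with
#' a warning.
#'
#' @inheritParams de_test
#' @param metadata Data.frame of cell annotations; rownames are cell ids
#'   covering every column of `normalized`.
#' @param primary_var Metadata column defining the groups.
#' @param secondary_var Second column, required for `mode = "conditional"`.
#' @param mode Comparison mode, see above.
#' @return A `de_result` data.frame combining all comparisons (one BH
#'   adjustment per comparison).
#' @export
run_de <- function(normalized, metadata, primary_var, secondary_var = NULL,
                   mode = c("one_vs_rest", "one_vs_one", "conditional"),
                   min_pct = 0.1, min_lfc = 0.25,
                   method = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (mode == "conditional" && is.null(secondary_var))
    stop("conditional mode requires `secondary_var`", call. = FALSE)
  if (!primary_var %in% names(metadata))
    stop("metadata has no column '", primary_var, "'", call. = FALSE)
  if (!is.null(secondary_var) && !secondary_var %in% names(metadata))
    stop("metadata has no column '", secondary_var, "'", call. = FALSE)
  if (is.null(rownames(metadata)) ||
      !all(colnames(normalized) %in% rownames(metadata)))
    stop("metadata rownames must cover all cells of the matrix",
         call. = FALSE)
  metadata <- metadata[colnames(normalized), , drop = FALSE]
  cmp <- .de_comparisons(metadata, primary_var, secondary_var, mode)
  res <- list()
  for (cm in cmp) {
    if (length(cm$cells1) < 3L || length(cm$cells2) < 3L) {
      warning("skipping comparison '", cm$id, "': a group has < 3 cells",
              call. = FALSE)
      next
    }
    res[[length(res) + 1L]] <-
      de_test(normalized, cm$cells1, cm$cells2, min_pct = min_pct,
              min_lfc = min_lfc, comparison = cm$id, method = method)
  }
  if (length(res) == 0L)
    return(structure(
      data.frame(comparison = character(), gene = character(),
                 n_cells_group1 = integer(), n_cells_group2 = integer(),
                 pct_expressing_1 = numeric(), pct_expressing_2 = numeric(),
                 log2_fold_change = numeric(), statistic = numeric(),
                 p_value = numeric(), fdr = numeric()),
      class = c("de_result", "data.frame")))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("de_result", "data.frame"))
}
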