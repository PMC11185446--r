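#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: one set per line — name, description, then
#' member genes. Set names must be unique and sets non-empty.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene symbols, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad))
    stop("GMT lines without genes (need name, description, >=1 gene): line ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicated gene-set names in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <-
    stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of per-set
#'   descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), length(sets) > 0L, !is.null(names(sets)))
  desc <- rep("na", length(sets))
  names(desc) <- names(sets)
  if (!is.null(descriptions)) desc[names(descriptions)] <- descriptions
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Background universe of consistently expressed genes
#'
#' The enrichment contingency table is built over genes "consistently
#' expressed" in the dataset, defined here as detected (count > 0) in at
#' least `min_frac` of cells. The 10% default is a convention of this
#' package; the threshold is fully configurable.
#'
#' @param counts Matrix (dense or sparse), genes x cells; any scale where 0
#'   means "not detected".
#' @param min_frac Minimum detection fraction (default 0.10).
#' @return Character vector of gene names.
#' @export
make_universe <- function(counts, min_frac = 0.10) {
  if (is.null(rownames(counts)))
    stop("`counts` needs gene rownames", call. = FALSE)
  if (ncol(counts) == 0L) stop("`counts` has no cells", call. = FALSE)
  frac <- Matrix::rowSums(counts > 0) / ncol(counts)
  universe <- rownames(counts)[frac >= min_frac & frac > 0]
  if (length(universe) == 0L)
    warning("no gene passes the detection threshold; empty universe")
  universe
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each gene set, genes of the universe are cross-classified by
#' differential-expression status and set membership, giving counts
#' `de_path`, `de_nonpath`, `nonde_path`, `nonde_nonpath`. The enrichment
#' magnitude is the literal odds ratio
#' `(de_path / nonde_path) / (de_nonpath / nonde_nonpath)` — 0 or `Inf` at
#' boundary tables, with no continuity correction — and significance is the
#' two-sided Fisher exact p-value, BH-adjusted across all sets of the
#' collection.
#'
#' @param de_genes Character vector of differentially expressed genes. Genes
#'   outside `universe` are dropped with a warning.
#' @param universe Character vector, the background gene universe (e.g. from
#'   [make_universe()]); set members outside it are ignored.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @return An `enrichment_result` data.frame with columns `set`, `de_path`,
#'   `de_nonpath`, `nonde_path`, `nonde_nonpath`, `odds_ratio`, `p_value`,
#'   `fdr`, sorted by `fdr` then `p_value`.
#' @examples
#' uni <- paste0("g", 1:100)
#' sets <- list(S1 = paste0("g", 1:10), S2 = paste0("g", 51:70))
#' fisher_enrich(paste0("g", 1:8), uni, sets)
#' @export
fisher_enrich <- function(de_genes, universe, sets) {
  universe <- unique(as.character(universe))
  de_genes <- unique(as.character(de_genes))
  if (length(de_genes) == 0L) stop("empty DE gene list", call. = FALSE)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (length(sets) == 0L || is.null(names(sets)))
    stop("`sets` must be a non-empty named list", call. = FALSE)
  outside <- setdiff(de_genes, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " DE gene(s) outside the universe dropped")
    de_genes <- intersect(de_genes, universe)
    if (length(de_genes) == 0L)
      stop("no DE gene remains inside the universe", call. = FALSE)
  }
  n_uni <- length(universe)
  n_de <- length(de_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    de_path <- length(intersect(de_genes, members))
    nonde_path <- length(members) - de_path
    de_nonpath <- n_de - de_path
    nonde_nonpath <- n_uni - n_de - nonde_path
    or <- (de_path / nonde_path) / (de_nonpath / nonde_nonpath)
    p <- stats::fisher.test(matrix(c(de_path, nonde_path, de_nonpath,
                                     nonde_nonpath), nrow = 2),
                            alternative = "two.sided")$p.value
    data.frame(set = nm, de_path = de_path, de_nonpath = de_nonpath,
               nonde_path = nonde_path, nonde_nonpath = nonde_nonpath,
               odds_ratio = or, p_value = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
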