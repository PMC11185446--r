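#' Create a partition ensemble
#'
#' N repeated clustering runs of the same cells at identical parameter values
#' but different random seeds, the input of the Clustering Uncertainty Score.
#'
#' @param partitions List of at least two [cell_partition()] objects with
#'   identical `cell_ids` (same order) and identical `param_name` and
#'   `param_value`.
#' @return An object of class `partition_ensemble`.
#' @export
partition_ensemble <- function(partitions) {
  if (length(partitions) < 2L)
    stop("an ensemble needs at least two runs (N >= 2)", call. = FALSE)
  lapply(partitions, function(p) stopifnot(inherits(p, "cell_partition")))
  for (p in partitions[-1]) .check_same_cells(partitions[[1]], p)
  pv <- vapply(partitions, `[[`, numeric(1), "param_value")
  pn <- vapply(partitions, `[[`, character(1), "param_name")
  if (length(unique(pn)) != 1L || length(unique(pv)) != 1L)
    stop("all runs of an ensemble must share one (param_name, param_value)",
         call. = FALSE)
  seeds <- unlist(lapply(partitions, function(p) p$seed %||% NA_integer_))
  if (!anyNA(seeds) && anyDuplicated(seeds))
    warning("duplicated seeds in ensemble; runs may not be independent")
  structure(partitions, class = "partition_ensemble")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("partition_ensemble: N = %d runs at %s = %s, %d cells\n",
              length(x), x[[1]]$param_name, format(x[[1]]$param_value),
              length(x[[1]]$cell_ids)))
  invisible(x)
}

## Cell-by-cell co-occurrence counts across runs: M[i, j] = number of runs in
## which i and j share a cluster. Accumulated as sparse Z Z^T per run so the
## dense I x I matrix is never built when co-membership is sparse.
.cooccurrence_counts <- function(partitions) {
  m <- NULL
  for (p in partitions) {
    f <- factor(p$labels)
    z <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
    zz <- Matrix::tcrossprod(z)
    m <- if (is.null(m)) zz else m + zz
  }
  m
}

#' Clustering Uncertainty Score
#'
#' For each cell i, consider the union mate set `J_i` of cells that were
#' co-clustered with i in at least one of the N runs. The agreement of i is
#' the average, over all pairs (j in `J_i`, run n), of the indicator that i
#' and j share a cluster in run n; `CUS_i = 1 - agreement_i`. CUS is 0 for a
#' perfectly stable cell (identical mate set in all runs) and grows towards 1
#' as co-membership becomes inconsistent. A cell that is a singleton in every
#' run has an empty `J_i` and is scored 0: consistently isolated is
#' consistently clustered.
#'
#' @param ensemble A [partition_ensemble()] of N >= 2 runs.
#' @return An object of class `uncertainty_scores`: data.frame with columns
#'   `cell_id` and `cus`, with attributes `param_name`, `param_value`,
#'   `n_runs`.
#' @examples
#' runs <- list(cell_partition(as.character(1:4), c(1, 1, 2, 2), seed = 1),
#'              cell_partition(as.character(1:4), c(1, 2, 1, 2), seed = 2))
#' cus(partition_ensemble(runs))  # 0.5 for every cell
#' @export
cus <- function(ensemble) {
  stopifnot(inherits(ensemble, "partition_ensemble"))
  n_runs <- length(ensemble)
  m <- .cooccurrence_counts(ensemble)
  Matrix::diag(m) <- 0           # j != i throughout
  j_size <- Matrix::rowSums(m > 0)
  agree_sum <- Matrix::rowSums(m)
  agreement <- ifelse(j_size > 0, agree_sum / (j_size * n_runs), 1)
  out <- data.frame(cell_id = ensemble[[1]]$cell_ids,
                    cus = as.numeric(1 - agreement))
  structure(out, class = c("uncertainty_scores", "data.frame"),
            param_name = ensemble[[1]]$param_name,
            param_value = ensemble[[1]]$param_value,
            n_runs = n_runs)
}

#' CUS profile across parameter values
#'
#' Computes [cus()] for each ensemble and stacks per-parameter distributions
#' and summaries, sorted by ascending parameter value, ready for
#' violin-plot export and minima detection.
#'
#' @param ensembles List of [partition_ensemble()] objects over the same
#'   cells at distinct parameter values (any input order).
#' @return An object of class `uncertainty_profile`: list with `scores`
#'   (long data.frame `param_value`, `cell_id`, `cus`) and `summary`
#'   (data.frame `param_value`, `n_runs`, `mean`, `median`, `q1`, `q3`,
#'   `min`, `max`).
#' @export
cus_profile <- function(ensembles) {
  if (length(ensembles) == 0L)
    stop("at least one ensemble is required", call. = FALSE)
  lapply(ensembles, function(e) stopifnot(inherits(e, "partition_ensemble")))
  for (e in ensembles[-1]) .check_same_cells(ensembles[[1]][[1]], e[[1]])
  pv <- vapply(ensembles, function(e) e[[1]]$param_value, numeric(1))
  if (anyDuplicated(pv))
    stop("ensembles must have distinct param_value", call. = FALSE)
  ensembles <- ensembles[order(pv)]
  pv <- sort(pv)
  scores <- vector("list", length(ensembles))
  summ <- vector("list", length(ensembles))
  for (k in seq_along(ensembles)) {
    s <- cus(ensembles[[k]])
    scores[[k]] <- data.frame(param_value = pv[k], cell_id = s$cell_id,
                              cus = s$cus)
    q <- stats::quantile(s$cus, c(0, .25, .5, .75, 1), names = FALSE)
    summ[[k]] <- data.frame(param_value = pv[k],
                            n_runs = attr(s, "n_runs"),
                            mean = mean(s$cus), median = q[3],
                            q1 = q[2], q3 = q[4], min = q[1], max = q[5])
  }
  structure(list(scores = do.call(rbind, scores),
                 summary = do.call(rbind, summ),
                 param_name = ensembles[[1]][[1]]$param_name),
            class = "uncertainty_profile")
}

#' @export
print.uncertainty_profile <- function(x, ...) {
  cat(sprintf("uncertainty_profile over %d values of %s\n",
              nrow(x$summary), x$param_name))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Local minima of a CUS profile
#'
#' Flags parameter values whose summary statistic is strictly smaller than
#' both neighbors — candidate values at which the clustering best matches the
#' structure of the data. Endpoints are never minima. A flat valley (a run of
#' tied values strictly below both flanking values) is reported once, at its
#' left-most parameter value.
#'
#' @param profile An [cus_profile()] result with at least three entries.
#' @param statistic Which per-parameter summary to scan: `"mean"` or
#'   `"median"`.
#' @return Numeric vector of parameter values at local minima (possibly
#'   empty).
#' @export
find_local_minima <- function(profile, statistic = c("mean", "median")) {
  stopifnot(inherits(profile, "uncertainty_profile"))
  statistic <- match.arg(statistic)
  v <- profile$summary[[statistic]]
  pv <- profile$summary$param_value
  if (length(v) < 3L)
    stop("minima detection needs a profile with at least three entries",
         call. = FALSE)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_min <- vapply(seq_along(r$values), function(k) {
    if (k == 1L || k == length(r$values)) return(FALSE)
    r$values[k] < r$values[k - 1L] && r$values[k] < r$values[k + 1L]
  }, logical(1))
  pv[starts[is_min]]
}
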