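#' Define an ambiguous-subpopulation scenario
#'
#' The benchmark scenario for CUS behavior: two stable clusters whose members
#' never change label, plus a set of ambiguous cells that independently join
#' cluster 1 with probability `p_assign` in each run (and cluster 2
#' otherwise). The default population is 220 consistently clustered cells
#' (split 200/20) plus 30 ambiguous cells.
#'
#' @param n_cluster1,n_cluster2 Stable cell counts of the two clusters.
#' @param n_ambiguous Number of ambiguous cells.
#' @param p_assign Probability that an ambiguous cell joins cluster 1 in any
#'   given run.
#' @param n_runs Number of runs N (>= 2).
#' @param master_seed Integer seed; all randomness derives from it.
#' @return An object of class `ambiguity_scenario`.
#' @export
ambiguity_scenario <- function(n_cluster1 = 200, n_cluster2 = 20,
                               n_ambiguous = 30, p_assign = 0.5,
                               n_runs = 20, master_seed = 1) {
  if (n_cluster1 < 0 || n_cluster2 < 0 || n_ambiguous < 0)
    stop("cell counts must be >= 0", call. = FALSE)
  if (p_assign < 0 || p_assign > 1)
    stop("p_assign must be in [0, 1]", call. = FALSE)
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  structure(list(n_cluster1 = as.integer(n_cluster1),
                 n_cluster2 = as.integer(n_cluster2),
                 n_ambiguous = as.integer(n_ambiguous),
                 p_assign = as.numeric(p_assign),
                 n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed)),
            class = "ambiguity_scenario")
}

.scenario_classes <- function(sc) {
  rep(c("stable1", "stable2", "ambiguous"),
      c(sc$n_cluster1, sc$n_cluster2, sc$n_ambiguous))
}

#' Simulate a partition ensemble with an ambiguous subpopulation
#'
#' Stable cells keep fixed labels across all runs; each ambiguous cell joins
#' cluster 1 with probability `p_assign`, independently per cell and per run.
#' Reproducible from `master_seed`.
#'
#' @param scenario An [ambiguity_scenario()].
#' @return A [partition_ensemble()] of `n_runs` partitions whose cell ids
#'   encode the cell class (`s1_*`, `s2_*`, `amb_*`).
#' @export
simulate_ambiguity <- function(scenario) {
  stopifnot(inherits(scenario, "ambiguity_scenario"))
  sc <- scenario
  n <- sc$n_cluster1 + sc$n_cluster2 + sc$n_ambiguous
  if (n < 2L) stop("scenario needs at least two cells", call. = FALSE)
  ids <- c(sprintf("s1_%03d", seq_len(sc$n_cluster1)),
           sprintf("s2_%03d", seq_len(sc$n_cluster2)),
           sprintf("amb_%03d", seq_len(sc$n_ambiguous)))
  base <- rep(c(1L, 2L), c(sc$n_cluster1, sc$n_cluster2))
  draws <- withr::with_seed(sc$master_seed,
    matrix(stats::rbinom(sc$n_ambiguous * sc$n_runs, 1L, sc$p_assign),
           nrow = sc$n_ambiguous, ncol = sc$n_runs))
  runs <- lapply(seq_len(sc$n_runs), function(nrun) {
    amb <- ifelse(draws[, nrun] == 1L, 1L, 2L)
    cell_partition(ids, c(base, amb), param_name = "resolution",
                   param_value = 1, seed = nrun)
  })
  partition_ensemble(runs)
}

#' Closed-form CUS expectation for the ambiguity model
#'
#' Under the independent-assignment model, the expected per-class mean CUS
#' and the Monte-Carlo standard error of that class mean have closed forms:
#' a stable-ambiguous pair agrees with probability p (cluster 1) or 1 - p
#' (cluster 2), an ambiguous-ambiguous pair with probability p^2 + (1-p)^2,
#' and stable-stable pairs always agree. The formulas take the union mate
#' set of every cell as complete, which holds up to terms of order
#' `(1-p)^N` + `p^N` — negligible for p in the interior at the default run
#' counts; at p = 0 or 1 all runs are identical and CUS is exactly 0.
#' The ambiguous-class moments are computed exactly over the distribution of
#' the per-run cluster-1 occupancy `S ~ Binomial(n_ambiguous, p)`.
#'
#' @param scenario An [ambiguity_scenario()].
#' @return Data.frame with columns `class` (`stable1`, `stable2`,
#'   `ambiguous`), `expected_cus` and `se` (standard error of the simulated
#'   class-mean under the model).
#' @export
cus_expected <- function(scenario) {
  stopifnot(inherits(scenario, "ambiguity_scenario"))
  sc <- scenario
  s1 <- sc$n_cluster1; s2 <- sc$n_cluster2; a <- sc$n_ambiguous
  p <- sc$p_assign; q <- 1 - p; N <- sc$n_runs
  cls <- c("stable1", "stable2", "ambiguous")
  if (a == 0L || p == 0 || p == 1)
    return(data.frame(class = cls, expected_cus = 0, se = 0))
  e_s1 <- a * q / (s1 - 1 + a)
  e_s2 <- a * p / (s2 - 1 + a)
  se_s1 <- sqrt(a * p * q / N) / (s1 - 1 + a)
  se_s2 <- sqrt(a * p * q / N) / (s2 - 1 + a)
  ## ambiguous class: mean over cells is an i.i.d. average over runs of
  ## h(S) = [s1*S + s2*(a-S) + 2*(choose(S,2) + choose(a-S,2))] / a
  d_mates <- s1 + s2 + a - 1
  s_vals <- 0:a
  w <- stats::dbinom(s_vals, a, p)
  h <- (s1 * s_vals + s2 * (a - s_vals) +
        2 * (choose(s_vals, 2) + choose(a - s_vals, 2))) / a
  e_h <- sum(w * h)
  v_h <- sum(w * (h - e_h)^2)
  e_amb <- 1 - e_h / d_mates
  se_amb <- sqrt(v_h / N) / d_mates
  data.frame(class = cls,
             expected_cus = c(e_s1, e_s2, e_amb),
             se = c(se_s1, se_s2, se_amb))
}

#' CUS response curves over an assignment-probability grid
#'
#' Reproduces the three benchmark configurations of the ambiguity model —
#' ambiguous cells joining the larger of two disparate clusters (200/20),
#' one of two balanced clusters (110/110), or the smaller cluster (20/200) —
#' and tabulates, at each probability of the grid, the per-class mean CUS
#' and the dataset-wide spread.
#'
#' @param p_grid Numeric vector of assignment probabilities in `[0, 1]`.
#' @param configuration `"larger"`, `"balanced"` or `"smaller"`: which
#'   cluster the assignment probability refers to.
#' @param n_ambiguous,n_stable Population sizes (defaults 30 and 220).
#' @param n_runs Runs per ensemble (default 200).
#' @param master_seed Integer master seed; each grid point uses a child seed
#'   `master_seed + index - 1`.
#' @return Data.frame with columns `p`, `class` (three cell classes plus
#'   `"all"`), `mean_cus`, `min`, `max`, `spread`.
#' @export
cus_response_curve <- function(p_grid,
                               configuration = c("larger", "balanced",
                                                 "smaller"),
                               n_ambiguous = 30, n_stable = 220,
                               n_runs = 200, master_seed = 1) {
  configuration <- match.arg(configuration)
  if (any(p_grid < 0 | p_grid > 1))
    stop("p_grid values must be in [0, 1]", call. = FALSE)
  sizes <- switch(configuration,
                  larger = c(round(n_stable * 10 / 11),
                             n_stable - round(n_stable * 10 / 11)),
                  balanced = c(floor(n_stable / 2), ceiling(n_stable / 2)),
                  smaller = c(n_stable - round(n_stable * 10 / 11),
                              round(n_stable * 10 / 11)))
  rows <- list()
  for (k in seq_along(p_grid)) {
    sc <- ambiguity_scenario(sizes[1], sizes[2], n_ambiguous,
                             p_assign = p_grid[k], n_runs = n_runs,
                             master_seed = master_seed + k - 1L)
    s <- cus(simulate_ambiguity(sc))
    cls <- .scenario_classes(sc)
    for (cl in c("stable1", "stable2", "ambiguous")) {
      v <- s$cus[cls == cl]
      rows[[length(rows) + 1L]] <-
        data.frame(p = p_grid[k], class = cl, mean_cus = mean(v),
                   min = min(v), max = max(v), spread = max(v) - min(v))
    }
    rows[[length(rows) + 1L]] <-
      data.frame(p = p_grid[k], class = "all", mean_cus = mean(s$cus),
                 min = min(s$cus), max = max(s$cus),
                 spread = max(s$cus) - min(s$cus))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Define a planted-cluster count model
#'
#' Negative-binomial count generator with planted structure used to exercise
#' the whole pipeline, emulating three features of real cell populations:
#' * each cluster has private marker genes up-shifted by `marker_fold`;
#' * clusters 1 and 2 share a program of genes up-shifted by `program_fold`
#'   in both — two related subtypes next to one distinct population, the
#'   typical shape of cell-type hierarchies, which merges the subtypes at
#'   low clustering resolution;
#' * all cells carry a continuous activity gradient (like activation or
#'   cell-cycle state) scaling a set of gradient genes up to
#'   `gradient_fold` — smooth heterogeneity that high clustering
#'   resolutions cut arbitrarily, producing seed-unstable splits.
#'
#' Signal genes (markers, program, gradient) draw their baseline means from
#' a moderately expressed regime, as canonical markers do; background genes
#' follow a broader log-normal. One planted gene set (the markers of
#' cluster 1) plus random decoy sets are emitted for enrichment testing.
#'
#' @param n_cells Integer vector of cells per cluster.
#' @param n_genes Total gene count.
#' @param n_markers Private marker genes per cluster.
#' @param marker_fold Fold change (> 1) of markers in their own cluster.
#' @param n_program Size of the shared cluster-1/2 program (0 disables it).
#' @param program_fold Fold change of program genes in clusters 1 and 2.
#' @param n_gradient Number of gradient genes (0 disables the gradient).
#' @param gradient_fold Maximum fold change along the activity gradient.
#' @param base_meanlog,base_sdlog Log-normal parameters of background gene
#'   means.
#' @param signal_meanlog,signal_sdlog Log-normal parameters of
#'   marker/program/gradient baseline means.
#' @param dispersion Negative-binomial size parameter (smaller = noisier).
#' @param lib_sdlog Log-normal sd of per-cell depth factors.
#' @param n_decoy_sets Random decoy gene sets written alongside the planted
#'   one.
#' @param master_seed Integer seed.
#' @return An object of class `planted_count_model`.
#' @export
planted_count_model <- function(n_cells = c(250, 200, 150), n_genes = 2000,
                                n_markers = 25, marker_fold = 2.5,
                                n_program = 25, program_fold = 2.5,
                                n_gradient = 40, gradient_fold = 4,
                                base_meanlog = log(0.3), base_sdlog = 1,
                                signal_meanlog = log(0.6), signal_sdlog = 0.4,
                                dispersion = 2, lib_sdlog = 0.3,
                                n_decoy_sets = 20, master_seed = 1) {
  if (any(n_cells < 0) || any(n_cells != round(n_cells)))
    stop("n_cells must be non-negative integers", call. = FALSE)
  if (marker_fold <= 1 && n_markers > 0)
    stop("marker_fold must be > 1", call. = FALSE)
  if (n_program > 0 && program_fold <= 1)
    stop("program_fold must be > 1", call. = FALSE)
  if (n_gradient > 0 && gradient_fold <= 1)
    stop("gradient_fold must be > 1", call. = FALSE)
  n_clusters <- length(n_cells)
  if (n_genes < n_clusters * n_markers + n_program + n_gradient)
    stop("n_genes too small for the requested signal genes", call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be > 0", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_markers = as.integer(n_markers),
                 marker_fold = as.numeric(marker_fold),
                 n_program = as.integer(n_program),
                 program_fold = as.numeric(program_fold),
                 n_gradient = as.integer(n_gradient),
                 gradient_fold = as.numeric(gradient_fold),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 signal_meanlog = signal_meanlog, signal_sdlog = signal_sdlog,
                 dispersion = as.numeric(dispersion),
                 lib_sdlog = as.numeric(lib_sdlog),
                 n_decoy_sets = as.integer(n_decoy_sets),
                 master_seed = as.integer(master_seed)),
            class = "planted_count_model")
}

#' Simulate counts with planted clusters, markers and a pathway
#'
#' @param model A [planted_count_model()].
#' @return List with `counts` (sparse genes x cells integer matrix),
#'   `labels` (cluster id per cell), `metadata` (data.frame `cell`,
#'   `cluster`, `activity`), `markers` (list of private marker genes per
#'   cluster), `program_genes`, `gradient_genes`, `gene_sets` (named list:
#'   `PLANTED_CLUSTER1_MARKERS` plus decoys) and `model`.
#' @export
simulate_counts <- function(model) {
  stopifnot(inherits(model, "planted_count_model"))
  md <- model
  n_clusters <- length(md$n_cells)
  n_total <- sum(md$n_cells)
  if (n_total == 0L) stop("model has no cells", call. = FALSE)
  genes <- sprintf("gene%04d", seq_len(md$n_genes))
  cells <- sprintf("cell%04d", seq_len(n_total))
  labels <- rep(seq_len(n_clusters), md$n_cells)
  n_signal <- n_clusters * md$n_markers + md$n_program + md$n_gradient

  withr::with_seed(md$master_seed, {
    base_mu <- stats::rlnorm(md$n_genes, md$base_meanlog, md$base_sdlog)
    base_mu[seq_len(n_signal)] <-
      stats::rlnorm(n_signal, md$signal_meanlog, md$signal_sdlog)
    idx <- 0L
    markers <- vector("list", n_clusters)
    for (k in seq_len(n_clusters)) {
      markers[[k]] <- genes[idx + seq_len(md$n_markers)]
      idx <- idx + md$n_markers
    }
    names(markers) <- paste0("cluster", seq_len(n_clusters))
    program <- if (md$n_program > 0) genes[idx + seq_len(md$n_program)]
               else character(0)
    idx <- idx + md$n_program
    gradient <- if (md$n_gradient > 0) genes[idx + seq_len(md$n_gradient)]
                else character(0)
    idx <- idx + md$n_gradient

    ## per-cluster gene means
    mu_cluster <- matrix(base_mu, nrow = md$n_genes, ncol = n_clusters)
    for (k in seq_len(n_clusters))
      mu_cluster[match(markers[[k]], genes), k] <-
        mu_cluster[match(markers[[k]], genes), k] * md$marker_fold
    if (length(program) > 0)
      for (k in seq_len(min(2L, n_clusters)))
        mu_cluster[match(program, genes), k] <-
          mu_cluster[match(program, genes), k] * md$program_fold

    activity <- stats::runif(n_total)        # latent per-cell state
    lib <- stats::rlnorm(n_total, 0, md$lib_sdlog)
    mu <- mu_cluster[, labels, drop = FALSE]
    if (length(gradient) > 0) {
      gi <- match(gradient, genes)
      mu[gi, ] <- mu[gi, , drop = FALSE] *
        rep(1 + (md$gradient_fold - 1) * activity, each = length(gi))
    }
    mu <- sweep(mu, 2, lib, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = md$dispersion),
                     nrow = md$n_genes, dimnames = list(genes, cells))
    decoy_pool <- genes[(idx + 1L):md$n_genes]
    decoys <- lapply(seq_len(md$n_decoy_sets), function(s)
      sample(decoy_pool, md$n_markers))
    names(decoys) <- sprintf("DECOY_SET_%02d", seq_len(md$n_decoy_sets))
  })

  gene_sets <- c(list(PLANTED_CLUSTER1_MARKERS = markers[[1]]), decoys)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       labels = labels,
       metadata = data.frame(cell = cells, cluster = paste0("c", labels),
                             activity = activity, row.names = cells),
       markers = markers, program_genes = program,
       gradient_genes = gradient, gene_sets = gene_sets, model = md)
}
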