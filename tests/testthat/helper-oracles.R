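# Brute-force reference implementations used as independent oracles.
# They deliberately mirror the definitions literally (explicit loops over
# cells, mates and runs) and share no code with the package internals.

# Per-cell co-clustering conservation by double loop over mate pairs.
cc_oracle <- function(prev_labels, curr_labels) {
  n <- length(prev_labels)
  vapply(seq_len(n), function(i) {
    mates <- setdiff(which(prev_labels == prev_labels[i]), i)
    if (length(mates) == 0L) return(NA_real_)
    kept <- 0L
    for (j in mates)
      if (curr_labels[j] == curr_labels[i]) kept <- kept + 1L
    kept / length(mates)
  }, numeric(1))
}

# Per-cell CUS by triple loop over cells, union mates, runs.
# label_matrix: cells x runs.
cus_oracle <- function(label_matrix) {
  n <- nrow(label_matrix)
  n_runs <- ncol(label_matrix)
  vapply(seq_len(n), function(i) {
    J <- integer(0)
    for (j in seq_len(n))
      if (j != i && any(label_matrix[j, ] == label_matrix[i, ]))
        J <- c(J, j)
    if (length(J) == 0L) return(0)
    agree <- 0L
    for (j in J)
      for (r in seq_len(n_runs))
        if (label_matrix[j, r] == label_matrix[i, r]) agree <- agree + 1L
    1 - agree / (length(J) * n_runs)
  }, numeric(1))
}

# Two-sided Fisher p by full hypergeometric enumeration over tables with the
# observed margins. Counts as in the package: de_path, nonde_path,
# de_nonpath, nonde_nonpath.
fisher_p_oracle <- function(de_path, nonde_path, de_nonpath, nonde_nonpath) {
  m <- de_path + de_nonpath          # DE genes
  n <- nonde_path + nonde_nonpath    # non-DE genes
  k <- de_path + nonde_path          # genes in the set
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(de_path, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random partition of n cells into at most k_max clusters (some may be empty,
# so the realized cluster count varies; singletons arise naturally).
rand_labels <- function(n, k_max) sample.int(k_max, n, replace = TRUE)

rand_partition <- function(n, k_max, param_value = 1, seed = NULL) {
  cell_partition(sprintf("cell%03d", seq_len(n)), rand_labels(n, k_max),
                 param_value = param_value, seed = seed)
}

rand_ensemble <- function(n, k_max, n_runs, param_value = 1) {
  partition_ensemble(lapply(seq_len(n_runs), function(s)
    rand_partition(n, k_max, param_value = param_value, seed = s)))
}

label_matrix_of <- function(ensemble) {
  do.call(cbind, lapply(ensemble, function(p) as.integer(factor(p$labels))))
}
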