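test_that("ambiguity simulator honors its analytic limits and determinism", {
  # p = 1: ambiguous cells always in cluster 1 -> identical runs, CUS 0
  for (p in c(0, 1)) {
    sc <- ambiguity_scenario(20, 10, 5, p_assign = p, n_runs = 5,
                             master_seed = 901)
    s <- cus(simulate_ambiguity(sc))
    expect_equal(s$cus, rep(0, 35))
  }

  sc <- ambiguity_scenario(20, 10, 5, p_assign = 0.5, n_runs = 6,
                           master_seed = 902)
  e1 <- simulate_ambiguity(sc)
  e2 <- simulate_ambiguity(sc)
  expect_identical(lapply(e1, `[[`, "labels"), lapply(e2, `[[`, "labels"))

  # stable cells never change label
  lm <- label_matrix_of(e1)
  expect_true(all(apply(lm[1:30, , drop = FALSE], 1,
                        function(x) length(unique(x)) == 1)))

  expect_error(ambiguity_scenario(p_assign = 1.2), "p_assign")
  expect_error(ambiguity_scenario(n_runs = 1), "n_runs")
})

test_that("Monte-Carlo class means recover the closed-form expectation", {
  cls_means <- function(scenario) {
    s <- cus(simulate_ambiguity(scenario))
    cls <- rep(c("stable1", "stable2", "ambiguous"),
               c(scenario$n_cluster1, scenario$n_cluster2,
                 scenario$n_ambiguous))
    tapply(s$cus, cls, mean)
  }
  for (p in c(0.25, 0.5, 0.75)) {
    sc <- ambiguity_scenario(110, 110, 30, p_assign = p, n_runs = 200,
                             master_seed = 903 + round(100 * p))
    ex <- cus_expected(sc)
    mc <- cls_means(sc)[ex$class]
    expect_true(all(abs(as.numeric(mc) - ex$expected_cus) <= 3 * ex$se),
                info = paste("p =", p))
  }
  # oracle agreement at small size: expectation formula vs direct brute force
  sc_small <- ambiguity_scenario(6, 4, 3, p_assign = 0.4, n_runs = 3,
                                 master_seed = 904)
  ens <- simulate_ambiguity(sc_small)
  expect_equal(cus(ens)$cus, cus_oracle(label_matrix_of(ens)))
})

test_that("response curves show symmetry and size-dependent spread", {
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pkey <- function(x) round(10 * x)     # float-safe grid matching
  bal <- cus_response_curve(grid, "balanced", n_runs = 100, master_seed = 905)
  dis_l <- cus_response_curve(grid, "larger", n_runs = 100, master_seed = 906)
  dis_s <- cus_response_curve(grid, "smaller", n_runs = 100,
                              master_seed = 907)

  amb <- bal[bal$class == "ambiguous", ]
  # symmetry of the balanced configuration about p = 0.5 (MC tolerance:
  # four combined standard errors from the closed-form model)
  for (p in c(0.1, 0.3)) {
    se_p <- cus_expected(ambiguity_scenario(110, 110, 30, p, 100))$se[3]
    tol <- 4 * sqrt(2) * se_p
    expect_lt(abs(amb$mean_cus[pkey(amb$p) == pkey(p)] -
                  amb$mean_cus[pkey(amb$p) == pkey(1 - p)]),
              tol)
  }
  # maximal ambiguity at p = 0.5
  expect_equal(amb$p[which.max(amb$mean_cus)], 0.5)

  # the disparate configuration (its two panel orientations: ambiguity
  # toward the larger or the smaller cluster) stretches the dataset-wide
  # CUS range beyond the balanced one at every matched p
  for (p in grid) {
    dis_spread <- max(dis_l$spread[dis_l$class == "all" &
                                     pkey(dis_l$p) == pkey(p)],
                      dis_s$spread[dis_s$class == "all" &
                                     pkey(dis_s$p) == pkey(p)])
    expect_gte(dis_spread,
               bal$spread[bal$class == "all" & pkey(bal$p) == pkey(p)])
  }
})

test_that("planted count simulation is reproducible with stated moments", {
  model <- planted_count_model(n_cells = c(60, 50), n_genes = 300,
                               n_markers = 10, n_program = 0,
                               n_gradient = 0, master_seed = 907)
  a <- simulate_counts(model)
  b <- simulate_counts(model)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_equal(dim(a$counts), c(300, 110))
  expect_equal(a$labels, rep(1:2, c(60, 50)))
  expect_true(all(a$counts >= 0 & a$counts == round(a$counts)))

  # NB moments on a fixed-mean model: per-gene mean within 4 SE, and the
  # dispersion inflates variance beyond Poisson
  model2 <- planted_count_model(n_cells = 500, n_genes = 200, n_markers = 0,
                                n_program = 0, n_gradient = 0,
                                base_meanlog = log(2), base_sdlog = 0,
                                dispersion = 2, lib_sdlog = 0,
                                master_seed = 908)
  sim <- simulate_counts(model2)
  mu <- 2; size <- 2; n <- 500
  sd_gene <- sqrt(mu + mu^2 / size)
  means <- Matrix::rowMeans(sim$counts)
  expect_true(all(abs(means - mu) <= 4 * sd_gene / sqrt(n)))
  vars <- apply(as.matrix(sim$counts), 1, var)
  expect_gt(mean(vars), mu)              # overdispersed beyond Poisson
  expect_lt(abs(mean(vars) - (mu + mu^2 / size)), 0.5)

  # markers are planted in the emitted gene sets
  expect_equal(a$gene_sets$PLANTED_CLUSTER1_MARKERS, a$markers$cluster1)
  expect_error(planted_count_model(marker_fold = 0.5), "marker_fold")
  expect_error(planted_count_model(n_genes = 10), "too small")
})

test_that("label-free data yields higher uncertainty than planted structure", {
  flat <- planted_count_model(n_cells = c(70, 70), n_genes = 500,
                              n_markers = 0, n_program = 0, n_gradient = 0,
                              master_seed = 909)
  planted <- planted_count_model(n_cells = c(70, 70), n_genes = 500,
                                 n_markers = 20, marker_fold = 4,
                                 n_program = 0, n_gradient = 0,
                                 master_seed = 909)
  run_med_cus <- function(model, res) {
    sim <- simulate_counts(model)
    g <- snn_graph(reduce_pca(normalize_counts(sim$counts), 10), k = 15)
    ens <- sweep_clustering(g, res, seeds = 1:5)$ensembles[[1]]
    median(cus(ens)$cus)
  }
  expect_gt(run_med_cus(flat, 0.8), run_med_cus(planted, 0.8))
})
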