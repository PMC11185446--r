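test_that("de_test reproduces exact Wilcoxon references and filters", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 2/20 = 0.1
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 1,
              dimnames = list("g1", paste0("c", 1:6)))
  res <- de_test(m, paste0("c", 1:3), paste0("c", 4:6),
                 min_pct = 0, min_lfc = 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 0)        # rank-sum W for group1

  # identical value multisets: lfc 0, exact p 1
  m2 <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 1,
               dimnames = list("g1", paste0("c", 1:6)))
  res2 <- de_test(m2, paste0("c", 1:3), paste0("c", 4:6),
                  min_pct = 0, min_lfc = 0)
  expect_equal(res2$log2_fold_change, 0)
  expect_equal(res2$p_value, 1)

  # min_pct filter: a gene detected in 5% of both groups is dropped
  set.seed(701)
  m3 <- matrix(0, nrow = 2, ncol = 40,
               dimnames = list(c("rare", "common"), paste0("c", 1:40)))
  m3["rare", c(1, 21)] <- 5               # 5% of each group of 20
  m3["common", ] <- rnorm(40, 5)
  res3 <- de_test(m3, paste0("c", 1:20), paste0("c", 21:40),
                  min_pct = 0.1, min_lfc = 0)
  expect_false("rare" %in% res3$gene)
  expect_true("common" %in% res3$gene)

  # constant gene (e.g. all zeros in both groups): no evidence, p = 1,
  # never NA from the degenerate tie-corrected variance
  m4 <- matrix(0, nrow = 2, ncol = 6,
               dimnames = list(c("const", "var"), paste0("c", 1:6)))
  m4["var", ] <- 1:6
  res4 <- de_test(m4, paste0("c", 1:3), paste0("c", 4:6),
                  min_pct = 0, min_lfc = 0)
  expect_equal(res4$p_value[res4$gene == "const"], 1)
  expect_false(anyNA(res4$p_value))

  # input validation
  expect_error(de_test(m, paste0("c", 1:3), paste0("c", 3:6)), "disjoint")
  expect_error(de_test(m, character(0), paste0("c", 4:6)), "non-empty")
})

test_that("percent-expressing, fold change and FDR columns are coherent", {
  set.seed(702)
  m <- matrix(rpois(50 * 30, 1), nrow = 50,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:30)))
  res <- de_test(m, paste0("c", 1:15), paste0("c", 16:30),
                 min_pct = 0, min_lfc = 0)
  expect_true(all(res$pct_expressing_1 >= 0 & res$pct_expressing_1 <= 100))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  g <- res$gene[1]
  expect_equal(res$log2_fold_change[1],
               log2((mean(m[g, 1:15]) + 1) / (mean(m[g, 16:30]) + 1)))
  expect_equal(res$fdr, p.adjust(res$p_value, "BH"))
})

test_that("exact and approximate paths agree closely at moderate sizes", {
  set.seed(703)
  dmax <- 0
  for (r in 1:30) {
    n1 <- sample(15:25, 1); n2 <- sample(15:25, 1)
    m <- matrix(rnorm(n1 + n2), nrow = 1,
                dimnames = list("g", paste0("c", seq_len(n1 + n2))))
    pe <- de_test(m, paste0("c", 1:n1), paste0("c", n1 + 1:n2),
                  0, 0, method = "exact")$p_value
    pa <- de_test(m, paste0("c", 1:n1), paste0("c", n1 + 1:n2),
                  0, 0, method = "approx")$p_value
    dmax <- max(dmax, abs(pe - pa))
  }
  expect_lte(dmax, 0.02)
})

test_that("grouping modes enumerate the right comparisons", {
  set.seed(704)
  n <- 60
  m <- matrix(rpois(30 * n, 2), nrow = 30,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:n)))
  meta <- data.frame(cluster = rep(c("a", "b", "c"), each = 20),
                     treatment = rep(c("ctl", "trt"), n / 2),
                     row.names = paste0("c", 1:n))

  ovr <- run_de(m, meta, "cluster", mode = "one_vs_rest",
                min_pct = 0, min_lfc = 0)
  expect_equal(sort(unique(ovr$comparison)),
               c("cluster=a_vs_rest", "cluster=b_vs_rest",
                 "cluster=c_vs_rest"))

  ovo <- run_de(m, meta, "cluster", mode = "one_vs_one",
                min_pct = 0, min_lfc = 0)
  expect_equal(length(unique(ovo$comparison)), 3L)  # 3 unordered pairs

  # 2 treatments x 3 clusters -> 3 conditional comparisons (1 pair each)
  cond <- run_de(m, meta, "treatment", secondary_var = "cluster",
                 mode = "conditional", min_pct = 0, min_lfc = 0)
  expect_equal(length(unique(cond$comparison)), 3L)
  expect_true(all(grepl("\\|cluster=", unique(cond$comparison))))

  expect_error(run_de(m, meta, "treatment", mode = "conditional"),
               "secondary_var")
  expect_error(run_de(m, meta, "nope"), "no column")

  # groups under 3 cells are skipped with a warning
  meta_small <- meta
  meta_small$cluster[1:58] <- "a"
  meta_small$cluster[59:60] <- "tiny"
  warns <- capture_warnings(
    res <- run_de(m, meta_small, "cluster", mode = "one_vs_rest",
                  min_pct = 0, min_lfc = 0))
  expect_true(any(grepl("< 3 cells", warns)))
  expect_false(any(grepl("tiny_vs_rest", res$comparison)))
})

test_that("null data is calibrated and planted markers dominate", {
  set.seed(705)
  # type-I error on 2000 null genes
  m <- matrix(rnbinom(2000 * 200, mu = 1, size = 2), nrow = 2000,
              dimnames = list(paste0("g", 1:2000), paste0("c", 1:200)))
  res <- de_test(m, paste0("c", 1:100), paste0("c", 101:200),
                 min_pct = 0, min_lfc = 0)
  frac <- mean(res$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), 3 * se)

  # planted effect: shifted genes rank above all null genes
  m2 <- m[1:200, ]
  m2[1:20, 1:100] <- m2[1:20, 1:100] +
    matrix(rnbinom(20 * 100, mu = 4, size = 2), 20)
  res2 <- de_test(m2, paste0("c", 1:100), paste0("c", 101:200),
                  min_pct = 0, min_lfc = 0)
  planted <- paste0("g", 1:20)
  expect_lt(max(res2$p_value[res2$gene %in% planted]),
            min(res2$p_value[!res2$gene %in% planted]))
})
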