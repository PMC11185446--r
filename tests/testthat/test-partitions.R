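test_that("co-clustering matrix is the literal indicator", {
  p <- cell_partition(c("a", "b", "c"), c("A", "A", "B"))
  ccm <- build_coclustering(p)
  expect_true(ccm[1, 2] && ccm[2, 1])
  expect_false(ccm[1, 3] || ccm[2, 3])
  expect_true(all(Matrix::diag(ccm)))

  one <- build_coclustering(cell_partition(as.character(1:4), rep(1, 4)))
  expect_true(all(as.matrix(one)))

  singletons <- build_coclustering(cell_partition(as.character(1:4), 1:4))
  expect_equal(as.matrix(singletons), diag(4) == 1, ignore_attr = TRUE)

  expect_error(cell_partition(character(0), integer(0)), "at least one")
})

test_that("conservation matches hand enumeration and brute force", {
  # prev {A=1..4, B=5,6}; curr {A'=1..3, C=4, B'=5,6}
  prev <- cell_partition(as.character(1:6), c(1, 1, 1, 1, 2, 2))
  curr <- cell_partition(as.character(1:6), c(1, 1, 1, 3, 2, 2))
  cc <- coclustering_conservation(prev, curr)
  expect_equal(unname(cc), c(2 / 3, 2 / 3, 2 / 3, 0, 1, 1))

  # identity on a partition with no singletons
  expect_equal(unname(coclustering_conservation(prev, prev)), rep(1, 6))

  # prev singleton is missing, never imputed
  prev2 <- cell_partition(as.character(1:3), c(1, 2, 2))
  curr2 <- cell_partition(as.character(1:3), c(1, 1, 1))
  expect_true(is.na(coclustering_conservation(prev2, curr2)[1]))

  # random instances against the double-loop oracle, exact
  set.seed(401)
  for (r in 1:25) {
    n <- sample(5:60, 1)
    a <- rand_partition(n, sample(2:8, 1))
    b <- cell_partition(a$cell_ids, rand_labels(n, sample(2:8, 1)),
                        param_value = 2)
    expect_equal(unname(coclustering_conservation(a, b)),
                 cc_oracle(a$labels, b$labels))
  }

  expect_error(
    coclustering_conservation(prev, cell_partition(letters[1:6], 1:6)),
    "identical cell_ids")
})

test_that("conservation is invariant to cluster relabeling", {
  set.seed(402)
  a <- rand_partition(40, 5)
  b <- cell_partition(a$cell_ids, rand_labels(40, 4), param_value = 2)
  perm_a <- cell_partition(a$cell_ids, match(a$labels, sample(5)),
                           param_value = 1)
  perm_b <- cell_partition(b$cell_ids, match(b$labels, sample(4)),
                           param_value = 2)
  expect_equal(coclustering_conservation(perm_a, perm_b),
               coclustering_conservation(a, b))
})

test_that("conservation profile summarizes each adjacent pair", {
  set.seed(403)
  base <- rand_partition(30, 3, param_value = 0.1)
  same <- cell_partition(base$cell_ids, base$labels, param_value = 0.2)
  shuffled <- cell_partition(base$cell_ids,
                             (match(base$labels, unique(base$labels)) %% 3) + 10,
                             param_value = 0.3)
  # step 2->3 relabels every cluster but keeps mate sets: CC stays 1
  sw <- partition_sweep(list(base, same, shuffled))
  prof <- conservation_profile(sw)
  expect_equal(nrow(prof$summary), 2)
  expect_true(all(prof$per_cell[[1]] == 1, na.rm = TRUE))

  expect_error(conservation_profile(partition_sweep(list(base))),
               "at least two")
})

test_that("a total reshuffle yields all-zero conservation", {
  # 2 clusters of 3 -> 3 clusters of 2 crossing the old boundary
  prev <- cell_partition(as.character(1:6), c(1, 1, 1, 2, 2, 2))
  curr <- cell_partition(as.character(1:6), c(1, 2, 3, 1, 2, 3))
  expect_equal(unname(coclustering_conservation(prev, curr)), rep(0, 6))
})

test_that("flow tables count moves and conserve weights", {
  prev <- cell_partition(as.character(1:6), c("A", "A", "A", "A", "B", "B"),
                         param_value = 0.4)
  curr <- cell_partition(as.character(1:6), c("A", "A", "A", "C", "B", "B"),
                         param_value = 0.5)
  fl <- flow_table(prev, curr)
  expect_equal(fl$n_cells[fl$from == "A" & fl$to == "A"], 3L)
  expect_equal(fl$n_cells[fl$from == "A" & fl$to == "C"], 1L)
  expect_equal(fl$n_cells[fl$from == "B" & fl$to == "B"], 2L)
  expect_equal(nrow(fl), 3)
  expect_true(all(grepl("^0\\.4:", fl$from_id)))

  # identity: only identity edges with weights = cluster sizes
  fl_id <- flow_table(prev, cell_partition(prev$cell_ids, prev$labels,
                                           param_value = 0.5))
  expect_true(all(fl_id$from == fl_id$to))
  expect_equal(sort(fl_id$n_cells), c(2L, 4L))

  # merge: two edges into one target summing to target size
  merged <- cell_partition(as.character(1:6), rep("M", 6), param_value = 0.5)
  fl_m <- flow_table(prev, merged)
  expect_equal(sum(fl_m$n_cells), 6L)
  expect_equal(nrow(fl_m), 2)

  # weight conservation on random pairs (out-sums and in-sums)
  set.seed(404)
  for (r in 1:100) {
    n <- sample(10:200, 1)
    a <- rand_partition(n, sample(2:10, 1), param_value = 1)
    b <- cell_partition(a$cell_ids, rand_labels(n, sample(2:10, 1)),
                        param_value = 2)
    fl <- flow_table(a, b)
    outs <- tapply(fl$n_cells, fl$from, sum)
    ins <- tapply(fl$n_cells, fl$to, sum)
    expect_equal(outs[order(names(outs))],
                 table(a$labels)[order(names(table(a$labels)))],
                 ignore_attr = TRUE)
    expect_equal(ins[order(names(ins))],
                 table(b$labels)[order(names(table(b$labels)))],
                 ignore_attr = TRUE)
    expect_equal(sum(fl$n_cells), n)
  }
})

test_that("sweeps validate ordering, cells and parameter axis", {
  a <- rand_partition(10, 3, param_value = 0.3)
  b <- cell_partition(a$cell_ids, rand_labels(10, 3), param_value = 0.1)
  sw <- partition_sweep(list(a, b))     # sorted ascending
  expect_equal(vapply(sw, `[[`, numeric(1), "param_value"), c(0.1, 0.3))

  dup <- cell_partition(a$cell_ids, a$labels, param_value = 0.3)
  expect_error(partition_sweep(list(a, dup)), "strictly increasing")
  other <- cell_partition(letters[1:10], rand_labels(10, 3), param_value = 1)
  expect_error(partition_sweep(list(a, other)), "identical cell_ids")
  npcs <- cell_partition(a$cell_ids, a$labels, param_name = "n_pcs",
                         param_value = 10)
  expect_error(partition_sweep(list(a, npcs)), "one param_name")
})
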