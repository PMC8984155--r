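test_that("clusterMean applies the expressing-fraction gate", {
  vals <- matrix(c(0, 0, 2, 2), nrow = 1, dimnames = list("gA", NULL))
  sce <- makeSCE(vals, cell_type = rep("T", 4), state = rep("NBM", 4))
  expect_equal(clusterMean(sce, "gA", "T", "NBM", min_expr_fraction = 0.10), 1.0)

  # expressed in 1 of 20 cells (5%) -> gated to zero
  vals20 <- matrix(c(10, rep(0, 19)), nrow = 1, dimnames = list("gA", NULL))
  sce20 <- makeSCE(vals20, cell_type = rep("T", 20), state = rep("NBM", 20))
  expect_equal(clusterMean(sce20, "gA", "T", "NBM"), 0)

  # min_expr_fraction = 0 disables gating
  vals4 <- matrix(c(0, 0, 0, 4), nrow = 1, dimnames = list("gA", NULL))
  sce4 <- makeSCE(vals4, cell_type = rep("T", 4), state = rep("NBM", 4))
  expect_equal(clusterMean(sce4, "gA", "T", "NBM", min_expr_fraction = 0), 1.0)

  expect_error(clusterMean(sce4, "gA", "B", "NBM"), "empty cluster")
})

test_that("exhaustive permutation p equals an independent enumeration", {
  set.seed(9)
  for (split in list(c(3, 3), c(2, 4), c(4, 4), c(2, 3))) {
    n <- sum(split)
    labels <- rep(c("A", "B"), times = split)
    lig <- round(rexp(n, 0.5), 2)
    rec <- round(rexp(n, 0.5), 2)
    vals <- rbind(gL = lig, gR = rec)
    sce <- makeSCE(vals, cell_type = labels, state = rep("NBM", n))
    pair <- makePairs("gL", "gR")
    got <- permutationTest(sce, pair, "A", "B", "NBM", mode = "exhaustive",
                           min_expr_fraction = 0.1)
    oracle <- bruteForcePermP(lig, rec, labels, "A", "B", 0.1)
    expect_equal(got$interaction_score, oracle$obs)
    expected_p <- if (oracle$obs == 0) 1 else oracle$p
    expect_equal(got$p_value, expected_p)
    # C(6,3) = 20 assignments for the 3+3 split
    if (all(split == c(3, 3))) {
      expect_equal(length(oracle$null), 20L)
    }
  }
})

test_that("degenerate inputs hit the zero-score and all-ties rules", {
  # ligand and receptor all-zero in their clusters -> score 0 -> p = 1
  vals <- rbind(gL = c(0, 0, 0, 0, 5, 5), gR = c(0, 0, 0, 0, 0, 0))
  labels <- c("A", "A", "A", "B", "B", "B")
  sce <- makeSCE(vals, cell_type = labels, state = rep("NBM", 6))
  got <- permutationTest(sce, makePairs("gL", "gR"), "A", "B", "NBM",
                         n_perm = 50, seed = 1)
  expect_equal(got$interaction_score, 0)
  expect_equal(got$p_value, 1)

  # identical expression in every cell: all permuted scores equal observed
  vals2 <- rbind(gL = rep(2, 6), gR = rep(3, 6))
  sce2 <- makeSCE(vals2, cell_type = labels, state = rep("NBM", 6))
  got2 <- permutationTest(sce2, makePairs("gL", "gR"), "A", "B", "NBM",
                          n_perm = 50, seed = 1)
  expect_equal(got2$p_value, 1)

  # missing gene -> informative skip error
  expect_error(permutationTest(sce2, makePairs("gL", "gX"), "A", "B", "NBM"),
               "pair inactive")
})

test_that("Monte Carlo p approaches the exhaustive p", {
  set.seed(4)
  n <- 8
  labels <- rep(c("A", "B"), each = 4)
  vals <- rbind(gL = rpois(n, 3), gR = rpois(n, 3))
  sce <- makeSCE(vals, cell_type = labels, state = rep("NBM", n))
  pair <- makePairs("gL", "gR")
  exact <- permutationTest(sce, pair, "A", "B", "NBM", mode = "exhaustive")
  mc <- permutationTest(sce, pair, "A", "B", "NBM", n_perm = 10000, seed = 2)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 10000)
  expect_lte(abs(mc$p_value - exact$p_value), 3 * se + 1e-4)
})

test_that("detectAll enumerates states x ordered type pairs x active pairs", {
  set.seed(12)
  n <- 40
  labels <- rep(c("A", "B"), each = n / 2)
  vals <- matrix(rpois(6 * n, 4), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), NULL))
  sce <- makeSCE(vals, cell_type = labels, state = rep("NBM", n))
  pairs <- makePairs(c("g1", "g3", "g5"), c("g2", "g4", "g6"))
  res <- detectAll(sce, pairs, n_perm = 100, seed = 5)
  tab <- cceTable(res)
  expect_equal(nrow(tab), 2 * 2 * 3)  # 2 types x 2 types x 3 pairs
  expect_setequal(unique(paste(tab$source_type, tab$target_type)),
                  c("A A", "A B", "B A", "B B"))
  # directional: A->B and B->A are distinct records
  expect_equal(sum(tab$source_type == "A" & tab$target_type == "B"), 3)

  res2 <- detectAll(sce, pairs, n_perm = 100, seed = 5)
  expect_identical(cceTable(res2)$p_value, tab$p_value)

  # inactive pair skipped with its id recorded
  pairs_na <- rbind(pairs, makePairs("g1", "gZ", ids = "P9"))
  res3 <- detectAll(sce, pairs_na, n_perm = 50, seed = 5)
  expect_false("P9" %in% cceTable(res3)$pair_id)
  expect_identical(detectionParams(res3)$skipped_pairs, "P9")

  # p-values respect the add-one floor
  expect_true(all(tab$p_value >= 1 / 101))
})

test_that("detectAll agrees with single-event permutationTest scores", {
  set.seed(21)
  n <- 30
  labels <- sample(rep(c("A", "B", "C"), each = 10))
  vals <- matrix(rpois(4 * n, 3), nrow = 4,
                 dimnames = list(sprintf("g%d", 1:4), NULL))
  sce <- makeSCE(vals, cell_type = labels, state = rep("MM", n))
  pairs <- makePairs(c("g1", "g3"), c("g2", "g4"))
  res <- cceTable(detectAll(sce, pairs, n_perm = 10, seed = 1))
  for (i in sample(nrow(res), 4)) {
    one <- permutationTest(sce, pairs[pairs$pair_id == res$pair_id[i], ],
                           res$source_type[i], res$target_type[i], "MM",
                           n_perm = 5, seed = 1)
    expect_equal(one$interaction_score, res$interaction_score[i])
    expect_equal(one$ligand_mean, res$ligand_mean[i])
    expect_equal(one$receptor_mean, res$receptor_mean[i])
  }
})

test_that("planted events are recovered as significant with high power", {
  hits <- 0L
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    pe <- data.frame(pair_id = "P2", source_type = "Monocyte",
                     target_type = "CD8T", state = "MGUS", effect_size = 3,
                     stringsAsFactors = FALSE)
    ds <- generateDataset(synthConfig(
      n_states = 2, n_cell_types = 2, n_samples_per_state = 1,
      n_cells_per_type_per_sample = 100, n_genes = 60, n_lr_pairs = 5,
      planted_events = pe, seed = 100 + s))
    res <- significantCCEs(detectAll(ds$sce, ds$pairs, n_perm = 400,
                                     seed = 200 + s))
    found <- any(res$state == "MGUS" & res$pair_id == "P2" &
                   res$source_type == "Monocyte" & res$target_type == "CD8T")
    if (found) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})
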