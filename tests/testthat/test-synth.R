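test_that("identical seeds give identical datasets", {
  cfg <- synthConfig(n_states = 2, n_cell_types = 2, n_samples_per_state = 1,
                     n_cells_per_type_per_sample = 20, n_genes = 30,
                     n_lr_pairs = 4, seed = 7)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(as.matrix(SummarizedExperiment::assay(d1$sce, "counts")),
                   as.matrix(SummarizedExperiment::assay(d2$sce, "counts")))
  expect_identical(d1$survival, d2$survival)
  expect_identical(d1$ppi, d2$ppi)
  cfg2 <- synthConfig(n_states = 2, n_cell_types = 2, n_samples_per_state = 1,
                      n_cells_per_type_per_sample = 20, n_genes = 30,
                      n_lr_pairs = 4, seed = 8)
  expect_false(identical(as.matrix(SummarizedExperiment::assay(d1$sce, "counts")),
                         as.matrix(SummarizedExperiment::assay(generateDataset(cfg2)$sce,
                                                               "counts"))))
})

test_that("planted events raise the targeted stratum means on raw counts", {
  pe <- data.frame(pair_id = "P3", source_type = "Monocyte", target_type = "CD8T",
                   state = "MGUS", effect_size = 5, stringsAsFactors = FALSE)
  cfg <- synthConfig(n_states = 2, n_cell_types = 2, n_samples_per_state = 1,
                     n_cells_per_type_per_sample = 150, n_genes = 40,
                     n_lr_pairs = 6, planted_events = pe, seed = 3)
  ds <- generateDataset(cfg)
  counts <- as.matrix(SummarizedExperiment::assay(ds$sce, "counts"))
  cd <- SummarizedExperiment::colData(ds$sce)
  lig <- ds$pairs$ligand[ds$pairs$pair_id == "P3"]
  rec <- ds$pairs$receptor[ds$pairs$pair_id == "P3"]
  m_src_planted <- mean(counts[lig, cd$cell_type == "Monocyte" & cd$state == "MGUS"])
  m_src_other <- mean(counts[lig, cd$cell_type == "Monocyte" & cd$state == "NBM"])
  expect_gt(m_src_planted, m_src_other)
  # empirical fold at least half the configured effect (effect 5, 150 cells)
  expect_gte(m_src_planted / m_src_other, 2.5)
  m_tgt_planted <- mean(counts[rec, cd$cell_type == "CD8T" & cd$state == "MGUS"])
  m_tgt_other <- mean(counts[rec, cd$cell_type == "CD8T" & cd$state == "NBM"])
  expect_gte(m_tgt_planted / m_tgt_other, 2.5)
})

test_that("non-planted gene means match the configured baseline", {
  cfg <- synthConfig(n_states = 1, n_cell_types = 1, n_samples_per_state = 1,
                     n_cells_per_type_per_sample = 1200, n_genes = 10,
                     n_lr_pairs = 2, baseline_mean = 2, dispersion = 0.5,
                     seed = 5)
  ds <- generateDataset(cfg)
  x <- as.numeric(SummarizedExperiment::assay(ds$sce, "counts")["G0009", ])
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 2), 3 * se)
})

test_that("planted event references are validated", {
  pe <- data.frame(pair_id = "P9", source_type = "Monocyte",
                   target_type = "CD8T", state = "NBM", effect_size = 2)
  cfg <- synthConfig(n_states = 1, n_cell_types = 2, n_lr_pairs = 3,
                     n_genes = 10, planted_events = pe, seed = 1)
  expect_error(generateDataset(cfg), "config error")
  expect_error(synthConfig(n_genes = 4, n_lr_pairs = 5), "n_genes")
  expect_error(synthConfig(censor_rate = 1.5), "censor_rate")
})

test_that("pseudoBulk averages per sample and ignores cell order", {
  vals <- matrix(c(1, 3, 0, 0,
                   2, 2, 4, 8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), sprintf("c%d", 1:4)))
  sce <- makeSCE(vals, cell_type = rep("T", 4), state = rep("NBM", 4),
                 sample_id = c("s1", "s1", "s2", "s2"))
  pb <- pseudoBulk(sce)
  expect_equal(pb["s1", "gA"], 2)
  expect_equal(pb["s2", "gA"], 0)  # all-zero gene in s2
  expect_equal(pb["s2", "gB"], 6)
  perm <- c(3, 1, 4, 2)
  pb2 <- pseudoBulk(sce[, perm])
  expect_equal(pb, pb2)
})

test_that("with zero betas survival is independent of expression (type I ~ 5%)", {
  reps <- 200
  hits <- 0L
  for (r in seq_len(reps)) {
    cfg <- synthConfig(n_states = 1, n_cell_types = 1, n_samples_per_state = 60,
                       n_cells_per_type_per_sample = 4, n_genes = 6,
                       n_lr_pairs = 2, censor_rate = 0.1,
                       risk_genes = data.frame(gene = "G0001", beta = 0),
                       seed = 1000 + r)
    ds <- generateDataset(cfg)
    pb <- pseudoBulk(ds$sce)
    grp <- data.frame(sample_id = rownames(pb),
                      group = ifelse(pb[, "G0001"] > median(pb[, "G0001"]),
                                     "hi", "lo"))
    p <- logrankTest(grp, ds$survival)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("written datasets are read back by the loaders", {
  d <- withr::local_tempdir()
  cfg <- synthConfig(n_states = 2, n_cell_types = 2, n_samples_per_state = 1,
                     n_cells_per_type_per_sample = 15, n_genes = 20,
                     n_lr_pairs = 3, risk_genes = data.frame(gene = "G0001",
                                                             beta = 0.5),
                     seed = 11)
  ds <- generateDataset(cfg)
  paths <- writeDataset(ds, d)
  sce <- loadExpression(paths["matrix"], paths["barcodes"], paths["features"])
  sce <- addCellMetadata(sce, paths[["cells"]])
  expect_identical(dim(sce), dim(ds$sce))
  expect_identical(as.matrix(SummarizedExperiment::assay(sce, "counts")),
                   as.matrix(SummarizedExperiment::assay(ds$sce, "counts")))
  pairs <- loadLRPairs(paths[["lr_pairs"]])
  expect_identical(pairs$ligand, ds$pairs$ligand)
  expect_identical(pairs$receptor, ds$pairs$receptor)
  ppi <- loadPPIEdges(paths[["ppi"]])
  expect_equal(ppi$combined_score, ds$ppi$combined_score)
  surv <- loadSurvival(paths[["survival"]])
  expect_equal(surv$time, ds$survival$time, tolerance = 1e-12)
})
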