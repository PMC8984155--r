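.DEFAULT_STATES <- c("NBM", "MGUS", "SMM", "MM")
.DEFAULT_TYPES <- c("Monocyte", "CD8T", "EarlyB", "NK", "CD4T", "DC")

#' Default state names used by the synthetic generator
#' @param n number of states (first n of NBM, MGUS, SMM, MM, then S5, ...).
#' @return character vector of length \code{n}.
#' @export
synthStateNames <- function(n) {
  c(.DEFAULT_STATES, sprintf("S%d", seq_len(max(0, n - 4)) + 4))[seq_len(n)]
}

#' Default cell-type names used by the synthetic generator
#' @param n number of cell types.
#' @return character vector of length \code{n}.
#' @export
synthCellTypeNames <- function(n) {
  c(.DEFAULT_TYPES, sprintf("CT%d", seq_len(max(0, n - 6)) + 6))[seq_len(n)]
}

#' Configuration for the synthetic dataset generator
#'
#' Defines a small bone-marrow-like study: several pathological states
#' observed in several samples, each containing the same cell types, with
#' negative-binomial counts per gene, optional logistic dropout, planted
#' ligand-receptor co-expression events specific to a (source type, target
#' type, state) triple, and exponential survival times whose log-hazard is a
#' known linear function of selected genes' pseudo-bulk expression.
#'
#' @param n_states number of pathological states (named NBM, MGUS, SMM, MM
#'   by default; see \code{synthStateNames}).
#' @param n_cell_types number of cell types per state.
#' @param n_samples_per_state samples (patients) per state.
#' @param n_cells_per_type_per_sample cells per (sample, cell type).
#' @param n_genes total genes; pair i uses genes \code{G<2i-1>}/\code{G<2i>}.
#' @param n_lr_pairs number of ligand-receptor pairs (requires
#'   \code{2 * n_lr_pairs <= n_genes}).
#' @param planted_events data.frame with columns pair_id, source_type,
#'   target_type, state, effect_size (a fold multiplier > 0 applied to the
#'   ligand gene's mean in (source_type, state) cells and the receptor
#'   gene's mean in (target_type, state) cells). Empty for a null dataset.
#' @param baseline_mean negative-binomial mean shared by all non-planted
#'   gene/cell combinations.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2).
#' @param dropout_logit_slope logistic dropout slope; 0 disables dropout.
#'   When positive, each count is kept with probability
#'   \code{plogis(slope * log1p(mu))}, so lowly expressed genes drop out more.
#' @param risk_genes data.frame with columns gene, beta: the true linear
#'   survival model over per-sample pseudo-bulk expression.
#' @param censor_rate probability a sample's survival time is censored.
#' @param seed integer RNG seed; identical seeds give identical datasets.
#' @param state_names,cell_type_names optional label vectors overriding the
#'   defaults (lengths must match \code{n_states} / \code{n_cell_types}).
#' @return validated config (classed list).
#' @export
synthConfig <- function(n_states = 2, n_cell_types = 3,
                        n_samples_per_state = 2,
                        n_cells_per_type_per_sample = 100,
                        n_genes = 100, n_lr_pairs = 10,
                        planted_events = NULL,
                        baseline_mean = 2, dispersion = 0.5,
                        dropout_logit_slope = 0,
                        risk_genes = NULL, censor_rate = 0.2,
                        seed = 1L, state_names = NULL,
                        cell_type_names = NULL) {
  stopifnot(n_states >= 1, n_cell_types >= 1, n_samples_per_state >= 1,
            n_cells_per_type_per_sample >= 1, n_genes >= 2, n_lr_pairs >= 1)
  if (2L * n_lr_pairs > n_genes) {
    stop("config error: need n_genes >= 2 * n_lr_pairs")
  }
  .checkFraction(censor_rate, "censor_rate")
  if (baseline_mean <= 0 || dispersion < 0) {
    stop("config error: baseline_mean must be > 0 and dispersion >= 0")
  }
  if (is.null(planted_events)) {
    planted_events <- data.frame(pair_id = character(), source_type = character(),
                                 target_type = character(), state = character(),
                                 effect_size = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(planted_events) && any(planted_events$effect_size <= 0)) {
    stop("config error: effect_size must be > 0")
  }
  if (is.null(state_names)) state_names <- synthStateNames(n_states)
  if (is.null(cell_type_names)) cell_type_names <- synthCellTypeNames(n_cell_types)
  if (length(state_names) != n_states || anyDuplicated(state_names)) {
    stop("config error: state_names must be ", n_states, " distinct labels")
  }
  if (length(cell_type_names) != n_cell_types || anyDuplicated(cell_type_names)) {
    stop("config error: cell_type_names must be ", n_cell_types, " distinct labels")
  }
  cfg <- list(n_states = as.integer(n_states),
              n_cell_types = as.integer(n_cell_types),
              n_samples_per_state = as.integer(n_samples_per_state),
              n_cells_per_type_per_sample = as.integer(n_cells_per_type_per_sample),
              n_genes = as.integer(n_genes), n_lr_pairs = as.integer(n_lr_pairs),
              planted_events = planted_events, baseline_mean = baseline_mean,
              dispersion = dispersion, dropout_logit_slope = dropout_logit_slope,
              risk_genes = risk_genes, censor_rate = censor_rate,
              seed = as.integer(seed), state_names = state_names,
              cell_type_names = cell_type_names)
  class(cfg) <- "cce_synth_config"
  cfg
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Draws negative-binomial counts for every cell, applies the configured
#' planted ligand-receptor effects, builds the LR pair table (receptor flags
#' alternate between partner_b and partner_a so role assignment is
#' exercised), a random PPI edge table over the LR gene universe with scores
#' Uniform(0.4, 1), and exponential survival times with log-hazard equal to
#' the configured linear predictor over per-sample pseudo-bulk expression
#' (baseline hazard log(2)/24, i.e. a 24-month median at the centred
#' predictor). The truth element records the planted events and each
#' sample's true linear predictor.
#'
#' @param config from \code{synthConfig}.
#' @return list: sce (counts + colData), pairs, ppi, survival, coefficients,
#'   truth (list: events, linear_predictor).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "cce_synth_config"))
  set.seed(config$seed)
  states <- config$state_names
  types <- config$cell_type_names
  genes <- sprintf("G%04d", seq_len(config$n_genes))

  # LR pairs over the first 2 * n_lr_pairs genes; even pairs swap flag side
  pid <- sprintf("P%d", seq_len(config$n_lr_pairs))
  lig <- genes[2L * seq_len(config$n_lr_pairs) - 1L]
  rec <- genes[2L * seq_len(config$n_lr_pairs)]
  swap <- seq_len(config$n_lr_pairs) %% 2L == 0L
  pairs_raw <- data.frame(
    pair_id = pid,
    partner_a = ifelse(swap, rec, lig),
    partner_b = ifelse(swap, lig, rec),
    a_is_receptor = ifelse(swap, "True", "False"),
    b_is_receptor = ifelse(swap, "False", "True"),
    stringsAsFactors = FALSE)

  pe <- config$planted_events
  if (nrow(pe)) {
    bad <- !(pe$pair_id %in% pid) | !(pe$source_type %in% types) |
      !(pe$target_type %in% types) | !(pe$state %in% states)
    if (any(bad)) {
      stop("config error: planted event references unknown pair/type/state: ",
           paste(pe$pair_id[bad], collapse = ", "))
    }
  }

  anno <- expand.grid(cell = seq_len(config$n_cells_per_type_per_sample),
                      cell_type = types,
                      sample = seq_len(config$n_samples_per_state),
                      state = states, stringsAsFactors = FALSE)
  anno$sample_id <- sprintf("%s_s%d", anno$state, anno$sample)
  anno$cell_id <- sprintf("%s_%s_c%04d", anno$sample_id, anno$cell_type, anno$cell)
  n_cells <- nrow(anno)

  # per-(gene, cell) NB mean: baseline, times planted effects where they apply
  mu <- matrix(config$baseline_mean, nrow = config$n_genes, ncol = n_cells,
               dimnames = list(genes, anno$cell_id))
  if (nrow(pe)) {
    for (i in seq_len(nrow(pe))) {
      j <- match(pe$pair_id[i], pid)
      src_cells <- anno$cell_type == pe$source_type[i] & anno$state == pe$state[i]
      tgt_cells <- anno$cell_type == pe$target_type[i] & anno$state == pe$state[i]
      mu[lig[j], src_cells] <- mu[lig[j], src_cells] * pe$effect_size[i]
      mu[rec[j], tgt_cells] <- mu[rec[j], tgt_cells] * pe$effect_size[i]
    }
  }
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  counts <- matrix(
    if (is.finite(size)) rnbinom(length(mu), mu = as.vector(mu), size = size)
    else stats::rpois(length(mu), lambda = as.vector(mu)),
    nrow = config$n_genes, dimnames = dimnames(mu))
  if (config$dropout_logit_slope > 0) {
    keep_p <- stats::plogis(config$dropout_logit_slope * log1p(as.vector(mu)))
    counts <- counts * matrix(rbinom(length(mu), 1L, keep_p), nrow = config$n_genes)
  }

  sce <- SingleCellExperiment(assays = list(counts = as(counts, "CsparseMatrix")))
  colData(sce) <- DataFrame(cell_id = anno$cell_id, cell_type = anno$cell_type,
                            sample_id = anno$sample_id,
                            state = factor(anno$state, levels = states, ordered = TRUE),
                            row.names = anno$cell_id)
  sce <- logNormalize(sce)

  pairs <- loadLRPairs(pairs_raw)
  pairs <- markActivePairs(pairs, sce)

  # random PPI graph over the LR gene universe, scores exercising the 0.7 cut
  lr_genes <- unique(c(pairs$ligand, pairs$receptor))
  ppi <- NULL
  if (length(lr_genes) >= 2) {
    all_pairs <- t(combn(lr_genes, 2L))
    n_edges <- min(nrow(all_pairs), max(1L, round(nrow(all_pairs) * 0.3)))
    pick <- sort(sample(nrow(all_pairs), n_edges))
    ppi <- data.frame(gene_u = all_pairs[pick, 1L], gene_v = all_pairs[pick, 2L],
                      combined_score = round(runif(n_edges, 0.4, 1.0), 3),
                      stringsAsFactors = FALSE)
  }

  # survival: log-hazard linear in pseudo-bulk expression of the risk genes
  rg <- config$risk_genes
  if (is.null(rg)) rg <- data.frame(gene = character(), beta = numeric())
  if (nrow(rg) && any(!rg$gene %in% genes)) {
    stop("config error: risk gene not in gene universe")
  }
  pb <- pseudoBulk(sce)
  lp <- rep(0, nrow(pb))
  if (nrow(rg)) lp <- as.numeric(pb[, rg$gene, drop = FALSE] %*% rg$beta)
  names(lp) <- rownames(pb)
  lambda0 <- log(2) / 24
  rate <- lambda0 * exp(lp - mean(lp))
  time <- rexp(length(lp), rate = rate)
  censored <- runif(length(lp)) < config$censor_rate
  event <- as.integer(!censored)
  time[censored] <- time[censored] * runif(sum(censored))
  survival <- data.frame(sample_id = rownames(pb), time = time, event = event,
                         stringsAsFactors = FALSE)

  list(sce = sce, pairs = pairs, pairs_raw = pairs_raw, ppi = ppi,
       survival = survival, coefficients = rg,
       truth = list(events = pe,
                    linear_predictor = data.frame(sample_id = rownames(pb),
                                                  linear_predictor = lp,
                                                  stringsAsFactors = FALSE)))
}

#' Per-sample pseudo-bulk expression
#'
#' Mean normalized (log1p library-size-scaled) expression per gene within
#' each sample; the bridge from single-cell data to sample-level survival
#' modelling. Invariant to cell order.
#'
#' @param sce experiment with \code{sample_id} in \code{colData} and a
#'   normalized assay (computed from counts if absent).
#' @return samples x genes numeric matrix.
#' @export
pseudoBulk <- function(sce) {
  if (!"sample_id" %in% names(colData(sce))) {
    stop("pseudoBulk requires 'sample_id' in colData")
  }
  E <- .normalizedAssay(sce)
  samples <- sort(unique(colData(sce)$sample_id))
  Z <- sparseMatrix(i = seq_len(ncol(E)),
                    j = match(colData(sce)$sample_id, samples),
                    x = 1, dims = c(ncol(E), length(samples)))
  n <- Matrix::colSums(Z)
  if (any(n == 0)) stop("pseudoBulk: sample without cells")
  pb <- Matrix::t(E %*% Z %*% Diagonal(x = 1 / n))
  pb <- as.matrix(pb)
  dimnames(pb) <- list(samples, rownames(E))
  pb
}

#' Write a generated dataset in the formats the loaders read
#'
#' Writes matrix.mtx + barcodes.tsv + features.tsv, cell metadata, LR pairs
#' (with CellPhoneDB-style "True"/"False" receptor flags), PPI edges,
#' survival, coefficients, and the truth tables.
#'
#' @param dataset from \code{generateDataset}.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  writeMM(assay(dataset$sce, "counts"), p("matrix.mtx"))
  writeLines(colnames(dataset$sce), p("barcodes.tsv"))
  writeLines(rownames(dataset$sce), p("features.tsv"))
  cd <- as.data.frame(colData(dataset$sce))
  cd$state <- as.character(cd$state)
  writeResultTable(cd, p("cells.tsv"))
  writeResultTable(dataset$pairs_raw, p("lr_pairs.tsv"))
  if (!is.null(dataset$ppi)) writeResultTable(dataset$ppi, p("ppi_edges.tsv"))
  writeResultTable(dataset$survival, p("survival.tsv"),
                   units = c(time = "months"))
  writeResultTable(dataset$coefficients, p("coefficients.tsv"))
  writeResultTable(dataset$truth$events, p("truth_events.tsv"))
  writeResultTable(dataset$truth$linear_predictor, p("truth_linear_predictor.tsv"))
  invisible(c(matrix = p("matrix.mtx"), barcodes = p("barcodes.tsv"),
              features = p("features.tsv"), cells = p("cells.tsv"),
              lr_pairs = p("lr_pairs.tsv"),
              ppi = if (!is.null(dataset$ppi)) p("ppi_edges.tsv") else NA,
              survival = p("survival.tsv"), coefficients = p("coefficients.tsv")))
}
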