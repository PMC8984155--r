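# shared fixture builders: tiny in-memory experiments and CCE tables

# genes x cells values used directly as normalized expression
makeSCE <- function(values, cell_type, state, sample_id = NULL) {
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%d", seq_len(ncol(values)))
  if (is.null(sample_id)) sample_id <- rep("s1", ncol(values))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(logcounts = Matrix::Matrix(values, sparse = TRUE)))
  SummarizedExperiment::colData(sce) <- S4Vectors::DataFrame(
    cell_id = colnames(values), cell_type = cell_type,
    sample_id = sample_id, state = state, row.names = colnames(values))
  sce
}

makePairs <- function(ligands, receptors, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%d", seq_along(ligands))
  data.frame(pair_id = ids, ligand = ligands, receptor = receptors,
             ambiguous = FALSE, stringsAsFactors = FALSE)
}

# build a valid CCEResult from minimal per-event inputs
makeCCEResult <- function(state, source_type, target_type, pair_id,
                          ligand_mean, receptor_mean, p_value, alpha = 0.05,
                          ligand = NULL, receptor = NULL) {
  n <- length(state)
  if (is.null(ligand)) ligand <- paste0(pair_id, "_L")
  if (is.null(receptor)) receptor <- paste0(pair_id, "_R")
  tab <- data.frame(state = state, source_type = source_type,
                    target_type = target_type, pair_id = pair_id,
                    ligand = ligand, receptor = receptor,
                    ligand_mean = ligand_mean, receptor_mean = receptor_mean,
                    interaction_score = (ligand_mean + receptor_mean) / 2,
                    p_value = p_value, significant = p_value < alpha,
                    stringsAsFactors = FALSE)
  new("CCEResult", table = tab, params = list(alpha = alpha, n_perm = NA,
                                              min_expr_fraction = 0.1))
}

# independent brute-force permutation p-value for a two-gene pair, two types:
# enumerates type-1 position subsets with combn, recomputes gated means by hand
bruteForcePermP <- function(lig_vals, rec_vals, labels, source_type, target_type,
                            min_expr_fraction = 0.1) {
  gated_mean <- function(x) {
    if (mean(x > 0) <= min_expr_fraction) 0 else mean(x)
  }
  score <- function(lab) {
    (gated_mean(lig_vals[lab == source_type]) +
       gated_mean(rec_vals[lab == target_type])) / 2
  }
  obs <- score(labels)
  types <- sort(unique(labels))
  stopifnot(length(types) == 2L)
  n1 <- sum(labels == types[1])
  subsets <- utils::combn(length(labels), n1, simplify = FALSE)
  null_scores <- vapply(subsets, function(s) {
    lab <- rep(types[2], length(labels))
    lab[s] <- types[1]
    score(lab)
  }, numeric(1))
  # mathematically tied scores must count as >= despite float rounding
  list(obs = obs, p = mean(null_scores >= obs - 1e-9 * (1 + obs)),
       null = null_scores)
}
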