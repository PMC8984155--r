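# ---- cluster means with expression-fraction gating --------------------------

# E: genes x cells dense matrix; B: (E > 0) as 0/1; labels: cell labels;
# types: cluster labels in fixed order. Returns genes x types gated means.
.gatedClusterMeans <- function(E, B, labels, types, min_expr_fraction) {
  n <- length(labels)
  Z <- matrix(0, nrow = n, ncol = length(types))
  j <- match(labels, types)
  sz <- tabulate(j, nbins = length(types))
  Z[cbind(seq_len(n), j)] <- 1 / sz[j]
  M <- E %*% Z
  F <- B %*% Z
  M[F <= min_expr_fraction] <- 0
  M
}

#' Gated mean expression of a gene in one (cell type, state) cluster
#'
#' Mean normalized expression of \code{gene} over the cells of
#' \code{cell_type} within \code{state}. If the fraction of those cells with
#' nonzero expression is at or below \code{min_expr_fraction} the mean is
#' gated to 0, so rarely expressed genes cannot drive interaction scores
#' (set \code{min_expr_fraction = 0} to disable gating).
#'
#' @param sce annotated experiment (needs \code{cell_type} and \code{state}
#'   in \code{colData} and a normalized assay).
#' @param gene gene identifier.
#' @param cell_type,state cluster coordinates.
#' @param min_expr_fraction gating threshold on the expressing-cell fraction.
#' @return nonnegative scalar.
#' @export
clusterMean <- function(sce, gene, cell_type, state, min_expr_fraction = 0.10) {
  .checkFraction(min_expr_fraction, "min_expr_fraction")
  cd <- colData(sce)
  sel <- cd$cell_type == cell_type & as.character(cd$state) == state
  if (!any(sel)) {
    stop(sprintf("empty cluster: no cells for (%s, %s)", cell_type, state))
  }
  if (!gene %in% rownames(sce)) stop("gene not in expression matrix: ", gene)
  x <- as.numeric(.normalizedAssay(sce)[gene, sel])
  if (mean(x > 0) <= min_expr_fraction) return(0)
  mean(x)
}

# enumerate all distinct assignments of a label multiset (small n only)
.labelAssignments <- function(labels) {
  n <- length(labels)
  types <- sort(unique(labels))
  counts <- table(factor(labels, levels = types))
  out <- list(rep(NA_character_, n))
  avail <- list(seq_len(n))
  for (tp in types[-length(types)]) {
    k <- counts[[tp]]
    nxt <- list(); nxt_avail <- list()
    for (i in seq_along(out)) {
      pos <- avail[[i]]
      ch <- combn(pos, k, simplify = FALSE)
      for (s in ch) {
        a <- out[[i]]; a[s] <- tp
        nxt[[length(nxt) + 1L]] <- a
        nxt_avail[[length(nxt_avail) + 1L]] <- setdiff(pos, s)
      }
    }
    out <- nxt; avail <- nxt_avail
  }
  last <- types[length(types)]
  for (i in seq_along(out)) out[[i]][avail[[i]]] <- last
  do.call(rbind, out)
}

#' Permutation test for a single candidate interaction event
#'
#' The observed interaction score is the mean of the ligand's gated cluster
#' mean in the source cell type and the receptor's gated cluster mean in the
#' target cell type, within one state. The null is built by shuffling the
#' cell-type labels among all of that state's cells (expression and state
#' fixed) and recomputing the score with identical gating. The Monte Carlo
#' p-value uses the add-one estimator \code{(1 + #(null >= obs)) / (1 +
#' n_perm)}; exhaustive mode enumerates every distinct label assignment and
#' reports the exact proportion with score >= observed. A zero observed
#' score yields p = 1 by definition.
#'
#' @param sce annotated experiment.
#' @param pair one-row data.frame with \code{pair_id}, \code{ligand},
#'   \code{receptor} (as from \code{loadLRPairs}).
#' @param source_type,target_type ordered cell-type pair (ligand side ->
#'   receptor side).
#' @param state state whose cells are tested.
#' @param n_perm number of label permutations (Monte Carlo mode).
#' @param min_expr_fraction gating threshold.
#' @param mode \code{"mc"} or \code{"exhaustive"} (enumeration; small cell
#'   numbers only).
#' @param seed optional RNG seed.
#' @param alpha significance level applied to the resulting p-value.
#' @return one-row data.frame in \code{CCEResult} table layout.
#' @export
permutationTest <- function(sce, pair, source_type, target_type, state,
                            n_perm = 1000, min_expr_fraction = 0.10,
                            mode = c("mc", "exhaustive"), seed = NULL,
                            alpha = 0.05) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_perm >= 1)
  cd <- colData(sce)
  in_state <- as.character(cd$state) == state
  labels <- as.character(cd$cell_type[in_state])
  if (!any(labels == source_type) || !any(labels == target_type)) {
    stop("empty cluster: source or target type absent from state ", state)
  }
  genes <- c(pair$ligand, pair$receptor)
  if (!all(genes %in% rownames(sce))) {
    stop("pair inactive: gene(s) missing from matrix: ",
         paste(setdiff(genes, rownames(sce)), collapse = ", "))
  }
  E <- as.matrix(.normalizedAssay(sce)[genes, in_state, drop = FALSE])
  B <- (E > 0) + 0
  types <- sort(unique(labels))
  score_of <- function(lab) {
    M <- .gatedClusterMeans(E, B, lab, types, min_expr_fraction)
    c(lig = unname(M[1L, match(source_type, types)]),
      rec = unname(M[2L, match(target_type, types)]))
  }
  obs_parts <- score_of(labels)
  obs <- mean(obs_parts)
  # scores equal up to float rounding are ties and must count as >= observed
  eps <- 1e-9 * (1 + obs)
  if (mode == "exhaustive") {
    assignments <- .labelAssignments(labels)
    null_scores <- apply(assignments, 1L, function(lab) mean(score_of(lab)))
    p <- mean(null_scores >= obs - eps)
  } else {
    ge <- 0L
    for (k in seq_len(n_perm)) {
      if (mean(score_of(sample(labels))) >= obs - eps) ge <- ge + 1L
    }
    p <- (1 + ge) / (1 + n_perm)
  }
  if (obs == 0) p <- 1
  data.frame(state = state, source_type = source_type, target_type = target_type,
             pair_id = pair$pair_id, ligand = pair$ligand, receptor = pair$receptor,
             ligand_mean = unname(obs_parts["lig"]),
             receptor_mean = unname(obs_parts["rec"]),
             interaction_score = obs, p_value = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Detect all candidate interaction events across states
#'
#' Enumerates every (state, ordered source type -> target type including
#' self-pairs, active ligand-receptor pair) combination and assigns each a
#' permutation p-value under the within-state label-shuffling null. All
#' pairs in a state share one set of label permutations, which makes the
#' scan a handful of matrix products per permutation; p-values of distinct
#' pairs remain essentially independent because they use disjoint genes.
#' No multiple-testing correction is applied: an event is significant when
#' its raw p-value is below \code{alpha}.
#'
#' @param sce annotated experiment (\code{cell_type}, \code{state},
#'   normalized assay).
#' @param pairs data.frame from \code{loadLRPairs}.
#' @param n_perm permutations per state (add-one p-value estimator, so
#'   p >= 1/(1 + n_perm)).
#' @param alpha significance level on the raw permutation p-value.
#' @param min_expr_fraction gating threshold (see \code{clusterMean}).
#' @param seed optional RNG seed; identical seeds give identical p-values.
#' @return \linkS4class{CCEResult}.
#' @export
detectAll <- function(sce, pairs, n_perm = 1000, alpha = 0.05,
                      min_expr_fraction = 0.10, seed = NULL) {
  .checkFraction(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  .checkFraction(min_expr_fraction, "min_expr_fraction")
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!"active" %in% names(pairs)) pairs <- markActivePairs(pairs, sce)
  skipped <- pairs$pair_id[!pairs$active]
  act <- pairs[pairs$active, , drop = FALSE]
  if (!nrow(act)) stop("no active ligand-receptor pairs")
  cd <- colData(sce)
  states <- if (is.factor(cd$state)) levels(droplevels(cd$state)) else unique(as.character(cd$state))
  genes <- unique(c(act$ligand, act$receptor))
  A <- .normalizedAssay(sce)
  li <- match(act$ligand, genes)
  ri <- match(act$receptor, genes)
  res <- vector("list", length(states))
  for (si in seq_along(states)) {
    st <- states[si]
    in_state <- as.character(cd$state) == st
    labels <- as.character(cd$cell_type[in_state])
    types <- sort(unique(labels))
    t_n <- length(types)
    E <- as.matrix(A[genes, in_state, drop = FALSE])
    B <- (E > 0) + 0
    src_idx <- rep(seq_len(t_n), times = t_n)
    tgt_idx <- rep(seq_len(t_n), each = t_n)
    M <- .gatedClusterMeans(E, B, labels, types, min_expr_fraction)
    L <- M[li, , drop = FALSE]
    R <- M[ri, , drop = FALSE]
    obs <- (L[, src_idx, drop = FALSE] + R[, tgt_idx, drop = FALSE]) / 2
    thr <- obs - 1e-9 * (1 + obs)  # tie tolerance: equal scores count as >=
    ge <- matrix(0L, nrow(obs), ncol(obs))
    for (k in seq_len(n_perm)) {
      Mk <- .gatedClusterMeans(E, B, sample(labels), types, min_expr_fraction)
      sk <- (Mk[li, src_idx, drop = FALSE] + Mk[ri, tgt_idx, drop = FALSE]) / 2
      ge <- ge + (sk >= thr)
    }
    p <- (1 + ge) / (1 + n_perm)
    p[obs == 0] <- 1
    n_pairs <- nrow(act)
    res[[si]] <- data.frame(
      state = st,
      source_type = rep(types[src_idx], each = n_pairs),
      target_type = rep(types[tgt_idx], each = n_pairs),
      pair_id = rep(act$pair_id, t_n * t_n),
      ligand = rep(act$ligand, t_n * t_n),
      receptor = rep(act$receptor, t_n * t_n),
      ligand_mean = as.vector(L[, src_idx, drop = FALSE]),
      receptor_mean = as.vector(R[, tgt_idx, drop = FALSE]),
      interaction_score = as.vector(obs),
      p_value = as.vector(p),
      significant = as.vector(p) < alpha,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, res)
  rownames(tab) <- NULL
  new("CCEResult", table = tab,
      params = list(alpha = alpha, n_perm = n_perm,
                    min_expr_fraction = min_expr_fraction,
                    seed = seed, skipped_pairs = skipped))
}
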