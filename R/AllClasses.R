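#' @import methods
NULL

.CCE_REQUIRED_COLS <- c("state", "source_type", "target_type", "pair_id",
                        "ligand", "receptor", "ligand_mean", "receptor_mean",
                        "interaction_score", "p_value", "significant")

#' CCEResult: permutation-test results for all candidate interaction events
#'
#' One row per (state, source cell type, target cell type, ligand-receptor
#' pair): the gated cluster means on each side, the interaction score (mean
#' of the two cluster means), the permutation p-value and the significance
#' call at the stored alpha.
#'
#' @slot table data.frame of interaction-event records.
#' @slot params list of detection parameters (alpha, n_perm,
#'   min_expr_fraction, seed, skipped pairs).
#' @export
setClass("CCEResult",
         slots = c(table = "data.frame", params = "list"))

setValidity("CCEResult", function(object) {
  tab <- object@table
  msgs <- character()
  missing_cols <- setdiff(.CCE_REQUIRED_COLS, names(tab))
  if (length(missing_cols)) {
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(tab)) {
    if (any(tab$p_value <= 0 | tab$p_value > 1)) {
      msgs <- c(msgs, "p_value must lie in (0, 1]")
    }
    alpha <- object@params$alpha
    if (!is.null(alpha) && !identical(tab$significant, tab$p_value < alpha)) {
      msgs <- c(msgs, "significant flag inconsistent with p_value < alpha")
    }
    score <- (tab$ligand_mean + tab$receptor_mean) / 2
    if (any(abs(score - tab$interaction_score) > 1e-9)) {
      msgs <- c(msgs, "interaction_score must equal mean(ligand_mean, receptor_mean)")
    }
    if (any(tab$ligand_mean < 0 | tab$receptor_mean < 0)) {
      msgs <- c(msgs, "cluster means must be nonnegative")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' RiskModel: gene coefficients of a linear survival risk score
#'
#' Holds the signature genes and their regression coefficients beta_i for the
#' linear risk score sum_i beta_i * expression_i.
#'
#' @slot coefficients named numeric vector of coefficients (names = genes).
#' @slot geneOrder character vector giving the gene order.
#' @export
setClass("RiskModel",
         slots = c(coefficients = "numeric", geneOrder = "character"))

setValidity("RiskModel", function(object) {
  genes <- names(object@coefficients)
  if (is.null(genes) || any(genes == "")) return("coefficients must be named by gene")
  if (anyDuplicated(genes)) return("coefficient genes must be distinct")
  if (!setequal(genes, object@geneOrder) ||
      length(genes) != length(object@geneOrder)) {
    return("geneOrder must be a permutation of the coefficient names")
  }
  if (any(!is.finite(object@coefficients))) return("coefficients must be finite")
  TRUE
})

#' StateNetwork: a pathological-state-specific ligand-receptor network
#'
#' Nodes are ligand/receptor genes of the state's significant interaction
#' events plus their direct PPI neighbours within the ligand-receptor gene
#' universe; edges are PPI edges passing the combined-score filter plus
#' provenance-tagged ligand-receptor pair edges.
#'
#' @slot state state label.
#' @slot nodes data.frame: gene, roles, state_specific, degree, is_hub.
#' @slot edges data.frame: gene_u, gene_v, combined_score, provenance.
#' @slot graph igraph object over the same nodes/edges.
#' @export
setClass("StateNetwork",
         slots = c(state = "character", nodes = "data.frame",
                   edges = "data.frame", graph = "ANY"))

setValidity("StateNetwork", function(object) {
  msgs <- character()
  nd <- object@nodes
  ed <- object@edges
  if (!all(c("gene", "degree") %in% names(nd))) {
    return("nodes must have 'gene' and 'degree' columns")
  }
  if (nrow(ed)) {
    if (!all(c(ed$gene_u, ed$gene_v) %in% nd$gene)) {
      msgs <- c(msgs, "every edge endpoint must be a node")
    }
    deg <- table(factor(c(ed$gene_u, ed$gene_v), levels = nd$gene))
    if (!all(as.integer(deg) == nd$degree)) {
      msgs <- c(msgs, "degree table inconsistent with edge list")
    }
  } else if (nrow(nd) && any(nd$degree != 0L)) {
    msgs <- c(msgs, "nonzero degree with no edges")
  }
  if (length(msgs)) msgs else TRUE
})
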