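#' @importFrom igraph graph_from_data_frame write_graph
NULL

#' Collect ligand/receptor genes of significant events, with state presence
#'
#' One record per (gene, role): the states in whose significant events the
#' gene appears in that role. A gene whose overall state presence (union
#' over roles) is a single state is state-specific to it.
#'
#' @param cces_by_state named list (state -> significant-event data.frame)
#'   or a \linkS4class{CCEResult}.
#' @param pairs LR pair table (unused columns tolerated; kept in the
#'   signature so callers can pass the pipeline's pair table for role
#'   provenance).
#' @return data.frame: gene, role, states_present (comma-joined),
#'   state_specific_to (NA when present in several states).
#' @export
collectLRGenes <- function(cces_by_state, pairs = NULL) {
  if (is(cces_by_state, "CCEResult")) {
    sig <- significantCCEs(cces_by_state)
    cces_by_state <- split(sig, sig$state)
  }
  recs <- list()
  for (st in names(cces_by_state)) {
    d <- cces_by_state[[st]]
    if (!nrow(d)) next
    recs[[length(recs) + 1L]] <- data.frame(
      gene = c(d$ligand, d$receptor),
      role = rep(c("ligand", "receptor"), each = nrow(d)),
      state = st, stringsAsFactors = FALSE)
  }
  if (!length(recs)) {
    return(data.frame(gene = character(), role = character(),
                      states_present = character(),
                      state_specific_to = character(),
                      stringsAsFactors = FALSE))
  }
  long <- unique(do.call(rbind, recs))
  gene_states <- lapply(split(long$state, long$gene), unique)
  by_rec <- split(long$state, paste(long$gene, long$role, sep = "\r"))
  keys <- names(by_rec)
  gene <- sub("\r.*$", "", keys)
  role <- sub("^.*\r", "", keys)
  states_present <- vapply(by_rec, function(s) paste(sort(unique(s)), collapse = ","), "")
  spec <- vapply(gene, function(g) {
    s <- gene_states[[g]]
    if (length(s) == 1L) s else NA_character_
  }, "")
  out <- data.frame(gene = gene, role = role, states_present = states_present,
                    state_specific_to = unname(spec), stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$role), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the interaction network of one pathological state
#'
#' Nodes are the state's ligand/receptor genes plus their direct PPI
#' neighbours within the full ligand-receptor gene universe; edges are PPI
#' edges with \code{combined_score >= score_min} between nodes, plus
#' (optionally) the state's intra-state ligand-receptor pair edges, each
#' tagged with its provenance. Hubs are the maximum-degree node(s).
#'
#' @param role_genes output of \code{collectLRGenes}.
#' @param ppi_edges PPI edge table (gene_u, gene_v, combined_score).
#' @param pairs LR pair table (pair_id, ligand, receptor).
#' @param state the state to extract.
#' @param score_min PPI combined-score filter (default 0.7; edges at exactly
#'   the threshold are kept).
#' @param include_lr_edges add ligand-receptor pair edges alongside PPI
#'   edges.
#' @param state_pair_ids optional pair ids significant in this state; when
#'   given, only those LR edges are added, otherwise any pair whose two
#'   genes are both state genes.
#' @return \linkS4class{StateNetwork}.
#' @export
buildStateNetwork <- function(role_genes, ppi_edges, pairs, state,
                              score_min = 0.7, include_lr_edges = TRUE,
                              state_pair_ids = NULL) {
  .checkFraction(score_min, "score_min")
  in_state <- vapply(strsplit(role_genes$states_present, ","),
                     function(s) state %in% s, TRUE)
  state_genes <- unique(role_genes$gene[in_state])
  universe <- unique(role_genes$gene)
  ppi <- ppi_edges[ppi_edges$combined_score >= score_min &
                     ppi_edges$gene_u %in% universe &
                     ppi_edges$gene_v %in% universe, , drop = FALSE]
  touches <- ppi$gene_u %in% state_genes | ppi$gene_v %in% state_genes
  neighbours <- setdiff(unique(c(ppi$gene_u[touches], ppi$gene_v[touches])),
                        state_genes)
  nodes <- sort(unique(c(state_genes, neighbours)))
  keep <- ppi$gene_u %in% nodes & ppi$gene_v %in% nodes
  edges <- ppi[keep, c("gene_u", "gene_v", "combined_score"), drop = FALSE]
  if (nrow(edges)) edges$provenance <- "ppi"
  else edges <- data.frame(gene_u = character(), gene_v = character(),
                           combined_score = numeric(), provenance = character(),
                           stringsAsFactors = FALSE)
  if (include_lr_edges) {
    lp <- pairs
    if (!is.null(state_pair_ids)) lp <- lp[lp$pair_id %in% state_pair_ids, , drop = FALSE]
    lp <- lp[lp$ligand %in% state_genes & lp$receptor %in% state_genes, , drop = FALSE]
    if (nrow(lp)) {
      lr_edges <- data.frame(gene_u = lp$ligand, gene_v = lp$receptor,
                             combined_score = NA_real_, provenance = "lr_pair",
                             stringsAsFactors = FALSE)
      # avoid duplicating an undirected edge already present from the PPI
      key <- function(d) paste(pmin(d$gene_u, d$gene_v), pmax(d$gene_u, d$gene_v))
      lr_edges <- lr_edges[!key(lr_edges) %in% key(edges), , drop = FALSE]
      lr_edges <- lr_edges[!duplicated(key(lr_edges)), , drop = FALSE]
      edges <- rbind(edges, lr_edges)
    }
  }
  deg <- table(factor(c(edges$gene_u, edges$gene_v), levels = nodes))
  roles <- vapply(nodes, function(g) {
    paste(sort(unique(role_genes$role[role_genes$gene == g])), collapse = ",")
  }, FUN.VALUE = "")
  spec <- role_genes$state_specific_to[match(nodes, role_genes$gene)]
  node_df <- data.frame(gene = nodes, roles = unname(roles),
                        state_specific = !is.na(spec) & spec == state,
                        degree = as.integer(deg), stringsAsFactors = FALSE)
  node_df$is_hub <- nrow(node_df) > 0 & node_df$degree == max(node_df$degree, 0L)
  g <- graph_from_data_frame(edges[, c("gene_u", "gene_v")], directed = FALSE,
                             vertices = node_df)
  rownames(node_df) <- NULL
  rownames(edges) <- NULL
  new("StateNetwork", state = state, nodes = node_df, edges = edges, graph = g)
}

#' Write a state network as GraphML plus node/edge TSVs
#'
#' @param net \linkS4class{StateNetwork}.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
writeStateNetwork <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, paste0("network_", net@state))
  write_graph(net@graph, paste0(base, ".graphml"), format = "graphml")
  writeResultTable(net@nodes, paste0(base, "_nodes.tsv"))
  writeResultTable(net@edges, paste0(base, "_edges.tsv"))
  invisible(c(paste0(base, ".graphml"), paste0(base, "_nodes.tsv"),
              paste0(base, "_edges.tsv")))
}
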