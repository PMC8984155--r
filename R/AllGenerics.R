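#' Accessors for CCEResult, StateNetwork and RiskModel
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors full candidate-event table of a \code{CCEResult}.
#' @export
setGeneric("cceTable", function(object) standardGeneric("cceTable"))

#' @describeIn accessors rows of the table with \code{significant == TRUE}.
#' @export
setGeneric("significantCCEs", function(object) standardGeneric("significantCCEs"))

#' @describeIn accessors detection parameter list of a \code{CCEResult}.
#' @export
setGeneric("detectionParams", function(object) standardGeneric("detectionParams"))

#' @describeIn accessors named coefficient vector of a \code{RiskModel}.
#' @export
setGeneric("riskCoefficients", function(object) standardGeneric("riskCoefficients"))

#' @describeIn accessors node table of a \code{StateNetwork}.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @describeIn accessors edge table of a \code{StateNetwork}.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @describeIn accessors igraph graph of a \code{StateNetwork}.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' @describeIn accessors maximum-degree gene(s) of a \code{StateNetwork}.
#' @export
setGeneric("hubGenes", function(object) standardGeneric("hubGenes"))

#' @rdname accessors
#' @export
setMethod("cceTable", "CCEResult", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("significantCCEs", "CCEResult",
          function(object) object@table[object@table$significant, , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("detectionParams", "CCEResult", function(object) object@params)

#' @rdname accessors
#' @export
setMethod("riskCoefficients", "RiskModel",
          function(object) object@coefficients[object@geneOrder])

#' @rdname accessors
#' @export
setMethod("networkNodes", "StateNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "StateNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("networkGraph", "StateNetwork", function(object) object@graph)

#' @rdname accessors
#' @export
setMethod("hubGenes", "StateNetwork", function(object) {
  nd <- object@nodes
  if (!nrow(nd)) return(character())
  nd$gene[nd$degree == max(nd$degree)]
})

setMethod("show", "CCEResult", function(object) {
  tab <- object@table
  cat("CCEResult with", nrow(tab), "candidate interaction events\n")
  if (nrow(tab)) {
    cat("  states:", paste(unique(tab$state), collapse = ", "), "\n")
    cat("  cell types:",
        paste(sort(unique(c(tab$source_type, tab$target_type))), collapse = ", "), "\n")
    cat("  significant (p <", object@params$alpha, "):", sum(tab$significant), "\n")
  }
  cat("  n_perm:", object@params$n_perm,
      " min_expr_fraction:", object@params$min_expr_fraction, "\n")
  invisible(object)
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel with", length(object@coefficients), "genes\n")
  print(riskCoefficients(object))
  invisible(object)
})

setMethod("show", "StateNetwork", function(object) {
  cat("StateNetwork for state", object@state, ":",
      nrow(object@nodes), "nodes,", nrow(object@edges), "edges\n")
  hubs <- hubGenes(object)
  if (length(hubs)) cat("  hub gene(s):", paste(hubs, collapse = ", "), "\n")
  invisible(object)
})
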