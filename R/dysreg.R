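#' Interaction-event expression: mean of receptor and ligand cluster means
#'
#' The expression level of an interaction event is the arithmetic mean of
#' the receptor's cluster mean (target side) and the ligand's cluster mean
#' (source side).
#'
#' @param receptor_mean,ligand_mean nonnegative cluster means (vectorized).
#' @return numeric vector of event expression values.
#' @export
cceExpression <- function(receptor_mean, ligand_mean) {
  if (any(receptor_mean < 0, na.rm = TRUE) || any(ligand_mean < 0, na.rm = TRUE)) {
    stop("validation error: cluster means must be nonnegative")
  }
  (receptor_mean + ligand_mean) / 2
}

#' Interaction fold change and dysregulation direction between two states
#'
#' Fold change between the event expression in State1 (\code{exp1}) and
#' State2 (\code{exp2}) is \code{(exp1 - exp2) / min(exp1, exp2)}. The event
#' is called up-regulated in State1 when the fold change exceeds
#' \code{threshold} or the State2 expression is zero (with nonzero State1
#' expression), down-regulated in State1 when the fold change is below
#' \code{-threshold} or the State1 expression is zero (with nonzero State2
#' expression), and unchanged otherwise. When both expressions are zero no
#' interaction exists in either state and the event is unchanged with fold
#' change 0; when exactly one is zero the fold change is the signed infinity
#' sentinel.
#'
#' @param exp1,exp2 nonnegative event expression in State1 / State2
#'   (vectorized).
#' @param threshold dysregulation threshold on |fold change| (default 0.25).
#' @return data.frame: fold_change, direction (\code{"up_in_state1"},
#'   \code{"down_in_state1"}, \code{"unchanged"}).
#' @export
foldChangeCCE <- function(exp1, exp2, threshold = 0.25) {
  if (any(exp1 < 0) || any(exp2 < 0)) {
    stop("validation error: event expression must be nonnegative")
  }
  if (threshold <= 0) stop("threshold must be > 0")
  mn <- pmin(exp1, exp2)
  fc <- ifelse(mn > 0, (exp1 - exp2) / mn,
               ifelse(exp1 > 0, Inf, ifelse(exp2 > 0, -Inf, 0)))
  up <- (exp1 > 0 & exp2 == 0) | fc > threshold
  down <- (exp2 > 0 & exp1 == 0) | fc < -threshold
  direction <- ifelse(up, "up_in_state1", ifelse(down, "down_in_state1", "unchanged"))
  data.frame(fold_change = fc, direction = direction, stringsAsFactors = FALSE)
}

#' Dysregulated interaction events between two pathological states
#'
#' Aligns the candidate events of the two states by (source type, target
#' type, pair), computes each side's event expression and the fold-change
#' classification relative to \code{state1}. The \code{scope} policy decides
#' which events enter and what a non-significant side contributes:
#' \describe{
#'   \item{significant_either}{events significant in at least one state; a
#'     side where the event is not significant counts as expression 0 (the
#'     event is absent from that state's significant table).}
#'   \item{significant_both}{only events significant in both states, using
#'     their observed expressions.}
#'   \item{all}{every candidate event with its observed expressions.}
#' }
#'
#' @param result \linkS4class{CCEResult} covering both states.
#' @param state1,state2 state labels; direction is relative to state1.
#' @param scope event selection policy (see Details).
#' @param threshold fold-change threshold.
#' @return data.frame with exp_state1, exp_state2, fold_change, direction and
#'   a logical \code{dysregulated} column; attributes state1/state2 record
#'   the comparison.
#' @export
dysregulatedCCEs <- function(result, state1, state2,
                             scope = c("significant_either", "significant_both", "all"),
                             threshold = 0.25) {
  scope <- match.arg(scope)
  tab <- if (is(result, "CCEResult")) cceTable(result) else result
  t1 <- tab[tab$state == state1, , drop = FALSE]
  t2 <- tab[tab$state == state2, , drop = FALSE]
  if (!nrow(t1) || !nrow(t2)) {
    stop("validation error: no events for one of the states")
  }
  key <- function(d) paste(d$source_type, d$target_type, d$pair_id, sep = "\r")
  k1 <- key(t1); k2 <- key(t2)
  if (!setequal(k1, k2)) {
    stop("validation error: the two states cover different event universes")
  }
  t2 <- t2[match(k1, k2), , drop = FALSE]
  e1 <- cceExpression(t1$receptor_mean, t1$ligand_mean)
  e2 <- cceExpression(t2$receptor_mean, t2$ligand_mean)
  keep <- rep(TRUE, nrow(t1))
  if (scope == "significant_either") {
    keep <- t1$significant | t2$significant
    e1[!t1$significant] <- 0
    e2[!t2$significant] <- 0
  } else if (scope == "significant_both") {
    keep <- t1$significant & t2$significant
  }
  fc <- foldChangeCCE(e1[keep], e2[keep], threshold = threshold)
  out <- data.frame(source_type = t1$source_type[keep],
                    target_type = t1$target_type[keep],
                    pair_id = t1$pair_id[keep],
                    ligand = t1$ligand[keep], receptor = t1$receptor[keep],
                    state1 = state1, state2 = state2,
                    exp_state1 = e1[keep], exp_state2 = e2[keep],
                    fold_change = fc$fold_change, direction = fc$direction,
                    dysregulated = fc$direction != "unchanged",
                    stringsAsFactors = FALSE)
  attr(out, "state1") <- state1
  attr(out, "state2") <- state2
  attr(out, "scope") <- scope
  attr(out, "threshold") <- threshold
  out
}
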