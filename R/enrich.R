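#' Focus selectors for contingency counting
#'
#' \code{cellTypeFocus(x)} matches events where cell type \code{x} is the
#' source or the target (an event is counted once even when \code{x} is
#' both, i.e. a self-interaction). \code{directedPairFocus(s, t)} matches
#' exactly the ordered pair source \code{s} -> target \code{t}.
#'
#' @param x,source,target cell-type labels.
#' @return focus object for \code{buildContingency}.
#' @export
cellTypeFocus <- function(x) {
  structure(list(kind = "cell_type", type = x,
                 label = x), class = "cce_focus")
}

#' @rdname cellTypeFocus
#' @export
directedPairFocus <- function(source, target) {
  structure(list(kind = "directed_pair", source = source, target = target,
                 label = paste0(source, "->", target)), class = "cce_focus")
}

.matchFocus <- function(df, focus) {
  stopifnot(inherits(focus, "cce_focus"))
  if (focus$kind == "cell_type") {
    df$source_type == focus$type | df$target_type == focus$type
  } else {
    df$source_type == focus$source & df$target_type == focus$target
  }
}

#' Build a 2x2 contingency table of interaction-event counts
#'
#' Rows are the two states, columns are (events matching the focus, all
#' other events), so each row sums to that state's total significant-event
#' count.
#'
#' @param cces_a,cces_b significant-event tables (data.frames) of the two
#'   states.
#' @param focus from \code{cellTypeFocus} or \code{directedPairFocus}.
#' @return 2x2 integer matrix \code{[[n_focus_a, n_other_a], [n_focus_b,
#'   n_other_b]]}.
#' @export
buildContingency <- function(cces_a, cces_b, focus) {
  if (!nrow(cces_a) || !nrow(cces_b)) {
    stop("empty significant-event table for a state (no denominator)")
  }
  fa <- sum(.matchFocus(cces_a, focus))
  fb <- sum(.matchFocus(cces_b, focus))
  matrix(c(fa, nrow(cces_a) - fa, fb, nrow(cces_b) - fb),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("state_a", "state_b"), c("focus", "other")))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities (margins
#' fixed) of every table at most as probable as the observed one. The odds
#' ratio is the sample odds ratio \code{(n11 * n22) / (n12 * n21)}; the
#' reported \code{log2_odds_ratio} adds the Haldane-Anscombe 0.5 continuity
#' correction to all cells when any cell is zero, so heatmap values stay
#' finite. A zero margin makes the odds ratio undefined (\code{NaN}) with
#' p = 1.
#'
#' @param table 2x2 nonnegative integer matrix.
#' @return list: odds_ratio, log2_odds_ratio, p_value.
#' @export
fisherExactTest <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)))
  if (any(table < 0) || any(table != round(table))) {
    stop("validation error: table must hold nonnegative integers")
  }
  n11 <- table[1, 1]; n12 <- table[1, 2]; n21 <- table[2, 1]; n22 <- table[2, 2]
  r1 <- n11 + n12; r2 <- n21 + n22; c1 <- n11 + n21; c2 <- n12 + n22
  any_zero <- any(table == 0)
  l2or <- if (any_zero) {
    log2(((n11 + 0.5) * (n22 + 0.5)) / ((n12 + 0.5) * (n21 + 0.5)))
  } else {
    log2((n11 * n22) / (n12 * n21))
  }
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    return(list(odds_ratio = NaN, log2_odds_ratio = l2or, p_value = 1))
  }
  odds_ratio <- if (n12 * n21 == 0) {
    if (n11 * n22 == 0) NaN else Inf
  } else (n11 * n22) / (n12 * n21)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(n11, r1, r2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  list(odds_ratio = odds_ratio, log2_odds_ratio = l2or, p_value = p)
}

#' Enrichment of interaction-event counts across states
#'
#' For every focus and every unordered pair of states, builds the 2x2
#' event-count table and runs the two-sided Fisher test, reporting the log2
#' odds ratio and significance flags at the 0.05 and 0.1 levels.
#'
#' @param cces_by_state named list (state -> significant-event data.frame),
#'   or a \linkS4class{CCEResult} (its significant events are split by
#'   state).
#' @param focus_list list of focus objects; defaults to one
#'   \code{cellTypeFocus} per observed cell type.
#' @return data.frame: focus, state_a, state_b, the four counts, odds_ratio,
#'   log2_odds_ratio, p_value, sig_05, sig_10.
#' @export
enrichmentMatrix <- function(cces_by_state, focus_list = NULL) {
  if (is(cces_by_state, "CCEResult")) {
    sig <- significantCCEs(cces_by_state)
    cces_by_state <- split(sig, sig$state)
  }
  states <- names(cces_by_state)
  if (length(states) < 2) stop("need at least two states")
  if (is.null(focus_list)) {
    types <- sort(unique(unlist(lapply(cces_by_state, function(d)
      c(d$source_type, d$target_type)))))
    focus_list <- lapply(types, cellTypeFocus)
  }
  combos <- combn(states, 2L, simplify = FALSE)
  rows <- list()
  for (f in focus_list) {
    for (cb in combos) {
      tab <- buildContingency(cces_by_state[[cb[1]]], cces_by_state[[cb[2]]], f)
      ft <- fisherExactTest(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        focus = f$label, state_a = cb[1], state_b = cb[2],
        n_focus_a = tab[1, 1], n_other_a = tab[1, 2],
        n_focus_b = tab[2, 1], n_other_b = tab[2, 2],
        odds_ratio = ft$odds_ratio, log2_odds_ratio = ft$log2_odds_ratio,
        p_value = ft$p_value,
        sig_05 = ft$p_value < 0.05, sig_10 = ft$p_value < 0.1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
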