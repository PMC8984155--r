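#' Linear risk score per sample
#'
#' The risk score of a sample is the linear combination
#' \code{sum_i beta_i * expression_i} over the model's signature genes.
#'
#' @param expr_by_sample samples x genes numeric matrix (e.g. from
#'   \code{pseudoBulk}) with sample identifiers as rownames, or a data.frame
#'   whose first column is \code{sample_id}.
#' @param model \linkS4class{RiskModel}.
#' @return data.frame: sample_id, risk_score.
#' @export
riskScore <- function(expr_by_sample, model) {
  stopifnot(is(model, "RiskModel"))
  if (is.data.frame(expr_by_sample)) {
    m <- as.matrix(expr_by_sample[, -1L, drop = FALSE])
    rownames(m) <- expr_by_sample[[1L]]
    expr_by_sample <- m
  }
  beta <- riskCoefficients(model)
  missing_genes <- setdiff(names(beta), colnames(expr_by_sample))
  if (length(missing_genes)) {
    stop("model genes missing from expression table: ",
         paste(missing_genes, collapse = ", "))
  }
  score <- as.numeric(expr_by_sample[, names(beta), drop = FALSE] %*% beta)
  data.frame(sample_id = rownames(expr_by_sample), risk_score = score,
             stringsAsFactors = FALSE)
}

#' Stratify samples into low / moderate / high risk groups
#'
#' Cutoffs are the score quantiles (tertiles by default): low strictly below
#' the first cutoff, moderate in [q1, q2), high at or above the second. The
#' threshold rule is deterministic under ties (stable in sample order). If
#' every score is identical all samples are assigned moderate, with a
#' warning.
#'
#' @param scores data.frame from \code{riskScore} (or a numeric vector with
#'   names).
#' @param quantiles two probabilities defining the cutoffs.
#' @return data.frame: sample_id, risk_score, group (ordered factor
#'   low < moderate < high).
#' @export
assignRiskGroups <- function(scores, quantiles = c(1/3, 2/3)) {
  stopifnot(length(quantiles) == 2, quantiles[1] < quantiles[2])
  if (is.numeric(scores)) {
    scores <- data.frame(sample_id = names(scores), risk_score = unname(scores),
                         stringsAsFactors = FALSE)
  }
  x <- scores$risk_score
  if (length(x) < 3) stop("need at least 3 samples to form three groups")
  if (length(unique(x)) == 1L) {
    warning("all risk scores identical; assigning every sample to 'moderate'")
    group <- rep("moderate", length(x))
  } else {
    q <- quantile(x, probs = quantiles, names = FALSE)
    group <- ifelse(x >= q[2], "high", ifelse(x >= q[1], "moderate", "low"))
  }
  scores$group <- factor(group, levels = c("low", "moderate", "high"), ordered = TRUE)
  scores
}

#' k-sample log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with their expectation under the hypergeometric at-risk distribution; the
#' chi-square statistic is the quadratic form of the summed observed minus
#' expected counts with their covariance matrix (k - 1 degrees of freedom),
#' and the p-value is the upper chi-square tail.
#'
#' @param groups data.frame with \code{sample_id} and \code{group}.
#' @param survival data.frame with \code{sample_id}, \code{time},
#'   \code{event}.
#' @return list: chi_square, df, p_value, and a per-group summary (n,
#'   observed, expected).
#' @export
logrankTest <- function(groups, survival) {
  d <- merge(groups[, c("sample_id", "group")], survival, by = "sample_id")
  if (nrow(d) < nrow(groups)) {
    stop("validation error: samples missing from survival table")
  }
  d$group <- droplevels(factor(d$group))
  k <- nlevels(d$group)
  if (k < 2) stop("need at least two non-empty groups")
  if (sum(d$event) == 0) stop("undefined statistic: zero total events")
  times <- sort(unique(d$time[d$event == 1]))
  O <- E <- setNames(numeric(k), levels(d$group))
  V <- matrix(0, k, k, dimnames = list(levels(d$group), levels(d$group)))
  for (t in times) {
    at_risk <- d$time >= t
    n <- sum(at_risk)
    if (n < 1) next
    nj <- tabulate(d$group[at_risk], nbins = k)
    dj <- tabulate(d$group[at_risk & d$time == t & d$event == 1], nbins = k)
    dt <- sum(dj)
    if (dt == 0) next
    O <- O + dj
    E <- E + dt * nj / n
    if (n > 1) {
      pj <- nj / n
      V <- V + dt * (n - dt) / (n - 1) * (diag(pj, k) - outer(pj, pj))
    }
  }
  z <- (O - E)[-k]
  Vsub <- V[-k, -k, drop = FALSE]
  chi <- tryCatch(as.numeric(crossprod(z, solve(Vsub, z))),
                  error = function(e) {
                    s <- svd(Vsub)
                    pos <- s$d > max(s$d) * 1e-10
                    ginv <- s$v[, pos, drop = FALSE] %*%
                      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
                    as.numeric(crossprod(z, ginv %*% z))
                  })
  df <- k - 1
  list(chi_square = chi, df = df,
       p_value = pchisq(chi, df = df, lower.tail = FALSE),
       summary = data.frame(group = levels(d$group),
                            n = as.integer(table(d$group)),
                            observed = as.numeric(O), expected = as.numeric(E)))
}

#' Kaplan-Meier step-function coordinates per group
#'
#' Product-limit survival estimate per risk group, as step coordinates for
#' plotting.
#'
#' @param groups data.frame with \code{sample_id}, \code{group}.
#' @param survival data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @return data.frame: group, time, survival, n_risk, n_event.
#' @export
kmCoordinates <- function(groups, survival) {
  d <- merge(groups[, c("sample_id", "group")], survival, by = "sample_id")
  out <- lapply(split(d, d$group), function(g) {
    tt <- sort(unique(g$time[g$event == 1]))
    s <- 1
    rows <- data.frame(group = g$group[1], time = 0, survival = 1,
                       n_risk = nrow(g), n_event = 0L)
    for (t in tt) {
      n <- sum(g$time >= t)
      ev <- sum(g$time == t & g$event == 1)
      s <- s * (1 - ev / n)
      rows <- rbind(rows, data.frame(group = g$group[1], time = t, survival = s,
                                     n_risk = n, n_event = ev))
    }
    rows
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$group <- as.character(out$group)
  out
}
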