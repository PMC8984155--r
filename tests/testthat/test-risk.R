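mk_model <- function(genes, betas) {
  new("RiskModel", coefficients = stats::setNames(betas, genes), geneOrder = genes)
}

test_that("risk scores are the linear combination of gene expression", {
  set.seed(50)
  genes <- sprintf("g%d", 1:7)
  expr <- matrix(rexp(10 * 7), 10, 7,
                 dimnames = list(sprintf("s%d", 1:10), genes))
  beta <- rnorm(7)
  got <- riskScore(expr, mk_model(genes, beta))
  # independent dot-product oracle
  want <- apply(expr, 1, function(row) sum(beta * row[genes]))
  expect_equal(got$risk_score, unname(want))

  expect_equal(riskScore(expr, mk_model(genes, rep(0, 7)))$risk_score, rep(0, 10))
  one <- riskScore(matrix(2.5, 1, 1, dimnames = list("s1", "gA")),
                   mk_model("gA", 1))
  expect_equal(one$risk_score, 2.5)
  expect_error(riskScore(expr[, 1:3], mk_model(genes, beta)), "missing")
})

test_that("risk score is linear in the expression", {
  set.seed(51)
  genes <- sprintf("g%d", 1:4)
  model <- mk_model(genes, rnorm(4))
  x <- matrix(rexp(8), 2, 4, dimnames = list(c("s1", "s2"), genes))
  y <- matrix(rexp(8), 2, 4, dimnames = list(c("s1", "s2"), genes))
  a <- 2.5; b <- -0.5
  lhs <- riskScore(a * x + b * y, model)$risk_score
  rhs <- a * riskScore(x, model)$risk_score + b * riskScore(y, model)$risk_score
  expect_equal(lhs, rhs)
})

test_that("three-group stratification follows the quantile cutoffs", {
  sc <- data.frame(sample_id = sprintf("s%d", 1:9), risk_score = 1:9)
  gr <- assignRiskGroups(sc)
  expect_equal(as.integer(table(gr$group)), c(3, 3, 3))
  expect_equal(as.character(gr$group[c(1, 5, 9)]), c("low", "moderate", "high"))

  # ties resolved deterministically by the threshold rule
  tie <- data.frame(sample_id = sprintf("s%d", 1:6),
                    risk_score = c(1, 1, 1, 9, 9, 9))
  g1 <- assignRiskGroups(tie)
  g2 <- assignRiskGroups(tie)
  expect_identical(g1$group, g2$group)
  expect_equal(as.character(g1$group), rep(c("moderate", "high"), each = 3))

  # custom quantiles: 25/50/25 on uniform scores
  u <- data.frame(sample_id = sprintf("s%d", 1:8), risk_score = 1:8)
  gq <- assignRiskGroups(u, quantiles = c(0.25, 0.75))
  expect_equal(as.integer(table(gq$group)), c(2, 4, 2))

  expect_warning(all_same <- assignRiskGroups(
    data.frame(sample_id = c("a", "b", "c"), risk_score = 5)), "identical")
  expect_true(all(all_same$group == "moderate"))
})

test_that("group assignment is invariant to monotone transforms of scores", {
  set.seed(52)
  sc <- data.frame(sample_id = sprintf("s%d", 1:20), risk_score = rnorm(20))
  g1 <- assignRiskGroups(sc)$group
  sc2 <- sc; sc2$risk_score <- exp(3 * sc$risk_score + 1)
  expect_identical(assignRiskGroups(sc2)$group, g1)
})

test_that("log-rank matches the hand-computed O-E oracle and survdiff", {
  groups <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                       group = c("A", "A", "B", "B"))
  surv <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                     time = c(1, 2, 3, 4), event = 1)
  lr <- logrankTest(groups, surv)
  # by hand: O_A = 2, E_A = 1/2 + 1/3 = 5/6, V = 1/4 + 2/9
  expect_equal(lr$chi_square, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  expect_equal(lr$df, 1)
  expect_equal(lr$summary$observed[lr$summary$group == "A"], 2)
  expect_equal(lr$summary$expected[lr$summary$group == "A"], 5 / 6)

  # identical duplicated groups -> statistic 0, p = 1
  dup <- data.frame(sample_id = sprintf("s%d", 1:8),
                    group = rep(c("A", "B"), 4))
  sdup <- data.frame(sample_id = sprintf("s%d", 1:8),
                     time = rep(c(2, 5, 7, 9), each = 2), event = 1)
  lr0 <- logrankTest(dup, sdup)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)

  # cross-check against survival::survdiff on random 3-group data
  set.seed(53)
  for (i in 1:5) {
    n <- 60
    df <- data.frame(sample_id = sprintf("s%d", 1:n),
                     group = sample(c("g1", "g2", "g3"), n, replace = TRUE),
                     time = round(rexp(n, 0.1), 2),
                     event = rbinom(n, 1, 0.8))
    lri <- logrankTest(df[, c("sample_id", "group")],
                       df[, c("sample_id", "time", "event")])
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
    expect_equal(lri$chi_square, sd$chisq, tolerance = 1e-8)
  }

  expect_error(logrankTest(groups, transform(surv, event = 0)), "zero total events")
})

test_that("strong planted hazard separates tertiles (power check)", {
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    set.seed(400 + s)
    n <- 300
    x <- rnorm(n)                      # risk score driving the hazard
    time <- rexp(n, rate = 0.05 * exp(log(3) * scale(x)[, 1]))
    df <- data.frame(sample_id = sprintf("s%d", 1:n), risk_score = x,
                     time = time, event = 1L)
    gr <- assignRiskGroups(df[, c("sample_id", "risk_score")])
    p <- logrankTest(gr, df[, c("sample_id", "time", "event")])$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_seeds))
})

test_that("Kaplan-Meier coordinates decrease stepwise from 1", {
  groups <- data.frame(sample_id = sprintf("s%d", 1:6),
                       group = rep(c("A", "B"), each = 3))
  surv <- data.frame(sample_id = sprintf("s%d", 1:6),
                     time = c(1, 2, 3, 4, 5, 6), event = c(1, 0, 1, 1, 1, 0))
  km <- kmCoordinates(groups, surv)
  for (g in c("A", "B")) {
    s <- km$survival[km$group == g]
    expect_equal(s[1], 1)
    expect_true(all(diff(s) <= 0))
  }
  # A: events at t=1 (3 at risk) and t=3 (1 at risk) -> 2/3 then 0
  expect_equal(km$survival[km$group == "A"], c(1, 2 / 3, 0))
})
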