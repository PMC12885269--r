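test_that("structure coefficients hit the correlation endpoints", {
  set.seed(21)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("Q1", "Q2")))
  y <- X[, 1] * 3 + 1
  m <- severity_model(X, y)
  Xte <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("Q1", "Q2")))
  pred <- predict(m, Xte)
  # features constructed from the prediction vector itself
  Xc <- cbind(Q1 = pred, Q2 = -pred)
  # model over (Q1, Q2) applied to Xc: correlations with prediction
  r <- structure_coefficients(m, Xc)
  pc <- predict(m, Xc)
  expect_equal(unname(r["Q1"]), cor(Xc[, "Q1"], pc))
  expect_equal(abs(unname(r)), c(1, 1), tolerance = 1e-12)
  # constant feature flagged NA with a warning
  Xflat <- cbind(Q1 = rnorm(10), Q2 = rep(2, 10))
  expect_warning(r2 <- structure_coefficients(m, Xflat), "Q2")
  expect_true(is.na(r2["Q2"]))
})

test_that("structure coefficients match a brute-force correlation oracle", {
  set.seed(22)
  for (k in 1:20) {
    X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("Q", 1:5)))
    y <- rnorm(30, 10, 5)
    m <- severity_model(X, y)
    Xte <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("Q", 1:5)))
    r <- structure_coefficients(m, Xte)
    pred <- drop(apply_standardizer(m$standardizer, Xte) %*% m$fit$coef) +
      m$fit$intercept
    for (j in 1:5)
      expect_equal(unname(r[j]), pearson_oracle(Xte[, j], pred),
                   tolerance = 1e-12)
  }
})

test_that("bootstrap handles degenerate statistics and reproduces exactly", {
  const <- bootstrap_infer(function(d) 5, 1:20, B = 400, seed = 1)
  expect_equal(const$ci_low, 5)
  expect_equal(const$ci_high, 5)
  expect_equal(const$p, 2 / 401)
  set.seed(99)
  d <- cbind(rnorm(40), rnorm(40))
  f <- function(dd) cor(dd[, 1], dd[, 2])
  b1 <- bootstrap_infer(f, d, B = 300, seed = 7)
  b2 <- bootstrap_infer(f, d, B = 300, seed = 7)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$estimate && b1$estimate <= b1$ci_high)
  # undefined draws are dropped, counted and flagged past 1%
  flaky <- function(dd) if (mean(dd) > 0.4) NA_real_ else mean(dd)
  fb <- bootstrap_infer(flaky, rnorm(30), B = 300, seed = 3)
  expect_equal(fb$n_undefined > 0.01 * 300, fb$flagged)
  expect_error(bootstrap_infer(function(d) 1, 1:5, B = 50), "at least 100")
})

test_that("bootstrap p-value is the sign-based rule with continuity correction", {
  set.seed(23)
  d <- rnorm(25, 1)
  stat <- function(dd) mean(dd)
  b <- bootstrap_infer(stat, d, B = 500, seed = 11)
  theta <- with(list(), {  # recompute the resample distribution independently
    set.seed(11)
    replicate(500, stat(d[sample.int(25, 25, replace = TRUE)]))
  })
  expect_equal(b$p,
               min(1, 2 * min(sum(theta <= 0) + 1, sum(theta >= 0) + 1) / 501))
})

test_that("BH adjustment equals the hand-worked and brute-force oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)  # m = 1 passes through
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(24)
  for (k in 1:100) {
    m <- sample(2:8, 1)
    p <- round(runif(m), 3)
    # exact up to floating-point associativity: (p*m)/j vs (m/j)*p
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-14)
  }
  # monotonicity: q >= p and q ordering preserves p ordering
  for (k in 1:20) {
    p <- runif(10)
    q <- fdr_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("ablation: duplicates are free, sole informative features are not", {
  set.seed(25)
  n <- 40
  X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("Q", 1:3)))
  X <- cbind(X, Q4 = X[, 1])         # exact duplicate of Q1
  y <- drop(2 + X[, 1] * 3)          # noise-free, Q1 (and Q4) informative
  Xte <- matrix(rnorm(20 * 3), 20, dimnames = list(NULL, paste0("Q", 1:3)))
  Xte <- cbind(Xte, Q4 = Xte[, 1])
  yte <- drop(2 + Xte[, 1] * 3)
  imp <- ablation_importance(X, y, Xte, yte, B = 200, seed = 1)
  expect_equal(nrow(imp), 4L)
  expect_lt(abs(imp$estimate[imp$qid == "Q4"]), 1e-8)
  expect_lt(abs(imp$estimate[imp$qid == "Q1"]), 1e-8)  # twin still present
  # without a twin, removing the only informative feature hurts
  imp2 <- ablation_importance(X[, 1:3], y, Xte[, 1:3], yte, B = 200, seed = 1)
  expect_gt(imp2$estimate[imp2$qid == "Q1"], 0.5)
  expect_true(all(abs(imp2$estimate[imp2$qid != "Q1"]) < 1e-8))
})

test_that("coefficient reports are ranked, FDR-consistent and categorized", {
  cohort <- generate_cohort(cohort_spec(80, seed = 26))
  X <- cohort$features
  y <- cohort$labels$phq8_total
  train <- 1:60; test <- 61:80
  m <- severity_model(X[train, ], y[train])
  rep <- coefficient_report("structure", model = m, x_test = X[test, ],
                            questions = question_set("depression23"),
                            B = 200, seed = 2)
  expect_s3_class(rep, "coefficient_report")
  expect_equal(nrow(rep), 23L)
  expect_true(all(diff(abs(rep$estimate)) <= 1e-15))  # sorted by |estimate|
  expect_true(all(rep$q >= rep$p - 1e-15))
  expect_true(all(rep$ci_low <= rep$estimate + 1e-12 &
                  rep$estimate <= rep$ci_high + 1e-12))
  expect_false(anyNA(rep$category))
  rep2 <- coefficient_report("structure", model = m, x_test = X[test, ],
                             questions = question_set("depression23"),
                             B = 200, seed = 2)
  expect_identical(as.data.frame(rep), as.data.frame(rep2))
})

test_that("univariate betas recover the analytic slope for a perfect feature", {
  set.seed(27)
  n <- 60
  y <- rnorm(n, 10, 5)
  X <- cbind(Q1 = y, Q2 = rnorm(n))
  rep <- univariate_report(X, y, B = 1000, seed = 5)
  r1 <- rep[rep$qid == "Q1", ]
  expect_equal(r1$estimate, sd(y), tolerance = 1e-12)
  expect_lt(r1$q, 0.05)
  r2 <- rep[rep$qid == "Q2", ]
  expect_gt(r2$p, 0.05)
})

test_that("independent-feature CIs cover zero at the nominal rate", {
  n_rep <- 150
  covered <- logical(n_rep)
  for (k in seq_len(n_rep)) {
    set.seed(3000 + k)
    x <- rnorm(40)
    y <- rnorm(40)
    b <- bootstrap_infer(function(d) phqlm:::univariate_beta(d[, 1], d[, 2]),
                         cbind(x, y), B = 200, seed = k)
    covered[k] <- b$ci_low <= 0 && 0 <= b$ci_high
  }
  # 93-97% band (percentile CIs run slightly narrow at small n) widened by
  # two Monte-Carlo SEs for 150 replications
  mc <- 2 * sqrt(0.95 * 0.05 / n_rep)
  expect_gte(mean(covered), 0.93 - mc)
  expect_lte(mean(covered), min(1, 0.97 + mc))
})
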