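random_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("Q", seq_len(p))))
  X
}

test_that("standardizer uses train parameters with the n-1 convention", {
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "Q1"))
  std <- fit_standardizer(X)
  expect_equal(drop(apply_standardizer(std, X)), c(-1, 0, 1))
  expect_equal(unname(std$sd), 1)  # sample SD of 1,2,3
  # test value equal to the train mean maps to 0
  expect_equal(unname(drop(apply_standardizer(std, matrix(2, 1, 1,
    dimnames = list(NULL, "Q1"))))), 0)
  Xtr <- random_design(50, 4, 1)
  stdr <- fit_standardizer(Xtr)
  Z <- apply_standardizer(stdr, Xtr)
  expect_true(all(abs(colMeans(Z)) < 1e-10))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-10))
  Xtr[, 2] <- 7
  expect_error(fit_standardizer(Xtr), "Q2")
})

test_that("noise-free linear data is interpolated exactly", {
  X <- random_design(40, 2, 2)
  y <- 2 * X[, 1] - X[, 2] + 3
  m <- severity_model(X, y)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
  # standardized betas scale by the train SDs; intercept is mean(y)
  expect_equal(unname(m$fit$coef), c(2 * sd(X[, 1]), -sd(X[, 2])),
               tolerance = 1e-8)
  expect_equal(unname(m$fit$intercept), mean(y), tolerance = 1e-8)
  expect_lt(abs(mean(residuals(m))), 1e-8)
  y_const <- rep(4, 40)
  mc <- severity_model(X, y_const)
  expect_true(all(abs(mc$fit$coef) < 1e-10))
  expect_equal(unname(mc$fit$intercept), 4)
})

test_that("OLS matches the normal-equations oracle on random instances", {
  for (k in 1:20) {
    X <- random_design(15 + k, min(2 + k %% 5, 6), 100 + k)
    set.seed(200 + k)
    y <- rnorm(nrow(X), sd = 3)
    m <- severity_model(X, y)
    Z <- apply_standardizer(m$standardizer, X)
    oracle <- ols_oracle(Z, y)
    expect_lt(max(abs(c(m$fit$intercept, m$fit$coef) - oracle)), 1e-8)
  }
})

test_that("rank-deficient designs are rejected naming collinear features", {
  X <- random_design(30, 3, 3)
  X <- cbind(X, Q4 = X[, 1])
  set.seed(4)
  expect_error(severity_model(X, rnorm(30)), "Q4")
})

test_that("prediction metrics follow their definitions", {
  m <- evaluate_predictions(c(2, 2), c(0, 4))
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, 2)
  y <- c(1, 5, 9, 13)
  perfect <- evaluate_predictions(y, y)
  expect_equal(c(perfect$mae, perfect$rmse, perfect$r2), c(0, 0, 1))
  const <- evaluate_predictions(rep(mean(y), 4), y)
  expect_equal(const$r2, 0)
  set.seed(6)
  for (k in 1:10) {
    pred <- rnorm(20); obs <- rnorm(20)
    mm <- evaluate_predictions(pred, obs)
    expect_gte(mm$rmse, mm$mae)
  }
  expect_true(is.na(evaluate_predictions(1, 1)$r2))
})

test_that("prediction refuses mismatched feature sets and can clip", {
  X <- random_design(30, 3, 7)
  set.seed(7)
  y <- rnorm(30, 10, 6)
  m <- severity_model(X, y)
  expect_error(predict(m, X[, 1:2]), "Q3")
  extra <- cbind(X, Q9 = rnorm(30))[, c(4, 2, 1, 3)]  # extra + reordered
  expect_equal(predict(m, extra), predict(m, X))
  lo <- matrix(rep(c(-50, 0, 50), each = 3), 3, byrow = TRUE,
               dimnames = list(NULL, colnames(X)))
  expect_true(all(predict(m, lo, clip = TRUE) >= 0 &
                  predict(m, lo, clip = TRUE) <= 24))
})

test_that("test rows never influence the fit (train/test hygiene)", {
  X <- random_design(60, 4, 8)
  set.seed(8)
  y <- rnorm(60, 10, 5)
  train <- 1:40
  m1 <- severity_model(X[train, ], y[train])
  y2 <- y; y2[50] <- y2[50] + 100  # perturb a test-row label
  X2 <- X; X2[45, ] <- X2[45, ] * 10
  m2 <- severity_model(X2[train, ], y2[train])
  expect_identical(m1$standardizer, m2$standardizer)
  expect_identical(m1$fit, m2$fit)
})

test_that("LOOCV folds exclude their own row (perturbation property)", {
  X <- random_design(25, 3, 9)
  set.seed(9)
  y <- rnorm(25, 8, 4)
  base <- phqlm:::loocv_ols_predictions(X, y)
  for (i in c(1L, 13L, 25L)) {
    y_pert <- y
    y_pert[i] <- y_pert[i] + 50
    pert <- phqlm:::loocv_ols_predictions(X, y_pert)
    expect_equal(pert[i], base[i])          # own fold untouched
    expect_false(isTRUE(all.equal(pert[-i], base[-i])))  # others refit
  }
})

test_that("SVR selects C by LOOCV MAE with deterministic tie-breaking", {
  cohort <- generate_cohort(cohort_spec(30, seed = 12))
  X <- cohort$features
  y <- cohort$labels$phq8_total
  m1 <- severity_model(X, y, family = "svr_rbf", C_grid = c(1, 8))
  m2 <- severity_model(X, y, family = "svr_rbf", C_grid = c(1, 8))
  expect_identical(m1$fit$C, m2$fit$C)
  expect_identical(m1$fit$loocv, m2$fit$loocv)
  single <- severity_model(X, y, family = "svr_rbf", C_grid = 4)
  expect_equal(single$fit$C, 4)
  expect_error(severity_model(X, y, family = "svr_rbf", C_grid = numeric(0)))
  expect_equal(nrow(m1$fit$loocv), 2L)
  pred <- predict(single, X)
  expect_length(pred, 30L)
})

test_that("stacking composes LOOCV base predictions under an OLS meta-model", {
  set.seed(13)
  n <- 50
  X <- cbind(random_design(n, 2, 13),
             Q3 = rnorm(n), Q4 = rnorm(n))
  y <- drop(3 + X[, "Q1"] * 2 + X[, "Q2"] * -1)  # category A is noise-free
  cats <- c(Q1 = "A", Q2 = "A", Q3 = "B", Q4 = "B")
  m <- severity_model(X, y, family = "stacking", categories = cats)
  expect_equal(dim(m$fit$meta_design), c(n, 2L))
  Xte <- cbind(Q1 = rnorm(20), Q2 = rnorm(20), Q3 = rnorm(20), Q4 = rnorm(20))
  yte <- drop(3 + Xte[, "Q1"] * 2 - Xte[, "Q2"])
  base_a <- m$fit$base[["A"]]
  pred_a <- drop(apply_standardizer(base_a$standardizer,
                                    Xte[, base_a$qids]) %*% base_a$coef) +
    base_a$intercept
  mae_stack <- mean(abs(predict(m, Xte) - yte))
  mae_base <- mean(abs(pred_a - yte))
  expect_lte(mae_stack, mae_base + 1e-6)
  expect_error(severity_model(X, y, family = "stacking",
                              categories = c(Q1 = "A", Q2 = "A", Q3 = "A",
                                             Q4 = "A")),
               "2 feature categories")
})

test_that("in-sample RMSE is monotone under feature-set nesting", {
  cohort <- generate_cohort(cohort_spec(80, seed = 14))
  X <- cohort$features
  y <- cohort$labels$phq8_total
  full <- severity_model(X, y)
  qs <- question_set("depression23")
  for (cat in unique(qs$category)) {
    sub <- severity_model(X, y, features = qs$qid[qs$category == cat])
    expect_gte(sub$train_metrics$rmse, full$train_metrics$rmse - 1e-10)
  }
})

test_that("simulate draws around the fitted values for the OLS family", {
  X <- random_design(30, 3, 15)
  set.seed(15)
  y <- rnorm(30, 10, 4)
  m <- severity_model(X, y)
  sims <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(30L, 3L))
  expect_identical(simulate(m, nsim = 2, seed = 9),
                   simulate(m, nsim = 2, seed = 9))
  msvr <- severity_model(X, y, family = "svr_rbf", C_grid = 1)
  expect_error(simulate(msvr), "OLS")
})
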