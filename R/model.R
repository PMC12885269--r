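# Severity models: standardized multiple OLS (primary), RBF-SVR with
# LOOCV-tuned cost, and a stacking ensemble over feature categories.

#' Fit a feature standardizer
#'
#' Per-feature mean and standard deviation (sample, n-1 convention) estimated
#' on training rows only; test data must be transformed with these training
#' parameters. Zero-variance features are rejected by name.
#'
#' @param x Numeric matrix with qid column names (training rows).
#' @return A \code{"standardizer"} with \code{mean}, \code{sd}, \code{qids}.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("feature columns must be named by qid")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  if (any(sd == 0))
    stop("zero training variance for feature(s): ",
         paste(colnames(x)[sd == 0], collapse = ", "))
  structure(list(mean = mu, sd = sd, qids = colnames(x)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A \code{"standardizer"}.
#' @param newdata Matrix with (at least) the standardizer's qid columns.
#' @return \code{apply_standardizer}: the z-scored matrix, columns in
#'   standardizer order.
#' @export
apply_standardizer <- function(std, newdata) {
  newdata <- as.matrix(newdata)
  if (!all(std$qids %in% colnames(newdata)))
    stop("newdata is missing feature(s): ",
         paste(setdiff(std$qids, colnames(newdata)), collapse = ", "))
  x <- newdata[, std$qids, drop = FALSE]
  sweep(sweep(x, 2L, std$mean, "-"), 2L, std$sd, "/")
}

# Least-squares fit of y on [1, X]. Rank-deficient designs either error
# (naming the collinear columns) or fall back to the SVD minimum-norm
# solution (used by ablation analyses where exact duplicates are legitimate).
ols_coefficients <- function(X, y, rank_deficient = c("error", "pinv")) {
  rank_deficient <- match.arg(rank_deficient)
  A <- cbind(`(Intercept)` = 1, X)
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A)) {
    if (rank_deficient == "error") {
      dropped <- colnames(A)[qr_A$pivot[-seq_len(qr_A$rank)]]
      stop("rank-deficient design; collinear feature(s): ",
           paste(dropped, collapse = ", "))
    }
    sv <- svd(A)
    pos <- sv$d > max(dim(A)) * .Machine$double.eps * sv$d[1L]
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
    coef <- drop(coef)
  } else {
    coef <- qr.coef(qr_A, y)
  }
  names(coef) <- colnames(A)
  coef
}

#' Fit a depression-severity model on extracted features
#'
#' The central fitting function: maps a participants-by-questions score
#' matrix to PHQ-8 totals. Predictors are z-scored with training parameters
#' before fitting (so OLS coefficients are standardized betas, comparable
#' across features). Three families are available:
#' \describe{
#'   \item{\code{"ols"}}{multiple linear regression (the primary model).}
#'   \item{\code{"svr_rbf"}}{epsilon-SVR with an RBF kernel; the cost
#'     parameter C is selected by leave-one-out cross-validation on the
#'     training rows, minimizing MAE (ties broken toward the smallest C).}
#'   \item{\code{"stacking"}}{one OLS base model per feature category; their
#'     leave-one-out out-of-fold training predictions form the design of an
#'     OLS meta-model, and the base models are refit on the full training
#'     set for prediction.}
#' }
#'
#' @param x Training features: a [feature_matrix] or numeric matrix with qid
#'   column names.
#' @param y PHQ-8 totals for the training rows.
#' @param family Model family (see above).
#' @param features Optional character vector of qids to restrict to.
#' @param categories Named character vector mapping qid to category
#'   (required for \code{"stacking"}; defaults to the depression23 layout
#'   when the qids match it).
#' @param C_grid Cost grid for \code{"svr_rbf"}; default
#'   \code{2^(-5:10)} (16 log-spaced points).
#' @param epsilon,gamma SVR tube width and kernel width; defaults 0.1 and
#'   \code{1 / (d * pooled variance)} on standardized features.
#' @param clip Clip predictions to the PHQ-8 range 0-24? Default \code{FALSE}
#'   (raw regression output).
#' @return A \code{"severity_model"} object with \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{simulate} and \code{plot} methods.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(sample(0:10, 200, TRUE), 20,
#'             dimnames = list(paste0("P", 1:20), paste0("Q", 1:10)))
#' y <- pmin(pmax(round(X %*% rep(0.3, 10) / 2), 0), 24)
#' m <- severity_model(X, as.numeric(y))
#' m
severity_model <- function(x, y, family = c("ols", "svr_rbf", "stacking"),
                           features = NULL, categories = NULL,
                           C_grid = 2^(-5:10), epsilon = 0.1, gamma = NULL,
                           clip = FALSE) {
  family <- match.arg(family)
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) stop("feature columns must be named by qid")
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(x)")
  if (anyNA(X) || anyNA(y)) stop("missing values in training data")
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least ", ncol(X) + 1L, " training rows for ", ncol(X),
         " features")
  std <- fit_standardizer(X)
  Xz <- apply_standardizer(std, X)
  fit <- switch(family,
    ols = {
      coef <- ols_coefficients(Xz, y)
      list(coef = coef[-1L], intercept = coef[1L])
    },
    svr_rbf = fit_svr_loocv(X, y, C_grid, epsilon, gamma),
    stacking = fit_stacking(X, y, resolve_categories(colnames(X), categories)))
  m <- structure(
    list(family = family, qids = colnames(X), standardizer = std,
         fit = fit, clip = clip, n_train = nrow(X),
         y_train = y, call = match.call()),
    class = "severity_model")
  m$fitted_train <- predict(m, X)
  m$train_metrics <- evaluate_predictions(m$fitted_train, y)
  m
}

resolve_categories <- function(qids, categories) {
  if (is.null(categories)) {
    qs <- question_set("depression23")
    if (all(qids %in% qs$qid)) {
      categories <- stats::setNames(qs$category, qs$qid)[qids]
    } else {
      stop("`categories` (named qid -> category vector) is required for ",
           "stacking on non-standard feature sets")
    }
  }
  if (!all(qids %in% names(categories)))
    stop("categories missing for: ",
         paste(setdiff(qids, names(categories)), collapse = ", "))
  categories[qids]
}

# --- RBF-SVR with LOOCV-selected cost ------------------------------------

fit_svr_loocv <- function(X, y, C_grid, epsilon, gamma) {
  C_grid <- sort(unique(as.numeric(C_grid)))
  if (!length(C_grid) || any(C_grid <= 0))
    stop("C_grid must be a non-empty grid of positive costs")
  n <- nrow(X)
  loocv_mae <- vapply(C_grid, function(C) {
    err <- vapply(seq_len(n), function(i) {
      std_i <- fit_standardizer(X[-i, , drop = FALSE])
      g <- gamma %||% (1 / (ncol(X) *
             mean(apply(apply_standardizer(std_i, X[-i, , drop = FALSE]), 2L,
                        stats::var))))
      fit <- e1071::svm(apply_standardizer(std_i, X[-i, , drop = FALSE]),
                        y[-i], type = "eps-regression", kernel = "radial",
                        cost = C, epsilon = epsilon, gamma = g, scale = FALSE)
      abs(stats::predict(fit, apply_standardizer(std_i, X[i, , drop = FALSE])) - y[i])
    }, 0)
    mean(err)
  }, 0)
  C_best <- C_grid[which.min(loocv_mae)]  # which.min takes the first = smallest C
  std <- fit_standardizer(X)
  Xz <- apply_standardizer(std, X)
  g <- gamma %||% (1 / (ncol(X) * mean(apply(Xz, 2L, stats::var))))
  list(svm = e1071::svm(Xz, y, type = "eps-regression", kernel = "radial",
                        cost = C_best, epsilon = epsilon, gamma = g,
                        scale = FALSE),
       C = C_best, epsilon = epsilon, gamma = g,
       loocv = data.frame(C = C_grid, mae = loocv_mae))
}

# --- stacking over feature categories ------------------------------------

# Out-of-fold LOOCV predictions of a per-category OLS; fold models never see
# the held-out row (standardization included).
loocv_ols_predictions <- function(X, y) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    std_i <- fit_standardizer(X[-i, , drop = FALSE])
    coef <- ols_coefficients(apply_standardizer(std_i, X[-i, , drop = FALSE]),
                             y[-i])
    drop(cbind(1, apply_standardizer(std_i, X[i, , drop = FALSE])) %*% coef)
  }, 0)
}

fit_stacking <- function(X, y, categories) {
  cats <- split(names(categories), categories)
  cats <- cats[order(match(vapply(cats, `[`, "", 1L), names(categories)))]
  if (length(cats) < 2L)
    stop("stacking needs at least 2 feature categories")
  if (any(!lengths(cats)))
    stop("category with zero features")
  meta_X <- vapply(cats, function(qids)
    loocv_ols_predictions(X[, qids, drop = FALSE], y), numeric(nrow(X)))
  colnames(meta_X) <- names(cats)
  meta_coef <- ols_coefficients(meta_X, y)
  base <- lapply(cats, function(qids) {
    std <- fit_standardizer(X[, qids, drop = FALSE])
    coef <- ols_coefficients(apply_standardizer(std, X[, qids, drop = FALSE]), y)
    list(qids = qids, standardizer = std, coef = coef[-1L],
         intercept = coef[1L])
  })
  list(base = base, meta_coef = meta_coef[-1L], meta_intercept = meta_coef[1L],
       meta_design = meta_X)
}

# --- methods ---------------------------------------------------------------

#' Predict severity for new participants
#'
#' @param object A \code{"severity_model"}.
#' @param newdata Feature matrix containing exactly the model's qids (extra
#'   columns are ignored; missing ones are an error).
#' @param clip Override the model's clip setting (limit predictions to
#'   0-24).
#' @param ... Unused.
#' @return Numeric vector of predicted PHQ-8 totals (raw regression output
#'   unless clipped).
#' @export
predict.severity_model <- function(object, newdata, clip = NULL, ...) {
  X <- as.matrix(newdata)
  if (!all(object$qids %in% colnames(X)))
    stop("newdata is missing feature(s): ",
         paste(setdiff(object$qids, colnames(X)), collapse = ", "))
  X <- X[, object$qids, drop = FALSE]
  storage.mode(X) <- "double"
  pred <- switch(object$family,
    ols = {
      Xz <- apply_standardizer(object$standardizer, X)
      drop(Xz %*% object$fit$coef) + object$fit$intercept
    },
    svr_rbf = {
      Xz <- apply_standardizer(object$standardizer, X)
      as.numeric(stats::predict(object$fit$svm, Xz))
    },
    stacking = {
      base_pred <- vapply(object$fit$base, function(b) {
        Xz <- apply_standardizer(b$standardizer, X[, b$qids, drop = FALSE])
        drop(Xz %*% b$coef) + b$intercept
      }, numeric(nrow(X)))
      if (nrow(X) == 1L) base_pred <- matrix(base_pred, 1L)
      drop(base_pred %*% object$fit$meta_coef) + object$fit$meta_intercept
    })
  pred <- as.numeric(pred)
  names(pred) <- rownames(X)
  if (clip %||% object$clip) pred <- pmin(pmax(pred, 0), 24)
  pred
}

#' @export
coef.severity_model <- function(object, ...) {
  switch(object$family,
    ols = c(`(Intercept)` = unname(object$fit$intercept), object$fit$coef),
    stacking = c(`(Intercept)` = unname(object$fit$meta_intercept),
                 object$fit$meta_coef),
    svr_rbf = stop("SVR has no linear coefficients; see object$fit"))
}

#' @export
fitted.severity_model <- function(object, ...) object$fitted_train

#' @export
residuals.severity_model <- function(object, ...)
  object$y_train - object$fitted_train

#' @export
print.severity_model <- function(x, ...) {
  cat(sprintf("<severity_model> %s on %d features, n_train = %d\n",
              x$family, length(x$qids), x$n_train))
  with(x$train_metrics,
       cat(sprintf("  train MAE %.3f, RMSE %.3f, R^2 %.3f\n", mae, rmse, r2)))
  if (x$family == "svr_rbf")
    cat(sprintf("  C = %g (LOOCV MAE %.3f), gamma = %.4g, epsilon = %g\n",
                x$fit$C, min(x$fit$loocv$mae), x$fit$gamma, x$fit$epsilon))
  invisible(x)
}

#' @export
summary.severity_model <- function(object, ...) {
  print(object)
  if (object$family == "ols") {
    cat("  standardized coefficients (top 10 by |beta|):\n")
    b <- sort(abs(object$fit$coef), decreasing = TRUE)
    shown <- object$fit$coef[names(b)[seq_len(min(10L, length(b)))]]
    print(round(shown, 3))
  }
  if (object$family == "stacking") {
    cat("  meta-model coefficients:\n")
    print(round(coef(object), 3))
  }
  invisible(object)
}

#' @export
plot.severity_model <- function(x, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    pred <- x$fitted_train; obs <- x$y_train; lab <- "train"
  } else {
    pred <- predict(x, newdata); obs <- as.numeric(y); lab <- "test"
  }
  graphics::plot(obs, pred, xlab = "actual PHQ-8", ylab = "predicted PHQ-8",
                 main = sprintf("%s (%s)", x$family, lab), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate PHQ-8 outcomes from a fitted linear severity model
#'
#' Draws \code{nsim} outcome vectors at the model's training design:
#' fitted values plus Gaussian noise with the residual standard deviation.
#' Only defined for the OLS family.
#'
#' @param object A \code{"severity_model"} with \code{family = "ols"}.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed (restores the caller's RNG state).
#' @param ... Unused.
#' @return Data frame with \code{nsim} columns.
#' @export
simulate.severity_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$family != "ols")
    stop("simulate() is defined for the OLS family only")
  resid_sd <- sqrt(sum(residuals(object)^2) /
                   (object$n_train - length(object$qids) - 1L))
  draw <- function() object$fitted_train + stats::rnorm(object$n_train, 0, resid_sd)
  sims <- if (is.null(seed)) replicate(nsim, draw())
          else with_local_rng(seed, replicate(nsim, draw()))
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Prediction-error metrics on the PHQ-8 scale
#'
#' MAE, RMSE, and the coefficient of determination
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} computed with the evaluation-set mean
#' (not squared correlation; can be negative). With fewer than 2 observations
#' the R^2 is flagged \code{NA}.
#'
#' @param pred Predicted severities.
#' @param y Observed PHQ-8 totals.
#' @return A \code{"prediction_metrics"} list: \code{mae}, \code{rmse},
#'   \code{r2}, \code{n}.
#' @export
#' @examples
#' evaluate_predictions(c(2, 2), c(0, 4))  # MAE 2, RMSE 2
evaluate_predictions <- function(pred, y) {
  pred <- as.numeric(pred); y <- as.numeric(y)
  stopifnot(length(pred) == length(y), !anyNA(pred), !anyNA(y))
  n <- length(y)
  res <- y - pred
  sstot <- sum((y - mean(y))^2)
  structure(list(
    mae = mean(abs(res)),
    rmse = sqrt(mean(res^2)),
    r2 = if (n < 2L || sstot == 0) NA_real_ else 1 - sum(res^2) / sstot,
    n = n), class = "prediction_metrics")
}

#' @export
print.prediction_metrics <- function(x, ...) {
  cat(sprintf("MAE %.3f | RMSE %.3f | R^2 %s | n = %d\n", x$mae, x$rmse,
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2), x$n))
  invisible(x)
}
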