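# Feature-contribution statistics with percentile-bootstrap inference and
# Benjamini-Hochberg FDR control.

#' Percentile bootstrap for an arbitrary row-resampling statistic
#'
#' Resamples the rows of \code{data} with replacement \code{B} times,
#' recomputes \code{statistic} on each resample, and returns the observed
#' estimate with the 2.5/97.5 percentile confidence interval and a
#' sign-based two-sided p-value with add-one continuity correction:
#' \deqn{p = \min(1, 2 \min(\#\{\theta^* \le 0\} + 1,
#'   \#\{\theta^* \ge 0\} + 1) / (B + 1)).}
#' Resamples on which the statistic is undefined (\code{NA}) are dropped and
#' counted; if more than 1\% are undefined the result is flagged. Fully
#' reproducible from \code{seed}.
#'
#' @param statistic Function of one argument (a resample of \code{data}, same
#'   type) returning a scalar.
#' @param data Vector, matrix or data frame; rows are the resampling unit.
#' @param B Number of bootstrap iterations (>= 100).
#' @param seed Integer seed.
#' @return List with \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{B}, \code{n_undefined}, \code{flagged}.
#' @export
#' @examples
#' d <- cbind(x = rnorm(50), y = rnorm(50))
#' bootstrap_infer(function(d) cor(d[, 1], d[, 2]), d, B = 200, seed = 1)
bootstrap_infer <- function(statistic, data, B = 10000L, seed = 0L) {
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100")
  n <- NROW(data)
  if (n < 1L) stop("data has no rows")
  take <- if (is.null(dim(data))) function(i) data[i]
          else function(i) data[i, , drop = FALSE]
  estimate <- statistic(data)
  theta <- with_local_rng(seed, {
    vapply(seq_len(B), function(b) {
      s <- statistic(take(sample.int(n, n, replace = TRUE)))
      if (is.null(s) || !is.finite(s)) NA_real_ else as.numeric(s)
    }, 0)
  })
  n_undefined <- sum(is.na(theta))
  theta <- theta[!is.na(theta)]
  if (!length(theta)) stop("statistic undefined on every bootstrap resample")
  ci <- unname(stats::quantile(theta, c(0.025, 0.975)))
  p <- min(1, 2 * min(sum(theta <= 0) + 1L, sum(theta >= 0) + 1L) / (B + 1))
  list(estimate = as.numeric(estimate), ci_low = ci[1L], ci_high = ci[2L],
       p = p, B = B, n_undefined = n_undefined,
       flagged = n_undefined > 0.01 * B)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, returned in the
#' original order. A thin validating wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p Vector of p-values in \code{[0, 1]} (NA allowed, passed through).
#' @return q-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
fdr_adjust <- function(p) {
  p_num <- as.numeric(p)
  if (any(p_num < 0 | p_num > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_num, method = "BH")
}

#' Structure coefficients of a fitted severity model
#'
#' The structure coefficient of feature j is the Pearson correlation between
#' the feature's raw values and the model's predicted outcome over the
#' evaluation rows -- an interpretive index of feature contribution that
#' remains readable under multicollinearity, where multiple-regression
#' coefficients and ablation importances become unstable. Standardizing the
#' feature does not change it.
#'
#' @param model A fitted [severity_model] (fit on training rows).
#' @param newdata Evaluation feature matrix (held-out rows).
#' @return Named vector of correlations in \code{[-1, 1]}; a feature constant
#'   on the evaluation rows gives \code{NA} (flagged by a warning).
#' @export
structure_coefficients <- function(model, newdata) {
  X <- as.matrix(newdata)[, model$qids, drop = FALSE]
  pred <- predict(model, newdata)
  r <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0 || stats::sd(pred) == 0) NA_real_
    else stats::cor(X[, j], pred)
  }, 0)
  names(r) <- model$qids
  if (anyNA(r))
    warning("structure coefficient undefined for constant feature(s): ",
            paste(names(r)[is.na(r)], collapse = ", "))
  r
}

#' Ablation-based feature importance
#'
#' For each feature j, refits the OLS model on the training rows without
#' feature j and evaluates on the test rows:
#' \eqn{\Delta MAE_j = MAE_{-j} - MAE_{full}}. A positive value means
#' removing the feature hurts prediction. Models are fit with the SVD
#' minimum-norm (pseudo-inverse) fallback so that exactly collinear designs
#' -- e.g. a duplicated feature, whose removal leaves predictions unchanged
#' -- are handled rather than rejected. Bootstrap CIs and p-values resample
#' the test rows with both fitted models held fixed.
#'
#' @param x_train,y_train Training features and PHQ-8 totals.
#' @param x_test,y_test Held-out features and PHQ-8 totals.
#' @param B,seed Bootstrap iterations and seed.
#' @return Data frame: \code{qid}, \code{estimate} (delta MAE),
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n}.
#' @export
ablation_importance <- function(x_train, y_train, x_test, y_test,
                                B = 10000L, seed = 0L) {
  Xtr <- as.matrix(x_train); Xte <- as.matrix(x_test)
  y_train <- as.numeric(y_train); y_test <- as.numeric(y_test)
  qids <- colnames(Xtr)
  pred_with <- function(keep) {
    std <- fit_standardizer(Xtr[, keep, drop = FALSE])
    coef <- ols_coefficients(apply_standardizer(std, Xtr[, keep, drop = FALSE]),
                             y_train, rank_deficient = "pinv")
    drop(cbind(1, apply_standardizer(std, Xte[, keep, drop = FALSE])) %*% coef)
  }
  full_pred <- pred_with(qids)
  abs_full <- abs(full_pred - y_test)
  rows <- lapply(seq_along(qids), function(j) {
    drop_pred <- pred_with(qids[-j])
    abs_drop <- abs(drop_pred - y_test)
    delta <- cbind(drop = abs_drop, full = abs_full)
    bt <- bootstrap_infer(function(d) mean(d[, 1L]) - mean(d[, 2L]),
                          delta, B = B, seed = seed + j)
    data.frame(qid = qids[j], estimate = mean(abs_drop) - mean(abs_full),
               ci_low = bt$ci_low, ci_high = bt$ci_high, p = bt$p,
               n = length(y_test), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# standardized univariate slope: beta = cor(x, y) * sd(y), the coefficient of
# a regression of y on z-scored x (re-standardized within each resample)
univariate_beta <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y) * stats::sd(y)
}

#' Feature-contribution report with bootstrap CIs and FDR control
#'
#' Assembles one of three per-feature statistics into a ranked report:
#' \describe{
#'   \item{\code{"structure"}}{structure coefficients of \code{model} on
#'     \code{x_test} ([structure_coefficients]); bootstrap resamples the
#'     evaluation rows with the trained model held fixed.}
#'   \item{\code{"beta"}}{standardized univariate regression coefficients of
#'     \code{y} on each feature of \code{x} (train rows); pairs bootstrap.}
#'   \item{\code{"ablation"}}{delta-MAE ablation importance
#'     ([ablation_importance]).}
#' }
#' P-values are FDR-adjusted across the feature set; rows are ordered by
#' absolute estimate (descending), ties broken by original qid order.
#'
#' @param kind \code{"structure"}, \code{"beta"} or \code{"ablation"}.
#' @param model Fitted [severity_model] (structure kind).
#' @param x,y Train features / outcomes (beta and ablation kinds).
#' @param x_test,y_test Evaluation features / outcomes (structure and
#'   ablation kinds).
#' @param questions Optional \code{"question_set"} used to attach categories.
#' @param B,seed Bootstrap iterations and seed.
#' @return A \code{"coefficient_report"} data frame: \code{qid},
#'   \code{category}, \code{estimate}, \code{ci_low}, \code{ci_high},
#'   \code{p}, \code{q}, \code{significance} (\code{fdr_significant} if
#'   q < 0.05, \code{nominal} if p < 0.05, else \code{ns}), \code{n}; with
#'   attributes \code{kind}, \code{B}, \code{seed}.
#' @export
coefficient_report <- function(kind = c("structure", "beta", "ablation"),
                               model = NULL, x = NULL, y = NULL,
                               x_test = NULL, y_test = NULL,
                               questions = NULL, B = 10000L, seed = 0L) {
  kind <- match.arg(kind)
  rep <- switch(kind,
    structure = {
      stopifnot(!is.null(model), !is.null(x_test))
      Xte <- as.matrix(x_test)[, model$qids, drop = FALSE]
      pred <- predict(model, x_test)
      rows <- lapply(seq_along(model$qids), function(j) {
        d <- cbind(Xte[, j], pred)
        bt <- bootstrap_infer(function(dd) {
          if (stats::sd(dd[, 1L]) == 0 || stats::sd(dd[, 2L]) == 0) NA_real_
          else stats::cor(dd[, 1L], dd[, 2L])
        }, d, B = B, seed = seed + j)
        data.frame(qid = model$qids[j], estimate = bt$estimate,
                   ci_low = bt$ci_low, ci_high = bt$ci_high, p = bt$p,
                   n = nrow(Xte), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    },
    beta = {
      stopifnot(!is.null(x), !is.null(y))
      X <- as.matrix(x); yv <- as.numeric(y)
      rows <- lapply(seq_len(ncol(X)), function(j) {
        d <- cbind(X[, j], yv)
        bt <- bootstrap_infer(function(dd) univariate_beta(dd[, 1L], dd[, 2L]),
                              d, B = B, seed = seed + j)
        data.frame(qid = colnames(X)[j], estimate = bt$estimate,
                   ci_low = bt$ci_low, ci_high = bt$ci_high, p = bt$p,
                   n = nrow(X), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    },
    ablation = {
      stopifnot(!is.null(x), !is.null(y), !is.null(x_test), !is.null(y_test))
      ablation_importance(x, y, x_test, y_test, B = B, seed = seed)
    })
  rep$q <- fdr_adjust(rep$p)
  rep$significance <- ifelse(!is.na(rep$q) & rep$q < 0.05, "fdr_significant",
                      ifelse(!is.na(rep$p) & rep$p < 0.05, "nominal", "ns"))
  if (!is.null(questions))
    rep$category <- questions$category[match(rep$qid, questions$qid)]
  else rep$category <- NA_character_
  ord <- order(-abs(rep$estimate), seq_len(nrow(rep)))
  rep <- rep[ord, c("qid", "category", "estimate", "ci_low", "ci_high",
                    "p", "q", "significance", "n")]
  rownames(rep) <- NULL
  structure(rep, kind = kind, B = B, seed = seed,
            class = c("coefficient_report", "data.frame"))
}

#' Univariate feature-relevance report
#'
#' Convenience wrapper for [coefficient_report] with \code{kind = "beta"}:
#' one standardized univariate regression per feature on the training rows,
#' with percentile-bootstrap CIs and FDR-adjusted p-values across the set.
#'
#' @inheritParams coefficient_report
#' @export
univariate_report <- function(x, y, questions = NULL, B = 10000L, seed = 0L) {
  coefficient_report("beta", x = x, y = y, questions = questions,
                     B = B, seed = seed)
}

#' @export
print.coefficient_report <- function(x, ...) {
  cat(sprintf("<coefficient_report> kind = %s, B = %d, %d features (%d FDR-significant)\n",
              attr(x, "kind"), attr(x, "B"), nrow(x),
              sum(x$significance == "fdr_significant")))
  print.data.frame(cbind(x[1:5], round(x[c("p", "q")], 4), x["significance"]),
                   digits = 3)
  invisible(x)
}

#' Feature-ladder plot of a coefficient report
#'
#' Dot-and-error-bar display: one row per feature, ordered by absolute
#' estimate, filled markers for FDR-significant features, open otherwise,
#' colored by feature category.
#'
#' @param x A \code{"coefficient_report"}.
#' @param ... Passed to \code{plot}.
#' @export
plot.coefficient_report <- function(x, ...) {
  n <- nrow(x)
  ypos <- rev(seq_len(n))
  cols <- c(clinical_symptoms = "firebrick", linguistic_patterns = "cyan4",
            cognitive_distortions = "purple3")
  col <- cols[x$category]
  col[is.na(col)] <- "grey40"
  xlim <- range(c(x$ci_low, x$ci_high, 0), na.rm = TRUE)
  graphics::plot(x$estimate, ypos, xlim = xlim, yaxt = "n", ylab = "",
                 xlab = attr(x, "kind"), pch = ifelse(
                   x$significance == "fdr_significant", 19, 1),
                 col = col, ...)
  graphics::axis(2, at = ypos, labels = x$qid, las = 1, cex.axis = 0.7)
  graphics::segments(x$ci_low, ypos, x$ci_high, ypos, col = col)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
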