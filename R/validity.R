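#' Spearman rank correlation with tie-aware average ranks
#'
#' Rank correlation computed as the Pearson correlation of average ranks,
#' with a two-sided p-value from the t approximation (the standard choice in
#' the presence of ties). Constant input yields an \code{NA} correlation,
#' flagged rather than silently zeroed.
#'
#' @param x,y Paired numeric vectors, \code{n >= 3}.
#' @return List with \code{rho}, \code{p}, \code{n}.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^2)$rho  # 1: monotone transform
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n))
  rho <- stats::cor(rank(x), rank(y))
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  list(rho = rho, p = p, n = n)
}

#' Construct-validity report for extracted features
#'
#' Quantifies how well each extracted feature tracks the external construct
#' it is meant to measure: clinical-symptom features are compared against
#' their linked PHQ-8 item scores, and linguistic-pattern features against
#' their lexicon-based reference metrics, via Spearman correlation. Questions
#' without a \code{reference_metric} link (emotion differentiation, cognitive
#' distortions, controls) are skipped -- no reference exists for them.
#' P-values are FDR-adjusted jointly across all linked features in the set.
#'
#' Following the original design, run this on training participants only.
#'
#' @param fm A [feature_matrix].
#' @param labels Label data frame (see [read_labels]); needs
#'   \code{phq8_item1..8} columns for the clinical links, otherwise those rows
#'   are flagged unavailable.
#' @param metrics Data frame of per-participant linguistic metrics (rbind of
#'   [linguistic_metrics] rows).
#' @param questions The \code{"question_set"} the matrix was extracted with.
#' @return A \code{"validity_report"} data frame: one row per linked
#'   question, with \code{qid}, \code{reference}, \code{rho}, \code{p},
#'   \code{q}, \code{n}, \code{available}.
#' @export
validity_report <- function(fm, labels, metrics, questions) {
  linked <- questions[!is.na(questions$reference_metric), , drop = FALSE]
  if (!nrow(linked)) stop("question set has no reference-linked questions")
  ids <- rownames(fm)
  labels <- labels[match(ids, labels$participant_id), , drop = FALSE]
  metrics <- metrics[match(ids, metrics$participant_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(linked)), function(k) {
    qid <- linked$qid[k]
    ref <- linked$reference_metric[k]
    ref_values <- if (startsWith(ref, "phq8_item")) {
      if (ref %in% names(labels)) labels[[ref]] else NULL
    } else {
      if (ref %in% names(metrics)) metrics[[ref]] else NULL
    }
    if (is.null(ref_values) || all(is.na(ref_values)))
      return(data.frame(qid = qid, reference = ref, rho = NA_real_,
                        p = NA_real_, q = NA_real_, n = 0L,
                        available = FALSE, stringsAsFactors = FALSE))
    s <- spearman_rho(fm[, qid], ref_values)
    data.frame(qid = qid, reference = ref, rho = s$rho, p = s$p, q = NA_real_,
               n = s$n, available = TRUE, stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  usable <- rep$available & !is.na(rep$p)
  rep$q[usable] <- fdr_adjust(rep$p[usable])
  class(rep) <- c("validity_report", "data.frame")
  rep
}
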