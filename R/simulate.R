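# Synthetic cohorts: latent severity, PHQ-8 items/totals, 0-10 feature
# matrices with category-structured correlated noise, and cue-word
# transcripts the mock backend can score -- so the whole pipeline runs with
# no corpus access.

#' Specify a synthetic cohort
#'
#' The generative model: each participant draws an integer severity
#' \eqn{s \in [0, 24]} from a right-skewed distribution (screening-cohort
#' shaped: most mass below 10, tail to 24), PHQ-8 items are allocated to sum
#' to \eqn{s} under the per-item cap of 3, and each question's 0-10 score is
#' \deqn{x_{iq} = round(clip(b_q + \lambda_q \cdot 10 s_i/24 +
#'   \varepsilon_{iq},\ 0,\ 10))}
#' with baseline \eqn{b_q = 0} for positively loaded questions and 10 for
#' negatively loaded ones (reverse-keyed items such as positive sentiment),
#' and \eqn{\varepsilon} Gaussian with SD \eqn{\sigma_q}, equicorrelated
#' \eqn{\rho} within each feature category.
#'
#' @param n Number of participants.
#' @param seed Integer seed; the whole cohort is deterministic given the spec.
#' @param preset Loading preset: \code{"strong"} (defaults below) or
#'   \code{"null"} (all loadings zero -- features carry no severity signal).
#' @param lambda Named per-question loadings; default (strong): 0.9 for the
#'   clinical items, -0.9/0.9/0.6/-0.6/-0.5 for Q9-Q13 (positive sentiment,
#'   present focus and emotion differentiation reverse-keyed), 0.8 for the
#'   distortions.
#' @param sigma Noise SD on the 0-10 scale (scalar or per question);
#'   default 1.5.
#' @param rho Within-category residual correlation; default 0.3.
#' @param severity_probs Probability weights over severities 0..24; default
#'   a discretized right-skewed Beta(1.6, 3.2) shape.
#' @param questions Question set to simulate scores for; default
#'   depression23.
#' @return A \code{"cohort_spec"} list.
#' @export
cohort_spec <- function(n, seed = 0L, preset = c("strong", "null"),
                        lambda = NULL, sigma = 1.5, rho = 0.3,
                        severity_probs = NULL,
                        questions = question_set("depression23")) {
  preset <- match.arg(preset)
  qids <- questions$qid
  if (is.null(lambda)) {
    lambda <- switch(preset,
      strong = stats::setNames(
        c(rep(0.9, 8), -0.9, 0.9, 0.6, -0.6, -0.5, rep(0.8, 10))[seq_along(qids)],
        qids),
      null = stats::setNames(rep(0, length(qids)), qids))
  }
  if (is.null(names(lambda))) names(lambda) <- qids
  if (!all(qids %in% names(lambda)))
    stop("lambda missing for: ", paste(setdiff(qids, names(lambda)), collapse = ", "))
  sigma <- if (length(sigma) == 1L) stats::setNames(rep(sigma, length(qids)), qids)
           else sigma
  if (is.null(severity_probs)) {
    grid <- (0:24 + 0.5) / 25
    severity_probs <- stats::dbeta(grid, 1.6, 3.2)
  }
  severity_probs <- severity_probs / sum(severity_probs)
  stopifnot(length(severity_probs) == 25L, all(severity_probs >= 0),
            n >= 1L, rho >= 0, rho < 1, all(sigma[qids] >= 0))
  structure(list(n = as.integer(n), seed = as.integer(seed), preset = preset,
                 lambda = lambda[qids], sigma = sigma[qids], rho = rho,
                 severity_probs = severity_probs, questions = questions),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec].
#' @return List with \code{features} (a [feature_matrix] of simulated 0-10
#'   scores), \code{labels} (participant_id, phq8_total, phq8_item1..8) and
#'   \code{truth} (the generating severity, loadings, noise SD and
#'   correlation -- for parameter-recovery checks).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(20, seed = 1))
#' stopifnot(all(rowSums(cohort$labels[paste0("phq8_item", 1:8)]) ==
#'               cohort$labels$phq8_total))
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  qs <- spec$questions
  qids <- qs$qid
  ids <- sprintf("S%04d", seq_len(spec$n))
  with_local_rng(spec$seed, {
    s <- sample(0:24, spec$n, replace = TRUE, prob = spec$severity_probs)
    items <- t(vapply(s, function(tot) {
      it <- integer(8L)
      for (k in seq_len(tot)) {
        open <- which(it < 3L)
        pick <- open[sample.int(length(open), 1L)]
        it[pick] <- it[pick] + 1L
      }
      it
    }, integer(8L)))
    cat_of <- qs$category
    z_cat <- matrix(stats::rnorm(spec$n * length(unique(cat_of))), spec$n,
                    dimnames = list(NULL, unique(cat_of)))
    values <- matrix(NA_integer_, spec$n, length(qids),
                     dimnames = list(ids, qids))
    for (j in seq_along(qids)) {
      lam <- spec$lambda[j]
      b <- if (lam >= 0) 0 else 10
      eps <- spec$sigma[j] * (sqrt(spec$rho) * z_cat[, cat_of[j]] +
                              sqrt(1 - spec$rho) * stats::rnorm(spec$n))
      values[, j] <- pmin(pmax(round(b + lam * 10 * s / 24 + eps), 0L), 10L)
    }
    labels <- data.frame(participant_id = ids, phq8_total = s,
                         stringsAsFactors = FALSE)
    labels[paste0("phq8_item", 1:8)] <- items
    list(features = feature_matrix(values, attr(qs, "name") %||% "custom",
                                   backend_id = "simulated", seed = spec$seed),
         labels = validate_labels(labels),
         truth = list(severity = stats::setNames(s, ids),
                      lambda = spec$lambda, sigma = spec$sigma,
                      rho = spec$rho, preset = spec$preset))
  })
}

# token pools for synthetic participant speech; chosen to avoid every
# lexicon entry so planted lexicon tokens alone drive the metrics
filler_tokens <- c("well", "okay", "yeah", "um", "uh", "like", "know",
                   "think", "kind", "sort", "really", "just", "stuff",
                   "things", "work", "school", "day", "week", "people",
                   "place", "home", "maybe", "pretty", "much", "lot",
                   "bit", "somewhere", "around", "about", "over")

interviewer_turns <- c(
  "how are you doing today",
  "tell me about where you are from",
  "how have you been sleeping lately",
  "what do you do when you are not working",
  "how would you describe your mood recently",
  "what are you like when you do not sleep well",
  "is there anything you wish you could change",
  "okay thanks for sharing that")

#' Generate cue-word transcripts for a synthetic cohort
#'
#' Builds one interviewer/participant transcript per participant. For every
#' question in the cohort's set, the participant's turns contain exactly as
#' many copies of that question's cue token (e.g. \code{"q2cue"}) as the
#' participant's ground-truth feature value, so mock-backend extraction
#' recovers the simulated feature matrix. Lexicon tokens (tone words,
#' pronouns, tense markers) are planted in proportion to the Q9-Q12 feature
#' values so lexicon reference metrics track the same constructs. Control
#' cue tokens (\code{nq*cue}) are planted with severity-independent counts,
#' and the direct-severity cue (\code{dq1cue}) with a noisy severity-graded
#' count. No linguistic realism is attempted.
#'
#' @param cohort Output of [generate_cohort].
#' @param seed Integer seed (transcripts deterministic given cohort + seed).
#' @param lexicon Lexicon used for planting reference tokens.
#' @return Named list of [transcript] objects.
#' @export
generate_transcripts <- function(cohort, seed = 0L,
                                 lexicon = default_lexicon()) {
  fm <- cohort$features
  ids <- rownames(fm)
  sev <- cohort$truth$severity
  has <- function(q) q %in% colnames(fm)
  lapply(stats::setNames(seq_along(ids), ids), function(i) {
    with_local_rng(seed + 131L * i, {
      toks <- character(0)
      for (q in colnames(fm))
        toks <- c(toks, rep(cue_token(q), fm[i, q]))
      toks <- c(toks, rep(cue_token("DQ1"),
                          min(max(round(10 * sev[i] / 24 +
                                        stats::rnorm(1, 0, 1.5)), 0L), 10L)))
      for (k in 1:10)
        toks <- c(toks, rep(cue_token(paste0("NQ", k)), sample(0:10, 1L)))
      plant <- function(pool, count)
        if (count > 0L) sample(pool, count, replace = TRUE) else character(0)
      if (has("Q9")) toks <- c(toks, plant(lexicon$tone_positive, fm[i, "Q9"]))
      if (has("Q10")) toks <- c(toks, plant(lexicon$tone_negative, fm[i, "Q10"]))
      if (has("Q11")) {
        toks <- c(toks, plant(c("i", "my", "me", "we"), fm[i, "Q11"] + 1L),
                  plant(c("they", "them", "their", "he", "she"),
                        10L - fm[i, "Q11"] + 1L))
      }
      if (has("Q12")) {
        toks <- c(toks, plant(c("am", "is", "are", "now"), fm[i, "Q12"] + 1L),
                  plant(c("was", "were", "did", "ago"), 10L - fm[i, "Q12"] + 1L),
                  plant(c("will", "soon"), 1L))
      }
      toks <- c(toks, sample(filler_tokens, 40L, replace = TRUE))
      toks <- sample(toks)
      n_turns <- length(interviewer_turns)
      turn_of <- sort(rep_len(seq_len(n_turns), length(toks)))
      speaker <- rep(c("Ellie", "Participant"), n_turns)
      text <- as.vector(rbind(interviewer_turns,
                              vapply(seq_len(n_turns), function(k) {
                                tk <- toks[turn_of == k]
                                if (!length(tk)) "mm hmm" else paste(tk, collapse = " ")
                              }, "")))
      transcript(ids[i], speaker, text)
    })
  })
}

#' Write a synthetic study to disk
#'
#' Materializes a cohort as the file layout the pipeline consumes: one
#' transcript file per participant (DAIC-WOZ-style TSV or plain text),
#' \code{labels.csv}, \code{split.csv} (a seeded random partition into
#' train / test1 / test2) and \code{truth.json}.
#'
#' @param cohort Output of [generate_cohort].
#' @param dir Output directory (created).
#' @param n_train,n_test1,n_test2 Partition sizes; must sum to the cohort
#'   size.
#' @param seed Seed for the transcript generator and the split shuffle.
#' @param dialect Transcript file format.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, n_train, n_test1, n_test2,
                         seed = 0L, dialect = c("daicwoz_tsv", "plain_text")) {
  dialect <- match.arg(dialect)
  ids <- rownames(cohort$features)
  if (n_train + n_test1 + n_test2 != length(ids))
    stop("partition sizes must sum to the cohort size")
  dir.create(file.path(dir, "transcripts"), recursive = TRUE,
             showWarnings = FALSE)
  trs <- generate_transcripts(cohort, seed = seed)
  for (id in ids) {
    u <- trs[[id]]$utterances
    if (dialect == "daicwoz_tsv") {
      start <- seq(0, by = 5, length.out = nrow(u))
      tab <- data.frame(start_time = start, stop_time = start + 4,
                        speaker = ifelse(u$speaker == "interviewer",
                                         "Ellie", "Participant"),
                        value = u$text)
      utils::write.table(tab, file.path(dir, "transcripts",
                                        paste0(id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else {
      writeLines(paste0(ifelse(u$speaker == "interviewer", "Ellie",
                               "Participant"), ": ", u$text),
                 file.path(dir, "transcripts", paste0(id, ".txt")))
    }
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  shuffled <- with_local_rng(seed + 1L, sample(ids))
  split_df <- data.frame(
    participant_id = shuffled,
    partition = rep(c("train", "test1", "test2"),
                    c(n_train, n_test1, n_test2)),
    stringsAsFactors = FALSE)
  utils::write.csv(split_df, file.path(dir, "split.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
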