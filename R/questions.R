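# Built-in prompting question banks.
#
# depression23: 23 items spanning three domains with established depression
# links -- clinical symptoms (Q1-Q8, adapted from the PHQ-8 items, one per DSM-5
# criterion), linguistic patterns (Q9-Q13: sentiment, social/temporal focus,
# emotion differentiation), and cognitive distortions (Q14-Q23, the ten
# representative types from the Cognitive Distortion Scale).
#
# control_nq: a 10-item non-clinical control bank used to check that
# predictive power comes from depression-relevant content rather than generic
# text comprehension. The texts here are placeholders on the documented themes
# (political opinions, musical interests, food preferences); substitute your
# own set via read_question_set() if you have one.
#
# direct_dq: a single direct severity question for end-to-end comparison.

depression23_texts <- c(
    "How much does Participant express having little interest or pleasure in doing things?",
    "How much does Participant express feeling down, depressed, irritable or hopeless?",
    "How much does Participant express trouble falling or staying asleep, or sleeping too much?",
    "How much does Participant express feeling tired or having little energy?",
    "How much does Participant express poor appetite or overeating?",
    "How much does Participant express feeling bad about themselves – or that they are a failure or have let themselves or their family down?",
    "How much does Participant express trouble concentrating on things, such as school work, reading or watching television?",
    "How much does Participant express moving or speaking so slowly that other people could have noticed? Or the opposite – being so fidgety or restless that they have been moving around a lot more than usual?",
    "How positive is Participant’s sentiment?",
    "How negative is Participant’s sentiment?",
    "To what extent is Participant’s language self-focused compared to other-focused (e.g., “I” vs. “They”)?",
    "To what extent is Participant’s language present-focused compared to past- or future-focused (e.g., “I’m” vs. “I used to”)?",
    "How effectively does Participant differentiate between similar emotions with distinct nuances (e.g., “sad” vs. “disappointed”)?",
    "(Mindreading) To what extent does Participant assume others are thinking negatively about them without sufficient evidence? (e.g., “My boss hasn’t replied to the email I sent about the project days ago. He must think I’m incompetent.”)",
    "(Catastrophizing) To what extent does Participant make negative predictions about the future without sufficient evidence? (e.g., “My boyfriend wants to spend more time with his friends. We’ll be distant and eventually break up.”)",
    "(All-or-Nothing Thinking) To what extent does Participant view situations in extremes, without considering middle ground? (e.g., “I got a B+ on the exam, not an A. I’m a failure.”)",
    "(Emotional Reasoning) To what extent does Participant believe something is true because it feels that way, even when the evidence suggests otherwise? (e.g., “My friends couldn’t get enough tickets for the concert. I know they didn’t mean to exclude me, but I feel rejected and believe they did.”)",
    "(Labeling) To what extent does Participant assign negative labels to themselves based on specific incidents? (e.g., “I asked a woman to dance and she turned me down. I am a loser.”)",
    "(Mental Filter) To what extent does Participant focus only on negative details, ignoring positive aspects? (e.g., “My boyfriend said I’m smart and fun, but also mentioned I’m demanding. I’m fixating on that comment and feeling bad.”)",
    "(Overgeneralization) To what extent does Participant assume that one negative event will lead to a pattern of failures? (e.g., “I failed my math exam. I’ll probably fail the exams in my other courses as well.”)",
    "(Personalization) To what extent does Participant assume personal responsibility for negative events that aren’t their fault? (e.g., “My company didn’t get the important contract. It must be my fault.”)",
    "(Should Statements) To what extent does Participant think that things should or must be a certain way? (e.g., “I should always get at least a 90 on my exams. I’m upset because I got an 85.”)",
    "(Minimizing or Disqualifying the Positive) To what extent does Participant ignore the positive things that happen to them? (e.g., “My boss said I did a great job on the sale, but I just got lucky with that. It wasn’t really because of my skill.”)")

control_nq_texts <- c(
  "How much does Participant express opinions about politics or current events?",
  "How much does Participant express interest in music or musical activities?",
  "How much does Participant express preferences about food or cooking?",
  "How much does Participant talk about travel or places they have visited?",
  "How much does Participant talk about movies or television shows?",
  "How much does Participant express interest in sports or physical exercise?",
  "How much does Participant talk about the weather or their local area?",
  "How much does Participant talk about technology or gadgets?",
  "How much does Participant express opinions about books or reading?",
  "How much does Participant talk about pets or animals?")

direct_dq_text <- "How severe are Participant’s depressive symptoms?"

#' Built-in question sets for prompt-based feature scoring
#'
#' @param name One of:
#'   \describe{
#'     \item{\code{"depression23"}}{the 23 depression-informed items: Q1-Q8
#'       clinical symptoms (each linked to its PHQ-8 item for validity
#'       checks), Q9-Q13 linguistic patterns (Q9-Q12 linked to lexicon
#'       reference metrics), Q14-Q23 cognitive distortions (no reference
#'       metric exists).}
#'     \item{\code{"control_nq"}}{10 non-depression control questions
#'       (placeholder texts on non-clinical themes; substitutable).}
#'     \item{\code{"direct_dq"}}{a single direct severity question.}
#'   }
#' @return A \code{"question_set"}: a data frame with columns \code{qid},
#'   \code{category}, \code{text}, \code{reference_metric} and a \code{"name"}
#'   attribute. Categories are \code{clinical_symptoms},
#'   \code{linguistic_patterns}, \code{cognitive_distortions}, \code{control},
#'   \code{direct_severity}.
#' @export
#' @examples
#' qs <- question_set("depression23")
#' table(qs$category)
question_set <- function(name = c("depression23", "control_nq", "direct_dq")) {
  name <- match.arg(name)
  qs <- switch(name,
    depression23 = data.frame(
      qid = paste0("Q", 1:23),
      category = rep(c("clinical_symptoms", "linguistic_patterns",
                       "cognitive_distortions"), c(8L, 5L, 10L)),
      text = depression23_texts,
      reference_metric = c(paste0("phq8_item", 1:8),
                           "tone_pos_rate", "tone_neg_rate",
                           "self_focus_ratio", "present_focus_ratio",
                           rep(NA_character_, 11L)),
      stringsAsFactors = FALSE),
    control_nq = data.frame(
      qid = paste0("NQ", 1:10),
      category = "control",
      text = control_nq_texts,
      reference_metric = NA_character_,
      stringsAsFactors = FALSE),
    direct_dq = data.frame(
      qid = "DQ1",
      category = "direct_severity",
      text = direct_dq_text,
      reference_metric = NA_character_,
      stringsAsFactors = FALSE))
  attr(qs, "name") <- name
  class(qs) <- c("question_set", "data.frame")
  validate_question_set(qs)
  qs
}

#' Load a custom question set from YAML or JSON
#'
#' The file holds a list of records with fields \code{qid}, \code{category},
#' \code{text} and optional \code{reference_metric} (a \code{phq8_item1..8}
#' label or a lexicon metric id). The set is validated with
#' [validate_question_set()] before being returned.
#'
#' @param path Path to a \code{.yml}/\code{.yaml} or \code{.json} file.
#' @param name Set name; defaults to the file name without extension.
#' @return A \code{"question_set"} data frame.
#' @export
read_question_set <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind, lapply(yaml::read_yaml(path), function(r)
      data.frame(qid = r$qid %||% NA_character_,
                 category = r$category %||% NA_character_,
                 text = r$text %||% NA_character_,
                 reference_metric = r$reference_metric %||% NA_character_,
                 stringsAsFactors = FALSE)))
  }
  qs <- as.data.frame(recs, stringsAsFactors = FALSE)
  if (is.null(qs$reference_metric)) qs$reference_metric <- NA_character_
  attr(qs, "name") <- name %||% sub("\\.[^.]*$", "", basename(path))
  class(qs) <- c("question_set", "data.frame")
  validate_question_set(qs)
  qs
}

#' Validate a question set
#'
#' Checks the schema: unique non-empty qids, known categories, non-empty
#' texts, and reference-metric links that resolve to a PHQ-8 item
#' (\code{phq8_item1..8}) or a lexicon metric (\code{tone_pos_rate},
#' \code{tone_neg_rate}, \code{self_focus_ratio}, \code{present_focus_ratio}).
#'
#' @param qs A \code{"question_set"} or data frame with the same columns.
#' @param stop_on_error Throw on the first violation (default) or return the
#'   report.
#' @return Invisibly, a character vector of violations (empty when valid).
#' @export
validate_question_set <- function(qs, stop_on_error = TRUE) {
  problems <- character(0)
  need <- c("qid", "category", "text")
  if (!all(need %in% names(qs))) {
    problems <- paste("missing columns:", paste(setdiff(need, names(qs)), collapse = ", "))
  } else {
    if (anyNA(qs$qid) || any(!nzchar(qs$qid)))
      problems <- c(problems, "empty qid")
    dup <- unique(qs$qid[duplicated(qs$qid)])
    if (length(dup))
      problems <- c(problems, paste0("duplicate qid: ", dup))
    known_cat <- c("clinical_symptoms", "linguistic_patterns",
                   "cognitive_distortions", "control", "direct_severity")
    bad_cat <- which(!qs$category %in% known_cat)
    if (length(bad_cat))
      problems <- c(problems, sprintf("%s: unknown category %s",
                                      qs$qid[bad_cat], dQuote(qs$category[bad_cat])))
    empty <- which(is.na(qs$text) | !nzchar(trimws(qs$text)))
    if (length(empty))
      problems <- c(problems, paste0(qs$qid[empty], ": empty question text"))
    refs <- qs$reference_metric %||% rep(NA_character_, nrow(qs))
    known_ref <- c(paste0("phq8_item", 1:8), "tone_pos_rate", "tone_neg_rate",
                   "self_focus_ratio", "present_focus_ratio")
    bad_ref <- which(!is.na(refs) & !refs %in% known_ref)
    if (length(bad_ref))
      problems <- c(problems, sprintf("%s: dangling reference_metric %s",
                                      qs$qid[bad_ref], dQuote(refs[bad_ref])))
  }
  if (length(problems) && stop_on_error)
    stop("invalid question set:\n  ", paste(problems, collapse = "\n  "))
  invisible(problems)
}

#' @export
print.question_set <- function(x, ...) {
  cat(sprintf("<question_set> %s: %d questions\n", attr(x, "name") %||% "?", nrow(x)))
  print(table(category = x$category))
  invisible(x)
}
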