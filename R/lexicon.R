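# Lexicon-based linguistic reference metrics.
#
# These serve as construct-validity references for the linguistic-pattern
# questions: positive/negative tone rates for the sentiment items, the
# first-person share of pronouns for self-focus, and the present-tense share
# of tense markers for temporal focus. The shipped lexicon is a compact open
# stand-in for proprietary dictionaries: pronoun and tense closed classes are
# faithful, tone lists are approximate and labelled heuristic.

lexicon_categories <- c("first_person", "second_person", "third_person",
                        "third_plural", "tense_present", "tense_past",
                        "tense_future", "tone_positive", "tone_negative")

#' Load a word-category lexicon
#'
#' \code{default_lexicon()} returns the lexicon shipped with the package;
#' \code{read_lexicon(path)} loads a user-supplied YAML file with the same
#' layout (one lowercase word list per category; see
#' \code{system.file("extdata", "lexicon.yml", package = "phqlm")}).
#'
#' @return A \code{"lexicon"}: a named list of character vectors, validated
#'   to be lowercase, duplicate-free, with pairwise-disjoint pronoun
#'   categories.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yml", package = "phqlm"))
}

#' @rdname default_lexicon
#' @param path Path to a lexicon YAML file.
#' @export
read_lexicon <- function(path) {
  lex <- yaml::read_yaml(path)
  missing <- setdiff(lexicon_categories, names(lex))
  if (length(missing))
    stop("lexicon missing categories: ", paste(missing, collapse = ", "))
  lex <- lapply(lex[lexicon_categories], as.character)
  for (cat in lexicon_categories) {
    words <- lex[[cat]]
    if (any(words != tolower(words)))
      stop("lexicon category ", cat, " contains non-lowercase entries")
    if (anyDuplicated(words))
      stop("lexicon category ", cat, " contains duplicates")
  }
  pronoun_cats <- c("first_person", "second_person", "third_person", "third_plural")
  all_pronouns <- unlist(lex[pronoun_cats], use.names = FALSE)
  if (anyDuplicated(all_pronouns))
    stop("pronoun categories overlap: ",
         paste(unique(all_pronouns[duplicated(all_pronouns)]), collapse = ", "))
  structure(lex, class = "lexicon")
}

#' Tokenize a participant's utterances
#'
#' Lowercased word tokens from participant utterances only (interviewer text
#' is never counted). Apostrophe-bearing contractions are kept whole
#' (\code{"i'm"} is one token); curly apostrophes are normalized to ASCII;
#' digits and punctuation are dropped. Deterministic.
#'
#' @param t A [transcript] passing QC.
#' @return Character vector of tokens.
#' @export
#' @examples
#' t <- transcript("P1", c("Ellie", "Participant"), c("hi", "I'm fine, thanks."))
#' tokenize_participant_text(t)
tokenize_participant_text <- function(t) {
  stopifnot(inherits(t, "transcript"))
  txt <- t$utterances$text[t$utterances$speaker == "participant"]
  txt <- tolower(paste(txt, collapse = " "))
  txt <- gsub("\u2019", "'", txt, fixed = TRUE)
  toks <- regmatches(txt, gregexpr("[a-z]+(?:'[a-z]+)*", txt))[[1L]]
  toks
}

#' Compute lexicon-based linguistic metrics for one participant
#'
#' Tone rates are matched tokens per 100 tokens. The self-focus ratio is the
#' first-person share among all matched pronouns; the present-focus ratio is
#' the present-tense share among all matched tense markers. A ratio whose
#' denominator category has zero matches is returned as \code{NA} (flagged
#' absent), never as 0.
#'
#' @param t A [transcript] passing QC.
#' @param lexicon A \code{"lexicon"}; default [default_lexicon()].
#' @return A one-row data frame with \code{participant_id},
#'   \code{tone_pos_rate}, \code{tone_neg_rate}, \code{self_focus_ratio},
#'   \code{present_focus_ratio}, \code{token_count}.
#' @export
linguistic_metrics <- function(t, lexicon = default_lexicon()) {
  toks <- tokenize_participant_text(t)
  if (!length(toks)) stop("no participant tokens in ", t$participant_id)
  n <- length(toks)
  count <- function(cat) sum(toks %in% lexicon[[cat]])
  pronouns <- count("first_person") + count("second_person") +
    count("third_person") + count("third_plural")
  tenses <- count("tense_present") + count("tense_past") + count("tense_future")
  data.frame(
    participant_id = t$participant_id,
    tone_pos_rate = 100 * count("tone_positive") / n,
    tone_neg_rate = 100 * count("tone_negative") / n,
    self_focus_ratio = if (pronouns > 0) count("first_person") / pronouns else NA_real_,
    present_focus_ratio = if (tenses > 0) count("tense_present") / tenses else NA_real_,
    token_count = n,
    stringsAsFactors = FALSE)
}
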