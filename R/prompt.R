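# The fixed scoring-prompt template. The interview body replaces
# [INSERT_INTERVIEW] and the question text replaces [INSERT_QUESTION]; the
# same template file ships in inst/extdata/prompt_template.txt.
prompt_template <- paste(
  "The following text is a semi-structured clinical interview conducted by the virtual interviewer “Ellie” with interviewee “Participant” with varying depressive symptoms.",
  "[Interview]",
  "[INSERT_INTERVIEW]",
  "[End of interview]",
  "Based on the interview text, answer the following question.",
  "Question: [INSERT_QUESTION]",
  "Answer should be a score between 0 and 10, where 0 means “Not at all” and 10 means “Extremely”. Return only the score.",
  sep = "\n\n")

#' Decoding configuration for a scoring backend
#'
#' Two presets are built in. The \code{deterministic} preset emulates greedy
#' decoding (\code{top_p = 0}, \code{temperature = 1e-4}) so repeated calls
#' give one fixed answer per prompt; \code{max_new_tokens} defaults to 4
#' rather than 1 so that a two-token completion such as \code{"10"} is never
#' truncated under tokenizations that split it (the strict [parse_score]
#' still enforces a single integer). The \code{stochastic} preset
#' (\code{top_p = 0.8}, \code{temperature = 0.7}) allows variable responses
#' across repeated runs.
#'
#' @param preset \code{"deterministic"}, \code{"stochastic"} or
#'   \code{"custom"}.
#' @param top_p Nucleus-sampling mass in \code{[0, 1]}.
#' @param temperature Softmax temperature, \code{> 0}.
#' @param max_new_tokens Positive integer cap on generated tokens.
#' @return A \code{"decoding_config"} list.
#' @export
decoding_config <- function(preset = c("deterministic", "stochastic", "custom"),
                            top_p = NULL, temperature = NULL,
                            max_new_tokens = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    deterministic = list(top_p = 0, temperature = 1e-4, max_new_tokens = 4L),
    stochastic = list(top_p = 0.8, temperature = 0.7, max_new_tokens = 4L),
    custom = list(top_p = 0.9, temperature = 1, max_new_tokens = 4L))
  cfg <- list(preset = preset,
              top_p = top_p %||% defaults$top_p,
              temperature = temperature %||% defaults$temperature,
              max_new_tokens = as.integer(max_new_tokens %||% defaults$max_new_tokens))
  stopifnot(cfg$top_p >= 0, cfg$top_p <= 1, cfg$temperature > 0,
            cfg$max_new_tokens >= 1L)
  structure(cfg, class = "decoding_config")
}

#' Assemble the scoring prompt for one (interview, question) pair
#'
#' Substitutes the rendered interview text and the question text into the
#' fixed template. The framing sentence, the \code{[Interview]} /
#' \code{[End of interview]} markers, the 0-10 anchor sentence and the final
#' \code{"Return only the score."} instruction each appear exactly once.
#'
#' @param interview_text Rendered interview body (see [render_interview]).
#' @param question_text One question's text.
#' @return The complete prompt string.
#' @export
#' @examples
#' p <- assemble_prompt("Ellie: hi\nParticipant: hello",
#'                      question_set("direct_dq")$text)
#' cat(substr(p, 1, 60), "...\n")
assemble_prompt <- function(interview_text, question_text) {
  stopifnot(is.character(interview_text), length(interview_text) == 1L,
            nzchar(interview_text),
            is.character(question_text), length(question_text) == 1L,
            nzchar(question_text))
  out <- sub("[INSERT_INTERVIEW]", interview_text, prompt_template, fixed = TRUE)
  sub("[INSERT_QUESTION]", question_text, out, fixed = TRUE)
}

#' Parse a backend completion into a 0-10 score
#'
#' Strict mode: after trimming whitespace the completion must be a bare
#' base-10 integer in \code{[0, 10]}. Anything else raises a condition of
#' class \code{"phqlm_parse_error"} (non-integer text) or
#' \code{"phqlm_range_error"} (integer outside the scale), both carrying the
#' raw completion in their \code{raw} field.
#'
#' @param raw Raw completion string from a scoring backend.
#' @return Integer score in 0..10.
#' @export
#' @examples
#' parse_score(" 7\n")
parse_score <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  s <- trimws(raw)
  if (!grepl("^[+-]?[0-9]+$", s))
    stop(structure(class = c("phqlm_parse_error", "error", "condition"),
                   list(message = sprintf("completion is not a bare integer: %s",
                                          dQuote(raw)),
                        call = sys.call(-1L), raw = raw)))
  v <- as.integer(s)
  if (is.na(v) || v < 0L || v > 10L)
    stop(structure(class = c("phqlm_range_error", "error", "condition"),
                   list(message = sprintf("score %s outside 0..10", s),
                        call = sys.call(-1L), raw = raw)))
  v
}
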