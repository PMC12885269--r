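#' Define a scoring backend
#'
#' A scoring backend is anything that maps a prompt string to a raw text
#' completion: a local instruction-tuned language model, a remote endpoint,
#' or the offline [mock_backend]. The contract is a function
#' \code{complete(prompt, config, seed)} returning a single string; a backend
#' declaring \code{deterministic = TRUE} must return identical completions
#' for identical \code{(prompt, config)}.
#'
#' @param id Short backend identifier recorded in feature-matrix metadata.
#' @param complete Function \code{(prompt, config, seed) -> character(1)}.
#' @param deterministic Does the backend guarantee reproducible completions?
#' @return A \code{"scoring_backend"} object. The number of completions
#'   served so far is available via [backend_calls()].
#' @export
scoring_backend <- function(id, complete, deterministic = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, is.function(complete))
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  structure(list(id = id, deterministic = isTRUE(deterministic),
                 complete = complete, counter = counter),
            class = "scoring_backend")
}

#' @rdname scoring_backend
#' @param backend A \code{"scoring_backend"}.
#' @export
backend_calls <- function(backend) backend$counter$n

call_backend <- function(backend, prompt, config, seed) {
  backend$counter$n <- backend$counter$n + 1L
  out <- backend$complete(prompt, config, seed)
  if (!is.character(out) || length(out) != 1L)
    stop("backend ", backend$id, " returned a non-string completion")
  out
}

#' @export
print.scoring_backend <- function(x, ...) {
  cat(sprintf("<scoring_backend> %s (%s), %d calls served\n", x$id,
              if (x$deterministic) "deterministic" else "stochastic",
              backend_calls(x)))
  invisible(x)
}

# Cue token planted by the synthetic generator for a given question id.
cue_token <- function(qid) paste0(tolower(qid), "cue")

#' Deterministic mock scoring backend
#'
#' An offline test double for a language model. It parses the prompt it is
#' handed (interview body between the \code{[Interview]} markers, question
#' after \code{"Question: "}), maps the question text back to its id using
#' the supplied question sets, and scores by counting that question's cue
#' token (e.g. \code{"q2cue"}) in the participant's lines -- the same tokens
#' [generate_transcripts] plants in proportion to the ground-truth feature
#' values. The count is mapped monotonically to 0-10 (capped at 10).
#'
#' Under a deterministic decoding preset the completion depends only on the
#' prompt; under the stochastic preset a seeded jitter of up to ±1 point
#' (clipped to 0-10) is added, reproducible from \code{(prompt, seed)} and
#' scaled by the configured temperature.
#'
#' @param question_sets List of question sets whose texts the backend should
#'   recognize; defaults to all built-in banks. Unrecognized questions score 0.
#' @return A \code{"scoring_backend"} with id \code{"mock"}.
#' @export
#' @examples
#' b <- mock_backend()
#' p <- assemble_prompt("Ellie: hi\nParticipant: q2cue q2cue",
#'                      question_set("depression23")$text[2])
#' b$complete(p, decoding_config("deterministic"), seed = 1)
mock_backend <- function(question_sets = list(question_set("depression23"),
                                              question_set("control_nq"),
                                              question_set("direct_dq"))) {
  registry <- do.call(rbind, lapply(question_sets, function(qs)
    data.frame(qid = qs$qid, text = qs$text, stringsAsFactors = FALSE)))
  complete <- function(prompt, config, seed) {
    q_text <- sub(".*\nQuestion: (.*)\n\nAnswer should be a score.*", "\\1", prompt)
    body <- sub(".*\\[Interview\\]\n\n(.*)\n\n\\[End of interview\\].*", "\\1", prompt)
    idx <- match(q_text, registry$text)
    if (is.na(idx)) return("0")
    lines <- strsplit(body, "\n", fixed = TRUE)[[1L]]
    part <- lines[startsWith(lines, "Participant: ")]
    cue <- cue_token(registry$qid[idx])
    n_cues <- sum(vapply(gregexpr(paste0("\\b", cue, "\\b"), part),
                         function(m) sum(m > 0L), 0L))
    score <- min(n_cues, 10L)
    if (identical(config$preset, "stochastic")) {
      # seeded +/-1 jitter; probability of moving grows with temperature
      p_move <- config$temperature / (1 + config$temperature)
      jitter <- with_local_rng(
        (string_seed(prompt) + as.integer(seed %% 1e6)) %% 2147483647L,
        sample(c(-1L, 0L, 1L), 1L,
               prob = c(p_move / 2, 1 - p_move, p_move / 2)))
      score <- min(max(score + jitter, 0L), 10L)
    }
    as.character(score)
  }
  scoring_backend("mock", complete, deterministic = TRUE)
}
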