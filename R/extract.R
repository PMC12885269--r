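#' Construct a feature matrix
#'
#' Participants x questions table of integer scores in 0-10 with provenance
#' metadata (question-set name, backend id, decoding config, seed, timestamp)
#' and a failure report listing any cells for which scoring failed.
#'
#' @param values Integer matrix, rows = participants, columns = qids.
#' @param question_set_name,backend_id,config,seed Provenance metadata.
#' @param failures Data frame of failed cells (participant_id, qid, reason),
#'   or NULL.
#' @return A \code{"feature_matrix"} object (an integer matrix with
#'   attributes \code{meta} and \code{failures}).
#' @export
feature_matrix <- function(values, question_set_name = "custom",
                           backend_id = "unknown", config = NULL, seed = NA,
                           failures = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("feature matrix needs participant row names and qid column names")
  ok <- is.na(values) | (values >= 0L & values <= 10L)
  if (!all(ok)) stop("feature values must be integers in 0..10")
  if (anyNA(values)) {
    listed <- if (is.null(failures)) character(0)
              else paste(failures$participant_id, failures$qid)
    miss <- which(is.na(values), arr.ind = TRUE)
    missing_keys <- paste(rownames(values)[miss[, 1L]], colnames(values)[miss[, 2L]])
    if (!all(missing_keys %in% listed))
      stop("missing cells must be listed in the failure report")
  }
  structure(values,
            meta = list(question_set = question_set_name,
                        backend = backend_id, config = config, seed = seed,
                        timestamp = format(Sys.time(), tz = "UTC")),
            failures = failures,
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<feature_matrix> %d participants x %d questions (%s, backend %s)\n",
              nrow(x), ncol(x), m$question_set, m$backend))
  nf <- NROW(attr(x, "failures"))
  if (nf) cat(sprintf("  %d failed cells (see attr(., 'failures'))\n", nf))
  invisible(x)
}

#' Extract features for a set of transcripts
#'
#' Runs the full prompting protocol: renders each transcript, assembles one
#' prompt per (participant, question), queries the backend, and parses each
#' completion into a 0-10 score. Parse or range failures are retried with
#' fresh draws under the stochastic preset (up to \code{retries} attempts);
#' under the deterministic preset a failure is final, since greedy decoding
#' would return the same completion again. Failed cells are recorded in the
#' failure report attached to the result, never silently imputed.
#'
#' When \code{cache_dir} is given, each scored cell is written to disk keyed
#' by (participant text, qid, backend id, decoding config, question text), so
#' interrupted or repeated runs only query the backend for missing cells.
#'
#' @param transcripts List of [transcript] objects, all QC-ok.
#' @param questions A \code{"question_set"}.
#' @param backend A \code{"scoring_backend"}; defaults to [mock_backend()].
#' @param config A [decoding_config]; default deterministic.
#' @param seed Integer seed forwarded to the backend.
#' @param retries Maximum attempts per cell under the stochastic preset.
#' @param cache_dir Optional directory for the on-disk cell cache.
#' @return A [feature_matrix].
#' @export
#' @examples
#' tr <- transcript("P1", c("Ellie", "Participant"), c("hi", "hello q1cue"))
#' extract_features(list(tr), question_set("direct_dq"))
extract_features <- function(transcripts, questions,
                             backend = mock_backend(),
                             config = decoding_config("deterministic"),
                             seed = 0L, retries = 3L, cache_dir = NULL) {
  stopifnot(inherits(backend, "scoring_backend"),
            inherits(config, "decoding_config"))
  if (inherits(transcripts, "transcript")) transcripts <- list(transcripts)
  qc <- vapply(transcripts, qc_missing_party, "")
  if (any(qc != "ok"))
    stop("transcript(s) fail QC: ",
         paste(vapply(transcripts[qc != "ok"], function(t) t$participant_id, ""),
               collapse = ", "))
  ids <- vapply(transcripts, function(t) t$participant_id, "")
  if (anyDuplicated(ids)) stop("duplicated participant ids")
  qids <- questions$qid
  values <- matrix(NA_integer_, length(ids), length(qids),
                   dimnames = list(ids, qids))
  failures <- list()
  cache <- if (!is.null(cache_dir)) cell_cache(cache_dir) else NULL
  for (i in seq_along(transcripts)) {
    body <- render_interview(transcripts[[i]])
    for (j in seq_along(qids)) {
      key <- if (!is.null(cache))
        cache_key(body, qids[j], questions$text[j], backend$id, config) else NULL
      if (!is.null(cache)) {
        hit <- cache$get(key)
        if (!is.null(hit)) { values[i, j] <- hit; next }
      }
      res <- score_one_cell(backend, body, questions$text[j], config, seed, retries)
      if (is.null(res$value)) {
        failures[[length(failures) + 1L]] <-
          data.frame(participant_id = ids[i], qid = qids[j],
                     reason = res$reason, attempts = res$attempts,
                     stringsAsFactors = FALSE)
      } else {
        values[i, j] <- res$value
        if (!is.null(cache)) cache$put(key, res$value)
      }
    }
  }
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  feature_matrix(values, attr(questions, "name") %||% "custom",
                 backend$id, config, seed, failures)
}

score_one_cell <- function(backend, body, question_text, config, seed, retries) {
  max_attempts <- if (identical(config$preset, "deterministic")) 1L
                  else max(1L, as.integer(retries))
  reason <- "unknown"
  for (attempt in seq_len(max_attempts)) {
    raw <- call_backend(backend, assemble_prompt(body, question_text), config,
                        seed + (attempt - 1L) * 7919L)
    value <- tryCatch(parse_score(raw), error = function(e) {
      reason <<- conditionMessage(e)
      NULL
    })
    if (!is.null(value))
      return(list(value = value, attempts = attempt))
  }
  list(value = NULL, reason = reason, attempts = max_attempts)
}

# content-addressed cell cache: one small file per scored cell
cache_key <- function(body, qid, question_text, backend_id, config) {
  md5_string(paste(md5_string(body), qid, md5_string(question_text), backend_id,
                   config$preset, config$top_p, config$temperature,
                   config$max_new_tokens, sep = "|"))
}

cell_cache <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  list(
    get = function(key) {
      f <- file.path(dir, paste0(key, ".txt"))
      if (file.exists(f)) as.integer(readLines(f, warn = FALSE)[1L]) else NULL
    },
    put = function(key, value) {
      writeLines(as.character(value), file.path(dir, paste0(key, ".txt")))
    })
}

#' Repeat extraction under stochastic decoding
#'
#' Runs [extract_features] \code{n_iter} times with distinct seeds under the
#' stochastic preset, mirroring repeated-generation robustness checks: the
#' downstream model can then be fit per iteration to obtain a distribution of
#' prediction errors.
#'
#' @inheritParams extract_features
#' @param n_iter Number of iterations.
#' @param seeds Optional integer vector of length \code{n_iter}; defaults to
#'   \code{seed + 0:(n_iter-1)}.
#' @return List of \code{n_iter} feature matrices.
#' @export
repeat_extraction <- function(transcripts, questions,
                              backend = mock_backend(),
                              config = decoding_config("stochastic"),
                              n_iter = 10L, seed = 0L, seeds = NULL,
                              retries = 3L) {
  if (!identical(config$preset, "stochastic"))
    stop("repeat_extraction requires the stochastic decoding preset")
  seeds <- seeds %||% (seed + seq_len(n_iter) - 1L)
  if (length(seeds) != n_iter || anyDuplicated(seeds))
    stop("need n_iter distinct seeds")
  lapply(seeds, function(s)
    extract_features(transcripts, questions, backend, config, seed = s,
                     retries = retries))
}

#' Write / read a feature matrix as CSV with sidecar metadata
#'
#' The CSV holds participants in rows and qids in columns (first column
#' \code{participant_id}); metadata travels in a JSON sidecar next to it.
#'
#' @param fm A [feature_matrix].
#' @param path CSV path; the sidecar is \code{<path>.meta.json}.
#' @return \code{write_feature_matrix}: \code{path}, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(participant_id = rownames(fm), as.data.frame(unclass(fm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- attr(fm, "meta")
  meta$config <- unclass(meta$config)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[-1L])
  rownames(values) <- df$participant_id
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::fromJSON(meta_path) else list()
  feature_matrix(values, meta$question_set %||% "custom",
                 meta$backend %||% "unknown", meta$config, meta$seed %||% NA)
}
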