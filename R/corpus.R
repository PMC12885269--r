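#' Construct an interview transcript object
#'
#' A transcript is the unit of feature extraction: an ordered sequence of
#' speaker-tagged utterances for one participant of a semi-structured clinical
#' interview with the virtual interviewer "Ellie".
#'
#' @param participant_id Single string identifying the participant.
#' @param speaker Character vector of speaker labels. Labels are normalized
#'   case-insensitively: "ellie"/"interviewer" map to \code{"interviewer"},
#'   "participant"/"subject" map to \code{"participant"}; anything else is an
#'   error.
#' @param text Character vector of utterance texts (same length as
#'   \code{speaker}); must not contain tabs or newlines.
#' @param start_time,stop_time Optional numeric vectors of utterance times in
#'   seconds; \code{stop_time} must not precede \code{start_time}.
#'
#' @return An object of class \code{"transcript"}: a list with
#'   \code{participant_id} and a data frame \code{utterances} with columns
#'   \code{speaker}, \code{start_time}, \code{stop_time}, \code{text}.
#' @export
#' @examples
#' t <- transcript("P1", c("Ellie", "Participant"), c("hi", "hello"))
#' qc_missing_party(t)
transcript <- function(participant_id, speaker, text,
                       start_time = NULL, stop_time = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L,
            nzchar(participant_id))
  speaker <- normalize_speaker(speaker)
  text <- as.character(text)
  if (length(text) != length(speaker))
    stop("`speaker` and `text` must have the same length")
  if (any(!nzchar(trimws(text))))
    stop("utterance text must be non-empty")
  if (any(grepl("[\t\n]", text)))
    stop("utterance text must not contain tab or newline characters")
  n <- length(text)
  start_time <- if (is.null(start_time)) rep(NA_real_, n) else as.numeric(start_time)
  stop_time <- if (is.null(stop_time)) rep(NA_real_, n) else as.numeric(stop_time)
  if (any(start_time < 0, na.rm = TRUE))
    stop("start_time must be >= 0")
  if (any(stop_time < start_time, na.rm = TRUE))
    stop("stop_time must be >= start_time")
  structure(
    list(participant_id = participant_id,
         utterances = data.frame(speaker = speaker, start_time = start_time,
                                 stop_time = stop_time, text = text,
                                 stringsAsFactors = FALSE)),
    class = "transcript")
}

normalize_speaker <- function(speaker) {
  s <- tolower(trimws(as.character(speaker)))
  out <- ifelse(s %in% c("ellie", "interviewer"), "interviewer",
         ifelse(s %in% c("participant", "subject"), "participant", NA_character_))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop(sprintf("unknown speaker label %s at utterance %d",
                 dQuote(speaker[bad]), bad))
  }
  out
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> participant %s: %d utterances (%d participant, %d interviewer)\n",
              x$participant_id, nrow(x$utterances),
              sum(x$utterances$speaker == "participant"),
              sum(x$utterances$speaker == "interviewer")))
  invisible(x)
}

#' Read an interview transcript from disk
#'
#' Supports two dialects: \code{"daicwoz_tsv"}, a tab-separated table with
#' header columns \code{start_time}, \code{stop_time}, \code{speaker},
#' \code{value} (case-insensitive, as distributed with the DAIC-WOZ corpus
#' family), and \code{"plain_text"}, lines of the form \code{"Speaker: text"}
#' where a line without a speaker prefix continues the previous utterance.
#'
#' Rows with empty text are dropped and counted in the parse report attached
#' to the result (\code{attr(x, "parse_report")}, with \code{rows_in},
#' \code{rows_dropped}, \code{utterances}).
#'
#' @param path Path to the transcript file.
#' @param dialect \code{"daicwoz_tsv"} or \code{"plain_text"}.
#' @param participant_id Participant identifier; defaults to the file name
#'   without extension.
#' @return A [transcript] object with a \code{"parse_report"} attribute.
#' @export
read_transcript <- function(path, dialect = c("daicwoz_tsv", "plain_text"),
                            participant_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(participant_id))
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "daicwoz_tsv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    if (!length(lines)) stop("format error: empty transcript table: ", path)
    header <- tolower(trimws(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]))
    need <- c("start_time", "stop_time", "speaker", "value")
    if (!all(need %in% header))
      stop("format error: missing header columns ",
           paste(setdiff(need, header), collapse = ", "), " in ", path)
    if (anyDuplicated(header[header %in% need]))
      stop("format error: ambiguous (duplicated) header columns in ", path)
    body <- lines[-1L]
    body <- body[nzchar(trimws(body))]
    fields <- strsplit(body, "\t", fixed = TRUE)
    get <- function(row, col) {
      i <- match(col, header)
      if (i <= length(row)) row[i] else ""
    }
    speaker <- vapply(fields, get, "", col = "speaker")
    text <- trimws(vapply(fields, get, "", col = "value"))
    start_time <- suppressWarnings(as.numeric(vapply(fields, get, "", col = "start_time")))
    stop_time <- suppressWarnings(as.numeric(vapply(fields, get, "", col = "stop_time")))
    keep <- nzchar(text)
    bad <- which(!speaker[keep] %in% c("Ellie", "ellie", "ELLIE", "interviewer",
                                       "Interviewer", "Participant", "participant",
                                       "PARTICIPANT", "subject", "Subject"))
    if (length(bad))
      stop(sprintf("unknown speaker label %s at line %d of %s",
                   dQuote(speaker[keep][bad[1L]]),
                   which(keep)[bad[1L]] + 1L, path))
    rows_in <- length(body)
    tr <- transcript(participant_id, speaker[keep], text[keep],
                     start_time[keep], stop_time[keep])
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    parsed <- parse_plain_text(lines, path)
    rows_in <- parsed$rows_in - parsed$continuations
    tr <- transcript(participant_id, parsed$speaker, parsed$text)
  }
  attr(tr, "parse_report") <- list(rows_in = rows_in,
                                   rows_dropped = rows_in - nrow(tr$utterances),
                                   utterances = nrow(tr$utterances))
  tr
}

# "Speaker: text" lines; continuation lines are appended to the previous
# utterance; blank lines are dropped.
parse_plain_text <- function(lines, path = "<text>") {
  lines <- lines[nzchar(trimws(lines))]
  speaker <- character(0)
  text <- character(0)
  continuations <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*:\\s*(.*)$", ln))[[1L]]
    is_prefixed <- length(m) == 3L &&
      tolower(m[2L]) %in% c("ellie", "interviewer", "participant", "subject")
    if (is_prefixed) {
      speaker <- c(speaker, m[2L])
      text <- c(text, trimws(m[3L]))
    } else if (length(m) == 3L && grepl("^[A-Za-z]+\\s*:", ln)) {
      stop(sprintf("unknown speaker label %s at line %d of %s",
                   dQuote(m[2L]), i, path))
    } else {
      if (!length(speaker))
        stop("format error: continuation line before any speaker line in ", path)
      text[length(text)] <- paste(text[length(text)], trimws(ln))
      continuations <- continuations + 1L
    }
  }
  keep <- nzchar(text)
  list(speaker = speaker[keep], text = text[keep], rows_in = length(lines),
       continuations = continuations)
}

#' Quality-control check for missing parties
#'
#' Interviews missing either party's text cannot be scored meaningfully;
#' corpora of this kind exclude such records. The decision to exclude is left
#' to the caller -- this function only flags.
#'
#' @param t A [transcript].
#' @return One of \code{"ok"}, \code{"no_interviewer_text"},
#'   \code{"no_participant_text"}.
#' @export
qc_missing_party <- function(t) {
  stopifnot(inherits(t, "transcript"))
  sp <- t$utterances$speaker
  if (!any(sp == "interviewer")) return("no_interviewer_text")
  if (!any(sp == "participant")) return("no_participant_text")
  "ok"
}

#' Render a transcript as interview text for prompting
#'
#' One line per utterance, formatted \code{"<Speaker>: <text>"} with speakers
#' printed as \code{"Ellie"} and \code{"Participant"}, in original order.
#' Deterministic byte-for-byte for a fixed transcript.
#'
#' @param t A [transcript] that passes [qc_missing_party].
#' @return A single string (lines joined by \code{"\n"}).
#' @export
render_interview <- function(t) {
  stopifnot(inherits(t, "transcript"))
  if (qc_missing_party(t) != "ok")
    stop("transcript fails QC (", qc_missing_party(t), "); refusing to render")
  label <- ifelse(t$utterances$speaker == "interviewer", "Ellie", "Participant")
  paste(paste0(label, ": ", t$utterances$text), collapse = "\n")
}

#' Read PHQ-8 label records
#'
#' Reads a CSV with header columns \code{participant_id}, \code{phq8_total}
#' and optionally \code{phq8_item1} .. \code{phq8_item8}, \code{age},
#' \code{sex}. When item columns are present, each row's items must sum to
#' its total.
#'
#' @param path CSV file path.
#' @return A data frame of validated label records.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_labels(df)
}

#' @keywords internal
#' @noRd
validate_labels <- function(df) {
  if (!all(c("participant_id", "phq8_total") %in% names(df)))
    stop("labels must have columns participant_id and phq8_total")
  df$participant_id <- as.character(df$participant_id)
  if (anyDuplicated(df$participant_id))
    stop("duplicated participant_id in labels")
  tot <- df$phq8_total
  if (any(tot != round(tot) | tot < 0 | tot > 24))
    stop("phq8_total must be integers in 0..24")
  item_cols <- paste0("phq8_item", 1:8)
  if (all(item_cols %in% names(df))) {
    items <- as.matrix(df[item_cols])
    if (any(items != round(items) | items < 0 | items > 3))
      stop("phq8 items must be integers in 0..3")
    bad <- which(rowSums(items) != tot)
    if (length(bad))
      stop(sprintf("PHQ-8 items of participant %s sum to %d but phq8_total is %d",
                   df$participant_id[bad[1L]], sum(items[bad[1L], ]), tot[bad[1L]]))
  }
  df
}

#' Read a train/test split assignment
#'
#' CSV with columns \code{participant_id} and \code{partition} (one of
#' \code{train}, \code{test1}, \code{test2}). Ids must be unique across
#' partitions.
#'
#' @param path CSV file path.
#' @return A list with character vectors \code{train_ids}, \code{test1_ids},
#'   \code{test2_ids}.
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("participant_id", "partition") %in% names(df)))
    stop("split file must have columns participant_id and partition")
  if (!all(df$partition %in% c("train", "test1", "test2")))
    stop("partition must be one of train, test1, test2")
  if (anyDuplicated(df$participant_id))
    stop("participant ", df$participant_id[duplicated(df$participant_id)][1L],
         " appears in more than one partition")
  split(as.character(df$participant_id), df$partition) -> parts
  list(train_ids = parts$train %||% character(0),
       test1_ids = parts$test1 %||% character(0),
       test2_ids = parts$test2 %||% character(0))
}
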