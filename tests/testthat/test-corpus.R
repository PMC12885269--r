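write_tsv_fixture <- function(rows, header = "start_time\tstop_time\tspeaker\tvalue") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, rows), path)
  path
}

test_that("TSV transcripts parse in order with normalized speakers", {
  path <- write_tsv_fixture(c("0.0\t1.2\tEllie\thi there",
                              "1.5\t2.0\tParticipant\thello",
                              "2.5\t4.0\tEllie\thow are you"))
  t <- read_transcript(path, "daicwoz_tsv", participant_id = "P1")
  expect_s3_class(t, "transcript")
  expect_equal(t$utterances$speaker,
               c("interviewer", "participant", "interviewer"))
  expect_equal(t$utterances$text, c("hi there", "hello", "how are you"))
  expect_equal(t$utterances$start_time, c(0, 1.5, 2.5))
  rep <- attr(t, "parse_report")
  expect_equal(rep$rows_in, rep$rows_dropped + rep$utterances)
})

test_that("empty-text rows are dropped and accounted for", {
  path <- write_tsv_fixture(c("0\t1\tEllie\thi",
                              "1\t2\tParticipant\t",
                              "2\t3\tParticipant\tfine"))
  t <- read_transcript(path, "daicwoz_tsv")
  expect_equal(nrow(t$utterances), 2L)
  rep <- attr(t, "parse_report")
  expect_equal(rep$rows_dropped, 1L)
  expect_equal(rep$rows_in, rep$rows_dropped + rep$utterances)
})

test_that("format and speaker errors are loud and specific", {
  bad_header <- write_tsv_fixture("0\t1\tEllie\thi", header = "a\tb\tc\td")
  expect_error(read_transcript(bad_header, "daicwoz_tsv"), "header")
  unknown <- write_tsv_fixture(c("0\t1\tEllie\thi", "1\t2\tDoctor\thello"))
  expect_error(read_transcript(unknown, "daicwoz_tsv"), "Doctor")
  expect_error(transcript("P1", "Narrator", "hi"), "Narrator")
  expect_error(transcript("P1", "Ellie", "has\ttab"), "tab")
})

test_that("QC flags identify the missing party, decisions left to caller", {
  both <- transcript("P1", c("Ellie", "Participant"), c("hi", "hello"))
  expect_equal(qc_missing_party(both), "ok")
  ellie_only <- transcript("P2", c("Ellie", "Ellie"), c("hi", "anyone there"))
  expect_equal(qc_missing_party(ellie_only), "no_participant_text")
  part_only <- transcript("P3", "Participant", "hello")
  expect_equal(qc_missing_party(part_only), "no_interviewer_text")
  expect_error(render_interview(ellie_only), "QC")
})

test_that("a participant-absent TSV is flagged, not rejected at parse", {
  path <- write_tsv_fixture(c("0\t1\tEllie\thi", "1\t2\tEllie\tstill me"))
  t <- read_transcript(path, "daicwoz_tsv")
  expect_equal(qc_missing_party(t), "no_participant_text")
})

test_that("plain-text dialect parses speakers and continuation lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Ellie: hi", "Participant: hello", "and more of the same turn",
               "Ellie: ok"), path)
  t <- read_transcript(path, "plain_text")
  expect_equal(nrow(t$utterances), 3L)
  expect_equal(t$utterances$text[2L], "hello and more of the same turn")
  expect_equal(t$utterances$speaker[c(1, 3)], rep("interviewer", 2))
  writeLines("Narrator: once upon a time", path)
  expect_error(read_transcript(path, "plain_text"), "Narrator")
})

test_that("rendering is deterministic, ordered, one line per utterance", {
  t <- transcript("P1", c("Ellie", "Participant"), c("hi", "hello"))
  expect_identical(render_interview(t), "Ellie: hi\nParticipant: hello")
  expect_identical(render_interview(t), render_interview(t))
  n <- 140L
  big <- transcript("P2", rep(c("Ellie", "Participant"), n / 2),
                    paste("utterance", seq_len(n)))
  expect_length(strsplit(render_interview(big), "\n")[[1L]], n)
})

test_that("read -> render -> re-parse round-trips the utterance sequence", {
  t <- transcript("P1",
                  c("Ellie", "Participant", "Ellie", "Participant"),
                  c("how are you", "i am okay i guess", "good", "yeah"))
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(strsplit(render_interview(t), "\n")[[1L]], path)
  t2 <- read_transcript(path, "plain_text", participant_id = "P1")
  expect_equal(t2$utterances$speaker, t$utterances$speaker)
  expect_equal(t2$utterances$text, t$utterances$text)
})

test_that("label records enforce item/total consistency by participant", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(participant_id = "A", phq8_total = 5L)
  df[paste0("phq8_item", 1:8)] <- as.list(c(1L, 1L, 0L, 2L, 0L, 0L, 1L, 0L))
  write.csv(df, path, row.names = FALSE)
  expect_silent(labels <- read_labels(path))
  expect_equal(labels$phq8_total, 5L)
  df$phq8_total <- 6L
  write.csv(df, path, row.names = FALSE)
  expect_error(read_labels(path), "participant A")
})

test_that("split files reject duplicated ids across partitions", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(participant_id = c("A", "B", "C"),
                       partition = c("train", "test1", "test2")),
            path, row.names = FALSE)
  s <- read_split(path)
  expect_equal(s$train_ids, "A")
  expect_equal(s$test2_ids, "C")
  write.csv(data.frame(participant_id = c("A", "A"),
                       partition = c("train", "test1")),
            path, row.names = FALSE)
  expect_error(read_split(path), "A")
})
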