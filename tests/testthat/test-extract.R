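cue_transcript <- function(id, cues) {
  body <- if (length(cues)) paste(cues, collapse = " ") else "nothing here"
  transcript(id, c("Ellie", "Participant"), c("how are you", body))
}

test_that("mock backend scores by cue-word count, capped at 10", {
  b <- mock_backend()
  cfg <- decoding_config("deterministic")
  q2 <- question_set("depression23")$text[2L]
  score_for <- function(n_cues) {
    t <- cue_transcript("P", rep("q2cue", n_cues))
    parse_score(b$complete(assemble_prompt(render_interview(t), q2), cfg, 0L))
  }
  expect_equal(score_for(0), 0L)
  expect_equal(score_for(3), 3L)
  expect_equal(score_for(15), 10L)
  # monotone in planted cues
  scores <- vapply(0:12, score_for, 0L)
  expect_true(all(diff(scores) >= 0L))
})

test_that("mock backend ignores interviewer text and other cues", {
  b <- mock_backend()
  cfg <- decoding_config("deterministic")
  qs <- question_set("depression23")
  t <- transcript("P", c("Ellie", "Participant"),
                  c("q2cue q2cue q2cue", "q3cue q3cue"))
  body <- render_interview(t)
  s2 <- parse_score(b$complete(assemble_prompt(body, qs$text[2L]), cfg, 0L))
  s3 <- parse_score(b$complete(assemble_prompt(body, qs$text[3L]), cfg, 0L))
  expect_equal(s2, 0L)  # cues in the interviewer's turn don't count
  expect_equal(s3, 2L)
  # q1cue must not match inside nq1cue
  t2 <- cue_transcript("P", c("nq1cue", "nq1cue"))
  s1 <- parse_score(b$complete(assemble_prompt(render_interview(t2),
                                               qs$text[1L]), cfg, 0L))
  expect_equal(s1, 0L)
})

test_that("deterministic extraction is complete, in range, reproducible", {
  cohort <- generate_cohort(cohort_spec(5, seed = 11))
  trs <- generate_transcripts(cohort, seed = 11)
  qs <- question_set("depression23")
  fm1 <- extract_features(trs, qs, seed = 1L)
  expect_equal(dim(fm1), c(5L, 23L))
  expect_true(all(fm1 >= 0L & fm1 <= 10L))
  expect_null(attr(fm1, "failures"))
  fm2 <- extract_features(trs, qs, seed = 1L)
  expect_identical(unclass(fm1)[, ], unclass(fm2)[, ])
})

test_that("a zero-cue transcript scores 0 on every question", {
  t <- cue_transcript("P0", character(0))
  fm <- extract_features(list(t), question_set("depression23"))
  expect_true(all(fm == 0L))
})

test_that("the cell cache eliminates repeat backend calls", {
  cohort <- generate_cohort(cohort_spec(3, seed = 5))
  trs <- generate_transcripts(cohort, seed = 5)
  qs <- question_set("depression23")
  cache <- withr::local_tempdir()
  b <- mock_backend()
  fm1 <- extract_features(trs, qs, backend = b, cache_dir = cache)
  calls_after_first <- backend_calls(b)
  expect_equal(calls_after_first, 3L * 23L)
  fm2 <- extract_features(trs, qs, backend = b, cache_dir = cache)
  expect_equal(backend_calls(b), calls_after_first)  # zero new calls
  expect_identical(unclass(fm1)[, ], unclass(fm2)[, ])
})

test_that("failures are recorded, never imputed, and account for all cells", {
  broken <- scoring_backend("broken", function(prompt, config, seed) "nope")
  t <- cue_transcript("P", "q1cue")
  qs <- question_set("depression23")
  fm <- extract_features(list(t), qs, backend = broken,
                         config = decoding_config("stochastic"), retries = 2L)
  fails <- attr(fm, "failures")
  expect_equal(nrow(fails), 23L)
  expect_true(all(is.na(fm)))
  expect_true(all(fails$attempts == 2L))
  expect_equal(sum(!is.na(fm)) + nrow(fails), 1L * 23L)
  # deterministic preset: one attempt only
  fm_det <- extract_features(list(t), qs, backend = broken,
                             config = decoding_config("deterministic"))
  expect_true(all(attr(fm_det, "failures")$attempts == 1L))
})

test_that("stochastic repetition yields distinct-seed reproducible matrices", {
  cohort <- generate_cohort(cohort_spec(4, seed = 2))
  trs <- generate_transcripts(cohort, seed = 2)
  qs <- question_set("direct_dq")
  reps1 <- repeat_extraction(trs, qs, n_iter = 10L, seed = 100L)
  expect_length(reps1, 10L)
  reps2 <- repeat_extraction(trs, qs, n_iter = 10L, seed = 100L)
  for (k in seq_len(10L))
    expect_identical(unclass(reps1[[k]])[, ], unclass(reps2[[k]])[, ])
  expect_error(repeat_extraction(trs, qs,
                                 config = decoding_config("deterministic")),
               "stochastic")
})

test_that("feature matrices validate their contract and round-trip CSV", {
  vals <- matrix(5L, 2, 2, dimnames = list(c("A", "B"), c("Q1", "Q2")))
  fm <- feature_matrix(vals, "custom", "mock")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  fm2 <- read_feature_matrix(path)
  expect_identical(unclass(fm)[, ], unclass(fm2)[, ])
  vals[1, 1] <- 99L
  expect_error(feature_matrix(vals), "0..10")
  vals[1, 1] <- NA
  expect_error(feature_matrix(vals), "failure report")
})
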