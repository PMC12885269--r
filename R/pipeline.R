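# End-to-end orchestration: extract -> fit -> evaluate -> interpret ->
# validate from a single config, with provenance (frozen config + content
# hashes) written alongside every run.

feature_subset_qids <- function(subset, questions) {
  if (length(subset) > 1L) return(subset)
  switch(subset,
    all = questions$qid,
    clinical = questions$qid[questions$category == "clinical_symptoms"],
    linguistic = questions$qid[questions$category == "linguistic_patterns"],
    distortion = questions$qid[questions$category == "cognitive_distortions"],
    stop("unknown feature subset ", dQuote(subset),
         "; use all/clinical/linguistic/distortion or a qid vector"))
}

resolve_question_set <- function(x) {
  if (inherits(x, "question_set")) return(x)
  if (x %in% c("depression23", "control_nq", "direct_dq")) return(question_set(x))
  read_question_set(x)
}

read_transcript_dir <- function(dir, dialect) {
  ext <- if (dialect == "daicwoz_tsv") "\\.tsv$" else "\\.txt$"
  files <- sort(list.files(dir, ext, full.names = TRUE))
  if (!length(files)) stop("no transcript files in ", dir)
  trs <- lapply(files, read_transcript, dialect = dialect)
  names(trs) <- vapply(trs, function(t) t$participant_id, "")
  trs
}

#' Run the full assessment pipeline
#'
#' Reads transcripts, labels and the train/test split, applies QC
#' exclusions, extracts features for every participant with the configured
#' backend, fits the severity model on the training partition, evaluates on
#' each test partition, and writes feature-contribution and validity
#' reports. All outputs land in \code{config$out_dir} together with
#' \code{manifest.json} (frozen resolved config plus an md5 content hash per
#' output file). Re-running with unchanged inputs reuses the on-disk
#' extraction cache and reproduces identical metric files.
#'
#' @param config A named list or path to a YAML file with fields:
#'   \code{transcripts_dir}, \code{dialect} (\code{"daicwoz_tsv"} or
#'   \code{"plain_text"}), \code{labels}, \code{split}, \code{out_dir},
#'   and optionally \code{question_set} (name or file; default
#'   \code{"depression23"}), \code{backend} (\code{"mock"}), \code{preset}
#'   (decoding preset), \code{family}, \code{features} (\code{"all"},
#'   \code{"clinical"}, \code{"linguistic"}, \code{"distortion"} or a qid
#'   vector), \code{B} (bootstrap iterations, default 1000), \code{seed},
#'   \code{clip}.
#' @param backend Optional \code{"scoring_backend"} instance overriding
#'   \code{config$backend} (the only built-in id is \code{"mock"}).
#' @return Invisibly, a list with the fitted model, per-partition metrics,
#'   the reports, and \code{out_dir}.
#' @export
run_pipeline <- function(config, backend = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("transcripts_dir", "labels", "split", "out_dir")
  if (!all(required %in% names(config)))
    stop("config missing fields: ",
         paste(setdiff(required, names(config)), collapse = ", "))
  cfg <- list(
    transcripts_dir = config$transcripts_dir,
    dialect = config$dialect %||% "daicwoz_tsv",
    labels = config$labels, split = config$split,
    out_dir = config$out_dir,
    question_set = config$question_set %||% "depression23",
    backend = config$backend %||% "mock",
    preset = config$preset %||% "deterministic",
    family = config$family %||% "ols",
    features = config$features %||% "all",
    B = as.integer(config$B %||% 1000L),
    seed = as.integer(config$seed %||% 0L),
    clip = isTRUE(config$clip))
  qs <- resolve_question_set(cfg$question_set)
  qids <- feature_subset_qids(cfg$features, qs)  # validate before any work
  if (is.null(backend)) {
    if (cfg$backend != "mock")
      stop("unknown backend id ", dQuote(cfg$backend),
           "; pass a scoring_backend object for custom backends")
    backend <- mock_backend()
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  trs <- read_transcript_dir(cfg$transcripts_dir, cfg$dialect)
  qc <- vapply(trs, qc_missing_party, "")
  excluded <- names(qc)[qc != "ok"]
  trs <- trs[qc == "ok"]
  labels <- read_labels(cfg$labels)
  split <- read_split(cfg$split)

  fm <- extract_features(trs, qs, backend,
                         decoding_config(cfg$preset), seed = cfg$seed,
                         cache_dir = file.path(cfg$out_dir, "cache"))
  write_feature_matrix(fm, file.path(cfg$out_dir, "features.csv"))

  part_rows <- function(ids) {
    ids <- intersect(ids, rownames(fm))
    list(x = fm[ids, , drop = FALSE],
         y = labels$phq8_total[match(ids, labels$participant_id)])
  }
  train <- part_rows(split$train_ids)
  model <- severity_model(train$x, train$y, family = cfg$family,
                          features = qids, clip = cfg$clip)

  partitions <- list(test1 = split$test1_ids, test2 = split$test2_ids)
  partitions <- partitions[lengths(partitions) > 0L]
  metrics <- do.call(rbind, lapply(names(partitions), function(p) {
    d <- part_rows(partitions[[p]])
    m <- evaluate_predictions(predict(model, d$x), d$y)
    data.frame(partition = p, mae = m$mae, rmse = m$rmse, r2 = m$r2, n = m$n)
  }))
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)

  test_ids <- unlist(partitions, use.names = FALSE)
  comb <- part_rows(test_ids)
  reports <- list(
    univariate = univariate_report(train$x[, qids, drop = FALSE], train$y,
                                   questions = qs, B = cfg$B, seed = cfg$seed),
    structure = if (cfg$family == "ols" && length(test_ids))
      coefficient_report("structure", model = model, x_test = comb$x,
                         questions = qs, B = cfg$B, seed = cfg$seed),
    ablation = if (cfg$family == "ols" && length(test_ids))
      coefficient_report("ablation", x = train$x[, qids, drop = FALSE],
                         y = train$y, x_test = comb$x[, qids, drop = FALSE],
                         y_test = comb$y, B = cfg$B, seed = cfg$seed))
  for (nm in names(reports))
    if (!is.null(reports[[nm]]))
      utils::write.csv(reports[[nm]],
                       file.path(cfg$out_dir, paste0(nm, "_report.csv")),
                       row.names = FALSE)

  validity <- NULL
  if (any(!is.na(qs$reference_metric))) {
    train_trs <- trs[intersect(split$train_ids, names(trs))]
    lm_rows <- do.call(rbind, lapply(train_trs, linguistic_metrics))
    validity <- validity_report(fm[rownames(train$x), , drop = FALSE],
                                labels, lm_rows, qs)
    utils::write.csv(validity, file.path(cfg$out_dir, "validity_report.csv"),
                     row.names = FALSE)
  }

  outputs <- list.files(cfg$out_dir, "\\.csv$|\\.json$", recursive = FALSE)
  manifest <- list(
    config = cfg,
    excluded = as.list(excluded),
    failures = NROW(attr(fm, "failures")),
    hashes = as.list(tools::md5sum(file.path(cfg$out_dir, outputs))))
  names(manifest$hashes) <- outputs
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(list(model = model, metrics = metrics, reports = reports,
                 validity = validity, features = fm, excluded = excluded,
                 out_dir = cfg$out_dir))
}

#' Compare prompting strategies
#'
#' Extracts features under each question set, fits the same model family on
#' the training rows, and evaluates on every test partition -- one table row
#' per (strategy, partition). Used to check that depression-informed
#' questions outperform non-clinical control questions and direct severity
#' prompting.
#'
#' @param transcripts Named list of QC-ok transcripts.
#' @param labels Label data frame.
#' @param split Split assignment (see [read_split]).
#' @param strategies Named list of question sets (names label the rows);
#'   default the three built-in banks.
#' @param backend,config,seed Extraction settings shared by all strategies.
#' @return Data frame with \code{strategy}, \code{partition}, \code{mae},
#'   \code{rmse}, \code{r2}, \code{n}.
#' @export
compare_strategies <- function(transcripts, labels, split,
                               strategies = list(
                                 depression23 = question_set("depression23"),
                                 control_nq = question_set("control_nq"),
                                 direct_dq = question_set("direct_dq")),
                               backend = mock_backend(),
                               config = decoding_config("deterministic"),
                               seed = 0L) {
  stopifnot(length(strategies) >= 1L)
  partitions <- list(test1 = split$test1_ids, test2 = split$test2_ids)
  partitions <- partitions[lengths(partitions) > 0L]
  do.call(rbind, lapply(names(strategies), function(nm) {
    fm <- extract_features(transcripts, strategies[[nm]], backend, config,
                           seed = seed)
    tr_ids <- intersect(split$train_ids, rownames(fm))
    model <- severity_model(fm[tr_ids, , drop = FALSE],
                            labels$phq8_total[match(tr_ids, labels$participant_id)])
    do.call(rbind, lapply(names(partitions), function(p) {
      ids <- intersect(partitions[[p]], rownames(fm))
      m <- evaluate_predictions(
        predict(model, fm[ids, , drop = FALSE]),
        labels$phq8_total[match(ids, labels$participant_id)])
      data.frame(strategy = nm, partition = p, mae = m$mae, rmse = m$rmse,
                 r2 = m$r2, n = m$n, stringsAsFactors = FALSE)
    }))
  }))
}
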