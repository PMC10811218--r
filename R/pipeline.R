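# End-to-end orchestration: simulate -> preprocess -> decode -> evaluate,
# with per-subject seeding so results do not depend on execution order.

decoder_registry <- function() {
  list(
    "csp-lda" = function(train, seed)
      fit_csp_lda(train),
    "fbcsp-svm" = function(train, seed)
      fit_fbcsp_svm(train),
    "mdrm" = function(train, seed)
      fit_mdrm(train),
    "tslda" = function(train, seed)
      fit_tslda(train),
    "dgfmdrm" = function(train, seed)
      fit_dgfmdrm(train),
    "twfb-dgfmdm" = function(train, seed)
      fit_twfb_dgfmdm(train, seed = seed)
  )
}

# Prepare the decoder's input view of a raw recording: the TWFB decoder
# consumes raw epochs; the classic decoders consume the 8-30 Hz filtered
# 0-4 s MI window (FBCSP gets the broadband window and filters per band).
decoder_input <- function(rec, method, mi_onset = 2.0) {
  if (method == "twfb-dgfmdm") return(rec)
  win <- extract_window(eeg_trials(rec), c(0, 4), mi_onset)
  if (method == "fbcsp-svm") return(win)
  bandpass_trials(win, 8, 30)
}

#' Decode one subject's recording with a named method
#'
#' @param rec An [mi_recording()].
#' @param method One of `"csp-lda"`, `"fbcsp-svm"`, `"mdrm"`, `"tslda"`,
#'   `"dgfmdrm"`, `"tslda-dgfmdrm"` (decision fusion), `"twfb-dgfmdm"`.
#' @param protocol `"cv10"` (stratified 10-fold cross-validation, the
#'   headline protocol) or `"holdout60"` (stratified 60/40 split).
#' @param seed Integer seed.
#' @param mi_onset MI onset within the epoch, seconds.
#' @param folds Folds for the `"cv10"` protocol.
#' @return A `decode_result`.
#' @export
decode_subject <- function(rec, method = "twfb-dgfmdm",
                           protocol = c("cv10", "holdout60"), seed = 1,
                           mi_onset = 2.0, folds = 10) {
  protocol <- match.arg(protocol)
  if (method == "tslda-dgfmdrm") {
    x <- decoder_input(rec, "mdrm", mi_onset)
    fuse_predict <- function(train, test) {
      m1 <- fit_tslda(train); m2 <- fit_dgfmdrm(train)
      predict_fusion(m1, m2, test)
    }
    if (protocol == "holdout60") {
      sp <- split_train_test(x, 0.6, seed)
      pred <- fuse_predict(sp$train, sp$test)
      return(new_decode_result(confusion_matrix(sp$test$labels, pred),
                               NULL, method, seed))
    }
    fold <- stratified_folds(x$labels, folds, seed)
    confusion <- matrix(0L, 2, 2)
    per_fold <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      pred <- fuse_predict(subset_trials(x, tr), subset_trials(x, te))
      cm <- confusion_matrix(x$labels[te], pred)
      confusion <- confusion + cm
      per_fold[f] <- sum(diag(cm)) / sum(cm)
    }
    return(new_decode_result(confusion, per_fold, method, seed))
  }
  fit <- decoder_registry()[[method]]
  if (is.null(fit)) stop("unknown decoding method: ", method, call. = FALSE)
  x <- decoder_input(rec, method, mi_onset)
  if (protocol == "holdout60") {
    sp <- split_train_test(x, 0.6, seed)
    model <- fit(sp$train, seed)
    evaluate_holdout(model, sp$test, method = method, seed = seed)
  } else {
    cross_validate(function(tr) fit(tr, seed), x, folds = folds,
                   seed = seed, method = method)
  }
}

#' Run the full simulate/decode/evaluate pipeline
#'
#' Generates a synthetic cohort, decodes every subject with the requested
#' methods under the chosen protocol, and writes per-stage outputs (dataset
#' tree, per-subject results, summary tables, a JSON summary and a run log)
#' into a results directory.
#'
#' @param config List with fields `out_dir` (required), and optionally
#'   `n_subjects` (default 3), `methods` (default `"twfb-dgfmdm"`),
#'   `protocol` (`"cv10"` or `"holdout60"`), `seed` (default 1),
#'   `synth` (overrides for [synthetic_config()]), `write_dataset`
#'   (default `FALSE`).
#' @return The results directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required",
                                    call. = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  methods <- config$methods %||% "twfb-dgfmdm"
  protocol <- config$protocol %||% "cv10"
  n_sub <- config$n_subjects %||% 3L
  synth_args <- modifyList(list(n_subjects = n_sub, seed = seed),
                           config$synth %||% list())
  cfg <- do.call(synthetic_config, synth_args)

  logf <- file.path(out, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("strokemi run, seed %d, protocol %s\nR %s, strokemi %s\n",
              seed, protocol, getRversion(),
              as.character(utils::packageVersion("strokemi"))),
      file = logf)

  cohort <- generate_cohort(cfg$n_subjects, seed = cfg$seed)
  subjects <- lapply(seq_len(cfg$n_subjects), function(i)
    generate_subject_recording(cohort[i, ], cfg,
                               seed = child_seed(cfg$seed, i)))
  logline("simulate: %d subjects x %d trials", cfg$n_subjects, cfg$n_trials)
  if (isTRUE(config$write_dataset)) {
    build_bids_tree(lapply(subjects, `[[`, "recording"), cohort,
                    file.path(out, "dataset"), overwrite = TRUE,
                    preprocess = FALSE)
    logline("dataset tree written")
  }

  all_summaries <- list()
  for (method in methods) {
    results <- lapply(seq_along(subjects), function(i) {
      tryCatch(
        decode_subject(subjects[[i]]$recording, method, protocol,
                       seed = child_seed(seed, 1000L + i)),
        error = function(e)
          stop(sprintf("decode stage failed for %s / %s: %s",
                       cohort$participant_id[i], method,
                       conditionMessage(e)), call. = FALSE))
    })
    names(results) <- cohort$participant_id
    agg <- aggregate_subjects(results)
    write.table(agg$summary,
                file.path(out, sprintf("summary_%s.csv", method)),
                sep = ",", row.names = FALSE, quote = FALSE)
    all_summaries[[method]] <- list(
      mean_accuracy = agg$summary$accuracy[nrow(agg$summary)],
      mean_kappa = agg$summary$kappa[nrow(agg$summary)],
      pooled_confusion = agg$pooled_confusion,
      per_subject = agg$summary[-nrow(agg$summary), ])
    logline("decode %s: mean accuracy %.4f", method,
            all_summaries[[method]]$mean_accuracy)
  }
  jsonlite::write_json(
    list(seed = seed, protocol = protocol, methods = all_summaries),
    file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out)
}
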