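#' Materialise recordings as an EEG-BIDS style directory tree
#'
#' Writes the dataset layout used by the deposit: `sourcedata/sub-xx/` MAT
#' containers with the raw trial tensors, `edffile/` EDF exports of the
#' preprocessed (baseline-removed, 0.5-40 Hz FIR-filtered) scalp channels, a
#' tab-separated participants table, a channel-location file and an event
#' definition table, plus a `stimuli/` placeholder folder.
#'
#' @param recordings List of [mi_recording()] objects.
#' @param participants Data frame of participant records (see
#'   [generate_cohort()]); one row per recording. May be `NULL` to write ids
#'   only.
#' @param root Target directory.
#' @param overwrite Refuse to write into an existing non-empty `root` unless
#'   `TRUE`.
#' @param preprocess Apply [remove_baseline()] + [fir_bandpass()] before the
#'   EDF export (the deposit's convention). Set `FALSE` to export raw scalp
#'   channels.
#' @return `root`, invisibly.
#' @export
build_bids_tree <- function(recordings, participants = NULL, root,
                            overwrite = FALSE, preprocess = TRUE) {
  if (dir.exists(root) && length(dir(root, all.files = TRUE, no.. = TRUE)) &&
      !overwrite)
    stop("target directory exists and is not empty: ", root, call. = FALSE)
  if (!is.null(participants) && nrow(participants) != length(recordings))
    stop("participants table must have one row per recording", call. = FALSE)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (d in c("stimuli", "stimuli/left-hand", "stimuli/right-hand",
              "sourcedata", "edffile"))
    dir.create(file.path(root, d), showWarnings = FALSE)
  writeLines(c("Placeholder for the motor-imagery guide videos.",
               "left-hand/: left-hand gripping clip; right-hand/: right-hand gripping clip."),
             file.path(root, "stimuli", "README.txt"))

  layout <- builtin_layout()
  ids <- vapply(recordings, function(r) r$subject_id, "")
  if (is.null(participants)) {
    participants <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  } else if (!"participant_id" %in% names(participants)) {
    participants <- cbind(participant_id = ids, participants)
  }
  write.table(participants, file.path(root, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  scalp <- layout[!is.na(layout$x), ]
  locs <- data.frame(index = scalp$index,
                     angle = round(atan2(scalp$x, scalp$y) * 180 / pi, 3),
                     radius = round(sqrt(scalp$x^2 + scalp$y^2) / 2, 4),
                     name = scalp$name)
  write.table(locs, file.path(root, "channel_location.locs"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  events <- data.frame(value = c(1L, 2L),
                       trial_type = c("trial-start", "mi-onset"),
                       description = c("epoching marker (trial sample 0)",
                                       "motor-imagery onset"))
  write.table(events, file.path(root, "task-motor-imagery_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  for (rec in recordings) {
    sdir <- file.path(root, "sourcedata", rec$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_raw_mat(rec, sdir)
    trials <- eeg_trials(rec)
    if (preprocess) {
      trials$data <- remove_baseline(trials$data)
      trials$data <- fir_bandpass(trials$data,
                                  sample_rate = trials$sample_rate)
      trials$band <- c(0.5, 40)
    }
    write_edf(trials, file.path(root, "edffile"))
  }
  invisible(root)
}
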