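#' Construct a raw motor-imagery recording
#'
#' Bundles one subject's trial tensor with its task labels, sampling rate and
#' montage. The canonical shape is 40 trials x 33 channels x 4000 samples at
#' 500 Hz; other trial counts are accepted but the channel count must match
#' the montage.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param labels Integer vector, one per trial; 1 = left-hand MI, 2 =
#'   right-hand MI. May be all-`NA` for epochs cut from a continuous stream
#'   whose labels are not yet known.
#' @param sample_rate Sampling rate in Hz.
#' @param layout An [builtin_layout()] montage.
#' @param subject_id Subject identifier, e.g. `"sub-01"`.
#' @return An object of class `mi_recording`.
#' @export
mi_recording <- function(data, labels, sample_rate = 500,
                         layout = builtin_layout(), subject_id = "sub-01") {
  rec <- structure(
    list(data = data, labels = as.integer(labels),
         sample_rate = sample_rate, layout = layout,
         subject_id = subject_id),
    class = "mi_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  d <- dim(rec$data)
  if (length(d) != 3L)
    stop("recording data must be a trials x channels x samples array",
         call. = FALSE)
  if (d[2] != nrow(rec$layout))
    stop(sprintf("expected %d channels, found %d", nrow(rec$layout), d[2]),
         call. = FALSE)
  if (length(rec$labels) != d[1])
    stop("one label per trial required", call. = FALSE)
  lab <- rec$labels[!is.na(rec$labels)]
  if (length(lab) && !all(lab %in% c(1L, 2L)))
    stop("labels must be 1 (left-hand MI) or 2 (right-hand MI)",
         call. = FALSE)
  mk <- rec$data[, marker_channel(rec$layout), , drop = TRUE]
  if (!all(unique(as.vector(mk)) %in% c(0, 1, 2)))
    stop("marker channel may only carry values 0, 1, 2", call. = FALSE)
  invisible(rec)
}

#' Construct a set of processed (EEG-only) trials
#'
#' @param data Numeric array `trials x channels x samples` holding scalp
#'   channels only (no EOG or marker channels).
#' @param labels Integer trial labels in `{1, 2}`.
#' @param sample_rate Sampling rate in Hz.
#' @param band Optional length-2 numeric `(low, high)` Hz describing the
#'   band-pass already applied.
#' @param subject_id Subject identifier.
#' @param channel_names Channel names, one per channel.
#' @return An object of class `mi_trials`.
#' @export
mi_trials <- function(data, labels, sample_rate = 500, band = NULL,
                      subject_id = "sub-01",
                      channel_names = builtin_layout()$name[scalp_channels()]) {
  d <- dim(data)
  if (length(d) != 3L)
    stop("trial data must be a trials x channels x samples array", call. = FALSE)
  if (length(channel_names) != d[2])
    stop("one channel name per channel required", call. = FALSE)
  if (!is.null(band) && band[1] >= band[2])
    stop("band must satisfy low < high", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != d[1] || !all(labels %in% c(1L, 2L)))
    stop("labels must be 1 or 2, one per trial", call. = FALSE)
  structure(list(data = data, labels = labels, sample_rate = sample_rate,
                 band = band, subject_id = subject_id,
                 channel_names = channel_names),
            class = "mi_trials")
}

#' Number of trials in a recording or trial set
#' @param x An `mi_recording` or `mi_trials`.
#' @return Integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Subset trials
#'
#' @param x An `mi_recording` or `mi_trials`.
#' @param i Trial indices to keep.
#' @return An object of the same class restricted to the selected trials.
#' @export
subset_trials <- function(x, i) UseMethod("subset_trials")

#' @export
subset_trials.mi_recording <- function(x, i) {
  x$data <- x$data[i, , , drop = FALSE]
  x$labels <- x$labels[i]
  x
}

#' @export
subset_trials.mi_trials <- subset_trials.mi_recording

#' Extract scalp EEG channels from a raw recording
#'
#' Drops the EOG and marker channels, keeping the 30 scalp channels
#' (including the all-zero CPz reference) in montage order.
#'
#' @param rec An `mi_recording`.
#' @param band Optional band annotation carried into the result.
#' @return An `mi_trials`.
#' @export
eeg_trials <- function(rec, band = NULL) {
  idx <- scalp_channels(rec$layout)
  mi_trials(rec$data[, idx, , drop = FALSE], rec$labels,
            sample_rate = rec$sample_rate, band = band,
            subject_id = rec$subject_id,
            channel_names = rec$layout$name[idx])
}

#' Slice a time window out of epoched trials
#'
#' @param x An `mi_trials`.
#' @param window Length-2 numeric `(start, end)` in seconds relative to the
#'   motor-imagery onset; the sample at `end` is excluded.
#' @param mi_onset Onset of the MI period within the epoch, seconds.
#' @return An `mi_trials` restricted to the window.
#' @export
extract_window <- function(x, window, mi_onset = 2.0) {
  fs <- x$sample_rate
  n <- dim(x$data)[3]
  i0 <- round((mi_onset + window[1]) * fs) + 1L
  i1 <- round((mi_onset + window[2]) * fs)
  if (i0 < 1L || i1 > n || i0 > i1)
    stop("window falls outside the epoch", call. = FALSE)
  x$data <- x$data[, , i0:i1, drop = FALSE]
  x
}

#' @export
print.mi_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mi_recording %s: %d trials x %d channels x %d samples @ %g Hz>\n",
              x$subject_id, d[1], d[2], d[3], x$sample_rate))
  tab <- table(factor(x$labels, levels = c(1, 2),
                      labels = c("left", "right")), useNA = "ifany")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mi_trials <- function(x, ...) {
  d <- dim(x$data)
  band <- if (is.null(x$band)) "broadband" else
    sprintf("%g-%g Hz", x$band[1], x$band[2])
  cat(sprintf("<mi_trials %s: %d trials x %d channels x %d samples, %s>\n",
              x$subject_id, d[1], d[2], d[3], band))
  invisible(x)
}
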