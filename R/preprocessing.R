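# Preprocessing chain: per-trial mean removal, zero-phase FIR and
# Butterworth band-pass filters, and marker-based epoching of a continuous
# stream. Filters are designed with the signal package and applied
# forward-and-backward by a compiled kernel, with odd-reflection padding of
# min(3 * (filter length - 1), n - 1) samples to suppress edge transients.

# Apply a zero-phase filter along the time axis of a vector, a
# channels x samples matrix, or a trials x channels x samples array.
apply_zero_phase <- function(data, b, a = 1) {
  pad <- 3L * (max(length(b), length(a)) - 1L)
  if (is.null(dim(data))) {
    m <- matrix(data, ncol = 1L)
    return(as.vector(.zerophase_filter_cpp(b, a, m, pad)))
  }
  d <- dim(data)
  if (length(d) == 2L) {             # channels x samples
    out <- .zerophase_filter_cpp(b, a, t(data), pad)
    return(t(out))
  }
  # trials x channels x samples: fold trials*channels into columns
  m <- matrix(aperm(data, c(3, 2, 1)), nrow = d[3])
  out <- .zerophase_filter_cpp(b, a, m, pad)
  aperm(array(out, dim = d[c(3, 2, 1)]), c(3, 2, 1))
}

n_time_samples <- function(data) {
  if (is.null(dim(data))) length(data) else dim(data)[length(dim(data))]
}

#' Remove the per-trial, per-channel temporal mean
#'
#' Baseline removal by the mean-removal method: for every trial and channel
#' the mean over time samples is subtracted, so each output channel has zero
#' temporal mean.
#'
#' @param data Numeric vector, `channels x samples` matrix, or
#'   `trials x channels x samples` array.
#' @return Same shape as `data`, mean-removed along time.
#' @export
remove_baseline <- function(data) {
  if (!all(is.finite(data)))
    stop("input contains non-finite values", call. = FALSE)
  if (is.null(dim(data))) return(data - mean(data))
  d <- dim(data)
  if (length(d) == 2L) return(data - rowMeans(data))
  mu <- apply(data, c(1, 2), mean)
  data - array(rep(mu, d[3]), dim = d)
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR design applied forward and
#' backward, giving zero net phase and a squared magnitude response. The
#' default 0.5-40 Hz band and 825 taps correspond to a ~2 Hz transition
#' width at 500 Hz; because that transition is wider than the 0.5 Hz low
#' edge, the per-channel temporal mean is removed before filtering so the
#' band-pass fully rejects DC (the operation stays linear).
#'
#' @param data Vector, `channels x samples` matrix or
#'   `trials x channels x samples` array.
#' @param low,high Band edges in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param n_taps Number of FIR coefficients; the signal must be longer than
#'   `3 * n_taps` samples.
#' @return Filtered data of the same shape.
#' @export
fir_bandpass <- function(data, low = 0.5, high = 40, sample_rate = 500,
                         n_taps = 825) {
  stopifnot(low > 0, low < high, high < sample_rate / 2)
  n <- n_time_samples(data)
  if (n <= 3L * n_taps)
    stop(sprintf("signal too short: %d samples for a %d-tap filter (need > %d)",
                 n, n_taps, 3L * n_taps), call. = FALSE)
  b <- signal::fir1(n_taps - 1L, c(low, high) / (sample_rate / 2),
                    type = "pass")
  apply_zero_phase(remove_baseline(data), b)
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 2nd-order Butterworth filter applied forward and backward (effective
#' 4th-order magnitude, zero phase), the filter used for all 8-30 Hz
#' validation analyses.
#'
#' @inheritParams fir_bandpass
#' @param order Butterworth order of each pass.
#' @return Filtered data of the same shape.
#' @export
butter_bandpass_zero_phase <- function(data, low = 8, high = 30, order = 2,
                                       sample_rate = 500) {
  stopifnot(low > 0, low < high, high < sample_rate / 2)
  if (n_time_samples(data) < 4L * (2L * order + 1L))
    stop("signal too short for the requested filter order", call. = FALSE)
  bt <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  apply_zero_phase(data, bt$b, bt$a)
}

#' Band-pass filter the trials of a recording or trial set
#'
#' @param x An `mi_trials` (all channels filtered) or `mi_recording` (scalp
#'   channels filtered; EOG and marker channels untouched).
#' @param low,high Band edges in Hz.
#' @param order Butterworth order.
#' @return The same class of object with its `band` annotation set (for
#'   `mi_trials`).
#' @export
bandpass_trials <- function(x, low = 8, high = 30, order = 2) {
  if (inherits(x, "mi_recording")) {
    idx <- scalp_channels(x$layout)
    x$data[, idx, ] <- butter_bandpass_zero_phase(
      x$data[, idx, , drop = FALSE], low, high, order, x$sample_rate)
    return(x)
  }
  x$data <- butter_bandpass_zero_phase(x$data, low, high, order,
                                       x$sample_rate)
  x$band <- c(low, high)
  x
}

#' Cut a continuous multichannel stream into trials at marker events
#'
#' One epoch of `epoch_len` samples starts at every sample where the marker
#' channel equals 1 (the epoching marker); the marker sample itself is the
#' epoch's first sample. Epochs running past the end of the stream are
#' dropped with a warning.
#'
#' @param continuous Numeric `channels x samples` matrix containing the full
#'   montage (marker channel included).
#' @param layout Montage describing the rows of `continuous`.
#' @param epoch_len Epoch length in samples.
#' @param labels Optional per-trial labels; if omitted the recording carries
#'   `NA` labels (the marker does not encode the task side).
#' @param subject_id Subject identifier for the result.
#' @return An [mi_recording()].
#' @export
epoch_by_marker <- function(continuous, layout = builtin_layout(),
                            epoch_len = 4000, labels = NULL,
                            subject_id = "sub-01") {
  if (nrow(continuous) != nrow(layout))
    stop("continuous data must contain all montage channels", call. = FALSE)
  marker <- continuous[marker_channel(layout), ]
  onsets <- which(marker == 1)
  if (!length(onsets))
    stop("no epoching markers (value 1) found in the marker channel",
         call. = FALSE)
  complete <- onsets[onsets + epoch_len - 1L <= ncol(continuous)]
  if (length(complete) < length(onsets))
    warning(sprintf("dropped %d incomplete epoch(s) at the end of the stream",
                    length(onsets) - length(complete)), call. = FALSE)
  if (!length(complete))
    stop("no complete epochs: stream shorter than one epoch", call. = FALSE)
  n_tr <- length(complete)
  out <- array(0, dim = c(n_tr, nrow(continuous), epoch_len))
  for (i in seq_len(n_tr))
    out[i, , ] <- continuous[, complete[i]:(complete[i] + epoch_len - 1L)]
  if (is.null(labels)) labels <- rep(NA_integer_, n_tr)
  mi_recording(out, labels, layout = layout, subject_id = subject_id)
}
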