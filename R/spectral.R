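# Qualitative-validation computations: ERD/ERS% time courses, Morlet
# time-frequency maps and band-power scalp topographies.

# Centered moving average with window `w` samples; edges use the partial
# window so the curve keeps its length and (approximately) its mean.
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  kern <- rep(1, w)
  num <- stats::filter(x, kern / w, sides = 2)
  norm <- stats::filter(rep(1, length(x)), kern / w, sides = 2)
  out <- as.vector(num / norm)
  out[is.na(out)] <- x[is.na(out)]
  out
}

# Welch power spectral density estimate (Hamming windows, 50% overlap).
welch_psd <- function(x, sample_rate, n_seg = 512) {
  n_seg <- min(n_seg, length(x))
  step <- max(1L, n_seg %/% 2L)
  starts <- seq(1L, length(x) - n_seg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n_seg - 1) / (n_seg - 1))
  scale <- sum(w^2) * sample_rate
  nf <- n_seg %/% 2L + 1L
  p <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg))^2 / scale
    p <- p + sp[1:nf]
  }
  p <- p / length(starts)
  p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  list(freq = (0:(nf - 1L)) * sample_rate / n_seg, psd = p)
}

band_power_welch <- function(x, band, sample_rate, n_seg = 512) {
  ps <- welch_psd(x, sample_rate, n_seg)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
}

#' ERD/ERS% time course for one channel
#'
#' Computes the event-related desynchronization/synchronization percentage:
#' trials of the requested label are band-pass filtered, squared, averaged
#' across trials, smoothed with a centered moving average (smoothness
#' coefficient = window length in samples), and expressed as
#' `ERD/ERS% = (X - M) / M * 100` where `X` is the smoothed averaged power at
#' each time sample and `M` its mean over the preparation (baseline) window.
#' Negative values are desynchronization (power loss), positive values
#' synchronization.
#'
#' @param rec An [mi_recording()].
#' @param channel Channel name, e.g. `"C3"`.
#' @param label Task label to average (1 = left-hand, 2 = right-hand MI).
#' @param band Band edges in Hz.
#' @param smooth Moving-average window in samples (0.4 s at 500 Hz by
#'   default).
#' @param baseline Length-2 numeric, baseline window in seconds relative to
#'   MI onset.
#' @param mi_onset MI onset within the epoch, seconds.
#' @return An object of class `erd_curve`: list with `time` (seconds
#'   relative to MI onset), `percent`, `channel`, `band`,
#'   `n_trials_averaged`.
#' @export
erd_ers_curve <- function(rec, channel, label, band = c(8, 30), smooth = 200,
                          baseline = c(-1, 0), mi_onset = 2.0) {
  sel <- which(rec$labels == label)
  if (!length(sel)) stop("no trials with label ", label, call. = FALSE)
  fs <- rec$sample_rate
  ch <- channel_index(rec$layout, channel)
  x <- rec$data[sel, ch, , drop = FALSE]          # trials x 1 x samples
  n <- dim(x)[3]
  xf <- butter_bandpass_zero_phase(x, band[1], band[2], sample_rate = fs)
  avg <- colMeans(matrix(xf^2, nrow = length(sel)))  # mean over trials
  sm <- moving_average(avg, smooth)
  t_rel <- (seq_len(n) - 1) / fs - mi_onset
  bsel <- t_rel >= baseline[1] & t_rel < baseline[2]
  if (!any(bsel)) stop("baseline window falls outside the epoch",
                       call. = FALSE)
  M <- mean(sm[bsel])
  if (abs(M) < .Machine$double.eps * 100)
    stop("degenerate baseline: mean power in the preparation window is zero",
         call. = FALSE)
  structure(list(time = t_rel, percent = (sm - M) / M * 100,
                 channel = channel, band = band,
                 n_trials_averaged = length(sel), baseline = baseline,
                 sample_rate = fs),
            class = "erd_curve")
}

#' @export
print.erd_curve <- function(x, ...) {
  cat(sprintf("<erd_curve %s %g-%g Hz, %d trials; min %.1f%%, max %.1f%%>\n",
              x$channel, x$band[1], x$band[2], x$n_trials_averaged,
              min(x$percent), max(x$percent)))
  invisible(x)
}

#' @export
plot.erd_curve <- function(x, ...) {
  graphics::plot(x$time, x$percent, type = "l",
                 xlab = "time rel. MI onset (s)", ylab = "ERD/ERS (%)",
                 main = sprintf("%s, %g-%g Hz", x$channel, x$band[1],
                                x$band[2]), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Morlet wavelet time-frequency map of one signal
#'
#' Convolves the signal with complex Morlet wavelets (fixed number of cycles
#' per frequency) and returns squared coefficient magnitudes, i.e. power per
#' (frequency, time) cell.
#'
#' @param x Numeric signal vector.
#' @param sample_rate Sampling rate in Hz.
#' @param freqs Frequency grid in Hz.
#' @param n_cycles Cycles per wavelet (time-frequency trade-off).
#' @param channel Channel name annotation.
#' @return An object of class `tfr_map`: `freqs`, `time`, `power`
#'   (freq x time, non-negative), `channel`.
#' @export
morlet_tfr <- function(x, sample_rate = 500, freqs = 8:30, n_cycles = 7,
                       channel = NA_character_) {
  if (any(freqs >= sample_rate / 2))
    stop("frequencies must lie below the Nyquist frequency", call. = FALSE)
  if (any(freqs <= 0)) stop("frequencies must be positive", call. = FALSE)
  n <- length(x)
  longest <- ceiling(7 * n_cycles / (2 * pi * min(freqs)) * sample_rate)
  if (n < longest)
    stop(sprintf("signal too short: %d samples; the %g Hz wavelet needs %d",
                 n, min(freqs), longest), call. = FALSE)
  nfft <- stats::nextn(2L * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  power <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sd_t <- n_cycles / (2 * pi * f)
    half <- min(ceiling(3.5 * sd_t * sample_rate), n - 1L)
    tt <- (-half:half) / sample_rate
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sd_t^2))
    w <- w / sqrt(sum(Mod(w)^2))                  # unit-energy wavelet
    W <- fft(c(w, rep(0, nfft - length(w))))
    conv <- fft(X * W, inverse = TRUE) / nfft
    power[i, ] <- Mod(conv[(half + 1L):(half + n)])^2
  }
  structure(list(freqs = freqs, time = (seq_len(n) - 1) / sample_rate,
                 power = power, channel = channel,
                 sample_rate = sample_rate, n_cycles = n_cycles),
            class = "tfr_map")
}

#' @export
print.tfr_map <- function(x, ...) {
  cat(sprintf("<tfr_map %s: %d freqs (%g-%g Hz) x %d samples>\n",
              x$channel, length(x$freqs), min(x$freqs), max(x$freqs),
              ncol(x$power)))
  invisible(x)
}

#' @export
plot.tfr_map <- function(x, ...) {
  graphics::image(x$time, x$freqs, t(x$power), xlab = "time (s)",
                  ylab = "frequency (Hz)", main = x$channel, ...)
  invisible(x)
}

#' Band-power scalp topography
#'
#' Mean squared band-filtered amplitude per scalp channel over a time
#' window, averaged across same-label trials, with an inverse-distance
#' weighted interpolation onto a unit-disc grid for plotting (brain
#' electrical activity mapping).
#'
#' @param rec An [mi_recording()].
#' @param label Task label to average.
#' @param band Band edges in Hz.
#' @param window Length-2 numeric, seconds relative to MI onset.
#' @param mi_onset MI onset within the epoch, seconds.
#' @param grid_n Interpolation grid resolution.
#' @return An object of class `topo_map`: `channel_power` (named), `grid`
#'   (list `x`, `y`, `z`), `band`, `label`.
#' @export
band_power_topomap <- function(rec, label, band = c(8, 30), window = c(0, 4),
                               mi_onset = 2.0, grid_n = 67) {
  sel <- which(rec$labels == label)
  if (!length(sel)) stop("no trials with label ", label, call. = FALSE)
  fs <- rec$sample_rate
  n <- dim(rec$data)[3]
  i0 <- round((mi_onset + window[1]) * fs) + 1L
  i1 <- round((mi_onset + window[2]) * fs)
  if (i0 < 1L || i1 > n || i0 > i1)
    stop("window falls outside the epoch", call. = FALSE)
  idx <- scalp_channels(rec$layout)
  x <- rec$data[sel, idx, , drop = FALSE]
  xf <- butter_bandpass_zero_phase(x, band[1], band[2], sample_rate = fs)
  pw <- apply(xf[, , i0:i1, drop = FALSE]^2, 2, mean)
  names(pw) <- rec$layout$name[idx]

  scalp <- rec$layout[idx, ]
  gx <- seq(-1, 1, length.out = grid_n)
  gz <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    if (gx[i]^2 + gx[j]^2 > 1.05) next
    d2 <- (scalp$x - gx[i])^2 + (scalp$y - gx[j])^2
    hit <- which(d2 < 1e-12)
    gz[i, j] <- if (length(hit)) pw[hit[1]] else
      sum(pw / d2) / sum(1 / d2)
  }
  structure(list(channel_power = pw,
                 grid = list(x = gx, y = gx, z = gz),
                 band = band, label = label, window = window),
            class = "topo_map")
}

#' @export
print.topo_map <- function(x, ...) {
  top <- names(sort(x$channel_power, decreasing = TRUE))[1:3]
  cat(sprintf("<topo_map label %d, %g-%g Hz; strongest: %s>\n",
              x$label, x$band[1], x$band[2], paste(top, collapse = ", ")))
  invisible(x)
}

#' @export
plot.topo_map <- function(x, ...) {
  graphics::image(x$grid$x, x$grid$y, x$grid$z, asp = 1,
                  xlab = "", ylab = "",
                  main = sprintf("label %d, %g-%g Hz", x$label,
                                 x$band[1], x$band[2]), ...)
  invisible(x)
}

#' Per-class C3/C4 band-power laterality table
#'
#' For each task label, compares mean band power at the left (C3) and right
#' (C4) sensorimotor electrodes over the MI window. A class is flagged
#' contralateral-dominant when the ipsilateral electrode keeps more power
#' than the (desynchronized) contralateral one by at least `min_asymmetry`
#' of their mean: C3 > C4 for left-hand MI, C4 > C3 for right-hand MI.
#'
#' @param rec An [mi_recording()].
#' @param band Band edges in Hz.
#' @param window MI window in seconds relative to onset.
#' @param mi_onset MI onset within the epoch, seconds.
#' @param min_asymmetry Minimum relative power asymmetry to flag dominance.
#' @return Data frame with columns `subject_id`, `label`, `p_c3`, `p_c4`,
#'   `contralateral_dominant`.
#' @export
laterality_report <- function(rec, band = c(8, 30), window = c(0, 4),
                              mi_onset = 2.0, min_asymmetry = 0.1) {
  if (!n_trials(rec)) stop("recording holds no trials", call. = FALSE)
  rows <- lapply(c(1L, 2L), function(lb) {
    if (!any(rec$labels == lb)) return(NULL)
    tm <- band_power_topomap(rec, lb, band, window, mi_onset)
    p3 <- tm$channel_power[["C3"]]
    p4 <- tm$channel_power[["C4"]]
    ipsi <- if (lb == 1L) p3 else p4              # same side as imagined hand
    contra <- if (lb == 1L) p4 else p3
    data.frame(subject_id = rec$subject_id, label = lb, p_c3 = p3, p_c4 = p4,
               contralateral_dominant =
                 (ipsi - contra) / ((ipsi + contra) / 2) > min_asymmetry)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("recording holds no labelled trials", call. = FALSE)
  out
}
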