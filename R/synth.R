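# Synthetic stroke-cohort MI-EEG generator. Each subject's recording
# emulates the statistical structure the analyses assume: mu (10 Hz) and
# beta (20 Hz) rhythm sources seated at C3 and C4, mixed into the scalp
# montage with Gaussian spatial falloff; class-dependent contralateral
# amplitude suppression (ERD) during the MI window with raised-cosine
# ramps; 1/f background noise; blink/saccade EOG artifacts leaking into
# frontal channels; a marker channel; and clinical covariates sampled from
# the cohort's summary statistics. Ground-truth sidecars expose the
# injected parameters for recovery tests.

#' Configuration of the synthetic MI-EEG generator
#'
#' Defaults reproduce the study conditions: 50 subjects, 40 trials of 8 s at
#' 500 Hz with the MI period spanning 2-6 s, and a contralateral ERD depth
#' of 0.4. Rhythm and noise amplitudes (mu 10 uV, beta 5 uV, pink noise
#' 15 uV RMS) place single-trial decodability in the 60-75% range
#' characteristic of acute-stroke MI data.
#'
#' @param n_subjects Number of subjects.
#' @param n_trials Trials per subject (alternating left/right).
#' @param sample_rate Sampling rate, Hz.
#' @param epoch_s Trial length, seconds.
#' @param mi_onset_s,mi_dur_s MI period within the trial, seconds.
#' @param erd_depth Fractional amplitude suppression of the contralateral
#'   rhythm source during MI, in `[0, 1]`.
#' @param ers_ipsi Fractional amplitude gain of the ipsilateral source.
#' @param mu_freq,beta_freq Rhythm frequencies, Hz.
#' @param mu_amp,beta_amp Rhythm amplitudes at the source electrode, uV.
#' @param noise_amp Pink-noise RMS amplitude per channel, uV.
#' @param noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param spatial_sigma Gaussian falloff of source mixing over unit-disc
#'   scalp distance.
#' @param amp_jitter Log-SD of the per-source, per-trial amplitude jitter.
#' @param blink_rate,blink_amp,eog_leak Blink arrival rate (Hz), blink
#'   amplitude (uV) and frontal leakage coefficient.
#' @param rhythm_freq_jitter Half-width (Hz) of the uniform per-subject
#'   jitter of the mu and beta peak frequencies (reactive rhythms vary
#'   across individuals).
#' @param emg_rate,emg_amp,emg_sigma Muscle/motion artifact bursts: Poisson
#'   arrival rate (per second), RMS amplitude (uV) of the 15-45 Hz
#'   band-limited bursts, and the Gaussian spatial spread tying them to the
#'   lateral temporal/frontal electrodes (part of the recorded trials carry
#'   such artifacts).
#' @param idle_freq,idle_amp,idle_jitter,idle_sigma Non-reactive "idle"
#'   beta rhythm (beta activity is bursty, with large trial-to-trial
#'   amplitude variability): frequency (Hz), amplitude (uV), log-SD of the
#'   per-trial amplitude, and Gaussian spatial spread around the vertex.
#'   Carries no class information.
#' @param erd_window Optional fixed `(start, end)` seconds relative to MI
#'   onset during which the ERD modulation is active. The default (`NULL`)
#'   samples a subject-specific transient window: onset uniform over
#'   `erd_onset_range` and duration uniform over `erd_dur_range`, mirroring
#'   the rise-and-recovery time course and between-subject variability of
#'   real event-related desynchronization.
#' @param erd_onset_range,erd_dur_range Ranges (s, relative to MI onset) for
#'   the sampled ERD onset and duration when `erd_window` is `NULL`.
#' @param erd_on_beta Apply the ERD modulation to the beta source as well as
#'   the mu source.
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 50, n_trials = 40,
                             sample_rate = 500, epoch_s = 8,
                             mi_onset_s = 2.0, mi_dur_s = 4.0,
                             erd_depth = 0.4, ers_ipsi = 0,
                             mu_freq = 10, beta_freq = 20,
                             mu_amp = 10, beta_amp = 5,
                             noise_amp = 15, noise_exponent = 1,
                             spatial_sigma = 0.3, amp_jitter = 0.45,
                             blink_rate = 0.2, blink_amp = 120,
                             eog_leak = 0.25,
                             rhythm_freq_jitter = 1.5,
                             emg_rate = 0.03, emg_amp = 40,
                             emg_sigma = 0.15,
                             idle_freq = 26, idle_amp = 8,
                             idle_jitter = 1, idle_sigma = 0.3,
                             erd_window = NULL,
                             erd_onset_range = c(0.25, 1.25),
                             erd_dur_range = c(1.5, 2.5),
                             erd_on_beta = TRUE,
                             seed = 42) {
  cfg <- as.list(environment())
  if (cfg$mi_onset_s + cfg$mi_dur_s > cfg$epoch_s)
    stop("MI period must end inside the epoch", call. = FALSE)
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  if (cfg$ers_ipsi < 0) stop("ers_ipsi must be >= 0", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

#' Sample a synthetic cohort of participant records
#'
#' Clinical covariates are drawn from clipped normal distributions matching
#' the cohort's published mean/SD and ranges: age N(56.70, 10.57) clipped to
#' 31-77 years, post-stroke duration N(5.78, 6.90) clipped to 1-30 days,
#' NIHSS N(4.16, 2.85) on 0-42, MBI N(70.94, 18.22) on 0-100, mRS
#' N(2.66, 1.44) on 0-5; 39/50 male, 27/50 left-side paralysis.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return Data frame with columns `participant_id`, `sex`, `age`,
#'   `duration_days`, `paralysis_side`, `nihss`, `mbi`, `mrs`.
#' @export
generate_cohort <- function(n = 50, seed = 42) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  with_seed(seed, data.frame(
    participant_id = sprintf("sub-%02d", seq_len(n)),
    sex = ifelse(runif(n) < 39 / 50, "male", "female"),
    age = clip(rnorm(n, 56.70, 10.57), 31, 77),
    duration_days = clip(rnorm(n, 5.78, 6.90), 1, 30),
    paralysis_side = ifelse(runif(n) < 27 / 50, "left", "right"),
    nihss = round(clip(rnorm(n, 4.16, 2.85), 0, 42)),
    mbi = clip(rnorm(n, 70.94, 18.22), 0, 100),
    mrs = round(clip(rnorm(n, 2.66, 1.44), 0, 5)),
    stringsAsFactors = FALSE))
}

# Columns of 1/f^(alpha/2)-shaped unit-RMS noise (n samples x m channels).
pink_noise <- function(n, m, exponent = 1) {
  white <- matrix(rnorm(n * m), n, m)
  f <- c(1, seq_len(n %/% 2), rev(seq_len(n - 1 - n %/% 2)))  # DC reused
  scale <- 1 / f^(exponent / 2)
  scale[1] <- 0                                  # no DC power
  shaped <- Re(mvfft(mvfft(white) * scale, inverse = TRUE)) / n
  sweep(shaped, 2, apply(shaped, 2, sd), `/`)
}

# Raised-cosine gate: 0 outside [t0, t1], 1 inside, cosine ramps of
# `ramp` seconds at both edges.
rc_gate <- function(t, t0, t1, ramp = 0.25) {
  g <- numeric(length(t))
  g[t >= t0 + ramp & t <= t1 - ramp] <- 1
  up <- t >= t0 & t < t0 + ramp
  g[up] <- 0.5 * (1 - cos(pi * (t[up] - t0) / ramp))
  dn <- t > t1 - ramp & t <= t1
  g[dn] <- 0.5 * (1 - cos(pi * (t1 - t[dn]) / ramp))
  g
}

# 300-ms blink pulse shape (area-normalised to unit peak).
blink_pulse <- function(sample_rate, dur = 0.3, tau = 0.075) {
  t <- seq(0, dur, by = 1 / sample_rate)
  (t / tau) * exp(1 - t / tau)
}

#' Generate one subject's synthetic recording
#'
#' Labels alternate left (1) / right (2). During the MI window the rhythm
#' source contralateral to the imagined hand (C3 for right-hand, C4 for
#' left-hand MI) is amplitude-scaled by `1 - erd_depth` and the ipsilateral
#' source by `1 + ers_ipsi`, with 250-ms raised-cosine ramps. The reference
#' channel CPz is identically zero, the marker channel carries 1 at the
#' first sample and 2 at MI onset.
#'
#' @param participant One-row data frame from [generate_cohort()] (or
#'   `NULL`).
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this subject.
#' @return List with `recording` (an [mi_recording()]) and `ground_truth`
#'   (injected parameters for recovery tests).
#' @export
generate_subject_recording <- function(participant = NULL,
                                       config = synthetic_config(),
                                       seed = config$seed) {
  cfg <- config
  fs <- cfg$sample_rate
  n <- round(cfg$epoch_s * fs)
  n_tr <- cfg$n_trials
  layout <- builtin_layout()
  scalp <- scalp_channels(layout)
  t <- (seq_len(n) - 1) / fs

  subject_id <- if (!is.null(participant)) participant$participant_id else
    "sub-01"
  labels <- rep_len(c(1L, 2L), n_tr)

  # Gaussian spatial mixing of the C3/C4 sources into the scalp channels
  src_names <- c("C3", "C4")
  src_idx <- channel_index(layout, src_names)
  lay_s <- layout[scalp, ]
  gains <- vapply(src_idx, function(si) {
    d2 <- (lay_s$x - layout$x[si])^2 + (lay_s$y - layout$y[si])^2
    exp(-d2 / (2 * cfg$spatial_sigma^2))
  }, numeric(length(scalp)))                       # scalp x 2

  # ERD gate: fixed window if configured, else a subject-specific transient
  ew <- cfg$erd_window
  if (is.null(ew)) {
    ew <- with_seed(child_seed(seed, 17L), {
      onset <- runif(1, cfg$erd_onset_range[1], cfg$erd_onset_range[2])
      dur <- runif(1, cfg$erd_dur_range[1], cfg$erd_dur_range[2])
      c(onset, min(onset + dur, cfg$mi_dur_s))
    })
  }
  gate <- rc_gate(t, cfg$mi_onset_s + ew[1], cfg$mi_onset_s + ew[2])

  frontal_d2 <- (lay_s$x)^2 + (lay_s$y - 1)^2     # distance to front pole
  leak <- cfg$eog_leak * exp(-frontal_d2 / (2 * 0.35^2))

  # EMG/motion artifact mixing: bursts are tied to the lateral
  # temporal/frontal ring with a tight spatial spread
  emg_sites <- intersect(c("T3", "T4", "F7", "F8", "FT7", "FT8",
                           "TP7", "TP8"), lay_s$name)
  emg_idx <- match(emg_sites, lay_s$name)
  emg_gain <- vapply(emg_idx, function(si) {
    d2 <- (lay_s$x - lay_s$x[si])^2 + (lay_s$y - lay_s$y[si])^2
    exp(-d2 / (2 * cfg$emg_sigma^2))
  }, numeric(nrow(lay_s)))

  data <- array(0, dim = c(n_tr, 33L, n))
  with_seed(seed, {
    # subject-specific reactive rhythm peaks
    mu_f <- cfg$mu_freq + runif(1, -1, 1) * cfg$rhythm_freq_jitter
    beta_f <- cfg$beta_freq + runif(1, -1, 1) * cfg$rhythm_freq_jitter
    for (tr in seq_len(n_tr)) {
      lb <- labels[tr]
      contra <- if (lb == 2L) 1L else 2L          # index into src (C3, C4)
      sig <- matrix(0, length(scalp), n)
      for (s in 1:2) {
        A <- exp(rnorm(1, 0, cfg$amp_jitter))
        scale_target <- if (s == contra) 1 - cfg$erd_depth else
          1 + cfg$ers_ipsi
        env <- 1 + (scale_target - 1) * gate
        rhythm <- cfg$mu_amp * sin(2 * pi * mu_f * t + runif(1, 0, 2 * pi))
        beta_env <- if (cfg$erd_on_beta) env else 1
        beta <- cfg$beta_amp * sin(2 * pi * beta_f * t + runif(1, 0, 2 * pi))
        src_sig <- A * (env * rhythm + beta_env * beta)
        sig <- sig + outer(gains[, s], rep(1, n)) *
          matrix(src_sig, length(scalp), n, byrow = TRUE)
      }
      # non-reactive vertex idle rhythm with bursty per-trial amplitude
      if (cfg$idle_amp > 0) {
        cz_gain <- exp(-((lay_s$x)^2 + (lay_s$y)^2) /
                         (2 * cfg$idle_sigma^2))
        idle <- cfg$idle_amp * exp(rnorm(1, 0, cfg$idle_jitter)) *
          sin(2 * pi * cfg$idle_freq * t + runif(1, 0, 2 * pi))
        sig <- sig + outer(cz_gain, idle)
      }
      # muscle/motion bursts (15-45 Hz) at lateral electrodes
      n_emg <- rpois(1, cfg$emg_rate * cfg$epoch_s)
      if (n_emg > 0 && cfg$emg_amp > 0) {
        for (bsti in seq_len(n_emg)) {
          dur <- round(runif(1, 0.3, 0.8) * fs)
          at <- sample.int(n - dur, 1)
          burst <- butter_bandpass_zero_phase(rnorm(dur), 15, 45,
                                              sample_rate = fs)
          burst <- burst / sd(burst) * cfg$emg_amp * exp(rnorm(1, 0, 0.3))
          burst <- burst * sin(pi * seq_len(dur) / dur)^2  # smooth on/off
          site <- sample(seq_along(emg_idx), 1)
          sig[, at:(at + dur - 1L)] <- sig[, at:(at + dur - 1L)] +
            outer(emg_gain[, site], burst)
        }
      }
      sig <- sig + t(pink_noise(n, length(scalp), cfg$noise_exponent)) *
        cfg$noise_amp
      # EOG channels and their frontal leakage
      veog <- heog <- numeric(n)
      n_blinks <- rpois(1, cfg$blink_rate * cfg$epoch_s)
      if (n_blinks > 0) {
        pulse <- blink_pulse(fs)
        for (b in seq_len(n_blinks)) {
          at <- sample.int(n - length(pulse), 1)
          amp <- cfg$blink_amp * exp(rnorm(1, 0, 0.2))
          veog[at:(at + length(pulse) - 1L)] <-
            veog[at:(at + length(pulse) - 1L)] + amp * pulse
        }
      }
      n_sacc <- rpois(1, 0.3 * cfg$epoch_s)
      if (n_sacc > 0) {
        pulse <- blink_pulse(fs, dur = 0.15, tau = 0.04)
        for (b in seq_len(n_sacc)) {
          at <- sample.int(n - length(pulse), 1)
          heog[at:(at + length(pulse) - 1L)] <-
            heog[at:(at + length(pulse) - 1L)] +
            0.3 * cfg$blink_amp * sample(c(-1, 1), 1) * pulse
        }
      }
      heog <- heog + 0.2 * veog                   # blinks bleed horizontally
      sig <- sig + outer(leak, rep(1, n)) *
        matrix(veog + 0.5 * heog, length(scalp), n, byrow = TRUE)
      sig[match(channel_index(layout, "CPz"), scalp), ] <- 0  # reference
      data[tr, scalp, ] <- sig
      data[tr, channel_index(layout, "HEOL"), ] <- heog +
        5 * pink_noise(n, 1, cfg$noise_exponent)
      data[tr, channel_index(layout, "VEOR"), ] <- veog +
        5 * pink_noise(n, 1, cfg$noise_exponent)
      data[tr, 33L, 1L] <- 1
      data[tr, 33L, round(cfg$mi_onset_s * fs) + 1L] <- 2
    }
  })

  gt <- list(
    labels = labels,
    erd_depth = cfg$erd_depth,
    ers_ipsi = cfg$ers_ipsi,
    source_channels = src_names,
    expected_power_ratio = (1 - cfg$erd_depth)^2,
    active_freqs = c(mu = mu_f,
                     beta = if (cfg$erd_on_beta) beta_f else NA_real_),
    erd_window_s = ew,                 # rel. MI onset
    mi_window_s = cfg$mi_onset_s + ew, # within the epoch
    seed = seed)
  list(recording = mi_recording(data, labels, sample_rate = fs,
                                layout = layout, subject_id = subject_id),
       ground_truth = gt)
}

#' Generate a full synthetic dataset on disk
#'
#' Samples a cohort, generates one recording per subject (each seeded
#' independently from the master seed), writes the EEG-BIDS style tree via
#' [build_bids_tree()] and stores per-subject ground-truth sidecars as JSON
#' under `ground_truth/`.
#'
#' @param config A [synthetic_config()].
#' @param root Target directory.
#' @param overwrite Passed to [build_bids_tree()].
#' @param preprocess Write FIR-preprocessed EDF exports (slower); see
#'   [build_bids_tree()].
#' @return `root`, invisibly.
#' @export
generate_dataset <- function(config = synthetic_config(), root,
                             overwrite = FALSE, preprocess = TRUE) {
  cohort <- generate_cohort(config$n_subjects, seed = config$seed)
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    generate_subject_recording(cohort[i, ], config,
                               seed = child_seed(config$seed, i)))
  build_bids_tree(lapply(subjects, `[[`, "recording"), cohort, root,
                  overwrite = overwrite, preprocess = preprocess)
  gt_dir <- file.path(root, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  for (i in seq_along(subjects)) {
    jsonlite::write_json(
      subjects[[i]]$ground_truth,
      file.path(gt_dir, paste0(cohort$participant_id[i], "_ground-truth.json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(root)
}
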