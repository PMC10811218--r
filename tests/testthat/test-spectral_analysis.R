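# Recording with a hand-built envelope at C3: amplitude scale `amp_mi`
# during the MI window, 1 elsewhere; a 10 Hz carrier everywhere.
envelope_recording <- function(amp_mi = 1, n_trials = 6, ch = "C3") {
  lay <- builtin_layout()
  fs <- 500; n <- 4000
  t <- (0:(n - 1)) / fs
  env <- rep(1, n)
  env[t >= 2 & t < 6] <- amp_mi
  data <- array(0, dim = c(n_trials, 33, n))
  for (tr in seq_len(n_trials))
    data[tr, channel_index(lay, ch), ] <-
      env * sin(2 * pi * 10 * t + tr)   # deterministic phase spread
  data[, 33, 1] <- 1
  data[, 33, 1001] <- 2
  mi_recording(data, rep_len(1:2, n_trials), layout = lay)
}

test_that("the ERD/ERS formula identities hold on constructed power", {
  # X == M everywhere -> 0% away from the epoch-edge filter transients
  rec <- envelope_recording(amp_mi = 1)
  cv <- erd_ers_curve(rec, "C3", 1)
  interior <- cv$time > -1.5 & cv$time < 5.5
  expect_lt(max(abs(cv$percent[interior])), 1.5)
  expect_equal(length(cv$percent), 4000L)
  expect_equal(cv$time[2] - cv$time[1], 1 / 500)

  # X == 0.5 M during MI -> -50% there
  rec2 <- envelope_recording(amp_mi = sqrt(0.5))
  cv2 <- erd_ers_curve(rec2, "C3", 1)
  mi <- cv2$time > 0.5 & cv2$time < 3.5   # clear of the envelope edges
  expect_equal(mean(cv2$percent[mi]), -50, tolerance = 0.04)
  base <- cv2$time > -0.8 & cv2$time < -0.3  # clear of the envelope step
  expect_lt(max(abs(cv2$percent[base])), 4)
})

test_that("ERD/ERS% is invariant to a common amplitude scale", {
  rec <- envelope_recording(amp_mi = 0.7)
  cv1 <- erd_ers_curve(rec, "C3", 1)
  rec$data <- rec$data * 3.7
  cv2 <- erd_ers_curve(rec, "C3", 1)
  expect_equal(cv1$percent, cv2$percent, tolerance = 1e-10)
})

test_that("smoothing preserves the epoch mean and degenerate baselines error", {
  set.seed(3)
  x <- abs(rnorm(4000)) + 1
  sm <- strokemi:::moving_average(x, 200)
  expect_equal(mean(sm), mean(x), tolerance = 0.01)

  rec <- envelope_recording(amp_mi = 1)
  expect_error(erd_ers_curve(rec, "C3", 1, baseline = c(-10, -9)),
               "baseline")
  # silent channel -> zero baseline power
  expect_error(erd_ers_curve(rec, "Fz", 1), "degenerate")
})

test_that("Morlet maps localise tones and track chirps", {
  fs <- 500
  x <- sin(2 * pi * 10 * (0:1999) / fs)
  tf <- morlet_tfr(x, fs)
  interior <- 400:1600
  ridge <- tf$freqs[apply(tf$power[, interior], 2, which.max)]
  expect_true(all(ridge == 10))
  expect_true(all(tf$power >= 0))

  expect_equal(max(morlet_tfr(rep(0, 2000), fs)$power), 0)

  # linear chirp 10 -> 20 Hz over 8 s; the ridge must follow the
  # instantaneous-frequency oracle f(t) = 10 + slope * t
  t <- (0:3999) / fs
  slope <- 1.25
  chirp <- sin(2 * pi * (10 * t + slope * t^2 / 2))
  tfc <- morlet_tfr(chirp, fs)
  interior <- seq(500, 3500, by = 250)
  ridge <- tfc$freqs[apply(tfc$power[, interior], 2, which.max)]
  oracle <- 10 + slope * t[interior]
  expect_true(all(abs(ridge - oracle) <= 1))
  expect_true(all(diff(ridge) >= 0))

  expect_error(morlet_tfr(x, fs, freqs = c(10, 300)), "Nyquist")
  expect_error(morlet_tfr(x[1:100], fs), "too short")
})

test_that("topomaps put the power where it was injected", {
  rec <- envelope_recording(amp_mi = 1)
  tm <- band_power_topomap(rec, 1)
  expect_equal(names(which.max(tm$channel_power)), "C3")
  # the interpolated maximum sits at the hottest channel's position
  lay <- builtin_layout()
  peak <- which(tm$grid$z == max(tm$grid$z, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(abs(tm$grid$x[peak[1]] - lay$x[14]), 0.1)
  expect_lt(abs(tm$grid$y[peak[2]] - lay$y[14]), 0.1)

  # identical channels give a flat map
  rec2 <- envelope_recording(amp_mi = 1)
  sig <- rec2$data[, 14, ]
  for (ch in strokemi:::scalp_channels()) rec2$data[, ch, ] <- sig
  tm2 <- band_power_topomap(rec2, 1)
  expect_lt(max(tm2$channel_power) / min(tm2$channel_power), 1.01)
  expect_lt(max(tm2$grid$z, na.rm = TRUE) /
              min(tm2$grid$z, na.rm = TRUE), 1.01)

  expect_error(band_power_topomap(rec, 1, window = c(5, 9)), "window")
})

test_that("laterality flags follow the injected contralateral asymmetry", {
  # bilateral symmetric rhythm: no dominance
  rec <- envelope_recording(amp_mi = 1)
  sig <- rec$data[, 14, ]
  rec$data[, 15, ] <- sig
  rep_sym <- laterality_report(rec)
  expect_false(any(rep_sym$contralateral_dominant))

  # strong contralateral ERD from the generator
  g <- fixture("lat_subj", function()
    generate_subject_recording(
      NULL, synthetic_config(erd_depth = 0.5, erd_window = c(0, 4)),
      seed = 21))
  rep_erd <- laterality_report(g$recording)
  expect_true(all(rep_erd$contralateral_dominant))
  expect_gt(rep_erd$p_c3[rep_erd$label == 1], rep_erd$p_c4[rep_erd$label == 1])
  expect_gt(rep_erd$p_c4[rep_erd$label == 2], rep_erd$p_c3[rep_erd$label == 2])

  empty <- subset_trials(rec, integer(0))
  expect_error(laterality_report(empty), "no trials")
})
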