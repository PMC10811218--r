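test_that("cohort covariates stay in their clinical ranges and are seeded", {
  co <- generate_cohort(50, seed = 42)
  expect_equal(nrow(co), 50L)
  expect_true(all(co$age >= 31 & co$age <= 77))
  expect_true(all(co$duration_days >= 1 & co$duration_days <= 30))
  expect_true(all(co$nihss >= 0 & co$nihss <= 42 & co$nihss %% 1 == 0))
  expect_true(all(co$mbi >= 0 & co$mbi <= 100))
  expect_true(all(co$mrs >= 0 & co$mrs <= 5 & co$mrs %% 1 == 0))
  expect_true(all(co$sex %in% c("male", "female")))
  expect_true(all(co$paralysis_side %in% c("left", "right")))
  expect_identical(co, generate_cohort(50, seed = 42))
  expect_error(generate_cohort(0), "positive")
})

test_that("subject recordings carry the deposit's structure", {
  g <- default_subject()
  rec <- g$recording
  expect_equal(dim(rec$data), c(40L, 33L, 4000L))
  expect_equal(rec$sample_rate, 500)
  expect_equal(as.vector(table(rec$labels)), c(20L, 20L))
  expect_equal(rec$labels[1:4], c(1L, 2L, 1L, 2L))
  # marker: 1 at the first sample, 2 at MI onset, 0 elsewhere
  expect_true(all(rec$data[, 33, 1] == 1))
  expect_true(all(rec$data[, 33, 1001] == 2))
  expect_equal(sum(rec$data[, 33, ] != 0), 80L)
  # CPz reference is identically zero
  expect_true(all(rec$data[, 18, ] == 0))
  # determinism
  g2 <- generate_subject_recording(NULL, synthetic_config(), seed = 11)
  expect_identical(g2$recording$data, rec$data)
  expect_error(
    generate_subject_recording(NULL, synthetic_config(mi_onset_s = 6)),
    "MI period")
})

test_that("rhythm sources concentrate their power at the configured frequencies", {
  cfg <- synthetic_config(noise_amp = 0, blink_rate = 0, eog_leak = 0,
                          erd_depth = 0, n_trials = 4)
  g <- generate_subject_recording(NULL, cfg, seed = 3)
  x <- g$recording$data[1, 14, ]              # C3, pure rhythm
  ps <- strokemi:::welch_psd(x, 500, n_seg = 1000)
  df <- ps$freq[2] - ps$freq[1]
  near <- (abs(ps$freq - cfg$mu_freq) <= 1) | (abs(ps$freq - cfg$beta_freq) <= 1)
  expect_gt(sum(ps$psd[near]) / sum(ps$psd), 0.8)
})

test_that("zero ERD depth leaves the classes spectrally indistinguishable", {
  # two-sample t statistics of C3 band power, label 2 vs 1, across seeds
  tstats <- vapply(1:20, function(s) {
    g <- generate_subject_recording(NULL, synthetic_config(erd_depth = 0),
                                    seed = 100 + s)
    rec <- g$recording
    bp <- vapply(seq_len(40), function(i) {
      xf <- butter_bandpass_zero_phase(rec$data[i, 14, 1001:3000],
                                       sample_rate = 500)
      mean(xf^2)
    }, numeric(1))
    unname(t.test(log(bp[rec$labels == 2]), log(bp[rec$labels == 1]))$statistic)
  }, numeric(1))
  # under a true null the expected maximum of 20 |t| values is ~2.8 and
  # exceeds 3 about once in ten batches, so the check bounds the batch,
  # not each draw
  expect_lt(mean(abs(tstats)), 1.5)
  expect_lt(max(abs(tstats)), 4)
})

test_that("the injected ERD depth is recovered from band-power ratios", {
  # compare the MI window against the pre-cue baseline WITHIN the same
  # label-2 trials: the per-trial source amplitude cancels exactly, so the
  # noise-corrected ratio equals (1 - depth)^2. The noise floor comes from
  # a rhythm-free regeneration with the identical noise realisation.
  g <- default_subject()                       # erd_depth 0.4, seed 11
  rec <- g$recording
  gt <- g$ground_truth
  fs <- rec$sample_rate
  gn <- fixture("noise_only", function()
    generate_subject_recording(
      NULL, synthetic_config(mu_amp = 0, beta_amp = 0), seed = 11))
  seg_power <- function(r, from_s, to_s) {
    i0 <- round(from_s * fs) + 1L; i1 <- round(to_s * fs)
    mean(vapply(which(r$labels == 2L), function(i)
      mean(butter_bandpass_zero_phase(r$data[i, 14, i0:i1],
                                      sample_rate = fs)^2), numeric(1)))
  }
  base <- c(1, 2)                              # -1..0 s before MI onset
  mi <- gt$mi_window_s + c(0.3, -0.3)          # clear of the ERD ramps
  ratio <- (seg_power(rec, mi[1], mi[2]) - seg_power(gn$recording, mi[1], mi[2])) /
    (seg_power(rec, base[1], base[2]) - seg_power(gn$recording, base[1], base[2]))
  expect_equal(ratio, g$ground_truth$expected_power_ratio, tolerance = 0.2)
})

test_that("datasets regenerate byte-identically and carry sidecars", {
  cfg <- synthetic_config(n_subjects = 2, n_trials = 4)
  td <- withr::local_tempdir()
  r1 <- file.path(td, "d1"); r2 <- file.path(td, "d2")
  generate_dataset(cfg, r1, preprocess = FALSE)
  generate_dataset(cfg, r2, preprocess = FALSE)
  mats1 <- list.files(file.path(r1, "sourcedata"), recursive = TRUE,
                      full.names = TRUE)
  expect_length(mats1, 2L)
  expect_true(dir.exists(file.path(r1, "sourcedata", "sub-02")))
  expect_false(dir.exists(file.path(r1, "sourcedata", "sub-03")))
  for (m in mats1) {
    twin <- sub(r1, r2, m, fixed = TRUE)
    expect_identical(unname(tools::md5sum(m)), unname(tools::md5sum(twin)))
  }
  gt <- jsonlite::read_json(
    file.path(r1, "ground_truth", "sub-01_ground-truth.json"),
    simplifyVector = TRUE)
  expect_equal(gt$erd_depth, 0.4)
  expect_length(gt$labels, 4L)
})
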