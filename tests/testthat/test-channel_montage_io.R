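test_that("the builtin montage matches the dataset's channel table", {
  lay <- builtin_layout()
  expect_equal(nrow(lay), 33L)
  expect_equal(sum(lay$role %in% c("eeg", "reference")), 30L)
  expect_equal(lay$role[31:32], c("eog", "eog"))
  expect_equal(lay$role[33], "marker")
  expect_equal(lay$name[18], "CPz")
  expect_equal(lay$role[18], "reference")
  expect_equal(lay$name[13:15], c("Cz", "C3", "C4"))
  expect_equal(lay$name[31], "HEOL")
  expect_equal(lay$name[1:12],
               c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "FCz",
                 "FC3", "FC4", "FT7", "FT8"))
  # channel 21 is the table's duplicated-FT7 entry, resolved to TP7
  expect_equal(lay$name[21:22], c("TP7", "TP8"))
})

test_that("scalp coordinates lie on the unit disc with mirrored pairs", {
  lay <- builtin_layout()
  scalp <- lay[!is.na(lay$x), ]
  expect_equal(nrow(scalp), 30L)
  expect_true(all(scalp$x^2 + scalp$y^2 <= 1 + 1e-9))
  pairs <- list(c("C3", "C4"), c("F3", "F4"), c("Fp1", "Fp2"),
                c("FC3", "FC4"), c("CP3", "CP4"), c("P3", "P4"),
                c("T3", "T4"), c("O1", "O2"), c("FT7", "FT8"),
                c("TP7", "TP8"), c("F7", "F8"), c("T5", "T6"))
  for (p in pairs) {
    i <- match(p, lay$name)
    expect_equal(lay$x[i[1]], -lay$x[i[2]], info = paste(p, collapse = "/"))
    expect_equal(lay$y[i[1]], lay$y[i[2]], info = paste(p, collapse = "/"))
  }
  # name lookup inverts the table
  expect_equal(channel_index(lay, lay$name), lay$index)
  expect_error(channel_index(lay, "XX7"), "unknown channel")
})

test_that("MAT containers round-trip raw recordings bit-identically", {
  rec <- small_recording()
  td <- withr::local_tempdir()
  p <- write_raw_mat(rec, td)
  expect_equal(basename(p), "sub-01_task-motor-imagery_eeg.mat")
  rec2 <- read_raw_mat(p)
  expect_identical(rec2$data, rec$data)
  expect_identical(rec2$labels, rec$labels)
  expect_equal(rec2$subject_id, "sub-01")
  expect_equal(rec2$sample_rate, 500)

  # canonical synthetic file has the deposit's shape
  full <- default_subject()$recording
  p2 <- write_raw_mat(full, file.path(td, "sub-07_task-motor-imagery_eeg.mat"))
  rec3 <- read_raw_mat(p2)
  expect_equal(dim(rec3$data), c(40L, 33L, 4000L))
  expect_equal(rec3$subject_id, "sub-07")
})

test_that("the MAT reader enforces the dataset schema", {
  td <- withr::local_tempdir()
  rec <- small_recording()
  # missing variable is named in the error
  f1 <- file.path(td, "bad1.mat")
  strokemi:::mat5_write(list(rawdata = rec$data), f1)
  expect_error(read_raw_mat(f1), "labels")
  # labels outside {1, 2}
  f2 <- file.path(td, "bad2.mat")
  strokemi:::mat5_write(list(rawdata = rec$data,
                             labels = c(1, 2, 3, 1, 2, 1, 2, 1)), f2)
  expect_error(read_raw_mat(f2), "1.*2")
  # wrong channel count
  f3 <- file.path(td, "bad3.mat")
  strokemi:::mat5_write(list(rawdata = rec$data[, 1:30, ],
                             labels = as.numeric(rec$labels)), f3)
  expect_error(read_raw_mat(f3), "channels")
  # row-oriented label vectors are accepted
  f4 <- file.path(td, "row.mat")
  strokemi:::mat5_write(list(rawdata = rec$data,
                             labels = matrix(as.numeric(rec$labels),
                                             nrow = 1)), f4)
  expect_identical(read_raw_mat(f4)$labels, rec$labels)
  expect_error(read_raw_mat(file.path(td, "nope.mat")), "not found")
})

test_that("the MAT reader understands compressed level-5 elements", {
  td <- withr::local_tempdir()
  rec <- small_recording()
  p <- write_raw_mat(rec, td)
  raw <- readBin(p, "raw", n = file.size(p))
  # re-wrap the uncompressed elements into one miCOMPRESSED element
  body <- raw[129:length(raw)]
  comp <- memCompress(body, type = "gzip")
  con <- file(file.path(td, "comp.mat"), "wb")
  writeBin(raw[1:128], con)
  writeBin(as.integer(c(15L, length(comp))), con, size = 4L,
           endian = "little")
  writeBin(comp, con)
  close(con)
  rec2 <- read_raw_mat(file.path(td, "comp.mat"))
  expect_identical(rec2$data, rec$data)
})

test_that("EDF export/import stays within the 16-bit quantization bound", {
  rec <- small_recording()
  trials <- eeg_trials(rec)
  td <- withr::local_tempdir()
  p <- write_edf(trials, td)
  expect_equal(basename(p), "sub01_task-motor-imagery_eeg.edf")

  hdr <- readBin(p, "raw", n = 256)
  n_sig <- as.integer(trimws(rawToChar(hdr[253:256])))
  expect_equal(n_sig, 30L)
  sig_hdr <- readBin(p, "raw", n = 256 * 31)
  samples_field <- trimws(rawToChar(
    sig_hdr[(257 + 216 * 30):(256 + 216 * 30 + 8)]))
  expect_equal(as.integer(samples_field), 500L)  # 500 Hz, 1-s records

  tr2 <- read_edf(p)
  qstep <- 2000 / 65535
  expect_lt(max(abs(tr2$data - trials$data)), qstep)
  expect_identical(tr2$labels, trials$labels)
  expect_equal(dim(tr2$data), dim(trials$data))

  # amplitudes beyond the physical range are clipped with a warning
  hot <- trials
  hot$data[1, 1, 1] <- 5000
  expect_warning(write_edf(hot, file.path(td, "clip.edf")), "clipped")
  clipped <- read_edf(file.path(td, "clip.edf"))
  expect_lt(abs(clipped$data[1, 1, 1] - 1000), qstep)

  expect_error(read_edf(file.path(td, "absent.edf")), "not found")
  writeBin(raw(300), file.path(td, "junk.edf"))
  expect_error(read_edf(file.path(td, "junk.edf")), "malformed")
})

test_that("the BIDS tree holds one MAT and one EDF per subject", {
  recs <- lapply(1:2, function(i) {
    r <- generate_subject_recording(
      NULL, synthetic_config(n_trials = 4), seed = i)$recording
    r$subject_id <- sprintf("sub-%02d", i)
    r
  })
  parts <- generate_cohort(2, seed = 1)
  td <- withr::local_tempdir()
  root <- file.path(td, "bids")
  build_bids_tree(recs, parts, root, preprocess = FALSE)
  expect_length(list.files(file.path(root, "sourcedata"), pattern = "\\.mat$",
                           recursive = TRUE), 2L)
  expect_length(list.files(file.path(root, "edffile"), pattern = "\\.edf$"), 2L)
  pt <- read.table(file.path(root, "participants.tsv"), sep = "\t",
                   header = TRUE)
  expect_equal(nrow(pt), 2L)
  expect_true(file.exists(file.path(root, "channel_location.locs")))
  expect_true(dir.exists(file.path(root, "stimuli")))

  # refuses to clobber a non-empty tree without overwrite
  expect_error(build_bids_tree(recs, parts, root), "not empty")
  expect_silent(build_bids_tree(recs, parts, root, overwrite = TRUE,
                                preprocess = FALSE))

  # empty subject list leaves metadata only
  root2 <- file.path(td, "empty")
  build_bids_tree(list(), NULL, root2)
  expect_true(file.exists(file.path(root2, "participants.tsv")))
  expect_length(list.files(file.path(root2, "sourcedata")), 0L)
})
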