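# EDF (European Data Format) export/import of preprocessed trials. Samples
# are 16-bit with a symmetric physical range (default +/-1000 uV) so the
# quantization step is (2 * phys_range) / 65535. One data record per second;
# the trial epoch length is recorded in the file-level reserved field so the
# reader can rebuild the trials x channels x samples tensor.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_filename <- function(subject_id) {
  sprintf("%s_task-motor-imagery_eeg.edf", sub("-", "", subject_id))
}

#' Write preprocessed trials to an EDF file
#'
#' @param trials An [mi_trials()] holding the 30 scalp channels.
#' @param path Target file, or a directory in which to place the canonically
#'   named `subxx_task-motor-imagery_eeg.edf` file.
#' @param phys_range Symmetric physical range in microvolts; amplitudes
#'   beyond it are clipped with a warning.
#' @return The path written, invisibly.
#' @export
write_edf <- function(trials, path, phys_range = 1000) {
  d <- dim(trials$data)
  fs <- trials$sample_rate
  if (d[3] %% fs != 0L)
    stop("epoch length must be a whole number of 1-s records", call. = FALSE)
  if (dir.exists(path))
    path <- file.path(path, edf_filename(trials$subject_id))
  n_rec_per_trial <- d[3] %/% fs
  n_records <- d[1] * n_rec_per_trial
  n_sig <- d[2]

  x <- trials$data
  n_clip <- sum(abs(x) > phys_range)
  if (n_clip > 0) {
    warning(sprintf("%d samples exceeded the +/-%g uV physical range and were clipped",
                    n_clip, phys_range), call. = FALSE)
    x[x > phys_range] <- phys_range
    x[x < -phys_range] <- -phys_range
  }
  gain <- 65535 / (2 * phys_range)
  dig <- round((x + phys_range) * gain) - 32768
  dig[dig > 32767] <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  band <- if (is.null(trials$band)) "" else
    sprintf(" BP:%g-%gHz", trials$band[1], trials$band[2])
  patient <- trials$subject_id
  if (!anyNA(trials$labels) && d[1] <= 60L)
    patient <- paste0(patient, " LBL=",
                      paste(c("L", "R")[trials$labels], collapse = ""))
  writeChar(paste0(
    edf_pad("0", 8L),
    edf_pad(patient, 80L),
    edf_pad(sprintf("Startdate X task motor-imagery%s", band), 80L),
    edf_pad("01.01.24", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(256L * (1L + n_sig), 8L),
    edf_pad(sprintf("EPOCHLEN=%d", d[3]), 44L),
    edf_pad(n_records, 8L),
    edf_pad("1", 8L),
    edf_pad(n_sig, 4L)), con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(trials$channel_names, 16L)
  field(rep("AgAgCl electrode", n_sig), 80L)
  field(rep("uV", n_sig), 8L)
  field(rep(-phys_range, n_sig), 8L)
  field(rep(phys_range, n_sig), 8L)
  field(rep(-32768L, n_sig), 8L)
  field(rep(32767L, n_sig), 8L)
  field(rep("", n_sig), 80L)
  field(rep(fs, n_sig), 8L)
  field(rep("", n_sig), 32L)

  # records: trial-major, then second within trial; each record holds fs
  # samples per signal, signals in montage order
  for (tr in seq_len(d[1])) {
    for (r in seq_len(n_rec_per_trial)) {
      s0 <- (r - 1L) * fs
      block <- t(dig[tr, , (s0 + 1L):(s0 + fs)])   # fs x n_sig
      writeBin(as.integer(block), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read preprocessed trials from an EDF file
#'
#' Inverts [write_edf()]: signals are converted back to physical units and
#' regrouped into trials using the epoch length stored in the header's
#' reserved field.
#'
#' @param path Path to the `.edf` file.
#' @return An [mi_trials()] (labels are unknown to EDF and set from the
#'   alternating left/right task order).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 256L) stop("malformed EDF header: file too short",
                             call. = FALSE)
  gets <- function(from, width) trimws(rawToChar(r[from:(from + width - 1L)]))
  if (gets(1L, 8L) != "0") stop("malformed EDF header: bad version field",
                                call. = FALSE)
  patient <- gets(9L, 80L)
  subject_id <- sub("\\s+LBL=.*$", "", patient)
  lbl <- regmatches(patient, regexpr("LBL=[LR]+", patient))
  reserved <- gets(193L, 44L)
  n_records <- as.integer(gets(237L, 8L))
  dur <- as.numeric(gets(245L, 8L))
  n_sig <- as.integer(gets(253L, 4L))
  if (is.na(n_records) || is.na(n_sig) || n_sig < 1L)
    stop("malformed EDF header: bad record/signal counts", call. = FALSE)
  sig_field <- function(block_off, width, i)
    gets(257L + block_off * n_sig + (i - 1L) * width, width)
  # per-signal byte offsets: label 0, transducer 16, dimension 96,
  # phys min 104, phys max 112, dig min 120, dig max 128, prefilter 136,
  # samples/record 216, reserved 224
  labels <- vapply(seq_len(n_sig), function(i) sig_field(0L, 16L, i), "")
  pmin_ <- as.numeric(vapply(seq_len(n_sig), function(i) sig_field(104L, 8L, i), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_sig), function(i) sig_field(112L, 8L, i), ""))
  ns <- as.integer(vapply(seq_len(n_sig), function(i) sig_field(216L, 8L, i), ""))
  if (length(unique(ns)) != 1L)
    stop("EDF files with mixed per-signal rates are not supported",
         call. = FALSE)
  fs <- ns[1] / dur
  off <- 256L * (1L + n_sig)
  vals <- readBin(r[(off + 1L):length(r)], "integer",
                  n = n_records * n_sig * ns[1], size = 2L, endian = "little")
  # -> samples x signals x records
  a <- array(as.double(vals), dim = c(ns[1], n_sig, n_records))
  phys <- array(0, dim = dim(a))
  for (i in seq_len(n_sig)) {
    gain <- (pmax_[i] - pmin_[i]) / 65535
    phys[, i, ] <- (a[, i, ] + 32768) * gain + pmin_[i]
  }
  m <- regmatches(reserved, regexpr("EPOCHLEN=[0-9]+", reserved))
  epoch_len <- if (length(m)) as.integer(sub("EPOCHLEN=", "", m)) else
    ns[1] * n_records
  rec_per_trial <- epoch_len %/% ns[1]
  n_tr <- n_records %/% rec_per_trial
  out <- array(0, dim = c(n_tr, n_sig, epoch_len))
  for (tr in seq_len(n_tr)) {
    recs <- ((tr - 1L) * rec_per_trial + 1L):(tr * rec_per_trial)
    out[tr, , ] <- aperm(phys[, , recs, drop = FALSE], c(2, 1, 3))
  }
  band <- NULL
  bm <- regmatches(gets(89L, 80L), regexpr("BP:[0-9.]+-[0-9.]+Hz", gets(89L, 80L)))
  if (length(bm)) {
    band <- as.numeric(strsplit(sub("Hz", "", sub("BP:", "", bm)), "-")[[1]])
  }
  trial_labels <- if (length(lbl)) {
    match(strsplit(sub("LBL=", "", lbl), "")[[1]], c("L", "R"))
  } else {
    # EDF itself carries no task labels; fall back to the alternating
    # left/right task order of the experimental protocol
    rep_len(c(1L, 2L), n_tr)
  }
  mi_trials(out, labels = trial_labels, sample_rate = fs,
            band = band, subject_id = subject_id, channel_names = labels)
}
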