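# MAT-file level-5 container I/O, restricted to what the dataset schema
# needs: named real numeric arrays. The writer emits uncompressed elements;
# the reader additionally understands zlib-compressed (miCOMPRESSED)
# elements and the small-element tag format that MATLAB uses for short
# fields. HDF5-backed (v7.3) containers are rejected with a clear error.

MI_MATRIX <- 14L
MI_COMPRESSED <- 15L

mat5_pad <- function(n) (8L - n %% 8L) %% 8L

mat5_write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, size = 4L, endian = "little")
}

mat5_write_array <- function(con, name, a) {
  dims <- dim(a)
  if (is.null(dims)) dims <- c(length(a), 1L)
  nb_name <- nchar(name, type = "bytes")
  nb_dims <- 4L * length(dims)
  nb_data <- 8L * length(a)
  total <- 16L +                                   # array flags
    8L + nb_dims + mat5_pad(nb_dims) +             # dimensions
    8L + nb_name + mat5_pad(nb_name) +             # name
    8L + nb_data + mat5_pad(nb_data)               # real data
  mat5_write_tag(con, MI_MATRIX, total)
  mat5_write_tag(con, 6L, 8L)                      # miUINT32 flags block
  writeBin(c(6L, 0L), con, size = 4L, endian = "little")  # mxDOUBLE_CLASS
  mat5_write_tag(con, 5L, nb_dims)                 # miINT32 dims
  writeBin(as.integer(dims), con, size = 4L, endian = "little")
  writeBin(raw(mat5_pad(nb_dims)), con)
  mat5_write_tag(con, 1L, nb_name)                 # miINT8 name
  writeBin(charToRaw(name), con)
  writeBin(raw(mat5_pad(nb_name)), con)
  mat5_write_tag(con, 9L, nb_data)                 # miDOUBLE data
  writeBin(as.double(a), con, size = 8L, endian = "little")
  writeBin(raw(mat5_pad(nb_data)), con)
}

mat5_write <- function(vars, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  # fixed text (no timestamp) so identical data yields byte-identical files
  desc <- "MATLAB 5.0 MAT-file, written by strokemi"
  hdr <- charToRaw(desc)
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                           # subsystem offset
  writeBin(as.integer(256L), con, size = 2L, endian = "little")  # 0x0100
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) mat5_write_array(con, nm, vars[[nm]])
  invisible(path)
}

# -- reader ------------------------------------------------------------------

mat5_num_type <- function(type) {
  switch(as.character(type),
         "1" = list(what = "integer", size = 1L, signed = TRUE),
         "2" = list(what = "integer", size = 1L, signed = FALSE),
         "3" = list(what = "integer", size = 2L, signed = TRUE),
         "4" = list(what = "integer", size = 2L, signed = FALSE),
         "5" = list(what = "integer", size = 4L, signed = TRUE),
         "6" = list(what = "integer", size = 4L, signed = TRUE),
         "7" = list(what = "numeric", size = 4L, signed = TRUE),
         "9" = list(what = "numeric", size = 8L, signed = TRUE),
         NULL)
}

# Read one sub-element tag + payload from raw vector `r` at offset `off`
# (1-based). Returns list(type, data_raw, next_off).
mat5_read_element <- function(r, off) {
  word <- readBin(r[off:(off + 3L)], "integer", size = 4L, endian = "little")
  small_nb <- bitwAnd(bitwShiftR(word, 16L), 0xFFFFL)
  if (small_nb > 0L) {                             # small element format
    type <- bitwAnd(word, 0xFFFFL)
    data <- r[(off + 4L):(off + 3L + small_nb)]
    list(type = type, data = data, next_off = off + 8L)
  } else {
    type <- word
    nb <- readBin(r[(off + 4L):(off + 7L)], "integer", size = 4L,
                  endian = "little")
    data <- if (nb > 0L) r[(off + 8L):(off + 7L + nb)] else raw(0)
    list(type = type, data = data, next_off = off + 8L + nb + mat5_pad(nb))
  }
}

mat5_parse_matrix <- function(body) {
  off <- 1L
  flags <- mat5_read_element(body, off); off <- flags$next_off
  cls <- as.integer(flags$data[1])
  dims_el <- mat5_read_element(body, off); off <- dims_el$next_off
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) / 4L,
                  size = 4L, endian = "little")
  name_el <- mat5_read_element(body, off); off <- name_el$next_off
  name <- rawToChar(name_el$data)
  data_el <- mat5_read_element(body, off)
  ti <- mat5_num_type(data_el$type)
  if (is.null(ti) || !cls %in% 6:15)
    stop(sprintf("variable '%s' is not a real numeric array", name),
         call. = FALSE)
  n <- length(data_el$data) %/% ti$size
  vals <- readBin(data_el$data, ti$what, n = n, size = ti$size,
                  signed = ti$signed, endian = "little")
  a <- array(as.double(vals), dim = dims)
  list(name = name, value = a)
}

mat5_parse_elements <- function(r, off, vars = list()) {
  nr <- length(r)
  while (off + 7L <= nr) {
    el <- mat5_read_element(r, off)
    off <- el$next_off
    if (el$type == MI_COMPRESSED) {
      body <- tryCatch(memDecompress(el$data, type = "gzip"),
                       error = function(e)
                         stop("cannot decompress MAT element: ",
                              conditionMessage(e), call. = FALSE))
      vars <- mat5_parse_elements(body, 1L, vars)
    } else if (el$type == MI_MATRIX) {
      m <- mat5_parse_matrix(el$data)
      vars[[m$name]] <- m$value
    } # other top-level types are skipped
  }
  vars
}

mat5_read <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 128L) stop("not a MAT-file: too short", call. = FALSE)
  desc <- rawToChar(r[1:20])
  if (grepl("MAT-file, Platform.*7\\.3", rawToChar(r[1:116])) ||
      grepl("HDF5", rawToChar(r[1:116])))
    stop("HDF5-backed (v7.3) MAT containers are not supported; ",
         "re-save as level 5 (-v7 or -v6)", call. = FALSE)
  if (!grepl("^MATLAB 5", desc))
    stop("not a level-5 MAT-file", call. = FALSE)
  endian <- rawToChar(r[127:128])
  if (endian != "IM")
    stop("big-endian MAT-files are not supported", call. = FALSE)
  mat5_parse_elements(r, 129L)
}

# -- dataset-level wrappers --------------------------------------------------

raw_mat_filename <- function(subject_id) {
  sprintf("%s_task-motor-imagery_eeg.mat", subject_id)
}

#' Read one subject's raw recording from its MAT container
#'
#' Loads the `rawdata` (trials x channels x samples) and `labels` variables
#' from a `sub-xx_task-motor-imagery_eeg.mat` file and validates them against
#' the dataset schema: 33 channels, labels in `{1, 2}`, marker channel
#' restricted to `{0, 1, 2}`. The label vector may be stored row- or
#' column-oriented.
#'
#' @param path Path to the `.mat` file.
#' @param layout Montage to attach; defaults to [builtin_layout()].
#' @return An [mi_recording()].
#' @export
read_raw_mat <- function(path, layout = builtin_layout()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- mat5_read(path)
  for (required in c("rawdata", "labels")) {
    if (is.null(vars[[required]]))
      stop(sprintf("MAT container is missing required variable '%s'",
                   required), call. = FALSE)
  }
  a <- vars$rawdata
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 3L)
    stop("'rawdata' must have shape trials x channels x samples",
         call. = FALSE)
  if (dim(a)[2] != nrow(layout))
    stop(sprintf("'rawdata' has %d channels; the montage defines %d",
                 dim(a)[2], nrow(layout)), call. = FALSE)
  labels <- as.vector(vars$labels)
  if (!all(labels %in% c(1, 2)))
    stop("'labels' may only contain 1 (left) and 2 (right)", call. = FALSE)
  if (length(labels) != dim(a)[1])
    stop("'labels' length does not match the number of trials", call. = FALSE)
  m <- regmatches(basename(path), regexpr("sub-?[0-9]+", basename(path)))
  subject_id <- if (length(m)) sub("^sub-?", "sub-", m) else "sub-01"
  mi_recording(a, labels, sample_rate = 500, layout = layout,
               subject_id = subject_id)
}

#' Write a raw recording as a level-5 MAT container
#'
#' Serialises the `rawdata`/`labels` schema. When `path` is a directory the
#' canonical file name `sub-xx_task-motor-imagery_eeg.mat` is derived from
#' the recording's subject id.
#'
#' @param rec An [mi_recording()]; its invariants are re-validated before
#'   writing.
#' @param path Target file, or a directory in which to place the canonically
#'   named file.
#' @return The path written, invisibly.
#' @export
write_raw_mat <- function(rec, path) {
  validate_recording(rec)
  if (anyNA(rec$labels))
    stop("cannot serialise a recording with missing labels", call. = FALSE)
  if (dir.exists(path))
    path <- file.path(path, raw_mat_filename(rec$subject_id))
  mat5_write(list(rawdata = rec$data,
                  labels = matrix(as.double(rec$labels), ncol = 1L)), path)
  invisible(path)
}
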