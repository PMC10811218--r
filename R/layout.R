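#' The fixed 33-channel recording montage
#'
#' Returns the channel layout used by the dataset: 29 scalp EEG electrodes
#' placed by the international 10-10 system plus the CPz reference (channel
#' 18), horizontal and vertical EOG electrodes (channels 31-32) and one
#' marker-event channel (channel 33). Scalp positions are 2-D unit-disc
#' projections (x toward the right ear, y toward the nose, Cz at the origin);
#' left/right homologue pairs have mirrored x coordinates.
#'
#' The published montage table lists "FT7" twice (channels 11 and 21);
#' channel 21 is paired with TP8 at channel 22 and is therefore taken to be
#' TP7. [read_raw_mat()] warns if a file disagrees.
#'
#' @return A data frame of class `mi_layout` with columns `index`, `name`,
#'   `role` (one of `"eeg"`, `"reference"`, `"eog"`, `"marker"`), `x`, `y`
#'   (`NA` for non-scalp channels).
#' @examples
#' lay <- builtin_layout()
#' lay[lay$name %in% c("C3", "C4"), ]
#' @export
builtin_layout <- function() {
  pos <- list(
    Fp1 = c(-0.309, 0.951), Fp2 = c(0.309, 0.951),
    Fz  = c(0, 0.50),
    F3  = c(-0.43, 0.55),  F4  = c(0.43, 0.55),
    F7  = c(-0.809, 0.5878), F8 = c(0.809, 0.5878),
    FCz = c(0, 0.25),
    FC3 = c(-0.46, 0.28),  FC4 = c(0.46, 0.28),
    FT7 = c(-0.92, 0.31),  FT8 = c(0.92, 0.31),
    Cz  = c(0, 0),
    C3  = c(-0.50, 0),     C4  = c(0.50, 0),
    T3  = c(-1.0, 0),      T4  = c(1.0, 0),
    CPz = c(0, -0.25),
    CP3 = c(-0.46, -0.28), CP4 = c(0.46, -0.28),
    TP7 = c(-0.92, -0.31), TP8 = c(0.92, -0.31),
    Pz  = c(0, -0.50),
    P3  = c(-0.43, -0.55), P4  = c(0.43, -0.55),
    T5  = c(-0.809, -0.5878), T6 = c(0.809, -0.5878),
    Oz  = c(0, -1.0),
    O1  = c(-0.309, -0.951), O2 = c(0.309, -0.951)
  )
  name <- c("Fp1", "Fp2", "Fz", "F3", "F4", "F7", "F8", "FCz", "FC3", "FC4",
            "FT7", "FT8", "Cz", "C3", "C4", "T3", "T4", "CPz", "CP3", "CP4",
            "TP7", "TP8", "Pz", "P3", "P4", "T5", "T6", "Oz", "O1", "O2",
            "HEOL", "VEOR", "MARKER")
  role <- rep("eeg", 33L)
  role[18L] <- "reference"
  role[31:32] <- "eog"
  role[33L] <- "marker"
  xy <- t(vapply(name, function(nm) pos[[nm]] %||% c(NA_real_, NA_real_),
                 numeric(2)))
  out <- data.frame(index = 1:33, name = name, role = role,
                    x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("mi_layout", "data.frame")
  out
}

#' Look up channel indices by name
#'
#' @param layout An `mi_layout`.
#' @param name Character vector of channel names.
#' @return Integer channel indices.
#' @export
channel_index <- function(layout, name) {
  idx <- match(name, layout$name)
  if (anyNA(idx)) {
    stop("unknown channel name(s): ",
         paste(name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  layout$index[idx]
}

# Indices of the 30 scalp channels kept in processed data (EEG + reference).
scalp_channels <- function(layout = builtin_layout()) {
  layout$index[layout$role %in% c("eeg", "reference")]
}

marker_channel <- function(layout = builtin_layout()) {
  layout$index[layout$role == "marker"]
}
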