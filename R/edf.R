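# Minimal European Data Format (EDF) I/O: 16-bit signals, one header,
# 1-s data records. Annotations travel in the sidecar CSV dialect
# (onset_s, offset_s, label) rather than an embedded annotation channel.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Signals are quantized to 16 bits over each channel's physical range and
#' stored in 1-s data records; a trailing partial second is dropped.
#' Annotations are written to `paste0(path, ".annotations.csv")` when
#' present (see [write_annotations()]).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  keep <- seq_len(n_rec * fs)
  data <- rec$data[, keep, drop = FALSE]

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  same <- pmax_ - pmin_ < 1e-9
  pmax_[same] <- pmin_[same] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    pad_field("0", 8),
    pad_field(rec$id, 80),
    pad_field(sprintf("Startdate 01-JAN-2000 %s", rec$reference), 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("EDF+C", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)
  )
  sig <- c(
    vapply(rec$channel_labels, pad_field, "", width = 16),
    rep(pad_field("AgAgCl electrode", 80), ns),
    rep(pad_field("uV", 8), ns),
    vapply(sprintf("%.8g", pmin_), pad_field, "", width = 8),
    vapply(sprintf("%.8g", pmax_), pad_field, "", width = 8),
    rep(pad_field(dmin, 8), ns),
    rep(pad_field(dmax, 8), ns),
    rep(pad_field("", 80), ns),
    rep(pad_field(fs, 8), ns),
    rep(pad_field("", 32), ns)
  )
  writeChar(paste0(c(hdr, sig), collapse = ""), con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    cols <- seq((r - 1) * fs + 1, r * fs)
    for (s in seq_len(ns)) {
      dig <- round((data[s, cols] - pmin_[s]) * scale[s] + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2,
               endian = "little")
    }
  }
  if (nrow(rec$annotations) > 0) {
    write_annotations(rec$annotations, paste0(path, ".annotations.csv"))
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads 16-bit EDF signals back to physical units. Channels can be
#' subset (and reordered) by label; by default the 16 canonical montage
#' channels are selected when present. Annotations are taken from
#' `annotations_path`, or from `paste0(path, ".annotations.csv")` if that
#' file exists.
#'
#' @param path EDF file path.
#' @param channels Channel labels to keep, default [montage_channels()]
#'   intersected with the file's labels (all channels if none match).
#' @param annotations_path Optional sidecar annotation CSV.
#' @return An [eeg_recording()].
#' @export
read_recording_edf <- function(path, channels = NULL,
                               annotations_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  id <- rd(80)
  rd(80); rd(8); rd(8)        # recording field, date, time
  rd(8)                       # header bytes
  rd(44)                      # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fld(16)
  fld(80); fld(8)
  pmin_ <- as.numeric(fld(8))
  pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8))
  dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  if (length(unique(spr)) != 1) {
    stop("mixed sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[s], size = 2, endian = "little",
                     signed = TRUE)
      data[s, seq((r - 1) * spr[s] + 1, r * spr[s])] <-
        (dig - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  rownames(data) <- labels

  if (is.null(channels)) {
    hit <- intersect(montage_channels(), labels)
    channels <- if (length(hit) > 0) hit else labels
  }
  miss <- setdiff(channels, labels)
  if (length(miss) > 0) {
    stop("channel(s) not in file: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- data[channels, , drop = FALSE]

  sidecar <- annotations_path %||% paste0(path, ".annotations.csv")
  ann <- if (file.exists(sidecar)) read_annotations(sidecar) else NULL
  eeg_recording(data, fs, channels, annotations = ann, id = id)
}
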