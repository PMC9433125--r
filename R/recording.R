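#' The 16-channel 10--20 montage used for absence-seizure recordings
#'
#' Channel order is fixed across the package: Fp1, Fp2, F7, F8, F3, F4, C3,
#' C4, P3, P4, T3, T4, T5, T6, O1, O2.
#'
#' @return Character vector of the 16 channel labels.
#' @export
montage_channels <- function() {
  c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "C3", "C4",
    "P3", "P4", "T3", "T4", "T5", "T6", "O1", "O2")
}

#' Construct a multichannel EEG recording
#'
#' Container for a monopolar average-referenced scalp EEG: a channels x
#' samples matrix of amplitudes in microvolts, the sampling rate, channel
#' labels and a table of state annotations (half-open intervals in seconds).
#'
#' @param data Numeric matrix, channels x samples, microvolts.
#' @param fs Sampling rate in Hz (the recordings modelled here use 200 Hz).
#' @param channel_labels Character vector, one label per row of `data`;
#'   defaults to [montage_channels()] when the matrix has 16 rows.
#' @param annotations Data frame with columns `onset_s`, `offset_s`,
#'   `label`; intervals are `[onset_s, offset_s)` and must lie inside the
#'   recording. Labels `"ictal"` and `"inter_ictal"` drive epoching.
#' @param reference Reference descriptor, default `"average"`.
#' @param id Recording identifier used in provenance strings.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(16 * 400), nrow = 16), fs = 200)
#' rec
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL,
                          annotations = NULL, reference = "average",
                          id = "recording") {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("data must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (nrow(data) == 16) montage_channels() else
      paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("channel_labels length must equal nrow(data)", call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  rownames(data) <- channel_labels
  ann <- normalize_annotations(annotations, ncol(data) / fs)
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         reference = reference, annotations = ann, id = id),
    class = "eeg_recording"
  )
}

normalize_annotations <- function(annotations, duration_s) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    return(tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          label = character()))
  }
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(annotations))) {
    stop("annotations need columns onset_s, offset_s, label", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotations)[, need]
  ann$onset_s <- as.numeric(ann$onset_s)
  ann$offset_s <- as.numeric(ann$offset_s)
  ann$label <- as.character(ann$label)
  if (any(ann$onset_s >= ann$offset_s)) {
    stop("annotation intervals must satisfy onset_s < offset_s", call. = FALSE)
  }
  if (any(ann$onset_s < 0) || any(ann$offset_s > duration_s + 1e-9)) {
    stop("annotation intervals must lie within the recording", call. = FALSE)
  }
  dplyr::arrange(ann, .data$onset_s)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording '%s'>  %d channels x %d samples @ %g Hz (%.1f s), %s reference\n",
              x$id, nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  if (nrow(x$annotations) > 0) {
    a <- x$annotations
    cat(sprintf("  annotations: %s\n",
                paste(sprintf("%s [%g, %g)", a$label, a$onset_s, a$offset_s),
                      collapse = "; ")))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Length in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$data) / rec$fs
}

#' Read / write sidecar annotation tables
#'
#' The annotation dialect is a plain CSV with columns `onset_s`, `offset_s`,
#' `label` (seconds from recording start, half-open intervals).
#'
#' @param path File path.
#' @return `read_annotations()` returns a tibble; `write_annotations()`
#'   returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s", "label")
  if (!all(need %in% names(ann))) {
    stop("annotation file needs columns onset_s, offset_s, label",
         call. = FALSE)
  }
  tibble::as_tibble(ann)[, need]
}

#' @rdname read_annotations
#' @param annotations Annotation data frame.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
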