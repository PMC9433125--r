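# Preprocessing: zero-phase filtering, epoching around annotated seizure
# onsets, and amplitude-based artifact rejection.

# Forward-backward filtering with reflect padding so that edge transients
# from the IIR start-up do not leak into the retained samples.
filtfilt_padded <- function(filt, x, fs, pad_s = 1) {
  n <- length(x)
  pad <- max(ceiling(pad_s * fs), 24L)
  pad <- min(pad, n - 1L)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[seq(pad + 1, pad + n)]
}

apply_channelwise <- function(rec, filt, pad_s = 1) {
  out <- t(apply(rec$data, 1, function(x) filtfilt_padded(filt, x, rec$fs, pad_s)))
  rec$data <- out
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default fourth order, 1--70 Hz) forward
#' and backward, giving zero phase distortion (effective order doubled).
#' Phase preservation matters downstream: phase-locking values are computed
#' from instantaneous Hilbert phases, which a causal filter's group delay
#' would distort.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Passband edges in Hz. Must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth design order (applied twice), default 4.
#' @param pad_s Reflect-padding length in seconds used to suppress edge
#'   transients, default 1.
#' @return A new filtered `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(16 * 1000), 16), fs = 200)
#' filtered <- bandpass_filter(rec)
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 70, order = 4,
                            pad_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (high_hz >= rec$fs / 2) {
    stop("invalid band: high_hz must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  if (any(!is.finite(rec$data))) stop("non-finite samples", call. = FALSE)
  filt <- signal::butter(order, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  apply_channelwise(rec, filt, pad_s)
}

#' Zero-phase notch filter for mains interference
#'
#' Order-2 Butterworth band-stop of half-width 0.5 Hz around `f0_hz`,
#' applied forward-backward. Attenuation at `f0_hz` far exceeds 20 dB while
#' frequencies 2 Hz or more away are passed within 1 percent of unity.
#'
#' @inheritParams bandpass_filter
#' @param f0_hz Mains frequency to remove, default 50 Hz.
#' @param half_width_hz Half-width of the stop band, default 0.5 Hz.
#' @return A new filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, f0_hz = 50, half_width_hz = 0.5, pad_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(f0_hz > 0 && f0_hz < rec$fs / 2)) {
    stop("invalid band: f0_hz must lie in (0, fs/2)", call. = FALSE)
  }
  filt <- signal::butter(
    2, c(f0_hz - half_width_hz, f0_hz + half_width_hz) / (rec$fs / 2),
    type = "stop"
  )
  apply_channelwise(rec, filt, pad_s)
}

new_epoch_series <- function(tbl, fs, channel_labels, provenance) {
  tbl <- tibble::as_tibble(tbl)
  structure(tbl, fs = fs, channel_labels = channel_labels,
            provenance = provenance,
            class = c("epoch_series", class(tbl)))
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series>  %d epochs of %g s @ %g Hz  (%s)\n",
              nrow(x), 1, attr(x, "fs"), attr(x, "provenance")))
  print(table(factor(x$state, levels = state_levels())))
  invisible(x)
}

#' Restore epoch-series attributes after row subsetting
#'
#' dplyr verbs return plain tibbles; this reattaches the sampling rate,
#' channel labels and provenance from a template series.
#'
#' @param tbl Tibble of epochs.
#' @param template The epoch series the rows came from.
#' @return An `epoch_series`.
#' @export
as_epoch_series <- function(tbl, template) {
  new_epoch_series(tbl[, c("epoch", "state", "t_rel", "start_s", "data")],
                   attr(template, "fs"), attr(template, "channel_labels"),
                   attr(template, "provenance"))
}

#' Segment a filtered recording into labelled 1-s epochs
#'
#' Epochs are half-open 1-s windows `[t, t+1)` aligned to the annotated
#' seizure onset (the grid origin), so ictal epochs have `t_rel = 0, 1, ...`
#' counted from onset. The `pre_ictal_s` windows immediately preceding each
#' onset are labelled pre-ictal (`t_rel = -30 .. -1` by default); windows
#' following the seizure offset are post-ictal; complete windows inside
#' annotations labelled `"inter_ictal"` form the background control group.
#' Partial trailing windows are dropped. A pre-ictal window that overlaps
#' another annotated seizure is excluded (with a message), since consecutive
#' seizures can encroach on the 30-s pre-ictal span.
#'
#' @param rec A filtered [eeg_recording()] with annotations; seizures carry
#'   the label `"ictal"`, background control intervals `"inter_ictal"`.
#' @param pre_ictal_s Number of 1-s pre-ictal windows before each onset,
#'   default 30.
#' @param inter_ictal_s Maximum number of background windows taken per
#'   `"inter_ictal"` annotation, default 30.
#' @param post_ictal_s Number of post-ictal windows after each offset,
#'   default 30.
#' @return An `epoch_series`: a tibble with columns `epoch`, `state`,
#'   `t_rel` (integer seconds relative to the governing seizure onset),
#'   `start_s`, and a `data` list-column of channels x fs matrices.
#' @examples
#' cfg <- sim_config(duration_s = 60, seizure_onset_s = 40,
#'                   seizure_offset_s = 50, background_interval_s = c(2, 32))
#' rec <- simulate_recording(cfg)
#' ep <- make_epochs(bandpass_filter(rec))
#' table(ep$state)
#' @export
make_epochs <- function(rec, pre_ictal_s = 30, inter_ictal_s = 30,
                        post_ictal_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  win <- round(fs)
  n <- ncol(rec$data)
  if (n < win) stop("empty series: recording shorter than 1 s", call. = FALSE)
  ann <- rec$annotations
  ict <- ann[ann$label == "ictal", , drop = FALSE]
  if (nrow(ict) > 1) {
    if (any(ict$onset_s[-1] < ict$offset_s[-nrow(ict)])) {
      stop("overlapping ictal annotations", call. = FALSE)
    }
  }
  dur <- n / fs
  onset_ref <- if (nrow(ict) > 0) ict$onset_s[1] else 0

  cand <- list()
  add <- function(start_s, state, t_rel) {
    tibble::tibble(start_s = start_s, state = state, t_rel = as.integer(t_rel))
  }
  for (k in seq_len(nrow(ict))) {
    onset <- ict$onset_s[k]; offset <- ict$offset_s[k]
    n_ict <- floor(offset - onset + 1e-9)
    if (n_ict >= 1) {
      cand[[length(cand) + 1]] <-
        add(onset + seq_len(n_ict) - 1, "ictal", seq_len(n_ict) - 1)
    }
    pre <- onset - seq_len(pre_ictal_s)
    pre <- pre[pre >= 0]
    if (length(pre) > 0) {
      keep <- vapply(pre, function(s) {
        other <- ict[-k, , drop = FALSE]
        !any(s < other$offset_s & (s + 1) > other$onset_s)
      }, logical(1))
      if (any(!keep)) {
        message(sprintf("excluded %d pre-ictal window(s) overlapping another seizure",
                        sum(!keep)))
      }
      pre <- pre[keep]
      if (length(pre) > 0) {
        cand[[length(cand) + 1]] <-
          add(pre, "pre_ictal", round(pre - onset))
      }
    }
    post0 <- onset + ceiling(offset - onset - 1e-9)
    post <- post0 + seq_len(post_ictal_s) - 1
    post <- post[post + 1 <= dur + 1e-9]
    if (length(post) > 0) {
      cand[[length(cand) + 1]] <-
        add(post, "post_ictal", round(post - onset))
    }
  }
  bg <- ann[ann$label == "inter_ictal", , drop = FALSE]
  for (k in seq_len(nrow(bg))) {
    n_bg <- min(floor(bg$offset_s[k] - bg$onset_s[k] + 1e-9), inter_ictal_s)
    if (n_bg >= 1) {
      starts <- bg$onset_s[k] + seq_len(n_bg) - 1
      cand[[length(cand) + 1]] <-
        add(starts, "inter_ictal", round(starts - onset_ref))
    }
  }
  if (length(cand) == 0) stop("empty series: no labelled windows", call. = FALSE)
  cand <- dplyr::bind_rows(cand)

  # priority ictal > pre > post > inter, then drop overlaps so epochs tile
  prio <- match(cand$state, c("ictal", "pre_ictal", "post_ictal", "inter_ictal"))
  cand <- cand[order(prio), , drop = FALSE]
  kept <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!kept[i]) next
    if (i < nrow(cand)) {
      j <- seq(i + 1, nrow(cand))
      ovl <- kept[j] &
        (cand$start_s[j] < cand$start_s[i] + 1) &
        (cand$start_s[j] + 1 > cand$start_s[i])
      kept[j][ovl] <- FALSE
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand <- cand[order(cand$start_s), , drop = FALSE]
  cand <- cand[cand$start_s >= -1e-9 & cand$start_s + 1 <= dur + 1e-9, ,
               drop = FALSE]
  if (nrow(cand) == 0) stop("empty series: no complete windows", call. = FALSE)

  cand$epoch <- seq_len(nrow(cand))
  cand$data <- lapply(cand$start_s, function(s) {
    i0 <- round(s * fs)
    rec$data[, seq(i0 + 1, i0 + win), drop = FALSE]
  })
  new_epoch_series(
    cand[, c("epoch", "state", "t_rel", "start_s", "data")],
    fs, rec$channel_labels,
    sprintf("%s | epochs aligned to onset at %g s", rec$id, onset_ref)
  )
}

#' Reject epochs with excessive amplitude
#'
#' A simple absolute-amplitude criterion stands in for component-based
#' artifact cleaning: any epoch containing a sample whose magnitude exceeds
#' `amp_limit_uv` (on any channel) is dropped; order is preserved. The
#' default of 200 microvolts is far above physiological scalp EEG after
#' band-pass filtering but below typical movement or electrode artifacts.
#'
#' @param series An `epoch_series`.
#' @param amp_limit_uv Rejection threshold in microvolts, default 200.
#' @return The filtered `epoch_series` (possibly empty).
#' @export
reject_artifact_epochs <- function(series, amp_limit_uv = 200) {
  stopifnot(inherits(series, "epoch_series"))
  if (!(amp_limit_uv > 0)) stop("amp_limit_uv must be positive", call. = FALSE)
  ok <- vapply(series$data, function(m) max(abs(m)) <= amp_limit_uv,
               logical(1))
  as_epoch_series(series[ok, , drop = FALSE], series)
}
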