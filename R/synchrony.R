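# Phase synchronization: Hilbert instantaneous phase, pairwise phase
# locking values, thresholded binary networks, and PLV time courses.

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

band_filter_matrix <- function(data, fs, band, pad_s = 1) {
  b <- resolve_band(band)
  if (identical(b$name, "broadband")) return(data)
  filt <- signal::butter(4, c(b$f_low, min(b$f_high, fs / 2 * 0.99)) / (fs / 2),
                         type = "pass")
  t(apply(data, 1, function(x) filtfilt_padded(filt, x, fs, pad_s)))
}

#' Instantaneous phase by the Hilbert transform
#'
#' Band-filters each channel (zero-phase) to the requested rhythm, forms
#' the analytic signal, and returns its phase in `(-pi, pi]`. Phase is
#' amplitude-invariant: rescaling a channel leaves it unchanged. Samples
#' within `guard` of either end are edge-contaminated by the transform's
#' circularity; the guard width is carried as an attribute so callers can
#' exclude them (the pipeline avoids the issue by transforming whole
#' recordings and cutting epochs from the interior).
#'
#' @param data Channels x samples numeric matrix (>= 32 samples).
#' @param fs Sampling rate in Hz.
#' @param band A band name, `"broadband"` (no extra filtering), or a
#'   `list(name, f_low, f_high)`.
#' @param guard Number of unreliable edge samples flagged, default 25.
#' @return A `phase_series`: channels x samples matrix of phases in
#'   radians with attributes `band` and `guard`.
#' @examples
#' t <- seq(0, 1 - 1/200, by = 1/200)
#' ph <- instantaneous_phase(rbind(cos(2 * pi * 5 * t)), 200, "broadband")
#' @export
instantaneous_phase <- function(data, fs, band = "broadband", guard = 25) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (ncol(data) < 32) stop("need at least 32 samples", call. = FALSE)
  flat <- which(apply(data, 1, stats::var) == 0)
  if (length(flat) > 0) {
    labs <- rownames(data)
    who <- if (is.null(labs)) paste0("ch", flat[1]) else labs[flat[1]]
    stop("degenerate phase: constant channel ", who, call. = FALSE)
  }
  filtered <- band_filter_matrix(data, fs, band)
  phases <- t(apply(filtered, 1, function(x) Arg(analytic_signal(x))))
  rownames(phases) <- rownames(data)
  structure(phases, band = resolve_band(band)$name, guard = guard,
            class = c("phase_series", "matrix", "array"))
}

#' Phase locking value of two phase sequences
#'
#' `PLV = |sum(exp(1i * (p1 - p2)))| / N`: the resultant length of the
#' phase-difference distribution over the `N` samples of the window. It is
#' 1 for any constant phase lag and tends to 0 for independent phases
#' (for i.i.d. uniform differences the expected value is about
#' `sqrt(pi / (4 N))`).
#'
#' @param p1,p2 Numeric phase vectors (radians) of equal length.
#' @return A number in `[0, 1]`.
#' @examples
#' plv_pair(1:10 / 3, 1:10 / 3 + 0.7)  # constant lag -> 1
#' @export
plv_pair <- function(p1, p2) {
  if (length(p1) != length(p2)) {
    stop("phase sequences differ in length", call. = FALSE)
  }
  if (length(p1) == 0) stop("empty phase sequences", call. = FALSE)
  min(1, Mod(mean(exp(1i * (p1 - p2)))))
}

plv_from_phases <- function(phases) {
  z <- exp(1i * phases)
  m <- Mod(z %*% Conj(t(z))) / ncol(phases)
  m <- pmin(m, 1)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(rownames(phases), rownames(phases))
  m
}

#' Pairwise PLV matrix of one epoch
#'
#' Computes the instantaneous phase of every channel (see
#' [instantaneous_phase()]) and the PLV of every unordered channel pair;
#' the matrix is symmetric with unit diagonal.
#'
#' @param epoch Channels x samples matrix (>= 2 channels), or a
#'   `phase_series`.
#' @param fs Sampling rate in Hz (ignored for a `phase_series`).
#' @param band Band selector passed to [instantaneous_phase()].
#' @return A `plv_matrix`: symmetric channels x channels matrix in
#'   `[0, 1]` with attribute `band`.
#' @export
plv_matrix <- function(epoch, fs = NULL, band = "broadband") {
  if (inherits(epoch, "phase_series")) {
    phases <- unclass(epoch)
    bname <- attr(epoch, "band")
  } else {
    if (nrow(epoch) < 2) stop("need at least 2 channels", call. = FALSE)
    phases <- unclass(instantaneous_phase(epoch, fs, band))
    bname <- resolve_band(band)$name
  }
  structure(plv_from_phases(phases), band = bname,
            class = c("plv_matrix", "matrix", "array"))
}

#' Threshold a PLV matrix into a binary synchronization network
#'
#' An edge joins channels `i != j` when `PLV[i, j] > tau` (strictly);
#' a PLV above 0.6 is read as strong phase coupling. The diagonal is zero.
#'
#' @param plv Symmetric PLV matrix.
#' @param tau Threshold in `[0, 1]`, default 0.6.
#' @return A `binary_network`: 0/1 adjacency matrix with attributes `tau`
#'   and `band`.
#' @export
binarize <- function(plv, tau = 0.6) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]", call. = FALSE)
  adj <- (unclass(plv) > tau) * 1L
  diag(adj) <- 0L
  structure(adj, tau = tau, band = attr(plv, "band"),
            class = c("binary_network", "matrix", "array"))
}

#' Edge count of a binary network
#' @param net A `binary_network`.
#' @return Number of undirected edges.
#' @export
edge_count <- function(net) sum(net[upper.tri(net)])

#' Long-format PLV table for an epoch series
#'
#' For each requested band the preprocessed recording is band-filtered
#' (zero-phase), the analytic phase computed over the whole recording (so
#' 1-s epochs carry no per-epoch edge transients), phases are cut at the
#' epoch boundaries, and the PLV of each of the `C(n, 2)` channel pairs is
#' computed per epoch.
#'
#' @param series An `epoch_series` from [make_epochs()].
#' @param rec The preprocessed [eeg_recording()] the series was cut from;
#'   if `NULL`, phases are computed per epoch (edge samples included).
#' @param bands Character vector of band names and/or `"broadband"`.
#' @return Tibble with columns `epoch`, `t_rel`, `state`, `band`, `ch_i`,
#'   `ch_j`, `plv`.
#' @export
plv_table <- function(series, rec = NULL, bands = "broadband") {
  stopifnot(inherits(series, "epoch_series"))
  fs <- attr(series, "fs")
  chans <- attr(series, "channel_labels")
  pairs <- which(upper.tri(diag(length(chans))), arr.ind = TRUE)
  per_band <- lapply(bands, function(bn) {
    if (!is.null(rec)) {
      ph_all <- unclass(instantaneous_phase(rec$data, fs, bn))
      phase_of_epoch <- function(i) {
        i0 <- round(series$start_s[i] * fs)
        ph_all[, seq(i0 + 1, i0 + round(fs)), drop = FALSE]
      }
    } else {
      phase_of_epoch <- function(i)
        unclass(instantaneous_phase(series$data[[i]], fs, bn))
    }
    rows <- lapply(seq_len(nrow(series)), function(i) {
      m <- plv_from_phases(phase_of_epoch(i))
      tibble::tibble(
        epoch = series$epoch[i], t_rel = series$t_rel[i],
        state = series$state[i], band = bn,
        ch_i = chans[pairs[, 1]], ch_j = chans[pairs[, 2]],
        plv = m[pairs]
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(per_band)
}

#' Mean-PLV time course
#'
#' Per epoch (and band), the mean PLV over all unordered channel pairs —
#' the global synchronization index whose rise and fall tracks seizure
#' evolution.
#'
#' @param x Either a long PLV table from [plv_table()] or an
#'   `epoch_series` (in which case `rec` and `band` are used to build one).
#' @param rec Optional preprocessed recording, see [plv_table()].
#' @param band Band name used when `x` is an `epoch_series`.
#' @return Tibble with columns `epoch`, `t_rel`, `state`, `band`,
#'   `plv_mean`, ordered by epoch.
#' @export
mean_plv_timecourse <- function(x, rec = NULL, band = "broadband") {
  if (inherits(x, "epoch_series")) {
    x <- plv_table(x, rec = rec, bands = band)
  }
  x |>
    dplyr::group_by(.data$epoch, .data$t_rel, .data$state, .data$band) |>
    dplyr::summarise(plv_mean = mean(.data$plv), .groups = "drop") |>
    dplyr::arrange(.data$band, .data$epoch)
}
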