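# Welch power spectral density and per-rhythm log band power.

make_window <- function(window, m) {
  switch(window,
    hamming     = as.numeric(signal::hamming(m)),
    hann        = as.numeric(signal::hanning(m)),
    rectangular = rep(1, m),
    stop("unknown window: ", window, call. = FALSE)
  )
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is cut into `L` segments of
#' `seg_len_s` seconds (overlapping by `overlap`), each segment is windowed
#' and its periodogram `I_i = |FFT(x_i w)|^2 / (U M)` computed with the
#' window-power normalization `U = mean(w^2)`; the estimate is the mean of
#' the `L` periodograms, scaled to a one-sided density in uV^2/Hz (non-DC,
#' non-Nyquist bins doubled). With a single segment (`L = 1`, the default
#' for a 1-s epoch at `seg_len_s = 1`) the estimate equals the single
#' windowed periodogram exactly.
#'
#' @param x Numeric vector of samples, or a channels x samples matrix
#'   (each row estimated independently).
#' @param fs Sampling rate in Hz.
#' @param seg_len_s Segment length in seconds, default 1.
#' @param overlap Fractional overlap between segments in `[0, 1)`, default 0.
#' @param window `"hamming"` (default), `"hann"` or `"rectangular"`.
#' @return A `spectrum_estimate`: list with `freqs` (Hz, 0 to fs/2), `psd`
#'   (bins x channels matrix, uV^2/Hz), `fs`, and `params`
#'   (`M`, `L`, `U`, `window`, `overlap`).
#' @examples
#' x <- sin(2 * pi * 3 * seq(0, 1 - 1/200, by = 1/200))
#' sp <- welch_psd(x, fs = 200)
#' sp$freqs[which.max(sp$psd[, 1])]  # 3 Hz
#' @export
welch_psd <- function(x, fs, seg_len_s = 1, overlap = 0, window = "hamming") {
  if (is.matrix(x)) {
    labs <- rownames(x)
    ests <- apply(x, 1, function(ch)
      welch_psd(ch, fs, seg_len_s, overlap, window), simplify = FALSE)
    psd <- do.call(cbind, lapply(ests, function(e) e$psd[, 1]))
    colnames(psd) <- labs
    out <- ests[[1]]
    out$psd <- psd
    return(out)
  }
  n <- length(x)
  m <- round(seg_len_s * fs)
  if (m > n) stop("invalid segmentation: segment longer than signal",
                  call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)",
                                        call. = FALSE)
  step <- max(1L, m - floor(overlap * m))
  starts <- seq(1L, n - m + 1L, by = step)
  L <- length(starts)
  w <- make_window(window, m)
  U <- mean(w^2)
  nfreq <- floor(m / 2) + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[seq(s, s + m - 1L)] * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    acc <- acc + Mod(X)^2
  }
  # |X|^2 / (U M) averaged over L, then /fs for density, one-sided doubling
  psd <- acc / (L * U * m * fs)
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (m %% 2 == 0) dbl[nfreq] <- 1
  psd <- psd * dbl
  structure(
    list(freqs = (seq_len(nfreq) - 1) * fs / m,
         psd = matrix(psd, ncol = 1),
         fs = fs,
         params = list(M = m, L = L, U = U, window = window,
                       overlap = overlap)),
    class = "spectrum_estimate"
  )
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf("<spectrum_estimate>  %d bins [0, %g] Hz x %d channel(s); M=%d, L=%d, %s window\n",
              length(x$freqs), max(x$freqs), ncol(x$psd),
              x$params$M, x$params$L, x$params$window))
  invisible(x)
}

band_bins <- function(freqs, f_low, f_high) {
  which(freqs >= f_low - 1e-9 & freqs < f_high - 1e-9)
}

#' Log band power of a spectrum
#'
#' Sums the PSD bins falling in the half-open band `[f_low, f_high)` and
#' takes `log10` (with an epsilon floor so silent channels stay finite).
#' Because power scales with squared amplitude, scaling the signal by `c`
#' adds exactly `2 * log10(c)` to every band's value.
#'
#' @param spec A `spectrum_estimate` from [welch_psd()].
#' @param band A band name from [eeg_bands()] or a
#'   `list(name, f_low, f_high)`.
#' @param eps Floor applied before the log, default `1e-12`.
#' @return Named numeric vector, one log10 band power per channel.
#' @examples
#' x <- sin(2 * pi * 3 * seq(0, 1 - 1/200, by = 1/200))
#' band_power(welch_psd(x, 200), "delta")
#' @export
band_power <- function(spec, band, eps = 1e-12) {
  stopifnot(inherits(spec, "spectrum_estimate"))
  if (!(eps > 0)) stop("eps must be positive", call. = FALSE)
  b <- resolve_band(band)
  idx <- band_bins(spec$freqs, b$f_low, b$f_high)
  if (length(idx) == 0) {
    stop("empty band: no PSD bins in [", b$f_low, ", ", b$f_high, ")",
         call. = FALSE)
  }
  tot <- colSums(spec$psd[idx, , drop = FALSE])
  log10(pmax(eps, tot))
}

#' Per-epoch, per-channel, per-rhythm log band power table
#'
#' Runs [welch_psd()] on every channel of every epoch (single 1-s Hamming
#' segment by default) and assembles the log10 band powers of the five
#' canonical rhythms into a tidy table.
#'
#' @param series An `epoch_series` from [make_epochs()].
#' @param bands Band definition table, default [eeg_bands()].
#' @param eps Epsilon floor for the log, default `1e-12`.
#' @param window Welch window, default `"hamming"`.
#' @return Tibble with columns `epoch`, `t_rel`, `state`, `channel`,
#'   `band`, `power` (log10 uV^2/Hz summed over band bins). Attributes
#'   `log_base` and `eps` record the scale conventions.
#' @export
band_power_table <- function(series, bands = eeg_bands(), eps = 1e-12,
                             window = "hamming") {
  stopifnot(inherits(series, "epoch_series"))
  fs <- attr(series, "fs")
  chans <- attr(series, "channel_labels")
  rows <- purrr::pmap(
    list(series$epoch, series$t_rel, series$state, series$data),
    function(epoch, t_rel, state, data) {
      sp <- welch_psd(data, fs, window = window)
      per_band <- purrr::pmap(bands, function(band, f_low, f_high) {
        p <- band_power(sp, list(name = as.character(band),
                                 f_low = f_low, f_high = f_high), eps = eps)
        tibble::tibble(channel = chans, band = as.character(band), power = p)
      })
      dplyr::bind_rows(per_band) |>
        dplyr::mutate(epoch = epoch, t_rel = t_rel, state = state,
                      .before = 1)
    }
  )
  out <- dplyr::bind_rows(rows)
  out$band <- factor(out$band, levels = levels(bands$band))
  out$channel <- factor(out$channel, levels = chans)
  attr(out, "log_base") <- 10
  attr(out, "eps") <- eps
  out
}

#' Whole-head mean total-power time course
#'
#' Per epoch, the PSD is summed over all bins per channel and averaged over
#' channels, giving the time course of total spectral power around a
#' seizure (the discharge makes it rise sharply at onset and decay after).
#'
#' @param series An `epoch_series`.
#' @param window Welch window, default `"hamming"`.
#' @return Tibble with columns `epoch`, `t_rel`, `state`, `mean_power`
#'   (uV^2/Hz summed over bins, averaged over channels), ordered by epoch
#'   start time.
#' @export
mean_psd_timecourse <- function(series, window = "hamming") {
  stopifnot(inherits(series, "epoch_series"))
  fs <- attr(series, "fs")
  nch <- vapply(series$data, nrow, integer(1))
  if (length(unique(nch)) > 1) {
    stop("inconsistent channel sets across epochs", call. = FALSE)
  }
  mp <- vapply(series$data, function(m) {
    sp <- welch_psd(m, fs, window = window)
    mean(colSums(sp$psd))
  }, numeric(1))
  tibble::tibble(epoch = series$epoch, t_rel = series$t_rel,
                 state = series$state, mean_power = mp)
}
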