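# Shared fixture builders: everything is generated in code at test time.

# A recording whose every channel is the same given signal.
sine_recording <- function(freq, fs = 200, dur_s = 10, amp = 1,
                           n_ch = 16, annotations = NULL) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = n_ch), nrow = n_ch), fs,
                annotations = annotations, id = "sine")
}

# Hand-built epoch series from a list of channels x fs matrices.
manual_series <- function(mats, fs = 200,
                          states = rep("ictal", length(mats)),
                          t_rel = seq_along(mats) - 1) {
  tbl <- tibble::tibble(
    epoch = seq_along(mats), state = states, t_rel = as.integer(t_rel),
    start_s = as.numeric(t_rel), data = mats
  )
  swdeeg:::new_epoch_series(tbl, fs,
                            rownames(mats[[1]]) %||%
                              paste0("ch", seq_len(nrow(mats[[1]]))),
                            "manual fixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Closed-form squared magnitude response of a digital filter evaluated
# from its coefficients (independent of the time-domain filtering path);
# forward-backward application squares the magnitude.
filter_gain_zero_phase <- function(filt, f, fs) {
  z <- exp(-2i * pi * f / fs)
  H <- sum(filt$b * z^(seq_along(filt$b) - 1)) /
    sum(filt$a * z^(seq_along(filt$a) - 1))
  Mod(H)^2
}

# Steady-state peak amplitude of a filtered sinusoid, interior samples.
steady_amp <- function(y, fs) {
  n <- length(y)
  max(abs(y[seq(round(n / 3), round(2 * n / 3))]))
}

# Lean default-config recovery run shared by simulator and acceptance
# tests: band powers for all epochs, PLV tables for the requested bands.
recovery_run <- function(seed, plv_bands = NULL) {
  rec <- simulate_recording(sim_config(rng_seed = seed))
  recf <- notch_filter(bandpass_filter(rec))
  ep <- make_epochs(recf, post_ictal_s = 0)
  out <- list(epochs = ep, band_power = band_power_table(ep))
  if (!is.null(plv_bands)) {
    out$plv <- plv_table(ep, rec = recf, bands = plv_bands)
  }
  out
}
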