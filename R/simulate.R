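# Synthetic 16-channel spike-wave-discharge EEG generator. Emulates the
# statistical structure the analysis assumes: 1/f background with a weak
# common-reference component, posterior alpha, a pre-ictal window with
# elevated delta/theta power, and ictal ~3 Hz frontal-dominant
# spike-and-wave discharges with graded front-to-back onset delay,
# attack/decay envelope and per-epoch phase jitter.

#' Simulation configuration
#'
#' All parameters of [simulate_recording()], with defaults describing a
#' typical absence-seizure recording: 200 Hz, 120 s, one 10-s seizure at
#' 70 s, a 30-s background (inter-ictal) interval at 5--35 s, 3 Hz
#' discharges peaking at 300 uV against a 20 uV-RMS background, pre-ictal
#' delta/theta power elevated 1.5x, ictal inter-channel phase jitter
#' 0.2 rad, and onset delays graded 0--80 ms from front to back.
#'
#' @param fs Sampling rate in Hz, default 200.
#' @param duration_s Recording length in seconds, default 120.
#' @param seizure_onset_s,seizure_offset_s Seizure interval(s), seconds;
#'   vectors give multiple seizures.
#' @param background_interval_s `c(start, end)` of the annotated
#'   inter-ictal control interval, default `c(5, 35)`.
#' @param swd_freq Spike-wave fundamental in Hz, default 3 (delta band).
#' @param swd_amp_uv Ictal peak discharge amplitude in uV, default 300.
#' @param background_amp_uv Background RMS per channel in uV, default 20.
#' @param alpha_amp_uv Posterior alpha amplitude in uV, default 10.
#' @param preictal_delta_gain,preictal_theta_gain Multiplicative power
#'   gains applied to the delta / theta background in the 30 s before
#'   each onset, default 1.5.
#' @param phase_jitter_rad SD of the per-channel, per-second ictal phase
#'   offset in radians, default 0.2.
#' @param spike_transient_uv Peak amplitude of the sharp Gaussian
#'   transient locked to each spike time, default 120 uV. The harmonic
#'   template tops out at the 5th harmonic, so this transient supplies
#'   the broadband (beta/gamma) energy real discharges carry; set to 0
#'   for a purely harmonic discharge.
#' @param spike_width_ms Gaussian SD of the spike transient in ms,
#'   default 6.
#' @param prop_delay_ms Named per-channel onset delay in ms; default
#'   graded 0 (frontopolar) to 80 (occipital).
#' @param frontal_gain Named per-channel amplitude weights; default
#'   frontal-dominant (1.0 front to 0.6 occipital).
#' @param attack_s,decay_s Discharge envelope attack / decay, default 2 / 3 s.
#' @param preictal_s Length of the elevated pre-ictal window, default 30 s.
#' @param common_frac Fraction of background power shared across channels
#'   (average-reference leakage), default 0.1.
#' @param rng_seed Integer seed; the recording is a deterministic function
#'   of the configuration.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(fs = 200, duration_s = 120,
                       seizure_onset_s = 70, seizure_offset_s = 80,
                       background_interval_s = c(5, 35),
                       swd_freq = 3, swd_amp_uv = 300,
                       background_amp_uv = 20, alpha_amp_uv = 10,
                       preictal_delta_gain = 1.5, preictal_theta_gain = 1.5,
                       phase_jitter_rad = 0.2,
                       spike_transient_uv = 120, spike_width_ms = 6,
                       prop_delay_ms = default_prop_delay(),
                       frontal_gain = default_frontal_gain(),
                       attack_s = 2, decay_s = 3, preictal_s = 30,
                       common_frac = 0.1, rng_seed = 1) {
  cfg <- list(fs = fs, duration_s = duration_s,
              seizure_onset_s = seizure_onset_s,
              seizure_offset_s = seizure_offset_s,
              background_interval_s = background_interval_s,
              swd_freq = swd_freq, swd_amp_uv = swd_amp_uv,
              background_amp_uv = background_amp_uv,
              alpha_amp_uv = alpha_amp_uv,
              preictal_delta_gain = preictal_delta_gain,
              preictal_theta_gain = preictal_theta_gain,
              phase_jitter_rad = phase_jitter_rad,
              spike_transient_uv = spike_transient_uv,
              spike_width_ms = spike_width_ms,
              prop_delay_ms = prop_delay_ms,
              frontal_gain = frontal_gain,
              attack_s = attack_s, decay_s = decay_s,
              preictal_s = preictal_s, common_frac = common_frac,
              rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

default_prop_delay <- function() {
  stats::setNames(
    c(Fp1 = 0, Fp2 = 0, F7 = 15, F8 = 15, F3 = 10, F4 = 10,
      C3 = 40, C4 = 40, P3 = 60, P4 = 60, T3 = 40, T4 = 40,
      T5 = 60, T6 = 60, O1 = 80, O2 = 80)[montage_channels()],
    montage_channels()
  )
}

default_frontal_gain <- function() {
  stats::setNames(
    c(Fp1 = 1, Fp2 = 1, F7 = 0.95, F8 = 0.95, F3 = 1, F4 = 1,
      C3 = 0.8, C4 = 0.8, P3 = 0.7, P4 = 0.7, T3 = 0.8, T4 = 0.8,
      T5 = 0.7, T6 = 0.7, O1 = 0.6, O2 = 0.6)[montage_channels()],
    montage_channels()
  )
}

validate_sim_config <- function(cfg) {
  on <- cfg$seizure_onset_s; off <- cfg$seizure_offset_s
  if (length(on) != length(off)) {
    stop("config error: onset/offset length mismatch", call. = FALSE)
  }
  if (any(on >= off) || any(on < 0) || any(off > cfg$duration_s)) {
    stop("config error: seizure intervals must satisfy 0 <= onset < offset <= duration",
         call. = FALSE)
  }
  if (!(cfg$swd_freq >= 1 && cfg$swd_freq < 4)) {
    stop("config error: swd_freq must lie in the delta band [1, 4)",
         call. = FALSE)
  }
  if (5 * cfg$swd_freq >= cfg$fs / 2) {
    stop("config error: 5th spike-wave harmonic above Nyquist",
         call. = FALSE)
  }
  amps <- c(cfg$swd_amp_uv, cfg$background_amp_uv, cfg$alpha_amp_uv,
            cfg$preictal_delta_gain, cfg$preictal_theta_gain)
  if (any(amps <= 0)) stop("config error: amplitudes/gains must be positive",
                           call. = FALSE)
  if (cfg$phase_jitter_rad < 0) {
    stop("config error: phase jitter must be >= 0", call. = FALSE)
  }
  if (cfg$spike_transient_uv < 0 || cfg$spike_width_ms <= 0) {
    stop("config error: spike transient must have non-negative amplitude and positive width",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Load a simulation configuration from YAML or JSON
#'
#' Keys mirror the arguments of [sim_config()]; absent keys keep their
#' defaults.
#'
#' @param path A `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("config error: unknown key(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

# Per-stage, per-channel seeds so adding a channel or stage never perturbs
# the others' streams.
derive_seed <- function(base, stage, ch = 0L) {
  ((as.numeric(base) * 10007 + stage * 613 + ch * 7) %% 2147483629) + 1
}

# Unit-RMS 1/f-amplitude noise (power slope ~ -1) by spectral shaping.
pink_noise <- function(n, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))              # avoid DC blow-up
  f <- pmin(f, n - f + 1)                # mirror for negative frequencies
  X <- X / sqrt(f)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}

#' Periodic spike-and-wave template
#'
#' Sum of a fundamental at `freq` and four decaying aligned harmonics
#' (amplitudes `1/k`, zero phases, so every period carries a sharp spike
#' riding on the slow wave), normalized to unit peak amplitude.
#'
#' @param freq Fundamental in Hz (its 5th harmonic must stay below
#'   Nyquist).
#' @param n_samples Number of samples to return.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `n_samples`, peak absolute value 1.
#' @examples
#' w <- swd_waveform(3, 200, 200)
#' max(abs(w))  # 1
#' @export
swd_waveform <- function(freq, n_samples, fs) {
  if (5 * freq >= fs / 2) {
    stop("config error: harmonic above Nyquist", call. = FALSE)
  }
  t <- (seq_len(n_samples) - 1) / fs
  swd_wave_fun(freq)(t)
}

# Continuous-time template closure; peak (at t = 0) equals sum(1/k).
swd_wave_fun <- function(freq) {
  k <- 1:5
  a <- 1 / k
  norm <- sum(a)
  function(t) {
    out <- numeric(length(t))
    for (i in k) out <- out + a[i] * cos(2 * pi * i * freq * t)
    out / norm
  }
}

#' Simulate a multichannel spike-wave-discharge recording
#'
#' Deterministic in the configuration (including its seed): two calls
#' with the same `sim_config` return bit-identical recordings. See
#' [sim_config()] for the generative model. Annotations for the
#' seizure(s) (`"ictal"`) and the background control interval
#' (`"inter_ictal"`) are attached.
#'
#' @param cfg A [sim_config()].
#' @return An [eeg_recording()] with annotations.
#' @examples
#' rec <- simulate_recording(sim_config(duration_s = 60,
#'   seizure_onset_s = 40, seizure_offset_s = 50,
#'   background_interval_s = c(2, 32)))
#' rec
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  chans <- montage_channels()
  nch <- length(chans)
  data <- matrix(0, nrow = nch, ncol = n, dimnames = list(chans, NULL))

  # --- background: independent + weakly common 1/f noise ----------------
  common <- pink_noise(n, derive_seed(cfg$rng_seed, 1L, 0L))
  alpha_w <- c(Fp1 = 0, Fp2 = 0, F7 = 0, F8 = 0, F3 = 0, F4 = 0,
               C3 = 0.2, C4 = 0.2, P3 = 0.6, P4 = 0.6, T3 = 0, T4 = 0,
               T5 = 0.6, T6 = 0.6, O1 = 1, O2 = 1)[chans]
  for (c_i in seq_len(nch)) {
    ind <- pink_noise(n, derive_seed(cfg$rng_seed, 2L, c_i))
    bg <- sqrt(1 - cfg$common_frac) * ind + sqrt(cfg$common_frac) * common
    data[c_i, ] <- cfg$background_amp_uv * bg
    if (alpha_w[c_i] > 0) {
      set.seed(derive_seed(cfg$rng_seed, 3L, c_i))
      drift <- cumsum(stats::rnorm(n, 0, 0.03))
      data[c_i, ] <- data[c_i, ] +
        cfg$alpha_amp_uv * alpha_w[c_i] * cos(2 * pi * 10 * t + drift)
    }
  }

  # --- pre-ictal delta/theta elevation ---------------------------------
  band_specs <- list(delta = c(1, 4, cfg$preictal_delta_gain),
                     theta = c(4, 8, cfg$preictal_theta_gain))
  for (s_i in seq_along(cfg$seizure_onset_s)) {
    onset <- cfg$seizure_onset_s[s_i]
    w0 <- max(0, onset - cfg$preictal_s)
    idx <- which(t >= w0 & t < onset)
    if (length(idx) < fs) next
    ramp <- pmin(1, (t[idx] - w0), (onset - t[idx]))  # 1-s cosine-free ramp
    for (b_i in seq_along(band_specs)) {
      bs <- band_specs[[b_i]]
      if (bs[3] <= 1) next
      filt <- signal::butter(4, bs[1:2] / (fs / 2), type = "pass")
      for (c_i in seq_len(nch)) {
        extra <- pink_noise(n, derive_seed(cfg$rng_seed,
                                           10L + 2L * s_i + b_i, c_i))
        extra <- filtfilt_padded(filt, extra, fs, 1)
        # background's own band RMS in the window sets the scale
        bg_band <- filtfilt_padded(filt, data[c_i, ], fs, 1)
        target_rms <- sqrt(bs[3] - 1) *
          sqrt(mean(bg_band[idx]^2))
        extra_rms <- sqrt(mean(extra[idx]^2))
        data[c_i, idx] <- data[c_i, idx] +
          ramp * extra[idx] * target_rms / extra_rms
      }
    }
  }

  # --- ictal spike-wave discharges -------------------------------------
  wave <- swd_wave_fun(cfg$swd_freq)
  delays <- cfg$prop_delay_ms[chans] / 1000
  gains <- cfg$frontal_gain[chans]
  for (s_i in seq_along(cfg$seizure_onset_s)) {
    onset <- cfg$seizure_onset_s[s_i]
    offset <- cfg$seizure_offset_s[s_i]
    idx <- which(t >= onset & t < offset)
    if (length(idx) == 0) next
    env <- pmax(0, pmin(1, (t[idx] - onset) / cfg$attack_s,
                        (offset - t[idx]) / cfg$decay_s))
    n_blocks <- ceiling(offset - onset)
    for (c_i in seq_len(nch)) {
      set.seed(derive_seed(cfg$rng_seed, 40L + s_i, c_i))
      jit <- stats::rnorm(n_blocks, 0, cfg$phase_jitter_rad)
      block <- pmin(floor(t[idx] - onset) + 1, n_blocks)
      shift <- jit[block] / (2 * pi * cfg$swd_freq)
      tau <- t[idx] - onset - delays[c_i] - shift
      contrib <- ifelse(tau >= 0, wave(tau), 0)
      if (cfg$spike_transient_uv > 0) {
        # sharp Gaussian transient at each spike time: supplies the
        # broadband (beta/gamma) energy the 5-harmonic template lacks
        sw <- cfg$spike_width_ms / 1000
        d <- tau - round(tau * cfg$swd_freq) / cfg$swd_freq
        contrib <- contrib + ifelse(
          tau >= 0,
          cfg$spike_transient_uv / cfg$swd_amp_uv * exp(-d^2 / (2 * sw^2)),
          0)
      }
      data[c_i, idx] <- data[c_i, idx] +
        cfg$swd_amp_uv * gains[c_i] * env * contrib
    }
  }

  ann <- dplyr::bind_rows(
    tibble::tibble(onset_s = cfg$seizure_onset_s,
                   offset_s = cfg$seizure_offset_s, label = "ictal"),
    tibble::tibble(onset_s = cfg$background_interval_s[1],
                   offset_s = cfg$background_interval_s[2],
                   label = "inter_ictal")
  )
  eeg_recording(data, fs, chans, annotations = ann,
                id = sprintf("sim-seed%d", cfg$rng_seed))
}
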