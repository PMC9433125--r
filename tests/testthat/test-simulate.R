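# Synthetic spike-wave-discharge generator.

test_that("spike-wave template has unit peak and the right fundamental", {
  w <- swd_waveform(3, 200, 200)
  expect_equal(max(abs(w)), 1, tolerance = 1e-9)
  sp <- welch_psd(w, 200, window = "rectangular")
  expect_equal(sp$freqs[which.max(sp$psd[, 1])], 3)
  expect_error(swd_waveform(25, 200, 200), "Nyquist")
})

test_that("template periodicity follows the fundamental (autocorrelation)", {
  fs <- 600  # fine grid so the 3 Hz period (200 samples) is integral
  for (freq in c(3, 4)) {
    w <- swd_waveform(freq, 4 * fs, fs)
    ac <- stats::acf(w, lag.max = fs / 2, plot = FALSE)$acf[-1]
    expect_equal(which.max(ac), round(fs / freq), tolerance = 1)
  }
})

test_that("simulation is a deterministic function of the config", {
  cfg <- sim_config(duration_s = 30, seizure_onset_s = 20,
                    seizure_offset_s = 28,
                    background_interval_s = c(1, 11), rng_seed = 9)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_recording(sim_config(duration_s = 30,
                                      seizure_onset_s = 20,
                                      seizure_offset_s = 28,
                                      background_interval_s = c(1, 11),
                                      rng_seed = 10))
  expect_false(identical(r1$data, r3$data))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(seizure_onset_s = 80, seizure_offset_s = 70),
               "config error")
  expect_error(sim_config(swd_freq = 6), "delta band")
  expect_error(sim_config(background_amp_uv = -1), "config error")
  expect_error(sim_config(phase_jitter_rad = -0.1), "config error")
  expect_error(sim_config(duration_s = 50), "config error")  # seizure outside
})

test_that("background noise has an approximately 1/f power slope", {
  x <- swdeeg:::pink_noise(2^13, 1234)
  sp <- welch_psd(x, 200, seg_len_s = 2^11 / 200, window = "rectangular")
  keep <- sp$freqs >= 1 & sp$freqs <= 80
  fit <- stats::lm(log10(sp$psd[keep, 1]) ~ log10(sp$freqs[keep]))
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.4)
})

test_that("discharge-to-background amplitude ratio drives the delta gap", {
  # default config: swd_amp / background = 300/20 = 15, i.e. > 2 decades
  # of power. The configured amplitude holds on the envelope plateau
  # (after the 2-s attack, before the 3-s decay), so the arithmetic is
  # checked on those epochs.
  gaps <- vapply(1:20, function(s) {
    run <- recovery_run(s)
    ep <- run$epochs
    plateau <- ep$epoch[ep$state == "ictal" & ep$t_rel >= 2 & ep$t_rel <= 6]
    bp <- run$band_power[run$band_power$band == "delta", ]
    mean(bp$power[bp$epoch %in% plateau]) -
      mean(bp$power[bp$state == "inter_ictal"])
  }, numeric(1))
  expect_true(all(gaps > 2))
})

test_that("ictal epochs peak spectrally in the 2-4 Hz delta range", {
  for (s in 1:5) {
    rec <- simulate_recording(sim_config(rng_seed = s))
    recf <- bandpass_filter(rec)
    ep <- make_epochs(recf, post_ictal_s = 0)
    ict <- ep[ep$state == "ictal" & ep$t_rel >= 2, ]
    peaks <- vapply(ict$data, function(m) {
      sp <- welch_psd(m, 200)
      sp$freqs[which.max(rowMeans(sp$psd))]
    }, numeric(1))
    expect_true(all(peaks >= 2 & peaks <= 4))
  }
})

test_that("the config round-trips through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("duration_s: 40", "seizure_onset_s: 25",
               "seizure_offset_s: 35", "swd_freq: 3.5",
               "background_interval_s: [1, 21]", "rng_seed: 5"), tmp)
  cfg <- sim_config_from_file(tmp)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$swd_freq, 3.5)
  expect_equal(cfg$rng_seed, 5L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("not_a_key: 1", bad)
  expect_error(sim_config_from_file(bad), "unknown key")
})
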