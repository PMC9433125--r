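# Zero-phase filtering and epoching.

test_that("band-pass gain matches the closed-form Butterworth response", {
  fs <- 200
  filt <- signal::butter(4, c(1, 70) / (fs / 2), type = "pass")

  zero <- eeg_recording(matrix(0, 16, 2000) + 0, fs)
  expect_equal(bandpass_filter(zero)$data, zero$data, ignore_attr = TRUE)

  rec10 <- sine_recording(10, fs = fs)
  g10 <- filter_gain_zero_phase(filt, 10, fs)
  out <- bandpass_filter(rec10)
  expect_equal(steady_amp(out$data[1, ], fs), g10, tolerance = 0.01)
  expect_gt(g10, 0.99)  # passband within 1% of unity

  rec90 <- sine_recording(90, fs = fs)
  g90 <- filter_gain_zero_phase(filt, 90, fs)
  out90 <- bandpass_filter(rec90)
  expect_lt(steady_amp(out90$data[1, ], fs), g90 + 1e-3)
})

test_that("band-pass rejects invalid bands and non-finite data", {
  rec <- sine_recording(10)
  expect_error(bandpass_filter(rec, high_hz = 100), "Nyquist")
  expect_error(bandpass_filter(rec, low_hz = 30, high_hz = 10), "low_hz")
  bad <- rec
  bad$data[3, 7] <- NaN
  expect_error(bandpass_filter(bad), "non-finite")
})

test_that("notch removes 50 Hz but passes neighbours within 5%", {
  zero <- eeg_recording(matrix(0, 16, 2000) + 0, 200)
  expect_equal(notch_filter(zero)$data, zero$data, ignore_attr = TRUE)

  rec50 <- sine_recording(50, dur_s = 20)
  expect_lt(steady_amp(notch_filter(rec50)$data[1, ], 200), 0.1)

  rec10 <- sine_recording(10, dur_s = 20)
  expect_equal(steady_amp(notch_filter(rec10)$data[1, ], 200), 1,
               tolerance = 0.05)
  expect_error(notch_filter(rec10, f0_hz = 120), "invalid band")
})

test_that("passband filtering is near-idempotent and channel-wise", {
  rec <- sine_recording(10)
  once <- bandpass_filter(rec)
  twice <- bandpass_filter(once)
  a1 <- steady_amp(once$data[1, ], 200)
  a2 <- steady_amp(twice$data[1, ], 200)
  expect_lt(abs(a2 - a1) / a1, 0.02)

  # permuting channels commutes with filtering
  set.seed(11)
  mixed <- eeg_recording(matrix(rnorm(4 * 800), 4), 200,
                         channel_labels = c("a", "b", "c", "d"))
  perm <- c(3, 1, 4, 2)
  permed <- eeg_recording(mixed$data[perm, ], 200,
                          channel_labels = c("c", "a", "d", "b"))
  expect_equal(bandpass_filter(permed)$data,
               bandpass_filter(mixed)$data[perm, ],
               ignore_attr = TRUE)
})

test_that("epoching labels 1-s windows on the onset-anchored grid", {
  fs <- 200
  ann <- data.frame(onset_s = c(40, 10), offset_s = c(50, 40),
                    label = c("ictal", "inter_ictal"))
  rec <- sine_recording(5, fs = fs, dur_s = 60, annotations = ann)
  ep <- make_epochs(rec)
  expect_s3_class(ep, "epoch_series")
  expect_true(all(vapply(ep$data, ncol, integer(1)) == fs))

  # 30 pre-ictal windows immediately before onset
  pre <- ep[ep$state == "pre_ictal", ]
  expect_equal(nrow(pre), 30)
  expect_equal(sort(pre$t_rel), -30:-1)

  # ictal tiling of a 10-s seizure
  ict <- ep[ep$state == "ictal", ]
  expect_equal(ict$t_rel, 0:9)
  expect_equal(ict$start_s, 40:49)

  # epochs tile without overlap
  starts <- sort(ep$start_s)
  expect_true(all(diff(starts) >= 1 - 1e-9))
})

test_that("partial trailing ictal windows are dropped (half-open grid)", {
  ann <- data.frame(onset_s = 10, offset_s = 19.5, label = "ictal")
  rec <- sine_recording(5, dur_s = 30, annotations = ann)
  ep <- make_epochs(rec)
  ict <- ep[ep$state == "ictal", ]
  expect_equal(ict$t_rel, 0:8)
  expect_false(any(ep$start_s == 19))  # the [19, 19.5) remnant
})

test_that("epoching degenerate inputs raise the documented errors", {
  short <- eeg_recording(matrix(rnorm(16 * 100), 16), 200)
  expect_error(make_epochs(short), "empty series")

  ann <- data.frame(onset_s = c(10, 15), offset_s = c(20, 25),
                    label = c("ictal", "ictal"))
  rec <- sine_recording(5, dur_s = 40, annotations = ann)
  expect_error(make_epochs(rec), "overlapping ictal")
})

test_that("pre-ictal windows overlapping an earlier seizure are excluded", {
  ann <- data.frame(onset_s = c(10, 40), offset_s = c(20, 50),
                    label = c("ictal", "ictal"))
  rec <- sine_recording(5, dur_s = 70, annotations = ann)
  expect_message(ep <- make_epochs(rec), "pre-ictal")
  # seizure 2's pre-ictal span [10, 40) loses the 10 windows inside
  # seizure 1 [10, 20); pre-ictal labelling outranks post-ictal on [20, 40)
  pre2 <- ep[ep$state == "pre_ictal" & ep$start_s >= 10, ]
  expect_true(all(pre2$start_s >= 20))
  expect_equal(nrow(pre2), 20)
  expect_false(any(ep$state == "pre_ictal" &
                     ep$start_s >= 10 & ep$start_s < 20))
})

test_that("amplitude rejection drops exactly the contaminated epochs", {
  set.seed(4)
  mats <- replicate(5, matrix(rnorm(16 * 200, sd = 10), 16),
                    simplify = FALSE)
  ser <- manual_series(mats)
  expect_equal(nrow(reject_artifact_epochs(ser, 200)), 5)

  mats2 <- mats
  mats2[[3]][5, 17] <- 2000
  ser2 <- manual_series(mats2)
  kept <- reject_artifact_epochs(ser2, 200)
  expect_equal(nrow(kept), 4)
  expect_equal(kept$epoch, c(1, 2, 4, 5))
  expect_equal(nrow(reject_artifact_epochs(ser2, Inf)), 5)
})
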