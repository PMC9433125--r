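# Welch PSD and log band power.

# Brute-force single-window periodogram oracle: direct discrete Fourier
# sum of the windowed signal, normalized by U = mean(w^2), one-sided
# density scaling. Independent of the FFT path in welch_psd().
direct_periodogram <- function(x, fs, w) {
  m <- length(x)
  nfreq <- floor(m / 2) + 1
  U <- mean(w^2)
  psd <- vapply(seq_len(nfreq) - 1, function(k) {
    X <- sum(x * w * exp(-2i * pi * k * (seq_len(m) - 1) / m))
    Mod(X)^2 / (U * m * fs)
  }, numeric(1))
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (m %% 2 == 0) dbl[nfreq] <- 1
  psd * dbl
}

test_that("single-segment Welch equals the direct windowed periodogram", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 3 * t)
  sp <- welch_psd(x, fs)
  expect_equal(sp$params$L, 1)
  oracle <- direct_periodogram(x, fs, as.numeric(signal::hamming(fs)))
  expect_equal(sp$psd[, 1], oracle, tolerance = 1e-10)
  expect_equal(sp$freqs[which.max(sp$psd[, 1])], 3)

  expect_equal(welch_psd(numeric(200) + 0, fs)$psd[, 1], numeric(101))
  expect_error(welch_psd(rnorm(100), fs, seg_len_s = 1),
               "invalid segmentation")
})

test_that("averaging identical segments is the identity", {
  set.seed(21)
  half <- rnorm(200)
  x <- c(half, half)
  two <- welch_psd(x, 200, seg_len_s = 1, overlap = 0)
  one <- welch_psd(half, 200, seg_len_s = 1)
  expect_equal(two$params$L, 2)
  expect_equal(two$psd, one$psd)
})

test_that("rectangular-window PSD satisfies Parseval's identity", {
  set.seed(22)
  for (n in c(200, 256, 501)) {
    x <- rnorm(n)
    sp <- welch_psd(x, 200, seg_len_s = n / 200, window = "rectangular")
    df <- sp$freqs[2] - sp$freqs[1]
    expect_equal(sum(sp$psd[, 1]) * df, mean(x^2), tolerance = 1e-6)
  }
})

test_that("Welch segment averaging reduces per-bin variance", {
  set.seed(23)
  fs <- 200
  n_rep <- 200
  v1 <- matrix(0, n_rep, 101)  # L = 1 over 4 s at 1-Hz-comparable bins
  v4 <- matrix(0, n_rep, 101)  # L = 4 x 1-s segments
  for (r in seq_len(n_rep)) {
    x <- rnorm(4 * fs)
    s1 <- welch_psd(x, fs, seg_len_s = 4)
    s4 <- welch_psd(x, fs, seg_len_s = 1)
    common <- match(s4$freqs, s1$freqs)
    v1[r, ] <- s1$psd[common, 1]
    v4[r, ] <- s4$psd[, 1]
  }
  expect_lt(mean(apply(v4, 2, var)), mean(apply(v1, 2, var)))
})

test_that("band power sums half-open bands on the log10 scale", {
  flat <- structure(
    list(freqs = 0:100, psd = matrix(1, 101, 1), fs = 200,
         params = list(M = 200, L = 1, U = 1, window = "rectangular",
                       overlap = 0)),
    class = "spectrum_estimate"
  )
  # delta [1, 4): bins 1, 2, 3
  expect_equal(unname(band_power(flat, "delta")), log10(3))
  # shared edges counted once: the five bands partition [1, 70)
  tot <- sum(vapply(as.character(eeg_bands()$band),
                    function(b) 10^band_power(flat, b), numeric(1)))
  expect_equal(tot, 69)

  silent <- flat
  silent$psd <- matrix(0, 101, 1)
  expect_equal(unname(band_power(silent, "delta", eps = 1e-12)), -12)
  expect_error(band_power(flat, list(name = "x", f_low = 0.1,
                                     f_high = 0.5)), "empty band")
})

test_that("amplitude scaling shifts every band power by 2 log10(c)", {
  set.seed(24)
  x <- rnorm(200)
  for (c_ in c(2, 10)) {
    s1 <- welch_psd(x, 200)
    s2 <- welch_psd(c_ * x, 200)
    for (b in as.character(eeg_bands()$band)) {
      expect_equal(unname(band_power(s2, b) - band_power(s1, b)),
                   2 * log10(c_), tolerance = 1e-9)
    }
  }
})

test_that("a 3 Hz tone concentrates power in delta, not gamma", {
  t <- seq(0, 1 - 1 / 200, by = 1 / 200)
  sp <- welch_psd(sin(2 * pi * 3 * t), 200)
  expect_gt(unname(band_power(sp, "delta") - band_power(sp, "gamma")), 3)
})

test_that("mean PSD time course averages channel totals", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  same <- manual_series(list(matrix(rep(x, each = 3), 3)), fs)
  tc <- mean_psd_timecourse(same)
  single <- sum(welch_psd(x, fs)$psd)
  expect_equal(tc$mean_power, single)

  # two channels with totals 2 and 4 -> mean 3: scale rows so that the
  # totals are exact multiples of the single-channel total
  tot1 <- sum(welch_psd(x, fs)$psd)
  two <- manual_series(list(rbind(x * sqrt(2 / tot1), x * sqrt(4 / tot1))),
                       fs)
  expect_equal(mean_psd_timecourse(two)$mean_power, 3, tolerance = 1e-9)

  bad <- manual_series(list(matrix(x, 1), matrix(rep(x, 2), 2)), fs)
  expect_error(mean_psd_timecourse(bad), "channel")
})
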