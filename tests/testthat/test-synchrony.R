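# Hilbert phase and phase locking values.

test_that("analytic phase of a cosine advances linearly", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  ph <- instantaneous_phase(rbind(cos(2 * pi * 5 * t)), fs, "broadband")
  g <- attr(ph, "guard")
  interior <- seq(g + 1, ncol(ph) - g)
  dphi <- diff(ph[1, interior]) %% (2 * pi)
  expect_lt(max(abs(dphi - 2 * pi * 5 / fs)), 0.05)
})

test_that("quadrature pair shows a constant pi/2 phase difference", {
  fs <- 200
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  th <- 2 * pi * 7 * t
  ph <- instantaneous_phase(rbind(cos(th), sin(th)), fs, "broadband")
  g <- attr(ph, "guard")
  interior <- seq(g + 1, ncol(ph) - g)
  d <- (ph[1, interior] - ph[2, interior]) %% (2 * pi)
  expect_lt(max(abs(d - pi / 2)), 0.05)
})

test_that("phase is invariant to amplitude scaling and errors on flat channels", {
  set.seed(31)
  x <- rnorm(400)
  fs <- 200
  p1 <- instantaneous_phase(rbind(x), fs)
  p7 <- instantaneous_phase(rbind(7 * x), fs)
  expect_equal(unclass(p1), unclass(p7), tolerance = 1e-12,
               ignore_attr = TRUE)

  flat <- rbind(a = x, b = rep(3, 400))
  expect_error(instantaneous_phase(flat, fs), "degenerate phase.*b")
  expect_error(instantaneous_phase(rbind(x[1:20]), fs), "32 samples")
})

test_that("plv_pair is exact for locked phases and matches random-phase theory", {
  set.seed(32)
  p <- runif(200, -pi, pi)
  expect_equal(plv_pair(p, p), 1)
  expect_equal(plv_pair(p, p + 0.7), 1, tolerance = 1e-12)
  expect_error(plv_pair(p, p[-1]), "length")

  # i.i.d. uniform phase differences: E[PLV] ~ sqrt(pi / (4 N))
  m <- mean(replicate(2000, plv_pair(runif(200, -pi, pi), numeric(200))))
  expect_equal(m, sqrt(pi / 800), tolerance = 0.005 / sqrt(pi / 800))
})

test_that("PLV is invariant to common phase offsets and amplitude", {
  set.seed(33)
  fs <- 200
  x <- matrix(rnorm(2 * 400), 2)
  base <- plv_matrix(x, fs)
  ph <- instantaneous_phase(x, fs)
  shifted <- plv_matrix(structure(unclass(ph) + 1.1, band = "broadband",
                                  guard = 25,
                                  class = class(ph)))
  expect_equal(unclass(base), unclass(shifted), tolerance = 1e-12)
  scaled <- plv_matrix(x * c(3, 0.2), fs)
  expect_equal(unclass(base), unclass(scaled), tolerance = 1e-10)
})

test_that("plv_matrix is symmetric with unit diagonal; locked pairs hit 1", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  same <- matrix(rep(sin(2 * pi * 6 * t) + 0.1 * cos(2 * pi * 11 * t),
                     each = 16), 16)
  m <- plv_matrix(same, fs)
  expect_equal(unclass(m), matrix(1, 16, 16), ignore_attr = TRUE)

  set.seed(34)
  x <- matrix(rnorm(4 * 256), 4)
  m2 <- plv_matrix(x, fs)
  expect_identical(unclass(m2), t(unclass(m2)))
  expect_true(all(m2 >= 0 & m2 <= 1))
  expect_error(plv_matrix(matrix(rnorm(200), 1), fs), "2 channels")
})

test_that("a 6 Hz locked pair separates from filtered noise in PLV", {
  fs <- 200
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  s <- sin(2 * pi * 6 * t)
  filt <- signal::butter(4, c(1, 70) / (fs / 2), "pass")
  set.seed(35)
  hits <- replicate(500, {
    noise <- signal::filtfilt(filt, rnorm(fs))
    m <- plv_matrix(rbind(s, s, noise), fs)
    c(m[1, 2], m[1, 3])
  })
  expect_true(all(abs(hits[1, ] - 1) < 1e-9))
  expect_gte(mean(hits[2, ] < 0.6), 0.95)
})

test_that("circular shift decorrelates an epoch from itself", {
  fs <- 200
  filt <- signal::butter(4, c(1, 70) / (fs / 2), "pass")
  set.seed(36)
  below <- replicate(200, {
    x <- signal::filtfilt(filt, rnorm(fs))
    shifted <- c(x[101:fs], x[1:100])
    m <- plv_matrix(rbind(x, x, shifted), fs)
    m[1, 3] < m[1, 2]  # shifted vs unshifted copy
  })
  expect_gte(mean(below), 0.95)
})

test_that("binarize uses a strict threshold and is antitone in tau", {
  m <- diag(16)
  m[m == 0] <- 0.3
  m[1, 2] <- m[2, 1] <- 0.61
  m[3, 4] <- m[4, 3] <- 0.60
  pm <- structure(m, band = "broadband",
                  class = c("plv_matrix", "matrix", "array"))
  net <- binarize(pm, 0.6)
  expect_equal(net[1, 2], 1L)
  expect_equal(net[3, 4], 0L)   # exactly at threshold: no edge
  expect_true(all(diag(net) == 0))

  all_low <- structure(diag(16) * 0.4 + 0.0, band = "broadband",
                       class = class(pm))
  expect_equal(edge_count(binarize(all_low, 0.6)), 0)

  pos <- structure(matrix(0.2, 16, 16) + diag(16) * 0.8, band = "broadband",
                   class = class(pm))
  expect_equal(edge_count(binarize(pos, 0)), 120)  # complete graph

  set.seed(37)
  r <- matrix(runif(256), 16)
  r <- (r + t(r)) / 2
  rp <- structure(r, band = "broadband", class = class(pm))
  counts <- vapply(seq(0, 1, 0.1),
                   function(tau) edge_count(binarize(rp, tau)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("mean PLV pools the 120 unordered pairs", {
  chans <- montage_channels()
  pairs <- t(utils::combn(chans, 2))
  plv_vals <- rep(0.2, 120)
  plv_vals[1] <- 0.8
  tbl <- tibble::tibble(epoch = 1L, t_rel = 0L, state = "ictal",
                        band = "broadband", ch_i = pairs[, 1],
                        ch_j = pairs[, 2], plv = plv_vals)
  tc <- mean_plv_timecourse(tbl)
  expect_equal(tc$plv_mean, (0.2 * 119 + 0.8) / 120)  # 0.205

  ones <- tbl
  ones$plv <- 1
  expect_equal(mean_plv_timecourse(ones)$plv_mean, 1)
})
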