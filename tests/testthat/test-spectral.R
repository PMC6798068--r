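test_that("welch_psd at the 500/500/0 settings is a single modified periodogram", {
  set.seed(2)
  x <- rnorm(500)
  psd <- welch_psd(x, 500)
  expect_equal(psd$n_segments, 1)
  expect_equal(psd$power, periodogram_oracle(x, 500, 500))
  expect_error(welch_psd(rnorm(400), 500), "shorter than the window")
})

test_that("every emitted PSD satisfies Parseval", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(c(500, 1500, 2000), 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    psd <- welch_psd(x, 500)
    # integral of PSD over frequency = window-power-corrected variance,
    # summed over segments (exact identity of the estimator)
    w <- as.numeric(signal::hamming(500))
    segs <- seq(1, n - 499, by = 500)
    expected <- mean(vapply(segs, function(s) {
      seg <- x[s:(s + 499)] - mean(x[s:(s + 499)])
      sum((w * seg)^2) / sum(w^2)
    }, numeric(1)))
    got <- sum(psd$power) * 500 / psd$nfft
    expect_lt(abs(got - expected) / expected, 1e-6)
  }
  # zero-padded short segment (the 75-sample pre-onset interval) too
  x <- rnorm(75)
  psd <- welch_psd(x, 500, nfft = 500, win_len = 75)
  w <- as.numeric(signal::hamming(75))
  expected <- sum((w * (x - mean(x)))^2) / sum(w^2)
  expect_lt(abs(sum(psd$power) - expected) / expected, 1e-6)
})

test_that("white-noise PSD integrates to the variance and a sinusoid to A^2/2", {
  set.seed(4)
  x <- rnorm(250000, 0, 3)                  # 500 segments of 500 samples
  psd <- welch_psd(x, 500)
  expect_equal(psd$n_segments, 500)
  tot <- sum(psd$power) * 500 / psd$nfft
  expect_lt(abs(tot - 9) / 9, 0.05)
  t <- seq(0, 0.998, by = 1 / 500)
  s <- 2 * sin(2 * pi * 10 * t)
  ps <- welch_psd(s, 500)
  tot <- band_power(ps, c(0, 250))$power_uv2
  expect_lt(abs(tot - 2) / 2, 0.05)         # A^2/2 = 2 uV^2
  expect_gt(band_power(ps, c(8, 13))$power_uv2 / tot, 0.95)
})

test_that("band integration owns bins by centre frequency on the 1 Hz grid", {
  psd <- welch_psd(rnorm(500), 500)
  expect_equal(psd$fs / psd$nfft, 1)
  expect_equal(sum(psd$freq_hz >= 8 & psd$freq_hz <= 13), 6)
  flat <- psd; flat$power <- rep(2, length(psd$power))
  expect_equal(band_power(flat, c(8, 13))$power_uv2, 12)   # 6 bins x 2 x 1 Hz
  # additivity across a partition of the band
  expect_equal(band_power(psd, c(8, 13))$power_uv2,
               band_power(psd, c(8, 10))$power_uv2 +
                 band_power(psd, c(10.999, 13))$power_uv2)
  expect_error(band_power(psd, c(300, 400)), "fs/2")
})

test_that("identical sinusoid trials give the closed-form alpha power in dB", {
  fs <- 500
  t_ms <- seq(-1000, 4998, by = 2)
  wave <- 2 * sin(2 * pi * 10 * t_ms / 1000)
  arr <- array(rep(wave, each = 10 * 24), c(10, 24, length(t_ms)))
  for (i in 1:10) for (ch in 1:24) arr[i, ch, ] <- wave
  ep <- make_epochs(arr, channels = default_montage())
  # same 8-13 Hz band under both estimation modes: averaging order is
  # irrelevant for identical trials
  sp <- feature_specs()[11:12, ]
  sp$band_lo_hz[2] <- 8; sp$band_hi_hz[2] <- 13
  rows <- compute_spectral_features(NULL, ep, ep, "P01", "FD", specs = sp)
  f11 <- rows$value[rows$feature == 11 & rows$epoch == "b2" & rows$location == "Cz"]
  f12 <- rows$value[rows$feature == 12 & rows$epoch == "b2" & rows$location == "Cz"]
  expect_lt(abs(f11 - 10 * log10(2)), 0.15)
  expect_equal(f11, f12)
})

test_that("averaged-trial and single-trial estimation are genuinely distinct paths", {
  fs <- 500
  t_ms <- seq(-1000, 4998, by = 2)
  gap <- function(n) {
    set.seed(5)
    arr <- array(0, c(n, 1, length(t_ms)))
    for (i in seq_len(n))
      arr[i, 1, ] <- 2 * sin(2 * pi * 10 * t_ms / 1000 + runif(1, 0, 2 * pi))
    ep <- make_epochs(arr, channels = "Cz")
    sp <- feature_specs()[11:12, ]
    sp$band_lo_hz[2] <- 8; sp$band_hi_hz[2] <- 13   # same band, two modes
    rows <- compute_spectral_features(NULL, ep, ep, "P01", "FD",
                                      groups = list(), specs = sp)
    f11 <- rows$value[rows$feature == 11 & rows$epoch == "b2"]
    f12 <- rows$value[rows$feature == 12 & rows$epoch == "b2"]
    f12 - f11
  }
  g10 <- gap(10); g40 <- gap(40)
  expect_gt(g10, 0)                          # on-average < single-trial mean
  expect_gt(g40, g10)                        # and the gap grows with trials
})

test_that("scaling all trials by c shifts every band power by 20*log10(c) dB", {
  set.seed(6)
  t_ms <- seq(-1000, 4998, by = 2)
  arr <- array(rnorm(8 * 1 * length(t_ms)), c(8, 1, length(t_ms)))
  ep1 <- make_epochs(arr, channels = "Cz")
  ep2 <- make_epochs(arr * 3, channels = "Cz")
  sp <- feature_specs()[11:12, ]
  r1 <- compute_spectral_features(NULL, ep1, ep1, "P", "FD", groups = list(),
                                  specs = sp)
  r2 <- compute_spectral_features(NULL, ep2, ep2, "P", "FD", groups = list(),
                                  specs = sp)
  expect_equal(r2$value - r1$value, rep(20 * log10(3), nrow(r1)),
               tolerance = 1e-9)
})

test_that("the pre-onset low-gamma feature is computed per single trial without baseline", {
  f <- small_features()
  r9 <- f[f$feature == 9, ]
  expect_equal(sort(unique(r9$epoch)), c("c1", "c2"))
  expect_equal(sum(r9$epoch == "c1"), 30)
  expect_true(all(is.finite(r9$value)))
})
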