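test_that("find_peak returns a unique local extremum exactly", {
  fs <- 500
  t_ms <- seq(-1000, 999, by = 2)
  x <- 3 * exp(-(t_ms - 150)^2 / (2 * 20^2))
  pk <- find_peak(x, fs, c(100, 200), "positive", t_start_ms = -1000)
  expect_equal(pk$amplitude_uv, 3)
  expect_equal(pk$latency_ms, 150)
  expect_true(pk$is_local)
  # negative polarity mirrors
  pkn <- find_peak(-x, fs, c(100, 200), "negative", t_start_ms = -1000)
  expect_equal(pkn$amplitude_uv, -3)
  expect_equal(pkn$latency_ms, 150)
})

test_that("find_peak falls back to the windowed extremum on monotone data", {
  fs <- 500
  x <- seq(0, 10, length.out = 1000)             # strictly increasing ramp
  pk <- find_peak(x, fs, c(400, 600), "positive", t_start_ms = 0)
  expect_false(pk$is_local)
  expect_equal(pk$latency_ms, 600)               # window's last sample
  expect_equal(pk$amplitude_uv, x[301])
  expect_error(find_peak(x, fs, c(1900, 2100), "positive"), "outside")
})

test_that("find_peak matches the exhaustive scan on random waveforms", {
  set.seed(99)
  fs <- 500
  for (i in 1:500) {
    n <- sample(150:400, 1)
    x <- as.numeric(stats::filter(rnorm(n), rep(1 / 5, 5), sides = 2))
    x[is.na(x)] <- 0
    w0 <- sample(0:200, 1)
    w1 <- w0 + sample(60:200, 1)
    pol <- sample(c("positive", "negative"), 1)
    nb <- sample(c(8, 20, 40), 1)
    if (round(w1 * fs / 1000) + 1 > n) w1 <- (n - 1) * 1000 / fs
    got <- find_peak(x, fs, c(w0, w1), pol, t_start_ms = 0, neighborhood_ms = nb)
    want <- peak_oracle(x, fs, c(w0, w1), pol, t_start_ms = 0,
                        neighborhood_ms = nb)
    expect_identical(got, want)
  }
})

test_that("the four onset components map onto features 1-8", {
  fs <- 500
  t_ms <- seq(-1000, 4998, by = 2)
  wave <- 4 * exp(-(t_ms - 150)^2 / (2 * 15^2)) -
    3 * exp(-(t_ms - 240)^2 / (2 * 15^2)) +
    2 * exp(-(t_ms - 340)^2 / (2 * 20^2)) +
    1 * exp(-(t_ms - 500)^2 / (2 * 30^2))
  arr <- array(rep(wave, each = 24), c(1, 24, length(t_ms)))
  ep <- make_epochs(arr, lock = "stimulus_on", channels = default_montage())
  erp <- average_erp(ep)
  rows <- compute_time_features(list(c1 = erp, c2 = erp), "P01", "FD",
                                min_trials = 1)
  c1 <- rows[rows$epoch == "c1" & rows$location == "Cz", ]
  amp <- c1$value[match(c(1, 3, 5, 7), c1$feature)]
  lat <- c1$value[match(c(2, 4, 6, 8), c1$feature)]
  expect_equal(amp, c(4, -3, 2, 1), tolerance = 1e-6)
  expect_equal(lat, c(150, 240, 340, 500))
  # group locations equal the peak of the group-averaged waveform
  expect_equal(rows$value[rows$feature == 1 & rows$epoch == "c1" &
                            rows$location == "L5"], 4, tolerance = 1e-6)
})

test_that("the reversal positivity is measured before its own button lock", {
  fs <- 500
  t_ms <- seq(-1000, 4998, by = 2)
  wave <- 2.5 * exp(-(t_ms + 250)^2 / (2 * 15^2))
  arr <- array(rep(wave, each = 24), c(1, 24, length(t_ms)))
  erp <- average_erp(make_epochs(arr, channels = default_montage()))
  rows <- compute_time_features(list(b2 = erp), "P01", "FD", min_trials = 1)
  r10 <- rows[rows$feature == 10 & rows$epoch == "b2" & rows$location == "P4", ]
  expect_equal(r10$value, 2.5, tolerance = 1e-6)
  # latency variant is not part of the canonical table; amplitude window is
  # [-300, -200] ms before the press
  pk <- find_peak(wave, fs, c(-300, -200), "positive", t_start_ms = -1000)
  expect_equal(pk$latency_ms, -250)
})

test_that("peak features are equivariant under scaling and time shifts", {
  set.seed(11)
  fs <- 500
  x <- as.numeric(stats::filter(rnorm(1500), rep(1 / 20, 20), sides = 2))
  x[is.na(x)] <- 0
  base <- find_peak(x, fs, c(300, 700), "positive", t_start_ms = 0)
  sc <- find_peak(3.7 * x, fs, c(300, 700), "positive", t_start_ms = 0)
  expect_equal(sc$amplitude_uv, 3.7 * base$amplitude_uv)
  expect_equal(sc$latency_ms, base$latency_ms)
  shift <- 40                                    # ms
  xs <- c(numeric(shift * fs / 1000), x)[seq_along(x)]
  sh <- find_peak(xs, fs, c(300 + shift, 700 + shift), "positive", t_start_ms = 0)
  expect_equal(sh$latency_ms, base$latency_ms + shift)
  expect_equal(sh$amplitude_uv, base$amplitude_uv)
})

test_that("contexts with too few trials yield missing rows with a reason", {
  fs <- 500
  t_ms <- seq(-1000, 4998, by = 2)
  arr <- array(rnorm(2 * 24 * length(t_ms)), c(2, 24, length(t_ms)))
  erp <- average_erp(make_epochs(arr, lock = "stimulus_on",
                                 channels = default_montage()))
  rows <- compute_time_features(list(c1 = erp), "P01", "FD", min_trials = 5)
  expect_true(all(is.na(rows$value[rows$epoch == "c1"])))
  expect_match(rows$note[1], "min 5")
})
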