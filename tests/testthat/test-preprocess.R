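test_that("the band-pass design is symmetric with the required response", {
  h <- design_bandpass(500)
  n <- length(h)
  expect_true(n %% 2 == 1)                       # type I (even order)
  expect_identical(h, rev(h))                    # exact windowed-sinc symmetry
  resp <- bistableEEG:::fir_response(h, c(0, 33.5, 4, 55, 75, 100), 500)
  expect_lt(resp[1], 0.01)                       # DC blocked
  expect_true(resp[2] > 0.99 && resp[2] < 1.01)  # mid-band
  expect_true(all(resp[3:4] > 0.99 & resp[3:4] < 1.01))
  expect_true(all(resp[5:6] < 10^(-50 / 20)))    # stopband >= 50 dB
  expect_error(design_bandpass(120, filter_spec(2, 65)), "Nyquist")
})

test_that("filtering is delay-compensated, length-preserving and removes DC", {
  fs <- 500
  t <- seq(0, 20, by = 1 / fs)
  x10 <- sin(2 * pi * 10 * t)
  rec <- eeg_recording(rbind(x10, x10 * 0 + 100, sin(2 * pi * 0.5 * t)),
                       fs, c("a", "b", "c"))
  out <- filter_recording(rec)
  expect_equal(ncol(out$data), ncol(rec$data))
  # cross-correlation peak of in/out at lag 0 (zero net group delay)
  cc <- stats::ccf(out$data[1, ], x10, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # 100 uV DC -> ~0
  expect_lt(abs(mean(out$data[2, ])), 0.5)
  # 0.5 Hz in deep stopband
  mid <- 2000:8000
  expect_lt(sqrt(mean(out$data[3, mid]^2)), 0.05 * sqrt(mean(rec$data[3, mid]^2)))
})

test_that("epoch windows follow the half-open 0-based convention", {
  fs <- 500
  data <- matrix(seq_len(10000) - 1, nrow = 1)  # x[s] = s (0-based)
  ev <- data.frame(sample = c(100L, 5000L), type = "stimulus_on",
                   trial = 0:1, condition = "c1")
  rec <- eeg_recording(data, fs, "Cz", ev)
  ep <- extract_epochs(rec, "stimulus_on", c(-1000, 5000))
  # the trial at sample 100 under-runs the recording start -> dropped
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(nrow(ep$dropped), 1)
  expect_equal(dim(ep$data)[3], 3000)
  expect_equal(ep$data[1, 1, 1], 4500)           # covers [4500, 7500)
  expect_equal(ep$data[1, 1, 3000], 7499)
})

test_that("baseline correction subtracts the prestimulus mean and is idempotent", {
  fs <- 500
  n <- 8000
  x <- rep(5, n)
  ev <- data.frame(sample = 4000L, type = "stimulus_on", trial = 0L,
                   condition = "c1")
  rec <- eeg_recording(matrix(x, 1), fs, "Cz", ev)
  ep <- baseline_correct(extract_epochs(rec, "stimulus_on", c(-1000, 1000)))
  expect_equal(max(abs(ep$data)), 0)             # constant epoch -> all zero
  # ramp over the baseline window: x[s] = s - 3500 on samples 3500..3999
  x2 <- numeric(n); x2[3501:4000] <- 0:499
  rec2 <- eeg_recording(matrix(x2, 1), fs, "Cz", ev)
  ep2 <- extract_epochs(rec2, "stimulus_on", c(-1000, 1000))
  expect_equal(ep2$baseline_means[1, 1], 249.5)  # mean of 0..499
  bc <- baseline_correct(ep2)
  expect_lt(abs(mean(bc$data[1, 1, 1:500])), 1e-9)
  expect_identical(baseline_correct(bc)$data, bc$data)
})

test_that("ERP averaging is the pointwise trial mean", {
  arr <- array(0, c(2, 1, 3000))
  v <- sin(seq_len(3000) / 50)
  arr[1, 1, ] <- v; arr[2, 1, ] <- -v
  ep <- make_epochs(arr, lock = "stimulus_on", channels = "Cz")
  expect_equal(max(abs(average_erp(ep)$data)), 0)      # +v / -v cancel
  ep1 <- make_epochs(arr[1, , , drop = FALSE], lock = "stimulus_on",
                     channels = "Cz")
  expect_equal(as.numeric(average_erp(ep1)$data), v)   # single trial identity
  expect_error(average_erp(ep, "c2"), "no trials")
  # 100 noise trials, sigma 10 -> ERP noise SD ~ 1
  set.seed(4)
  arrn <- array(rnorm(100 * 1 * 500, 0, 10), c(100, 1, 500))
  epn <- make_epochs(arrn, lock = "stimulus_on", window_ms = c(0, 1000),
                     channels = "Cz")
  expect_lt(abs(stats::sd(average_erp(epn)$data) - 1), 0.3)
})

test_that("channel groups average to virtual locations forming 30 in total", {
  g <- channel_groups()
  expect_equal(g$L5, c("Fp1", "F7", "FC1", "TP9", "CP5", "CP1", "P3", "O1"))
  expect_true(!length(intersect(g$L5, g$L6)))
  expect_length(analysis_locations(), 30)
  data <- matrix(rnorm(24 * 100), 24)
  expect_equal(group_signal(data, default_montage(), g$L5),
               colMeans(data[match(g$L5, default_montage()), ]))
  same <- matrix(rep(sin(1:100), each = 24), 24, byrow = FALSE)
  expect_equal(group_signal(same, default_montage(), g$L1), same[1, ])
  expect_error(group_signal(data, default_montage(), c("Fp1", "XX")), "XX")
  loc <- bistableEEG:::location_signals(data, default_montage(), g)
  expect_equal(nrow(loc), 30)
})

test_that("onset- and button-locked epochs agree on their overlapping samples", {
  b <- small_bundle()
  filt <- filter_recording(b$recording)
  on <- extract_epochs(filt, "stimulus_on", c(-1000, 5000))
  b1 <- extract_epochs(filt, "button1", c(-1000, 5000))
  tt <- b$trial_table
  tr <- intersect(on$trial, b1$trial)[1]
  o <- tt$stimulus_on[tt$trial == tr]; bb <- tt$button1[tt$trial == tr]
  shift <- bb - o                                 # samples between the locks
  io <- which(on$trial == tr); ib <- which(b1$trial == tr)
  overlap <- dim(on$data)[3] - shift
  expect_gt(overlap, 0)
  expect_equal(on$data[io, , (shift + 1):dim(on$data)[3]],
               b1$data[ib, , 1:overlap])
})

test_that("filtering and epoching commute for interior epochs", {
  b <- small_bundle()
  h <- design_bandpass(b$recording$fs)
  ctx <- length(h)                                # context margin in samples
  filt <- filter_recording(b$recording)
  tt <- b$trial_table
  e <- tt$stimulus_on[3]
  s0 <- e - 500; s1 <- e + 1000
  direct <- filt$data[1, (s0 + 1):s1]
  wide <- b$recording$data[1, (s0 - ctx + 1):(s1 + ctx)]
  wide_f <- bistableEEG:::apply_fir(wide, h)
  expect_lt(max(abs(wide_f[(ctx + 1):(ctx + length(direct))] - direct)), 1e-6)
})
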