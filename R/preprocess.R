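#' Band-pass filter specification
#'
#' Hamming-windowed linear-phase FIR band-pass, 2-65 Hz by default. The
#' order follows the Hamming design rule `3.3 / (tbw / fs)` using the
#' narrower (low-edge) transition bandwidth, rounded up to an even number so
#' the filter is type I with an integer group delay.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param transition_low_hz,transition_high_hz Transition bandwidths at the
#'   two edges (defaults 2 and 10 Hz).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 2, high_hz = 65,
                        transition_low_hz = 2, transition_high_hz = 10) {
  if (low_hz <= 0 || high_hz <= low_hz)
    stop("need 0 < low_hz < high_hz")
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 transition_low_hz = transition_low_hz,
                 transition_high_hz = transition_high_hz),
            class = "filter_spec")
}

#' Design the band-pass FIR filter
#'
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric vector of symmetric filter coefficients (odd length).
#' @export
design_bandpass <- function(fs, spec = filter_spec()) {
  if (spec$high_hz >= fs / 2)
    stop("high_hz must be below the Nyquist frequency fs/2")
  tbw <- min(spec$transition_low_hz, spec$transition_high_hz)
  ord <- ceiling(3.3 / (tbw / fs))
  if (ord %% 2 == 1) ord <- ord + 1
  h <- as.numeric(signal::fir1(ord, c(spec$low_hz, spec$high_hz) / (fs / 2),
                               type = "pass", window = signal::hamming(ord + 1)))
  (h + rev(h)) / 2    # enforce exact linear-phase symmetry

}

# Frequency response magnitude of an FIR filter at frequencies f (Hz).
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(ff) abs(sum(h * exp(-2i * pi * ff * k / fs))), numeric(1))
}

# Zero-net-delay application of a symmetric FIR filter to one channel:
# reflect-pad both ends, filter causally, trim by the group delay.
apply_fir <- function(x, h) {
  d <- (length(h) - 1) / 2
  n <- length(x)
  if (n <= 3 * (length(h) - 1))
    stop("recording too short for the designed filter (need > 3x filter order)")
  pad_l <- x[(d + 1):2]
  pad_r <- x[(n - 1):(n - d)]
  xp <- c(pad_l, x, pad_r)
  y <- signal::fftfilt(h, xp)
  y[(2 * d + 1):(2 * d + n)]
}

#' Filter a continuous recording
#'
#' Applies the Hamming-windowed band-pass FIR with group-delay compensation
#' (single forward pass, shifted by order/2), preserving the designed
#' magnitude response exactly and adding no net delay. Edges are padded by
#' reflection and trimmed, so output length equals input length.
#'
#' @param recording An [eeg_recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [eeg_recording()].
#' @export
filter_recording <- function(recording, spec = filter_spec()) {
  h <- design_bandpass(recording$fs, spec)
  out <- recording
  for (ch in seq_len(nrow(recording$data)))
    out$data[ch, ] <- apply_fir(recording$data[ch, ], h)
  out$metadata$filter <- spec
  out
}

#' Extract event-locked epochs
#'
#' One epoch per event of the requested lock type, over the half-open
#' sample window `[event + round(w1*fs/1000), event + round(w2*fs/1000))`.
#' Epochs that would run outside the recording are dropped with a recorded
#' reason. The per-trial prestimulus baseline mean (over `[-1000, 0)` ms
#' before the same trial's stimulus onset) is computed here from the
#' continuous data and stored, so that [baseline_correct()] can anchor
#' button-locked epochs to the stimulus-onset baseline.
#'
#' @param recording An [eeg_recording()] (normally already filtered).
#' @param lock `"stimulus_on"`, `"button1"` or `"button2"`.
#' @param window_ms Length-2 window in ms relative to the lock event.
#' @param trials Optional subset of trial ids to keep (e.g. test trials).
#' @param baseline_window_ms Baseline window relative to stimulus onset.
#' @return Object of class `eeg_epochs`: `data` is a trials x channels x
#'   samples array.
#' @export
extract_epochs <- function(recording, lock = c("stimulus_on", "button1", "button2"),
                           window_ms = c(-1000, 5000), trials = NULL,
                           baseline_window_ms = c(-1000, 0)) {
  lock <- match.arg(lock)
  fs <- recording$fs
  ev <- recording$events
  locks <- ev[ev$type == lock, , drop = FALSE]
  if (!is.null(trials)) locks <- locks[locks$trial %in% trials, , drop = FALSE]
  off <- ms_to_samples(window_ms, fs)
  n_win <- off[2] - off[1]
  boff <- ms_to_samples(baseline_window_ms, fs)
  stim <- ev[ev$type == "stimulus_on", c("trial", "sample")]
  n_samples <- ncol(recording$data)
  nch <- nrow(recording$data)

  if (nrow(locks) == 0) {
    warning("no events of type '", lock, "' found; returning empty epoch set")
    return(new_epochs(array(0, c(0, nch, n_win)), lock, window_ms, fs,
                      integer(0), character(0), recording$channels,
                      baseline_means = matrix(0, 0, nch),
                      baseline_window_ms = baseline_window_ms,
                      dropped = data.frame(trial = integer(), reason = character())))
  }

  keep <- logical(nrow(locks))
  drop_reason <- character(0); drop_trial <- integer(0)
  bl <- matrix(NA_real_, nrow(locks), nch)
  for (i in seq_len(nrow(locks))) {
    e <- locks$sample[i]
    s0 <- e + off[1]; s1 <- e + off[2]
    st <- stim$sample[match(locks$trial[i], stim$trial)]
    if (s0 < 0 || s1 > n_samples) {
      drop_trial <- c(drop_trial, locks$trial[i])
      drop_reason <- c(drop_reason, "epoch window outside recording")
    } else if (is.na(st) || st + boff[1] < 0) {
      drop_trial <- c(drop_trial, locks$trial[i])
      drop_reason <- c(drop_reason, "prestimulus baseline window unavailable")
    } else {
      keep[i] <- TRUE
      bl[i, ] <- rowMeans(recording$data[, (st + boff[1] + 1):(st + boff[2]),
                                         drop = FALSE])
    }
  }
  locks <- locks[keep, , drop = FALSE]
  bl <- bl[keep, , drop = FALSE]
  dat <- array(0, c(nrow(locks), nch, n_win))
  for (i in seq_len(nrow(locks))) {
    e <- locks$sample[i]
    dat[i, , ] <- recording$data[, (e + off[1] + 1):(e + off[2]), drop = FALSE]
  }
  new_epochs(dat, lock, window_ms, fs, locks$trial, locks$condition,
             recording$channels, baseline_means = bl,
             baseline_window_ms = baseline_window_ms,
             dropped = data.frame(trial = drop_trial, reason = drop_reason,
                                  stringsAsFactors = FALSE))
}

# Low-level epoch-set constructor (exported for building epoch sets directly
# in analyses and tests).
#' Construct an epoch set from an array
#'
#' @param data trials x channels x samples array (microvolts).
#' @param lock,window_ms,fs,trial,condition,channels Epoch metadata.
#' @param baseline_means trials x channels matrix of prestimulus means
#'   (zero matrix if unknown).
#' @param baseline_window_ms Baseline window (ms, relative to stimulus onset).
#' @param baseline_applied Whether the baseline was already subtracted.
#' @param dropped Data frame of dropped trials and reasons.
#' @return Object of class `eeg_epochs`.
#' @export
new_epochs <- function(data, lock, window_ms, fs, trial, condition, channels,
                       baseline_means = NULL,
                       baseline_window_ms = c(-1000, 0),
                       baseline_applied = FALSE,
                       dropped = data.frame(trial = integer(),
                                            reason = character())) {
  stopifnot(length(dim(data)) == 3)
  n_expect <- ms_to_samples(window_ms[2], fs) - ms_to_samples(window_ms[1], fs)
  if (dim(data)[3] != n_expect)
    stop("sample count ", dim(data)[3], " inconsistent with window (expected ",
         n_expect, ")")
  if (is.null(baseline_means)) baseline_means <- matrix(0, dim(data)[1], dim(data)[2])
  structure(list(data = data, lock = lock, window_ms = window_ms, fs = fs,
                 trial = trial, condition = condition, channels = channels,
                 baseline_means = baseline_means,
                 baseline_window_ms = baseline_window_ms,
                 baseline_applied = baseline_applied, dropped = dropped),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples, locked to %s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock))
  cat(sprintf("  window [%g, %g] ms, baseline %s; conditions: %s; dropped: %d\n",
              x$window_ms[1], x$window_ms[2],
              if (x$baseline_applied) "applied" else "not applied",
              paste(sprintf("%s=%d", names(table(x$condition)),
                            as.integer(table(x$condition))), collapse = ", "),
              nrow(x$dropped)))
  invisible(x)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean over that trial's
#' `[-1000, 0)` ms window before *stimulus onset* — also for button-locked
#' epochs, whose own prestimulus interval contains reversal-related
#' activity. Idempotent: applying twice equals applying once.
#'
#' @param epochs An `eeg_epochs` object from [extract_epochs()].
#' @return The corrected epoch set with `baseline_applied = TRUE`.
#' @export
baseline_correct <- function(epochs) {
  if (isTRUE(epochs$baseline_applied)) return(epochs)
  for (i in seq_len(dim(epochs$data)[1]))
    epochs$data[i, , ] <- epochs$data[i, , , drop = FALSE][1, , ] -
      epochs$baseline_means[i, ]
  epochs$baseline_applied <- TRUE
  epochs
}

#' Average epochs into an ERP
#'
#' @param epochs An `eeg_epochs` object.
#' @param condition Optional condition label to average (`NULL` = all trials).
#' @return Object of class `eeg_erp` with a channels x samples `data`
#'   matrix and the underlying trial count.
#' @export
average_erp <- function(epochs, condition = NULL) {
  idx <- if (is.null(condition)) seq_len(dim(epochs$data)[1]) else
    which(epochs$condition == condition)
  if (!length(idx))
    stop(sprintf("no trials to average (lock %s, condition %s)",
                 epochs$lock, condition %||% "all"))
  dat <- if (length(idx) == 1) epochs$data[idx, , , drop = TRUE] else
    apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  if (is.null(dim(dat))) dat <- matrix(dat, nrow = dim(epochs$data)[2])
  structure(list(data = dat, n_trials = length(idx), lock = epochs$lock,
                 condition = condition %||% "all", window_ms = epochs$window_ms,
                 fs = epochs$fs, channels = epochs$channels),
            class = "eeg_erp")
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %s / %s: %d channels x %d samples, %d trials\n",
              x$lock, x$condition, nrow(x$data), ncol(x$data), x$n_trials))
  invisible(x)
}

#' Average a channel group into a virtual channel
#'
#' Unweighted mean across the group's channels. With the six groups L1-L6
#' this produces the virtual locations that, together with the 24
#' electrodes, form the 30 analysis locations.
#'
#' @param data Channels x samples matrix.
#' @param channels Labels for the rows of `data`.
#' @param group Character vector of channel labels to average.
#' @return Numeric vector (one virtual-channel waveform).
#' @export
group_signal <- function(data, channels, group) {
  idx <- match(group, channels)
  if (anyNA(idx))
    stop("channel(s) missing from data: ",
         paste(group[is.na(idx)], collapse = ", "))
  colMeans(data[idx, , drop = FALSE])
}
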