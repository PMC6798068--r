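#' Welch power spectral density estimate
#'
#' Averages modified (Hamming-windowed, mean-detrended) periodograms over
#' non-overlapping segments. With the default settings used throughout the
#' analysis — fft length 500, window 500 samples, no overlap — a 500-sample
#' input reduces to a single modified periodogram. Normalisation is such
#' that the integral of the one-sided PSD over frequency equals the
#' window-power-corrected variance of the detrended signal (Parseval).
#' Segments shorter than `nfft` are zero-padded after windowing (the data
#' itself is never padded into a longer window).
#'
#' @param x Numeric waveform (microvolts).
#' @param fs Sampling rate in Hz.
#' @param nfft FFT length (>= `win_len`); sets the frequency grid `fs/nfft`.
#' @param win_len Segment/window length in samples.
#' @param overlap Segment overlap in samples (default 0).
#' @param detrend Remove each segment's mean before windowing.
#' @return Object of class `eeg_psd`: `freq_hz`, `power` (uV^2/Hz,
#'   one-sided), `nfft`, `win_len`, `n_segments`.
#' @export
welch_psd <- function(x, fs, nfft = 500, win_len = 500, overlap = 0,
                      detrend = TRUE) {
  n <- length(x)
  if (n < win_len)
    stop("segment of length ", n, " is shorter than the window (", win_len,
         " samples); no zero-padding of data")
  if (nfft < win_len) stop("nfft must be >= win_len")
  w <- as.numeric(signal::hamming(win_len))
  step <- win_len - overlap
  starts <- seq(1, n - win_len + 1, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + win_len - 1)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(c(w * seg, numeric(nfft - win_len)))
    P <- Mod(X[seq_len(nfft %/% 2 + 1)])^2 / (fs * sum(w^2))
    scale2 <- rep(2, length(P)); scale2[1] <- 1
    if (nfft %% 2 == 0) scale2[length(P)] <- 1
    acc <- acc + P * scale2
  }
  structure(list(freq_hz = (0:(nfft %/% 2)) * fs / nfft,
                 power = acc / length(starts),
                 nfft = nfft, win_len = win_len, n_segments = length(starts),
                 fs = fs, window = "hamming"),
            class = "eeg_psd")
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("<eeg_psd> %d bins, df = %g Hz, %d segment(s) of %d samples\n",
              length(x$freq_hz), x$fs / x$nfft, x$n_segments, x$win_len))
  invisible(x)
}

#' Integrate band power from a PSD
#'
#' Rectangle-rule integral over the frequency bins whose centres lie in
#' `[low, high]` inclusive. With fs = 500 and nfft = 500 the grid spacing
#' is 1 Hz, so the 8-13 Hz alpha band owns exactly 6 bins.
#'
#' @param psd An `eeg_psd` from [welch_psd()].
#' @param band_hz Length-2 band limits in Hz.
#' @return List with `power_uv2` (band-integrated power) and `power_db`
#'   (`10*log10` of it).
#' @export
band_power <- function(psd, band_hz) {
  if (band_hz[1] < 0 || band_hz[2] > psd$fs / 2)
    stop("band must lie within [0, fs/2]")
  tol <- 1e-9
  sel <- psd$freq_hz >= band_hz[1] - tol & psd$freq_hz <= band_hz[2] + tol
  if (!any(sel)) stop("no frequency bins inside the requested band")
  df <- psd$fs / psd$nfft
  p <- sum(psd$power[sel]) * df
  list(power_uv2 = p, power_db = 10 * log10(p))
}

# Band power of one location waveform segment under the analysis settings:
# Hamming window of the full segment, nfft 500 (zero-padded when the
# segment is shorter, e.g. the 75-sample pre-onset interval).
segment_band_power_uv2 <- function(x, fs, band, nfft = 500) {
  wl <- min(length(x), nfft)
  band_power(welch_psd(x[seq_len(wl)], fs, nfft = nfft, win_len = wl),
             band)$power_uv2
}

#' Compute the spectral features for one participant
#'
#' Feature 9 (low gamma 26-40 Hz, `[-200, -50]` ms before onset) is
#' estimated per single trial on *uncorrected* epochs (its window lies
#' inside the baseline interval) and the per-trial band powers averaged;
#' feature 11 (alpha 8-13 Hz) is estimated from the Welch PSD of the
#' trial-averaged pre-button waveform; feature 12 (gamma 26-60 Hz) is the
#' mean of single-trial estimates. Values are reported in dB
#' (`10*log10` of the band power in uV^2); the linear power is kept in an
#' auxiliary column of the pipeline output.
#'
#' @param onset_epochs Stimulus-onset-locked epochs *without* baseline
#'   correction (both conditions).
#' @param b1_epochs,b2_epochs Button-locked epochs of the bistable
#'   condition.
#' @param participant,group Identifiers copied into the rows.
#' @param groups Channel groups.
#' @param specs Feature table from [feature_specs()].
#' @param min_trials Minimum trial count for a context to contribute.
#' @return Data frame of feature rows (value in dB, `value_uv2` auxiliary).
#' @export
compute_spectral_features <- function(onset_epochs, b1_epochs, b2_epochs,
                                      participant, group,
                                      groups = channel_groups(),
                                      specs = feature_specs(),
                                      min_trials = 5) {
  specs <- specs[specs$kind == "band_power", ]
  rows <- list()
  emit <- function(id, ctx, locs, vals, n, note = NA_character_) {
    r <- feature_row(participant, group, id, ctx, locs, 10 * log10(vals), n, note)
    r$value_uv2 <- vals
    rows[[length(rows) + 1]] <<- r
  }
  emit_missing <- function(id, ctx, n, reason) {
    r <- feature_row(participant, group, id, ctx,
                     analysis_locations(default_montage(), groups),
                     NA_real_, n, reason)
    r$value_uv2 <- NA_real_
    rows[[length(rows) + 1]] <<- r
  }

  # feature 9: per-trial, per condition, uncorrected onset epochs
  sp9 <- specs[specs$id == 9, ]
  for (cond in if (nrow(sp9)) c("c1", "c2") else character(0)) {
    idx <- which(onset_epochs$condition == cond)
    if (length(idx) < min_trials) {
      emit_missing(9, cond, length(idx),
                   sprintf("only %d trials (min %d)", length(idx), min_trials))
      next
    }
    vals <- spectral_trials_mean(onset_epochs, idx, sp9, groups)
    emit(9, cond, names(vals), vals, length(idx))
  }

  # features 11 (averaged-trial) and 12 (single-trial mean), b1 vs b2
  for (ctx in c("b1", "b2")) {
    ep <- if (ctx == "b1") b1_epochs else b2_epochs
    n <- if (is.null(ep)) 0L else dim(ep$data)[1]
    for (id in intersect(c(11, 12), specs$id)) {
      sp <- specs[specs$id == id, ]
      if (n < min_trials) {
        emit_missing(id, ctx, n, sprintf("only %d trials (min %d)", n, min_trials))
        next
      }
      if (sp$estimation == "on_average") {
        erp <- average_erp(ep)
        seg <- epoch_segment(erp$data, erp$window_ms, erp$fs,
                             c(sp$window_lo_ms, sp$window_hi_ms))
        loc <- location_signals(seg, erp$channels, groups)
        vals <- apply(loc, 1, segment_band_power_uv2, fs = erp$fs,
                      band = c(sp$band_lo_hz, sp$band_hi_hz))
        emit(id, ctx, rownames(loc), vals, n)
      } else {
        vals <- spectral_trials_mean(ep, seq_len(n), sp, groups)
        emit(id, ctx, names(vals), vals, n)
      }
    }
  }
  do.call(rbind, rows)
}

# Mean over trials of per-trial band power at every location.
spectral_trials_mean <- function(epochs, idx, sp, groups) {
  band <- c(sp$band_lo_hz, sp$band_hi_hz)
  win <- c(sp$window_lo_ms, sp$window_hi_ms)
  acc <- NULL
  for (i in idx) {
    trial <- matrix(epochs$data[i, , ], nrow = dim(epochs$data)[2])
    seg <- epoch_segment(trial, epochs$window_ms, epochs$fs, win)
    loc <- location_signals(seg, epochs$channels, groups)
    v <- apply(loc, 1, segment_band_power_uv2, fs = epochs$fs, band = band)
    acc <- if (is.null(acc)) v else acc + v
  }
  acc / length(idx)
}

# Slice a channels x samples epoch matrix to a half-open ms window on the
# epoch's time axis.
epoch_segment <- function(data, window_ms, fs, seg_ms) {
  i0 <- ms_to_samples(seg_ms[1] - window_ms[1], fs) + 1L
  i1 <- ms_to_samples(seg_ms[2] - window_ms[1], fs)
  if (i0 < 1 || i1 > ncol(data)) stop("segment window outside the epoch")
  data[, i0:i1, drop = FALSE]
}
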