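#' Canonical table of the 12 features
#'
#' The twelve ERP/spectral features of the analysis: peak amplitude and
#' latency of the positivity (100-200 ms), negativity (200-280 ms),
#' frontoparietal positivity (280-400 ms) and late positivity (400-600 ms)
#' after stimulus onset (features 1-8); low gamma power 26-40 Hz in
#' [-200, -50] ms before onset (feature 9, computed without baseline
#' correction); peak amplitude of the reversal positivity in
#' [-300, -200] ms before the button press (feature 10); alpha power
#' 8-13 Hz (feature 11, Welch on the trial-averaged waveform) and gamma
#' power 26-60 Hz (feature 12, mean of single-trial Welch estimates) in
#' [-1000, 0] ms before the button press.
#'
#' @return Data frame with one row per feature: id, name, lock, window,
#'   polarity, kind, band, estimation mode and baseline handling.
#' @export
feature_specs <- function() {
  data.frame(
    id = 1:12,
    name = c("positivity amplitude", "positivity latency",
             "negativity amplitude", "negativity latency",
             "frontoparietal positivity amplitude",
             "frontoparietal positivity latency",
             "late positivity amplitude", "late positivity latency",
             "low gamma power before onset",
             "reversal positivity amplitude",
             "alpha power before button press",
             "gamma power before button press"),
    lock = c(rep("stimulus_on", 9), rep("button", 3)),
    window_lo_ms = c(100, 100, 200, 200, 280, 280, 400, 400, -200, -300, -1000, -1000),
    window_hi_ms = c(200, 200, 280, 280, 400, 400, 600, 600, -50, -200, 0, 0),
    polarity = c("positive", "positive", "negative", "negative", "positive",
                 "positive", "positive", "positive", NA, "positive", NA, NA),
    kind = c(rep(c("peak_amplitude", "peak_latency"), 4), "band_power",
             "peak_amplitude", "band_power", "band_power"),
    band_lo_hz = c(rep(NA, 8), 26, NA, 8, 26),
    band_hi_hz = c(rep(NA, 8), 40, NA, 13, 60),
    estimation = c(rep("on_average", 8), "single_trial_mean", "on_average",
                   "on_average", "single_trial_mean"),
    baseline = c(rep("standard", 8), "none", rep("standard", 3)),
    stringsAsFactors = FALSE)
}

#' Find a local peak in a windowed waveform
#'
#' Searches the feature window for the extremum of the requested polarity
#' among samples that are strict local extrema within a +/-`neighborhood_ms`
#' neighbourhood (clipped to the window). If no local extremum of that
#' polarity exists, the absolute windowed extremum is returned with
#' `is_local = FALSE`. Ties are broken by the earliest latency.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param window_ms Length-2 search window in ms (inclusive at both ends
#'   after ms -> sample rounding), on the epoch's time axis.
#' @param polarity `"positive"` (maximum) or `"negative"` (minimum);
#'   amplitudes are returned signed.
#' @param t_start_ms Time of the first sample of `x`, in ms.
#' @param neighborhood_ms Half-width of the local-extremum neighbourhood.
#' @return List with `amplitude_uv`, `latency_ms` and `is_local`.
#' @export
find_peak <- function(x, fs, window_ms, polarity = c("positive", "negative"),
                      t_start_ms = 0, neighborhood_ms = 20) {
  polarity <- match.arg(polarity)
  i0 <- ms_to_samples(window_ms[1] - t_start_ms, fs) + 1L
  i1 <- ms_to_samples(window_ms[2] - t_start_ms, fs) + 1L
  if (i0 < 1 || i1 > length(x))
    stop("feature window lies outside the epoch")
  if (i1 < i0) stop("empty feature window after ms -> sample conversion")
  idx <- i0:i1
  wf <- if (polarity == "positive") x else -x
  nb <- ms_to_samples(neighborhood_ms, fs)
  # strict local extremum within +/-nb samples of the *full* waveform (so a
  # monotone run ending at the window edge is not a local peak), vectorised
  # via shifted comparisons; -Inf beyond the data boundaries
  m <- length(wf)
  loc_full <- rep(TRUE, m)
  for (k in seq_len(min(nb, m - 1))) {
    lag <- c(rep(-Inf, k), wf[seq_len(m - k)])
    lead <- c(wf[(k + 1):m], rep(-Inf, k))
    loc_full <- loc_full & wf > lag & wf > lead
  }
  w <- wf[idx]
  is_loc <- loc_full[idx]
  pick <- if (any(is_loc)) which(is_loc)[which.max(w[which(is_loc)])] else
    which.max(w)
  samp <- idx[pick]
  list(amplitude_uv = x[samp],
       latency_ms = t_start_ms + samples_to_ms(samp - 1, fs),
       is_local = any(is_loc))
}

feature_row <- function(participant, group, feature, epoch, location, value,
                        n_trials, note = NA_character_) {
  data.frame(participant = participant, group = group, feature = feature,
             epoch = epoch, location = location, value = value,
             value_uv2 = NA_real_, n_trials = n_trials, note = note,
             stringsAsFactors = FALSE)
}

#' Compute the time-domain features for one participant
#'
#' Features 1-8 are measured on the condition-wise stimulus-onset-locked
#' ERP (both conditions); feature 10 on the button1- and button2-locked
#' ERPs of the bistable condition, each within [-300, -200] ms of its own
#' lock (latencies are negative). Group-location features are measured on
#' the group-averaged waveform. A context contributes values only if at
#' least `min_trials` trials underlie the ERP; otherwise a missing row with
#' a reason is emitted.
#'
#' @param erps Named list of `eeg_erp` objects: `c1`, `c2` (onset-locked)
#'   and `b1`, `b2` (button-locked, bistable condition).
#' @param participant,group Identifiers copied into the rows.
#' @param groups Channel groups, see [channel_groups()].
#' @param specs Feature table from [feature_specs()].
#' @param neighborhood_ms Local-peak neighbourhood, see [find_peak()].
#' @param min_trials Minimum trial count for a context to contribute.
#' @return Data frame of feature rows (participant, group, feature, epoch,
#'   location, value, n_trials, note).
#' @export
compute_time_features <- function(erps, participant, group,
                                  groups = channel_groups(),
                                  specs = feature_specs(),
                                  neighborhood_ms = 20, min_trials = 5) {
  specs <- specs[specs$kind %in% c("peak_amplitude", "peak_latency"), ]
  rows <- list()
  contexts <- list(c1 = "stimulus_on", c2 = "stimulus_on",
                   b1 = "button", b2 = "button")
  for (ctx in names(contexts)) {
    erp <- erps[[ctx]]
    sp <- specs[specs$lock == contexts[[ctx]], ]
    if (!nrow(sp)) next
    if (is.null(erp) || erp$n_trials < min_trials) {
      reason <- if (is.null(erp)) "no trials" else
        sprintf("only %d trials (min %d)", erp$n_trials, min_trials)
      for (k in seq_len(nrow(sp)))
        rows[[length(rows) + 1]] <- feature_row(
          participant, group, sp$id[k], ctx,
          analysis_locations(erp$channels %||% default_montage(), groups),
          NA_real_, erp$n_trials %||% 0L, reason)
      next
    }
    loc <- location_signals(erp$data, erp$channels, groups)
    for (k in seq_len(nrow(sp))) {
      win <- c(sp$window_lo_ms[k], sp$window_hi_ms[k])
      vals <- vapply(seq_len(nrow(loc)), function(l) {
        pk <- find_peak(loc[l, ], erp$fs, win, sp$polarity[k],
                        t_start_ms = erp$window_ms[1],
                        neighborhood_ms = neighborhood_ms)
        if (sp$kind[k] == "peak_amplitude") pk$amplitude_uv else pk$latency_ms
      }, numeric(1))
      rows[[length(rows) + 1]] <- feature_row(
        participant, group, sp$id[k], ctx, rownames(loc), vals, erp$n_trials)
    }
  }
  do.call(rbind, rows)
}
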