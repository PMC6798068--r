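# Synthetic EEG experiment generator.
#
# Background noise is synthesised in the frequency domain (white, or 1/f
# "pink" above 1 Hz with a flat floor below it), which makes the expected
# band power of the background analytic: band modulations scale their added
# burst to (gain - 1) times that expectation, so measured Welch band-power
# ratios converge to the configured gain.

# Fraction of total noise variance falling in [low, high] (one-sided),
# under the continuous spectral-shape approximation.
noise_band_fraction <- function(band, fs, model) {
  shape_integral <- function(a, b) {
    if (model == "white") return(b - a)
    # density proportional to 1/max(f, 1)
    flat <- max(0, min(b, 1) - min(a, 1))
    flat + log(max(b, 1) / max(a, 1))
  }
  shape_integral(band[1], band[2]) / shape_integral(0, fs / 2)
}

# Expected band power (uV^2) of the background in a band.
noise_band_power <- function(band, fs, sigma, model) {
  sigma^2 * noise_band_fraction(band, fs, model)
}

# One channel of background noise, exact length n, unit-variance expectation
# scaled to sigma.
gen_noise <- function(n, fs, sigma, model) {
  if (sigma == 0) return(numeric(n))
  if (model == "white") return(rnorm(n, 0, sigma))
  # synthesise at a 2-3-5-smooth length (fast FFT) and truncate
  nfft <- stats::nextn(n, c(2, 3, 5))
  k <- seq_len(floor((nfft - 1) / 2))
  f <- k * fs / nfft
  s2 <- 1 / pmax(f, 1)
  X <- complex(real = rnorm(length(k), 0, sqrt(s2 / 2)),
               imaginary = rnorm(length(k), 0, sqrt(s2 / 2)))
  spec <- complex(length.out = nfft)
  spec[k + 1] <- X
  spec[nfft - k + 1] <- Conj(X)
  if (nfft %% 2 == 0) {
    fn <- (nfft / 2) * fs / nfft
    spec[nfft / 2 + 1] <- rnorm(1, 0, sqrt(1 / pmax(fn, 1)))
  }
  x <- Re(fft(spec, inverse = TRUE)) / nfft
  # expected per-sample variance of the construction
  tot <- 2 * sum(s2) + if (nfft %% 2 == 0) 1 / pmax((nfft / 2) * fs / nfft, 1) else 0
  # per-sample variance of the construction is tot / nfft^2
  x[seq_len(n)] * sigma * nfft / sqrt(tot)
}

# Band-limited unit burst of length L samples with cosine on/off ramps,
# normalised so its mean square over the window equals `target_ms`.
gen_burst <- function(L, fs, band, ramp_ms, target_ms) {
  if (target_ms <= 0 || L < 8) return(numeric(L))
  k <- seq_len(floor((L - 1) / 2))
  f <- k * fs / L
  sel <- which(f >= band[1] & f <= band[2])
  if (!length(sel)) return(numeric(L))
  spec <- complex(length.out = L)
  X <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  spec[sel + 1] <- X
  spec[L - sel + 1] <- Conj(X)
  x <- Re(fft(spec, inverse = TRUE)) / L
  r <- min(ms_to_samples(ramp_ms, fs), floor(L / 2))
  env <- rep(1, L)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / (r + 1)))
    env[seq_len(r)] <- ramp
    env[L - r + seq_len(r)] <- rev(ramp)
  }
  x <- x * env
  ms <- mean(x^2)
  if (ms <= 0) return(numeric(L))
  x * sqrt(target_ms / ms)
}

scope_matches <- function(scope, value) scope == "both" || scope == value

# Exact stratified condition assignment for one block.
assign_conditions <- function(n, p_c1) {
  n1 <- round(n * p_c1)
  sample(c(rep("c1", n1), rep("c2", n - n1)))
}

#' Generate one synthetic participant
#'
#' Simulates the full session of a single participant: 10 training trials
#' followed by three test blocks of 100 trials (by default), each trial
#' consisting of a fixation cross (800-1300 ms), stimulus onset, an optional
#' first button press, an optional second (reversal) press on bistable
#' trials, and a fixed 5000 ms response slot followed by the inter-trial
#' gap. Background noise, injected ERP components and band-power
#' modulations are realised per the configuration; unambiguous (c2) trials
#' never receive a second press.
#'
#' @param config A [sim_config()].
#' @param participant_id Identifier string.
#' @param group `"FD"`, `"FI"` or `"FN"`.
#' @param seed Integer seed for this participant (defaults to a seed derived
#'   from `config$seed`).
#' @return List with elements `recording` ([eeg_recording]), `trial_table`
#'   (data frame, one row per trial, 0-based event samples, `NA` for absent
#'   presses) and `ground_truth` (planted parameters and realised trial
#'   schedule).
#' @export
generate_participant <- function(config, participant_id = "P01",
                                 group = c("FD", "FI", "FN"), seed = NULL) {
  group <- match.arg(group)
  validate_sim_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, 1L)
  fs <- config$fs
  with_seed(seed, {
    n_train <- config$n_training_trials
    blocks <- c(if (n_train > 0) list(data.frame(
      phase = "training", block = 0L,
      condition = assign_conditions(n_train, 0.5),
      stringsAsFactors = FALSE)) else NULL,
      lapply(seq_len(config$n_blocks), function(b) data.frame(
        phase = "test", block = b,
        condition = assign_conditions(config$trials_per_block, config$p_c1),
        stringsAsFactors = FALSE)))
    tt <- do.call(rbind, blocks)
    n_trials <- nrow(tt)
    tt$trial <- seq_len(n_trials) - 1L
    tt$stimulus_id <- ifelse(tt$phase == "training",
                             ifelse(tt$condition == "c1", 101L, 102L),
                             NA_integer_)
    for (cond in c("c1", "c2")) {
      i <- which(tt$phase == "test" & tt$condition == cond)
      pool <- if (cond == "c1") 1:50 else 51:100
      if (length(i))
        tt$stimulus_id[i] <- sample(pool, length(i), replace = length(i) > length(pool))
    }

    p_rev <- switch(group, FD = config$p_reversal_fd, FI = config$p_reversal_fi,
                    FN = config$p_reversal_fn)
    pre_roll <- ms_to_samples(1500, fs)
    post_roll <- ms_to_samples(6000, fs)
    gap <- ms_to_samples(config$gap_ms, fs)
    timeout <- ms_to_samples(config$timeout_ms, fs)

    fix_ms <- runif(n_trials, config$fixation_ms_range[1], config$fixation_ms_range[2])
    press1 <- runif(n_trials) < config$p_press1
    rt1 <- pmin(pmax(rlnorm(n_trials, config$rt1_ms["meanlog"], config$rt1_ms["sdlog"]),
                     150), config$timeout_ms - 300)
    rev_draw <- runif(n_trials) < p_rev
    rt2 <- pmax(rlnorm(n_trials, config$rt2_ms["meanlog"], config$rt2_ms["sdlog"]), 100)

    cur <- pre_roll
    tt$fixation_on <- tt$stimulus_on <- tt$trial_end <- NA_integer_
    tt$button1 <- tt$button2 <- NA_integer_
    for (i in seq_len(n_trials)) {
      tt$fixation_on[i] <- cur
      stim <- cur + ms_to_samples(fix_ms[i], fs)
      tt$stimulus_on[i] <- stim
      end <- stim + timeout
      if (press1[i]) {
        b1 <- stim + ms_to_samples(rt1[i], fs)
        tt$button1[i] <- b1
        if (tt$condition[i] == "c1" && rev_draw[i]) {
          b2 <- b1 + ms_to_samples(min(rt2[i], config$timeout_ms - rt1[i] - 100), fs)
          if (b2 > b1 && b2 < stim + timeout) {
            tt$button2[i] <- b2
            end <- b2
          }
        }
      }
      tt$trial_end[i] <- end
      cur <- stim + timeout + gap
    }
    tt$reversal <- !is.na(tt$button2)
    n_samples <- cur - gap + post_roll

    nch <- length(config$montage)
    data <- matrix(0, nch, n_samples)
    for (ch in seq_len(nch))
      data[ch, ] <- gen_noise(n_samples, fs, config$noise_sigma_uv,
                              config$noise_model)

    # inject ERP components (additive on the background)
    for (comp in config$erp_components) {
      if (!scope_matches(comp$group_scope, group)) next
      idx <- match(comp$channels, config$montage)
      half <- ms_to_samples(5 * comp$width_ms, fs)
      for (i in seq_len(n_trials)) {
        if (!scope_matches(comp$condition_scope, tt$condition[i])) next
        lockv <- switch(comp$lock, stimulus_on = tt$stimulus_on[i],
                        button1 = tt$button1[i], button2 = tt$button2[i])
        if (is.na(lockv)) next
        centre <- lockv + ms_to_samples(comp$latency_ms, fs)
        s0 <- max(0L, centre - half); s1 <- min(n_samples - 1L, centre + half)
        if (s1 < s0) next
        t_rel <- (s0:s1 - centre) * 1000 / fs
        bump <- comp$amplitude_uv * exp(-t_rel^2 / (2 * comp$width_ms^2))
        data[idx, (s0 + 1):(s1 + 1)] <-
          data[idx, (s0 + 1):(s1 + 1), drop = FALSE] +
          outer(comp$gains, bump)
      }
    }

    # band-power modulations (independent band-limited bursts per channel)
    for (bm in config$band_modulations) {
      if (!scope_matches(bm$group_scope, group)) next
      bg <- noise_band_power(bm$band_hz, fs, config$noise_sigma_uv,
                             config$noise_model)
      idx <- match(bm$channels, config$montage)
      for (i in seq_len(n_trials)) {
        if (!scope_matches(bm$condition_scope, tt$condition[i])) next
        lockv <- switch(bm$lock, stimulus_on = tt$stimulus_on[i],
                        button1 = tt$button1[i], button2 = tt$button2[i])
        if (is.na(lockv)) next
        s0 <- lockv + ms_to_samples(bm$window_ms[1], fs)
        s1 <- lockv + ms_to_samples(bm$window_ms[2], fs)
        if (s0 < 0 || s1 > n_samples) next
        L <- s1 - s0
        for (j in seq_along(idx)) {
          v <- (bm$power_gain - 1) * bm$gains[j]^2 * bg
          burst <- gen_burst(L, fs, bm$band_hz, bm$ramp_ms, v)
          if (length(burst))
            data[idx[j], (s0 + 1):s1] <- data[idx[j], (s0 + 1):s1] + burst
        }
      }
    }

    events <- trial_table_to_events(tt)
    rec <- eeg_recording(data, fs, config$montage, events,
                         participant_id = participant_id, group = group)
    gt <- list(participant_id = participant_id, group = group, seed = seed,
               trial_table = tt,
               erp_components = config$erp_components,
               band_modulations = config$band_modulations)
    list(recording = rec, trial_table = tt, ground_truth = gt)
  })
}

# Expand a trial table into the long event stream.
trial_table_to_events <- function(tt) {
  rows <- lapply(seq_len(nrow(tt)), function(i) {
    r <- tt[i, ]
    samp <- c(r$fixation_on, r$stimulus_on, r$button1, r$button2, r$trial_end)
    typ <- c("fixation_on", "stimulus_on", "button1", "button2", "trial_end")
    keep <- !is.na(samp)
    data.frame(sample = as.integer(samp[keep]), type = typ[keep],
               trial = r$trial, condition = r$condition,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev[order(ev$sample), , drop = FALSE]
}

#' Generate a full synthetic cohort
#'
#' Participant-level seeds are derived deterministically from `config$seed`,
#' so two cohorts from the same configuration are identical. Groups are
#' assigned in the order FD, FI, FN.
#'
#' @param config A [sim_config()].
#' @return List of participant bundles as returned by
#'   [generate_participant()], with names `P01`, `P02`, ...
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  groups <- c(rep("FD", config$n_fd), rep("FI", config$n_fi),
              rep("FN", config$n_fn))
  if (!length(groups)) stop_config("n_fd", "cohort must have at least one participant")
  ids <- sprintf("P%02d", seq_along(groups))
  out <- vector("list", length(groups))
  for (i in seq_along(groups))
    out[[i]] <- generate_participant(config, ids[i], groups[i],
                                     seed = derive_seed(config$seed, i))
  names(out) <- ids
  out
}

# Seeds generate_cohort would use, without generating data (used by the
# pipeline to stream participants without holding the cohort in memory).
cohort_plan <- function(config) {
  groups <- c(rep("FD", config$n_fd), rep("FI", config$n_fi),
              rep("FN", config$n_fn))
  data.frame(participant = sprintf("P%02d", seq_along(groups)),
             group = groups,
             seed = vapply(seq_along(groups), function(i)
               derive_seed(config$seed, i), integer(1)),
             stringsAsFactors = FALSE)
}

#' Generate Hidden Figures Test item responses
#'
#' Exchangeable ("parallel") item model: each participant's per-item success
#' probability is drawn from a Beta distribution centred on their ability
#' with dispersion set by the target inter-item correlation `rho`
#' (`rho = 1/(a+b+1)` for a Beta(a, b) mixing distribution), then items are
#' conditionally independent Bernoulli draws. With `p_blank = 0` the
#' observed inter-item correlation equals `rho`, so Cronbach's alpha of a
#' large generated matrix approaches the Spearman-Brown value
#' `k*rho / (1 + (k-1)*rho)`. An optional item difficulty vector shifts
#' per-item log-odds (breaking exchangeability).
#'
#' @param abilities Numeric vector in `[0, 1]`, one entry per participant.
#' @param n_items Number of items; must be even (the instrument has two
#'   equal parts; default 32).
#' @param rho Target inter-item correlation in `[0, 1)`.
#' @param p_blank Probability an item is left blank.
#' @param item_difficulty Length-`n_items` log-odds shifts (default 0).
#' @param seed Integer seed.
#' @return Character matrix participants x items with entries `"correct"`,
#'   `"incorrect"`, `"blank"`.
#' @export
generate_hft_responses <- function(abilities, n_items = 32, rho = 0,
                                   p_blank = 0.1, item_difficulty = NULL,
                                   seed = 1L) {
  if (n_items %% 2 != 0)
    stop("n_items must be even: the instrument has two equal parts")
  if (any(abilities < 0 | abilities > 1))
    stop("abilities must lie in [0, 1]")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (is.null(item_difficulty)) item_difficulty <- rep(0, n_items)
  if (length(item_difficulty) != n_items)
    stop("item_difficulty must have length n_items")
  with_seed(seed, {
    n <- length(abilities)
    pi_i <- if (rho == 0) abilities else {
      s <- (1 - rho) / rho
      vapply(abilities, function(a) {
        if (a <= 0) 0 else if (a >= 1) 1 else rbeta(1, a * s, (1 - a) * s)
      }, numeric(1))
    }
    out <- matrix("incorrect", n, n_items)
    for (i in seq_len(n)) {
      p <- if (all(item_difficulty == 0)) rep(pi_i[i], n_items) else
        stats::plogis(stats::qlogis(pmin(pmax(pi_i[i], 1e-12), 1 - 1e-12)) +
                        item_difficulty)
      correct <- runif(n_items) < p
      blank <- runif(n_items) < p_blank
      out[i, ] <- ifelse(blank, "blank", ifelse(correct, "correct", "incorrect"))
    }
    rownames(out) <- names(abilities) %||% sprintf("P%02d", seq_len(n))
    colnames(out) <- sprintf("item%02d", seq_len(n_items))
    out
  })
}
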