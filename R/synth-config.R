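#' Describe an injected ERP component
#'
#' A component is a Gaussian-windowed bump (latency = centre, width = SD)
#' added to the background noise on a subset of channels, time-locked to one
#' of the three trial events. Scopes restrict the injection to a stimulus
#' condition and/or participant group, which is how condition and group
#' ground-truth effects are planted.
#'
#' @param lock One of `"stimulus_on"`, `"button1"`, `"button2"`.
#' @param latency_ms Centre of the bump relative to the lock event (may be
#'   negative, e.g. a reversal positivity peaking before the button press).
#' @param width_ms Gaussian SD in ms; must be positive.
#' @param amplitude_uv Signed peak amplitude in microvolts.
#' @param channels Channel labels the component projects to.
#' @param gains Optional per-channel gain multipliers (default 1).
#' @param condition_scope `"c1"`, `"c2"` or `"both"`.
#' @param group_scope `"FD"`, `"FI"` or `"both"` (`"both"` includes FN).
#' @return An object of class `erp_component`.
#' @export
erp_component <- function(lock = c("stimulus_on", "button1", "button2"),
                          latency_ms, width_ms, amplitude_uv, channels,
                          gains = NULL,
                          condition_scope = c("both", "c1", "c2"),
                          group_scope = c("both", "FD", "FI")) {
  lock <- match.arg(lock)
  condition_scope <- match.arg(condition_scope)
  group_scope <- match.arg(group_scope)
  if (!is.numeric(width_ms) || width_ms <= 0)
    stop_config("width_ms", "must be > 0")
  if (is.null(gains)) gains <- rep(1, length(channels))
  if (length(gains) != length(channels))
    stop_config("gains", "length must match channels")
  structure(list(lock = lock, latency_ms = latency_ms, width_ms = width_ms,
                 amplitude_uv = amplitude_uv, channels = channels,
                 gains = gains, condition_scope = condition_scope,
                 group_scope = group_scope),
            class = "erp_component")
}

#' Describe a band-limited power modulation
#'
#' Multiplies the expected band power of the background noise by
#' `power_gain` inside a time window around a lock event, implemented by
#' adding an independent band-limited noise burst (cosine on/off ramps)
#' whose variance is `(power_gain - 1)` times the background's expected
#' band power. This makes Welch band-power ratios converge to `power_gain`.
#'
#' @param band_hz Length-2 numeric, 0 < low < high < fs/2.
#' @param lock,window_ms Lock event and window (ms relative to the lock)
#'   over which the modulation is active.
#' @param power_gain Multiplicative band-power factor, > 0.
#' @inheritParams erp_component
#' @param ramp_ms Cosine ramp length at each edge of the window.
#' @return An object of class `band_modulation`.
#' @export
band_modulation <- function(band_hz, lock = c("stimulus_on", "button1", "button2"),
                            window_ms, power_gain, channels, gains = NULL,
                            condition_scope = c("both", "c1", "c2"),
                            group_scope = c("both", "FD", "FI"),
                            ramp_ms = 100) {
  lock <- match.arg(lock)
  condition_scope <- match.arg(condition_scope)
  group_scope <- match.arg(group_scope)
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop_config("band_hz", "need 0 < low < high")
  if (!is.numeric(power_gain) || power_gain <= 0)
    stop_config("power_gain", "must be > 0")
  if (is.null(gains)) gains <- rep(1, length(channels))
  structure(list(band_hz = band_hz, lock = lock, window_ms = window_ms,
                 power_gain = power_gain, channels = channels, gains = gains,
                 condition_scope = condition_scope, group_scope = group_scope,
                 ramp_ms = ramp_ms),
            class = "band_modulation")
}

#' Default planted effects
#'
#' The default ground-truth effect set emulates the qualitative findings of
#' the bistable-perception ERP literature: four post-onset components
#' (positivity 150 ms, negativity 240 ms, frontoparietal positivity 340 ms,
#' late positivity 500 ms), a reversal positivity peaking 250 ms before the
#' second button press, an alpha-power elevation before the first button
#' press relative to the second, a gamma elevation before the reversal at
#' Fz, and Field-Dependent-specific gamma effects (pre-reversal gamma at
#' T8/CP6/TP10, pre-onset low gamma at TP10) plus a stronger frontoparietal
#' positivity for FD participants.
#'
#' @return List with elements `erp_components` and `band_modulations`.
#' @export
default_effects <- function() {
  posterior <- c("TP9", "CP5", "CP1", "P3", "O1", "TP10", "CP6", "CP2", "P4",
                 "O2", "CPz", "Pz")
  frontal <- c("Fp1", "F7", "FC1", "Fp2", "F8", "FC2", "Fz")
  all_ch <- default_montage()
  list(
    erp_components = list(
      erp_component("stimulus_on", 150, 12, 2.5, posterior),
      erp_component("stimulus_on", 150, 12, 0.6, posterior,
                    condition_scope = "c1"),
      erp_component("stimulus_on", 240, 15, -2.5, all_ch),
      erp_component("stimulus_on", 240, 15, -0.5, posterior,
                    condition_scope = "c2"),
      erp_component("stimulus_on", 340, 20, 2.0, c(frontal, "Cz", "CPz", "Pz")),
      erp_component("stimulus_on", 340, 20, 0.8, c("F7", "T7", "CP5", "FC1"),
                    group_scope = "FD"),
      erp_component("stimulus_on", 500, 30, 1.5, posterior),
      erp_component("button2", -250, 15, 2.0, posterior),
      erp_component("button2", -250, 15, 0.8, "P4", group_scope = "FD")
    ),
    band_modulations = list(
      band_modulation(c(8, 13), "button1", c(-1000, 0), 1.8, all_ch),
      band_modulation(c(26, 60), "button2", c(-1000, 0), 1.6, "Fz"),
      band_modulation(c(26, 60), "button2", c(-1000, 0), 2.0,
                      c("T8", "CP6", "TP10"), group_scope = "FD"),
      band_modulation(c(26, 40), "stimulus_on", c(-400, 0), 1.5, "TP10",
                      group_scope = "FD", ramp_ms = 50)
    )
  )
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic experiment. Defaults reproduce
#' the study design: 500 Hz sampling, the 24-electrode montage, 10 training
#' trials followed by three blocks of 100 test trials with an exact shuffled
#' 50/50 split between the bistable (c1) and unambiguous (c2) condition,
#' fixation 800-1300 ms, a 5000 ms response timeout, and the default planted
#' effects of [default_effects()].
#'
#' @param n_fd,n_fi,n_fn Participant counts per group.
#' @param fs Sampling rate in Hz.
#' @param montage Ordered channel labels.
#' @param n_training_trials,n_blocks,trials_per_block Trial schedule.
#' @param p_c1 Fraction of bistable trials per test block (exact stratified
#'   split, not i.i.d. sampling).
#' @param fixation_ms_range Uniform range of the fixation-cross duration.
#' @param timeout_ms Response timeout after stimulus onset.
#' @param gap_ms Inter-trial gap (background plus blink reminder).
#' @param rt1_ms,rt2_ms Lognormal parameters `(meanlog, sdlog)` for the
#'   first-press latency after onset and the press-to-press reversal time.
#' @param p_press1 Probability a trial gets a first button press.
#' @param p_reversal_fd,p_reversal_fi,p_reversal_fn Probability a c1 trial
#'   with a first press also gets a second (reversal) press, per group.
#' @param noise_sigma_uv Background noise SD in microvolts.
#' @param noise_model `"pink"` (1/f above 1 Hz, the default: raw EEG is not
#'   white) or `"white"` for analytically clean tests.
#' @param erp_components,band_modulations Planted effects; see
#'   [erp_component()] and [band_modulation()].
#' @param hft_ability Named list of group ability means in `[0, 1]` plus
#'   `sd` (within-group spread) used by [generate_hft_responses()].
#' @param seed Integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_fd = 14, n_fi = 7, n_fn = 10,
                       fs = 500,
                       montage = default_montage(),
                       n_training_trials = 10,
                       n_blocks = 3,
                       trials_per_block = 100,
                       p_c1 = 0.5,
                       fixation_ms_range = c(800, 1300),
                       timeout_ms = 5000,
                       gap_ms = 1500,
                       rt1_ms = c(meanlog = log(800), sdlog = 0.3),
                       rt2_ms = c(meanlog = log(1400), sdlog = 0.35),
                       p_press1 = 0.95,
                       p_reversal_fd = 0.70,
                       p_reversal_fi = 0.85,
                       p_reversal_fn = 0.78,
                       noise_sigma_uv = 10,
                       noise_model = c("pink", "white"),
                       erp_components = default_effects()$erp_components,
                       band_modulations = default_effects()$band_modulations,
                       hft_ability = list(FD = 0.2, FN = 0.5, FI = 0.8, sd = 0.05),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(n_fd = n_fd, n_fi = n_fi, n_fn = n_fn, fs = fs,
              montage = montage, n_training_trials = n_training_trials,
              n_blocks = n_blocks, trials_per_block = trials_per_block,
              p_c1 = p_c1, fixation_ms_range = fixation_ms_range,
              timeout_ms = timeout_ms, gap_ms = gap_ms,
              rt1_ms = rt1_ms, rt2_ms = rt2_ms, p_press1 = p_press1,
              p_reversal_fd = p_reversal_fd, p_reversal_fi = p_reversal_fi,
              p_reversal_fn = p_reversal_fn,
              noise_sigma_uv = noise_sigma_uv, noise_model = noise_model,
              erp_components = erp_components,
              band_modulations = band_modulations,
              hft_ability = hft_ability,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(field, ok, msg) if (!isTRUE(ok)) stop_config(field, msg)
  chk("n_fd", cfg$n_fd >= 0 && cfg$n_fi >= 0 && cfg$n_fn >= 0,
      "participant counts must be >= 0")
  chk("fs", is.numeric(cfg$fs) && cfg$fs > 0, "must be > 0")
  chk("p_c1", cfg$p_c1 >= 0 && cfg$p_c1 <= 1, "must be in [0, 1]")
  chk("fixation_ms_range",
      length(cfg$fixation_ms_range) == 2 &&
        cfg$fixation_ms_range[1] > 0 &&
        cfg$fixation_ms_range[2] >= cfg$fixation_ms_range[1] &&
        cfg$fixation_ms_range[2] < cfg$timeout_ms,
      "must lie within (0, timeout_ms)")
  chk("p_press1", cfg$p_press1 >= 0 && cfg$p_press1 <= 1, "must be in [0, 1]")
  for (f in c("p_reversal_fd", "p_reversal_fi", "p_reversal_fn"))
    chk(f, cfg[[f]] >= 0 && cfg[[f]] <= 1, "must be in [0, 1]")
  chk("noise_sigma_uv", cfg$noise_sigma_uv >= 0, "must be >= 0")
  chk("montage", length(cfg$montage) >= 1 && !anyDuplicated(cfg$montage),
      "must be non-empty without duplicates")
  for (comp in cfg$erp_components) {
    chk("erp_components", inherits(comp, "erp_component"),
        "entries must be erp_component objects")
    chk("erp_components", all(comp$channels %in% cfg$montage),
        "component channels must be a subset of the montage")
    chk("erp_components",
        comp$latency_ms >= -1000 && comp$latency_ms <= 5000,
        "component latency must fall inside the epoch window")
  }
  for (bm in cfg$band_modulations) {
    chk("band_modulations", inherits(bm, "band_modulation"),
        "entries must be band_modulation objects")
    chk("band_modulations", all(bm$channels %in% cfg$montage),
        "modulation channels must be a subset of the montage")
    chk("band_modulations", bm$band_hz[2] < cfg$fs / 2,
        "band must lie below fs/2")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic bistable-perception experiment configuration\n")
  cat(sprintf("  participants: %d FD, %d FI, %d FN\n", x$n_fd, x$n_fi, x$n_fn))
  cat(sprintf("  fs %g Hz, %d channels; %d training + %d x %d test trials\n",
              x$fs, length(x$montage), x$n_training_trials, x$n_blocks,
              x$trials_per_block))
  cat(sprintf("  noise: %s, sigma %g uV; %d ERP components, %d band modulations\n",
              x$noise_model, x$noise_sigma_uv, length(x$erp_components),
              length(x$band_modulations)))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
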