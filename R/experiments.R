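# Simulation experiments that validate the pipeline against its own
# ground truth: parameter recovery, null error control, and power for a
# planted group effect. These are the package's calibration studies; the
# methods vignette documents the chosen problem sizes.

#' ERP parameter-recovery experiment
#'
#' Repeatedly simulates a single-channel session with one injected
#' component (amplitude 2.5 uV, SD width 10 ms — a typical early visual
#' positivity — at 150 ms on Pz) in 1 uV pink noise, runs the full
#' preprocessing chain (2-65 Hz FIR, epoching, prestimulus baseline,
#' trial averaging, local-peak search in the 100-200 ms window) and
#' records the recovered amplitude and latency.
#'
#' @param n_runs Number of independently seeded runs.
#' @param seed Master seed.
#' @param amplitude_uv,latency_ms,width_ms Injected component parameters.
#' @param noise_sigma_uv Background (pink) noise SD.
#' @param n_trials Trials per run.
#' @return Data frame with one row per run: recovered `amplitude_uv` and
#'   `latency_ms`.
#' @export
erp_recovery_experiment <- function(n_runs = 100, seed = 1L,
                                    amplitude_uv = 2.5, latency_ms = 150,
                                    width_ms = 10, noise_sigma_uv = 1,
                                    n_trials = 150) {
  out <- data.frame(run = seq_len(n_runs), amplitude_uv = NA_real_,
                    latency_ms = NA_real_)
  for (r in seq_len(n_runs)) {
    cfg <- sim_config(
      n_fd = 1, n_fi = 0, n_fn = 0, montage = c("Cz", "Pz"),
      n_blocks = 1, trials_per_block = n_trials, n_training_trials = 0,
      p_c1 = 1, noise_sigma_uv = noise_sigma_uv,
      erp_components = list(erp_component("stimulus_on", latency_ms,
                                          width_ms, amplitude_uv, "Pz")),
      band_modulations = list(), seed = derive_seed(seed, r))
    b <- generate_participant(cfg, "P01", "FD", seed = derive_seed(seed, r))
    filt <- filter_recording(b$recording)
    ep <- baseline_correct(extract_epochs(filt, "stimulus_on", c(-1000, 300)))
    erp <- average_erp(ep, "c1")
    pk <- find_peak(erp$data[2, ], erp$fs, c(100, 200), "positive",
                    t_start_ms = -1000)
    out$amplitude_uv[r] <- pk$amplitude_uv
    out$latency_ms[r] <- pk$latency_ms
  }
  out
}

#' Null-cohort familywise error experiment
#'
#' Simulates cohorts in which the two stimulus conditions are generated
#' identically (all planted components apply to both conditions; no band
#' modulations), runs the condition-comparison family for the stimulus-
#' onset features at all 30 locations with per-feature Holm correction,
#' and records, per replicate and feature, whether any location was
#' rejected. Under the null the per-family rejection probability is at
#' most `alpha`.
#'
#' @param n_reps Number of simulated cohorts.
#' @param seed Master seed.
#' @param n_participants Cohort size.
#' @param trials_per_block Trials per (single) block, split 50/50.
#' @param feature_ids Onset features to include (subset of 1:9).
#' @param alpha Familywise level.
#' @return Logical matrix `n_reps` x features: family had >= 1 rejection.
#' @export
null_fwer_experiment <- function(n_reps = 60, seed = 2L, n_participants = 5,
                                 trials_per_block = 10, feature_ids = 1:9,
                                 alpha = 0.05) {
  shared <- list(
    erp_component("stimulus_on", 150, 12, 2.5,
                  c("TP9", "CP5", "CP1", "P3", "O1", "TP10", "CP6", "CP2",
                    "P4", "O2", "CPz", "Pz")),
    erp_component("stimulus_on", 240, 15, -2.5, default_montage()),
    erp_component("stimulus_on", 340, 20, 2.0, c("Fz", "Cz", "CPz", "Pz")))
  res <- matrix(FALSE, n_reps, length(feature_ids),
                dimnames = list(NULL, paste0("f", feature_ids)))
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_fd = n_participants, n_fi = 0, n_fn = 0,
                      n_blocks = 1, trials_per_block = trials_per_block,
                      n_training_trials = 0, erp_components = shared,
                      band_modulations = list(),
                      seed = derive_seed(seed, 7919L + r))
    plan <- cohort_plan(cfg)
    feats <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      b <- generate_participant(cfg, plan$participant[i], plan$group[i],
                                seed = plan$seed[i])
      feats[[i]] <- participant_features(b$recording, b$trial_table,
                                         feature_ids = feature_ids,
                                         window_ms = c(-1000, 700),
                                         min_trials = trials_per_block %/% 2)
    }
    cmp <- run_comparisons(do.call(rbind, feats), alpha = alpha,
                           families = "condition")
    rej <- tapply(cmp$reject, cmp$feature, any)
    res[r, paste0("f", names(rej))] <- as.logical(rej)
  }
  res
}

#' Power experiment for the planted group gamma effect
#'
#' Simulates cohorts with the default Field-Dependent pre-reversal gamma
#' elevation (power gain 2 at T8, CP6 and TP10), computes the pre-button
#' gamma feature and tests FD vs FI at every location with per-feature
#' Holm correction, recording per replicate whether each planted location
#' was detected.
#'
#' @param n_reps Number of simulated cohorts.
#' @param seed Master seed.
#' @param n_fd,n_fi Group sizes.
#' @param trials_per_block Trials per (single) block.
#' @param alpha Familywise level.
#' @return Logical matrix `n_reps` x 3 (detection of T8, CP6, TP10).
#' @export
planted_gamma_power_experiment <- function(n_reps = 8, seed = 3L, n_fd = 7,
                                           n_fi = 5, trials_per_block = 24,
                                           alpha = 0.05) {
  planted <- c("T8", "CP6", "TP10")
  res <- matrix(FALSE, n_reps, 3, dimnames = list(NULL, planted))
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(n_fd = n_fd, n_fi = n_fi, n_fn = 0, n_blocks = 1,
                      trials_per_block = trials_per_block,
                      n_training_trials = 0,
                      seed = derive_seed(seed, 104729L + r))
    plan <- cohort_plan(cfg)
    feats <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      b <- generate_participant(cfg, plan$participant[i], plan$group[i],
                                seed = plan$seed[i])
      feats[[i]] <- participant_features(b$recording, b$trial_table,
                                         feature_ids = 12,
                                         window_ms = c(-1000, 100),
                                         min_trials = 4)
    }
    cmp <- run_comparisons(do.call(rbind, feats), alpha = alpha,
                           families = "group")
    hit <- cmp$location[cmp$feature == 12 & cmp$reject]
    res[r, ] <- planted %in% hit
  }
  res
}
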