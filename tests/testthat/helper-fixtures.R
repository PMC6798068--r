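# Shared small fixtures, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# A small noiseless config with a single channel: full default trial
# schedule, instant to simulate.
schedule_only_config <- function(seed = 1L) {
  sim_config(n_fd = 1, n_fi = 0, n_fn = 0, montage = "Cz",
             noise_sigma_uv = 0, erp_components = list(),
             band_modulations = list(), seed = seed)
}

# A small cohort config with planted effects, cheap enough for unit tests.
small_cfg <- function(seed = 7L, ...) {
  sim_config(n_fd = 2, n_fi = 2, n_fn = 0, n_blocks = 1,
             trials_per_block = 20, n_training_trials = 0, seed = seed, ...)
}

small_bundle <- function() {
  memo("small_bundle",
       generate_participant(small_cfg(), "P01", "FD", seed = 123L))
}

# Feature table for the small bundle (all 12 features, all 30 locations).
small_features <- function() {
  memo("small_features", {
    b <- small_bundle()
    participant_features(b$recording, b$trial_table, min_trials = 4)
  })
}

# Build an epoch set directly from a trials x channels x samples array with
# zero baselines (for constructed-waveform tests).
make_epochs <- function(arr, lock = "button2", window_ms = c(-1000, 5000),
                        fs = 500, condition = rep("c1", dim(arr)[1]),
                        channels = sprintf("ch%d", seq_len(dim(arr)[2]))) {
  new_epochs(arr, lock, window_ms, fs, trial = seq_len(dim(arr)[1]) - 1L,
             condition = condition, channels = channels,
             baseline_applied = TRUE)
}

# Random long feature table: n participants (half FD, half FI) x the 30
# locations for one feature/epoch context.
fake_feature_rows <- function(n, feature, epoch, sd = 1, mean = 0,
                              groups = NULL, seed = 1) {
  set.seed(seed)
  locs <- analysis_locations()
  if (is.null(groups)) groups <- rep(c("FD", "FI"), length.out = n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant = sprintf("P%02d", i), group = groups[i],
               feature = feature, epoch = epoch, location = locs,
               value = rnorm(length(locs), mean, sd),
               value_uv2 = NA_real_, n_trials = 20L, note = NA_character_,
               stringsAsFactors = FALSE)
  }))
}
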