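test_that("a default session presents 310 stimuli with exact per-block condition balance", {
  b <- generate_participant(schedule_only_config(), "P01", "FD", seed = 42L)
  ev <- b$recording$events
  expect_equal(sum(ev$type == "stimulus_on"), 310)
  tt <- b$trial_table
  test <- tt[tt$phase == "test", ]
  expect_equal(nrow(test), 300)
  counts <- tapply(test$condition == "c1", test$block, sum)
  expect_true(all(counts == 50))
  expect_equal(sum(tt$phase == "training"), 10)
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- generate_participant(cfg, "P01", "FI", seed = 9L)
  b <- generate_participant(cfg, "P01", "FI", seed = 9L)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$trial_table, b$trial_table)
  expect_identical(a$ground_truth$seed, b$ground_truth$seed)
})

test_that("every trial obeys the event grammar", {
  for (seed in c(3L, 17L)) {
    b <- generate_participant(small_cfg(seed), "P01",
                              if (seed == 3L) "FD" else "FI", seed = seed)
    tt <- b$trial_table
    expect_true(all(tt$fixation_on < tt$stimulus_on))
    has1 <- !is.na(tt$button1); has2 <- !is.na(tt$button2)
    expect_true(all(tt$stimulus_on[has1] <= tt$button1[has1]))
    expect_true(all(has1[has2]))                   # button2 implies button1
    expect_true(all(tt$button1[has2] < tt$button2[has2]))
    expect_true(all(tt$button2[has2] <= tt$trial_end[has2]))
    expect_true(all(tt$condition[has2] == "c1"))   # never in c2
    ends <- tt$trial_end
    expect_true(all(diff(tt$stimulus_on) > 0))
  }
})

test_that("noiseless injection reproduces the analytic component waveform", {
  cfg <- sim_config(n_fd = 1, n_fi = 0, n_fn = 0, montage = c("Cz", "Pz"),
                    n_blocks = 1, trials_per_block = 4, n_training_trials = 0,
                    p_c1 = 1, noise_sigma_uv = 0,
                    erp_components = list(
                      erp_component("stimulus_on", 150, 12, 4, "Pz")),
                    band_modulations = list(), seed = 5L)
  b <- generate_participant(cfg, "P01", "FD", seed = 5L)
  tt <- b$trial_table
  n <- ncol(b$recording$data)
  expected <- numeric(n)
  for (i in seq_len(nrow(tt))) {
    centre <- tt$stimulus_on[i] + round(150 * 500 / 1000)
    t_rel <- (seq_len(n) - 1 - centre) * 1000 / 500
    expected <- expected + 4 * exp(-t_rel^2 / (2 * 12^2)) *
      (abs(t_rel) <= 5 * 12)
  }
  expect_lt(max(abs(b$recording$data["Pz" == cfg$montage, ] - expected)), 1e-9)
  expect_equal(max(abs(b$recording$data[1, ])), 0)  # untouched channel
})

test_that("a planted band modulation scales measured band power by its gain", {
  # gain 2 on gamma for c1 trials only; c2 trials are the unmodulated baseline
  cfg <- sim_config(n_fd = 1, n_fi = 0, n_fn = 0, montage = "Cz",
                    n_blocks = 1, trials_per_block = 100,
                    n_training_trials = 0, noise_sigma_uv = 5,
                    noise_model = "white", erp_components = list(),
                    band_modulations = list(
                      band_modulation(c(26, 60), "stimulus_on", c(0, 1000), 2,
                                      "Cz", condition_scope = "c1")),
                    seed = 8L)
  b <- generate_participant(cfg, "P01", "FD", seed = 8L)
  tt <- b$trial_table
  pow <- function(rows) {
    vapply(rows, function(i) {
      s0 <- tt$stimulus_on[i]
      seg <- b$recording$data[1, (s0 + 1):(s0 + 500)]
      band_power(welch_psd(seg, 500), c(26, 60))$power_uv2
    }, numeric(1))
  }
  ratio <- mean(pow(which(tt$condition == "c1"))) /
    mean(pow(which(tt$condition == "c2")))
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("cohorts have the configured group sizes and reproducible seeds", {
  cfg <- sim_config(n_fd = 14, n_fi = 7, n_fn = 10, montage = "Cz",
                    n_blocks = 1, trials_per_block = 2, n_training_trials = 0,
                    noise_sigma_uv = 0, erp_components = list(),
                    band_modulations = list(), seed = 2L)
  coh <- generate_cohort(cfg)
  expect_length(coh, 31)
  groups <- vapply(coh, function(b) b$ground_truth$group, character(1))
  expect_equal(unname(table(groups)[c("FD", "FI", "FN")]),
               c(14, 7, 10), ignore_attr = TRUE)
  plan1 <- bistableEEG:::cohort_plan(cfg)
  plan2 <- bistableEEG:::cohort_plan(cfg)
  expect_identical(plan1$seed, plan2$seed)
  expect_true(all(plan1$seed >= 0 & plan1$seed < 2^31))
  expect_error(generate_cohort(sim_config(n_fd = 0, n_fi = 0, n_fn = 0)),
               "at least one participant")
})

test_that("HFT response generation honours ability extremes and the two-part design", {
  r1 <- generate_hft_responses(rep(1, 5), p_blank = 0, seed = 1L)
  expect_true(all(r1 == "correct"))
  expect_equal(unname(score_hft(r1)), rep(32, 5))
  r0 <- generate_hft_responses(rep(0, 5), p_blank = 0, seed = 1L)
  expect_true(all(r0 == "incorrect"))
  expect_error(generate_hft_responses(0.5, n_items = 31), "even")
})

test_that("invalid configuration fields are rejected with the field name", {
  expect_error(sim_config(p_c1 = 1.5), "p_c1")
  expect_error(sim_config(fixation_ms_range = c(800, 6000)), "fixation_ms_range")
  expect_error(sim_config(noise_sigma_uv = -1), "noise_sigma_uv")
  expect_error(sim_config(erp_components = list(
    erp_component("stimulus_on", 150, 12, 4, "NotAChannel"))),
    "erp_components")
})
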