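# bistableEEG

Event-locked EEG analysis of bistable perception, with a synthetic
experiment generator and a Field Dependence–Independence (FDI) group
comparison.

## The scientific problem

When an observer views a bistable (ambiguous) image — a Necker cube, the
old/young woman — their perception alternates spontaneously between two
interpretations. These *perceptual reversals* leave signatures in the EEG:
a reversal positivity (100–200 ms after stimulus onset), a reversal
negativity (200–280 ms), a frontoparietal positivity (280–400 ms), a late
positivity (400–600 ms), and changes in alpha (8–13 Hz) and gamma
(26–60 Hz) band power around the button presses that report the reversal.
A parallel question from the study of cognitive styles is whether these
reversal signatures differ between *Field Dependent* (FD) and *Field
Independent* (FI) individuals, as classified by the 32-item Hidden Figures
Test (HFT, score = correct − incorrect).

`bistableEEG` implements the full analysis chain for this paradigm:

1. **Preprocessing** — 2–65 Hz Hamming-windowed linear-phase FIR filter
   (zero net delay), extraction of three overlapping event-locked epoch
   sets per trial (stimulus onset, first button press, second/reversal
   button press), each spanning −1000…+5000 ms, with per-trial baseline
   correction anchored to the prestimulus interval [−1000, 0] ms.
2. **Features** — 12 features per participant: local-peak amplitudes and
   latencies of the four post-onset components (features 1–8), low-gamma
   power 26–40 Hz in [−200, −50] ms before onset (feature 9, computed
   without baseline correction), the reversal positivity in [−300, −200] ms
   before the button press (feature 10), and alpha/gamma power in
   [−1000, 0] ms before the button press (features 11–12). Spectral
   features use Welch's method with an FFT length of 500 points, a
   500-point Hamming window and no overlap; alpha is estimated from the
   trial-averaged waveform, the gamma features from single trials.
   Every feature is evaluated at 30 locations: the 24 electrodes of the
   10–20 montage plus six channel groups L1–L6 (left/right frontal,
   left/right rear, and their unions).
3. **Statistics** — the comparison matrix: paired t-tests between
   conditions (bistable c1 vs unambiguous c2) and between the two button
   presses, pooled two-sample t-tests between FD and FI groups, with
   Holm–Bonferroni familywise error control per feature across the 30
   locations. Raw and adjusted p-values are always reported side by side.
4. **Synthesis** — a generator that simulates complete experiments
   (10 training trials plus three blocks of 100 trials, exact 50/50
   condition split per block, fixation 800–1300 ms, 5000 ms response
   timeout, pink-noise background, injected Gaussian ERP components, and
   band-limited power modulations with controlled gain), so the entire
   chain is testable against known ground truth, including HFT item
   responses with controllable reliability.

## A worked example

```r
library(bistableEEG)

cfg <- sim_config(n_fd = 2, n_fi = 2, n_fn = 0, n_blocks = 1,
                  trials_per_block = 20, n_training_trials = 0, seed = 7)
b <- generate_participant(cfg, "P01", "FD", seed = 123)
b$recording
#> <eeg_recording> 24 channels x 102307 samples @ 500 Hz (204.6 s)
#>   participant P01 (FD)
#>   events: 88 (button1=19, button2=7, fixation_on=20, stimulus_on=20, trial_end=20)

f <- participant_features(b$recording, b$trial_table, min_trials = 4)
subset(f, feature == 12 & location == "T8")
#>     participant group feature epoch location    value value_uv2 n_trials note
#> 645         P01    FD      12    b1       T8 11.23175  13.27928       14 <NA>
#> 705         P01    FD      12    b2       T8 14.78206  30.07500       11 <NA>
```

The two rows are the pre-button gamma power (dB) at electrode T8 before
the first and the second button press: this simulated FD participant
carries the planted pre-reversal gamma elevation (the default ground
truth plants a power gain of 2, i.e. about +3 dB, at T8, CP6 and TP10 for
FD participants), and the feature recovers it (+3.6 dB).

A full run — simulation, features, HFT scoring, comparisons, report —
is one call:

```r
run_pipeline(cfg, "run1")
cat(readLines("run1/report.txt")[1:4], sep = "\n")
#> == bistable (c1) vs unambiguous (c2) ==
#> positivity amplitude (feature 1): no location passes the threshold
#> positivity latency (feature 2): no location passes the threshold
#> negativity amplitude (feature 3):
```

Rerunning with the same configuration reproduces every output file
byte-identically.

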