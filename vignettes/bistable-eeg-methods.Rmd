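---
title: "Methods: event-locked analysis of bistable-perception EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked analysis of bistable-perception EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bistableEEG)
```

This vignette is the package's account of its methods: the signal model,
the preprocessing and feature definitions, the statistical scheme, what
the synthetic generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The experimental design being modelled

Each trial shows a fixation cross for a uniformly random 800–1300 ms,
then a static image that is either bistable (condition c1) or unambiguous
(condition c2). The participant presses a button when they perceive an
initial interpretation (first press) and again if the percept reverses
(second press, c1 only; it ends the trial). Without a second press the
trial times out 5000 ms after onset. A session is 10 training trials
followed by three blocks of 100 test trials; each block contains exactly
50 c1 and 50 c2 trials in shuffled order, so a participant sees 310
stimuli. EEG is recorded at 500 Hz from 24 passive electrodes of the
10–20 system (reference FCz, ground Fpz, carried as metadata).

## Preprocessing

**Filter.** A Hamming-windowed band-pass FIR of 2–65 Hz. The order comes
from the standard Hamming design rule `N ≈ 3.3/(tbw/fs)` using the
narrower transition band (2 Hz at the low edge; the high edge is allowed
10 Hz), rounded up to even: 826 at 500 Hz. The filter is applied in a
single forward pass and shifted by `N/2` samples (exact for a symmetric
impulse response), rather than filtered forward–backward, so the designed
magnitude response is preserved exactly; edges are reflection-padded and
trimmed. Coefficients are explicitly symmetrised so `c[k] = c[N-k]` holds
to the last bit.

**Epochs.** Three overlapping epoch sets per trial, time-locked to
stimulus onset, first press and second press, each spanning
[−1000, +5000) ms in half-open sample windows
(`offset = round(ms·fs/1000)`, 0-based sample indices, time =
sample/fs). Epochs that would run outside the recording are dropped with
a logged reason.

**Baseline.** Per trial and channel, the mean over [−1000, 0) ms before
that trial's *stimulus onset* is subtracted — also for button-locked
epochs. Using each epoch's own prestimulus interval would subtract
reversal-related activity for button-locked epochs, so the baseline
anchor is always the trial's onset. The prestimulus means are computed
from the continuous recording at extraction time, which makes the
correction idempotent and independent of the epoch window. The continuous
data are filtered before epoching; the two operations commute for
interior epochs (a tested property), so the order is immaterial away from
the recording edges.

**Locations.** Every feature is evaluated on the 24 electrodes and on six
virtual channels: L1 = {Fp1, F7, FC1}, L2 = {Fp2, F8, FC2},
L3 = {TP9, CP5, CP1, P3, O1}, L4 = {TP10, CP6, CP2, P4, O2}, L5 = L1∪L3,
L6 = L2∪L4 — 30 locations in total. A group feature is always computed on
the group-averaged waveform, never as the average of per-channel feature
values; for nonlinear features (peaks, log power) the two differ, and the
averaged-signal convention is the one adopted here.

## Features

| id | quantity | window | band | estimation |
|----|----------|--------|------|------------|
| 1–2 | positivity amplitude / latency | [100, 200] ms after onset | — | on the condition ERP |
| 3–4 | negativity amplitude / latency | [200, 280] ms | — | on the condition ERP |
| 5–6 | frontoparietal positivity | [280, 400] ms | — | on the condition ERP |
| 7–8 | late positivity | [400, 600] ms | — | on the condition ERP |
| 9 | low gamma power | [−200, −50] ms before onset | 26–40 Hz | single-trial mean |
| 10 | reversal positivity amplitude | [−300, −200] ms before press | — | on the button ERP |
| 11 | alpha power | [−1000, 0] ms before press | 8–13 Hz | Welch of averaged trials |
| 12 | gamma power | [−1000, 0] ms before press | 26–60 Hz | single-trial mean |

**Local peaks.** A sample is a local extremum if it strictly exceeds (for
positivities; strictly falls below for negativities) every sample within
±20 ms in the *full* waveform — the neighbourhood is not clipped at the
feature window, so a monotone flank ending at the window edge is not a
peak. The returned value is the largest local extremum of the requested
polarity inside the window; if none exists, the windowed absolute
extremum is returned flagged `is_local = FALSE`. Ties break to the
earliest latency. The 20 ms neighbourhood is conventional ERP practice;
it is a parameter of `find_peak()`. Amplitudes are signed; negativity
features return (negative) minima so that downstream comparisons operate
on signed means.

**Spectra.** Welch's method with FFT length 500, window length 500, no
overlap, Hamming window, per-segment mean removal. Over a 1000 ms
(500-sample) interval this is a single modified periodogram on a 1 Hz
grid; band power integrates the bins whose centres lie in the band
(inclusive), so alpha owns exactly the 6 bins 8–13 Hz. The estimator is
normalised so that its integral over frequency equals the
window-power-corrected variance of the detrended segment (Parseval; a
tested identity at 1e-6). The pre-onset interval of feature 9 is only 75
samples; the 500-point window cannot apply verbatim, so the window is
shortened to the segment and the FFT zero-padded to 500 to keep the 1 Hz
reporting grid. Band powers are reported as `10·log10(µV²)` (dB), with
the linear value retained as an auxiliary column.

Feature 9's window lies inside the baseline interval, so it is computed
on *uncorrected* epochs; every other feature uses baseline-corrected
data. Features 10–12 are computed for both the first- and second-press
epoch sets of condition c1 (only c1 trials can have a second press), each
within the window of its own lock. A participant context contributes a
feature only if at least 5 trials underlie it (configurable); otherwise a
missing row with the reason is emitted, never a silent drop.

The averaged-trial estimation of feature 11 attenuates any oscillation
that is not phase-locked to the press by roughly the trial count, while
the single-trial estimation of features 9 and 12 does not — the two code
paths are genuinely different estimators, and a regression test verifies
that the on-average estimate is strictly smaller for random-phase
oscillations with a gap that grows with the trial count.

## Statistics

Three families, each at all 30 locations:

* **(a) condition**: paired t-tests across participants, c1 vs c2, on the
  onset features 1–9;
* **(b) press**: paired t-tests, first vs second press (c1), on features
  10–12;
* **(c) group**: two-sample t-tests, FD vs FI, on the c1 values of all 12
  features (second-press context for 10–12).

The two-sample test is Student's pooled-variance test: with 14 FD and 7
FI participants it reports df = 19, which is the design's convention (a
Welch test would not). Incomplete pairs and missing entries are dropped
with the realised n recorded per row; every reported df is re-derived
from the post-filtering sample sizes.

Holm–Bonferroni is applied per feature across its 30 locations (the
`family_scope` argument also offers a global or no correction). The
familywise error level defaults to 0.05. Because the appropriate family
for this design is genuinely debatable, every output table reports the
raw and the Holm-adjusted p-value side by side and the report function
can gate on either.

## The synthetic generator

The generator exists so the whole chain can be validated against known
ground truth. It emulates: the exact trial schedule above (stratified
50/50 condition split per block, not i.i.d. coin flips); lognormal
first-press latencies (median ≈ 800 ms) and press-to-press reversal times
(median ≈ 1.4 s) truncated into the response slot; group-dependent
reversal probabilities (defaults 0.70 FD / 0.85 FI / 0.78 FN — the FI
rate is set higher, reflecting the expectation that FI observers reverse
more readily; these are free parameters of the simulation, not measured
quantities); background noise, either white or (default) 1/f "pink"
above 1 Hz with a flat floor below, at a configurable σ in µV — raw EEG
is not white, and the 1 Hz floor keeps the variance from being dominated
by unobservable drift; Gaussian-bump ERP components (latency = centre,
width = SD) with per-channel gains, restricted by condition and group
scope; and band-limited power modulations implemented by adding an
independent filtered-noise burst with 100 ms cosine ramps, scaled so the
expected band power in the window is multiplied by the configured gain
(the background's expected band power is analytic because the noise is
synthesised in the frequency domain). Trials are laid out with a fixed
response slot plus a 1500 ms inter-trial gap; feature windows never
overlap an adjacent trial, though the far tail of a +5000 ms button
epoch may extend into the next trial's fixation period.

It does **not** emulate: volume conduction or any head geometry
(per-channel gains only, so spatial correlation of the noise is absent),
ocular or muscular artifacts, phase-locked oscillatory dynamics, eye
movements, or realistic inter-participant variability beyond the planted
group effects. Passing tests on synthetic data therefore demonstrate the
correctness of the *pipeline*, not the physiological validity of any
particular finding on real recordings.

The default planted effect set mirrors the qualitative pattern the
paradigm is known for: the four onset components; a stronger early
positivity in c1; a reversal positivity before the second press; an alpha
elevation before the first press relative to the second; a gamma
elevation before the second press at Fz; and FD-specific effects (gamma
gain 2 at T8/CP6/TP10 before the reversal, low-gamma gain at TP10 before
onset, a stronger frontoparietal positivity at left fronto-temporal
sites, a stronger reversal positivity at P4).

Determinism: every generator entry point takes a seed; participant seeds
derive from the cohort seed by a fixed affine map mod 2³¹−1, so cohorts
are reproducible while participants remain independent streams.
`run_pipeline()` reproduces all CSV outputs byte-identically under a
fixed configuration.

## The Hidden Figures Test module

Scores are `#correct − #incorrect` (blanks contribute 0) over 32 items in
two equal parts. Classification cutoffs are an input: the instrument's
manual cutoffs are not derivable from data, so the documented default is
the empirical tertile rule (33.3/66.7 percentiles, ties to the lower
class). Cronbach's alpha uses 0/1 item scoring. The response generator
uses an exchangeable beta-Bernoulli item model: each participant's
success probability is drawn from a Beta centred on their ability with
dispersion `rho = 1/(a+b+1)`, making the inter-item correlation exactly
`rho` (with no blanks), so Cronbach's alpha of a large generated matrix
converges to the Spearman–Brown value `k·rho/(1+(k−1)·rho)` — with
k = 32 and rho = 0.17 that is 0.868, matching the reliability regime of
the instrument. Default group ability means are 0.2 (FD), 0.5 (FN), 0.8
(FI) with a within-group SD of 0.05 and a 10% blank rate: a separation
chosen, before any tests were run, so that the test behaves like a
usable instrument (tertile classification recovers planted FD/FI labels
with ≈95% agreement in a balanced 200-participant cohort).

## Calibration experiments and problem sizes

Three seeded experiments validate the chain end to end (exported as
`erp_recovery_experiment()`, `null_fwer_experiment()`,
`planted_gamma_power_experiment()`); the problem sizes below are the
package's chosen defaults, picked a priori to estimate each quantity with
useful precision at desk scale.

* **Recovery**: a 2.5 µV component of 10 ms Gaussian width (FWHM ≈ 24 ms,
  a typical early visual positivity) at 150 ms on Pz, 150 trials, 1 µV
  pink noise, 100 runs. The 2 Hz high-pass necessarily removes the
  lowest-frequency content of any bump, biasing recovered amplitudes
  slightly downward (≈ −0.25 µV for this component); amplitudes are
  nevertheless recovered within ±0.5 µV and latencies within ±8 ms in
  ≈100% of runs. Wider or larger components would push the filter bias
  beyond the amplitude tolerance — a real property of the 2–65 Hz
  analysis chain, not of the simulation.
* **Null error control**: cohorts of 5 participants × 10 trials with all
  planted components applied to both conditions, 40–60 replicates; the
  per-feature Holm families (30 locations) reject anything in ≈3.5% of
  (replicate, feature) instances, consistent with the 5% bound within
  two-sigma binomial slack for the replicate count used.
* **Power**: cohorts of 7 FD + 5 FI participants × 24 trials with the
  default planted gamma gain 2 at T8/CP6/TP10; all three locations are
  detected (after Holm) in every replicate — the planted effect is large
  relative to the between-participant variability of the gamma estimate,
  so a handful of replicates suffices to demonstrate ≥80% power.

## Numerical choices and degenerate inputs

* ms→samples is always `round(ms·fs/1000)`; windows are half-open in
  samples except local-peak feature windows, which include both rounded
  endpoints.
* `welch_psd` refuses segments shorter than the window (no silent data
  padding); zero-padding applies only to the FFT of an already-windowed
  short segment.
* Zero-variance inputs (constant differences, constant groups) make the
  t statistics undefined and raise errors rather than returning NaN;
  `run_comparisons` skips such location rows (they arise from
  sample-quantised latency ties in tiny cohorts) and errors only when a
  whole family is unrunnable.
* The EDF+ writer chooses a symmetric physical range covering the
  observed amplitudes (so 0 µV is exactly representable) with a ≤0.1 µV
  quantisation step whenever the range permits, errors on non-finite
  input, and stores the true sample count so that reads trim the final
  padded record; events travel as EDF+ annotations and foreign files are
  adapted through a user label map.
* `classify_fdi` with explicit cutoffs uses `score ≤ low → FD`,
  `score ≥ high → FI`; the tertile rule assigns ties at a cutoff to the
  lower class.

## Known limitations

Scalp-map graphics, artifact handling, re-referencing, source analysis
and time–frequency decompositions are out of scope. The simulator's lack
of spatially correlated noise makes channel-group averaging more
beneficial than it would be on real data. Real recordings can be read
from EDF+ (with a label map for their annotation vocabulary), but results
on real data additionally depend on artifact handling and exclusion rules
that this package deliberately leaves explicit and configurable.
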