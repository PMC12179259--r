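---
title: "wristmet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wristmet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Hip-worn actigraphy count equations are the de-facto standard for
free-living energy-expenditure (EE) estimation, but they are calibrated
mostly in non-obese samples and degrade with altered gait, device tilt
and body composition. `wristmet` estimates metabolic equivalents of
task (METs) from the raw 20 Hz accelerometer and gyroscope stream of a
wrist-worn device instead, targeting minute-scale EE in adults with
obesity while remaining fully open and re-trainable.

A MET is defined here as oxygen uptake relative to the conventional
resting value: `MET = VO2[ml/kg/min] / 3.5`. The criterion comes from
breath-by-breath indirect calorimetry through the abbreviated Weir
equation, `EE [kcal/min] = 3.941·VO2 + 1.106·VCO2` with gas volumes in
L/min. An alternative kcal-referenced MET convention
(`EE / (weight · 0.0175 kcal/kg/min)`) is selectable in
`ee_to_met(convention = "kcal")`; the default is the VO2-referenced
form because the 3.5 constant is dimensionally an oxygen uptake.
Breath events are event-sampled, so the MET series is moved onto the
IMU clock with a previous-value hold rather than interpolation.

## The two-stage model

Wrist movement correlates with EE very differently in sedentary and
ambulatory behaviour (typing can out-move slow walking at the wrist),
so the estimator separates the two regimes:

1. **Sedentary gate** — an XGBoost binary classifier over 42
   descriptive statistics: {median, mean, max, min, range, sample sd,
   rms} for each of the six channels. Windows gated sedentary receive
   exactly 1.0 MET.
2. **Intensity regression** — a random forest over three
   signal-intensity features of the accelerometer plus demographics
   (age, sex as 0/1, weight, height, BMI, and the 10 pairwise
   products), fitted **only on truly non-sedentary training windows**
   and floored at 1.0 MET at prediction time.

The gate-then-regress structure makes the pipeline robust to gate
errors by construction: a sedentary window misrouted to stage 2 carries
near-floor intensity features, so the forest returns a near-resting
value rather than an ambulatory one. This only holds when the
regression training distribution includes non-sedentary windows near
the resting rate — which measured calorimetry provides (standing or
light housework in adults with obesity measures well below compendium
MET assignments) and which the synthetic generator therefore emulates
(see below).

### Intensity features

All three are computed after per-channel L2 normalisation of the
window (`l2_normalize()`), which rescales each channel vector to unit
Euclidean norm:

- `km_motion()` — the pooled-dispersion magnitude
  `sqrt(var(x) + var(y) + var(z))`, implemented in its running-sums
  form and asserted equal to the variance form at 1e-10 in tests.
- `rmssd()` — successive-difference energy
  `sqrt(Σ[(xᵢ−xᵢ₊₁)² + (yᵢ−yᵢ₊₁)² + (zᵢ−zᵢ₊₁)²] / m)`. Printed
  formulations of this statistic disagree on the divisor (sample count
  vs pair count, with the pair index running out of range in the
  former); the default divides by the number of adjacent pairs
  `m = n − 1`, and `scaling = "literal_n"` reproduces the sample-count
  variant. At window lengths of 100+ samples the two differ by well
  under 1 %.
- `dominant_frequency()` — a 4th-order Butterworth band-pass (0.3–8 Hz
  passband, covering human movement; applied forward–backward so the
  phase is zero and the effective order doubles) followed by the FFT
  magnitude spectrum; the returned value is the frequency of the
  largest in-band bin, DC excluded. Resolution is one FFT bin,
  `1/window_s` Hz. The feature is evaluated on the acceleration
  magnitude signal, so it is insensitive to device orientation.

A consequence of L2 normalisation worth stating: for a zero-mean
channel the normalised variance is ~`1/n` regardless of movement
amplitude, so post-normalisation amplitude information survives mainly
(a) in the gravity-bearing channel, where the oscillation is scaled
relative to the 1 g baseline, and (b) in RMSSD, which encodes the
noise-to-signal frequency structure. Feature selection regularly keeps
`rmssd` first on synthetic data for exactly this reason. The gyroscope
contributes to the 42 gate statistics but not to the intensity
features, which are defined over the accelerometer axes.

### Feature selection

`select_features()` is a greedy forward wrapper: starting from the best
single feature by participant-grouped 3-fold cross-validated RMSE of a
small random forest, it adds the best remaining candidate until the
improvement drops below `selection_tol` (default 1e-3 MET). Selection
is nested inside each LOPO fold by default, so the held-out participant
never influences the chosen subset; `select = FALSE` disables it (all
18 candidates enter the forest, which tolerates uninformative features
well). `evaluation_report()` defaults to `select = FALSE` because the
nine-window sweep refits the model `9 × participants` times and the
forest's own feature weighting makes per-window nested selection a poor
use of that budget; single-window analyses keep the nested default.

### Key parameters

| parameter | default | meaning |
|---|---|---|
| `window_s` | 60 s | window length; 5–90 s supported, 50 % overlap |
| `trim_s` | 120 s | head of each activity excluded (VO2 stabilisation) |
| `overlap` | 0.5 | fractional window overlap |
| `sedentary_met`, `met_floor` | 1.0 | resting assignment and floor |
| `selection_tol` | 1e-3 MET | wrapper stopping tolerance |
| `stage1_params` | depth 4, eta 0.3, 50 rounds | XGBoost gate |
| `stage2_params` | 300 trees | random forest |
| filter | 0.3–8 Hz, order 4 | dominant-frequency band-pass |

Stage learner settings are library defaults with a fixed seed; the
pipeline's accuracy on both synthetic and recorded data is driven far
more by windowing and feature choices than by these hyperparameters,
and a seeded default keeps every refit reproducible.

## Preprocessing conventions

- **Units.** Canonical units are g (acceleration) and deg/s (angular
  velocity) because the ENMO-based comparator equations are defined in
  g; `imu_schema()` flags convert Android-convention m/s² and rad/s
  exports at read time.
- **Handedness.** Left-wrist recordings are reflected through the
  sagittal plane: `ax` flips sign, and the angular-velocity components
  about the in-plane axes (`gy`, `gz`) flip because angular velocity is
  a pseudo-vector. The map is configurable; it is an involution and
  preserves per-sample vector norms. (Published sensitivity analyses
  find EE estimation essentially unaffected by wrist choice, so any
  consistent mirror is acceptable.)
- **Windowing.** Windows never span an annotation boundary in-lab, and
  free-living streams are segmented at timestamp gaps exceeding two
  sample periods. A segment of duration `D` yields
  `floor((D − w)/(w(1−o))) + 1` windows; trailing partials are
  dropped. Window MET ground truth is the arithmetic mean of in-window
  samples (median selectable).

## Degenerate inputs and tie-breaks

- Zero-norm channels pass through `l2_normalize()` unchanged.
- `statistical_features()`, `km_motion()` and `rmssd()` require ≥ 2
  samples; `dominant_frequency()` requires ≥ 1 s of signal and an
  upper band edge below Nyquist.
- An empty intensity stratum reports RMSE `NA` (absent), never 0.
- A gate that predicts no positives yields `NaN` precision with a
  warning rather than a silent 0.
- `rm_anova()` on a matrix with no within-cell variance (e.g.
  identical columns) reports a degenerate `NaN` F with p = 1 instead
  of dividing by zero; no sphericity correction is applied.
- Paired comparisons with constant non-zero differences report an
  infinite Cohen's d sentinel with a warning; identical columns give
  d = 0, adjusted p = 1. Cohen's d uses the paired denominator
  `mean(diff)/sd(diff)` with `diff = method_a − method_b`, so listing
  the proposed method first makes negative d mean "proposed better
  (lower RMSE)".
- Bland–Altman limits use the n−1 SD; with identical series the limits
  collapse to the mean difference and nothing is flagged.

## The synthetic study conditions

`generate_cohort()` emulates a supervised in-lab protocol: 12
activities (3 per intensity class) of 5 minutes each with 5-minute
seated rests, 20 Hz 6-axis IMU, breath-by-breath gas exchange at
0.25 Hz (a typical adult respiratory rate), and demographics drawn
from adult ranges with BMI ≥ 30. Acceleration is a gravity unit vector
plus an activity-specific sinusoid (amplitude `0.13·(MET−1)` g,
frequency 0.5–2.2 Hz) plus white noise (sd 0.01 g); VO2 per breath is
`(latent MET + N(0, 0.1)) · 3.5 · weight / 1000` L/min with VCO2 at a
respiratory exchange ratio of 0.85, so the Weir/MET chain recovers the
latent MET up to per-breath noise.

Latent MET values follow **measured-calorimetry levels** for these
activity types in adults with obesity (standing ≈ 1.4, sweeping ≈ 2.0,
vigorous stepping ≈ 7.5) rather than compendium assignments. This
matters structurally: measured light activity sits near the resting
rate, giving the stage-2 forest training support just above 1 MET —
the property the misclassification-robustness behaviour of the
pipeline relies on. With the default calibration the lightest
non-sedentary amplitude (≈ 0.05 g) still exceeds the sedentary ceiling
(0.02 g) by ≥ 5 noise SDs, keeping the classes separable. Latent MET
is amplitude-driven by default so `km`/`rmssd` are the informative
features; `default_protocol(met_driver = "frequency")` holds amplitude
constant and drives MET through motion frequency instead, exercising
`dominant_frequency()`.

What the generator deliberately does **not** emulate: biomechanical
gait structure (harmonics, impacts, asymmetry), autocorrelated sensor
noise and drift, orientation changes within an activity, behavioural
transitions inside windows, metabolic inertia (VO2 on/off kinetics are
instantaneous here apart from the head-trim), and between-participant
differences in the amplitude→MET mapping. Passing tests on synthetic
cohorts therefore demonstrate that the pipeline's machinery is correct
and that the estimator recovers a recoverable latent mapping under
realistic noise — not that the reported error levels transfer to
recorded human data, where the mapping is weaker and
participant-specific. On synthetic cohorts the LOPO RMSE (~0.11 MET at
60 s) is bounded below by the ground-truth noise and the 1.0-MET
pinning of sedentary windows; recorded-data errors are several times
larger.

## Evaluation harness

`lopo_evaluate()` refits the full pipeline once per participant,
excluding that participant's windows *and demographics* (and the
feature-selection data) from training, and asserts on every run that
the folds partition the window set with zero leakage. RMSE is reported
overall and within {sedentary, light, moderate/vigorous} strata
(moderate and vigorous pooled); the strata satisfy
`overall² = Σ nₛ·RMSEₛ² / Σ nₛ` exactly. `evaluation_report()` sweeps
the nine standard window sizes {5, 10, 12.8, 15, 30, 40, 50, 60, 90} s
(12.8 s is exactly 256 samples at 20 Hz) and tabulates classification
metrics at the subset of sizes used by published count-based methods.
Free-living intensity classes, when needed for agreement plots, use
the conventional MET cut-points on the reference estimate (sedentary
< 1.5, light 1.5–2.99, MVPA ≥ 3).

Comparator equations (ENMO-based Hildebrand linear/nonlinear;
Freedson and Sasaki counts-per-minute forms) evaluate coefficient rows
from an editable, citation-annotated CSV rather than hard-coded
constants, because published calibrations vary by wear site, device
and population; the bundled nonlinear row carries placeholder
coefficients marked as such. Trained-model baselines are consumed as
external per-window prediction CSVs, not re-implemented.

## Problem sizes used by the test-suite

The packaged tests run the recovery analysis on a 10-participant
synthetic cohort at the 60-s window with nested feature selection, and
the structural nine-window report on a 5-participant cohort without
selection; the agreement machinery is exercised at 10⁴–10⁵ windows.
These sizes were chosen as the smallest at which the cohort-level
properties (LOPO stability, stratum occupancy, normal-theory coverage)
are comfortably identifiable.

## Known limitations

- Sedentary windows are pinned to exactly 1.0 MET, so the sedentary
  stratum RMSE is bounded below by the true variability of resting EE.
- The gate is binary; posture subtypes (sitting vs lying) and
  stationary-but-active behaviours (cycling) are out of scope.
- No sphericity correction in the repeated-measures ANOVA.
- ActiGraph count generation is proprietary; counts are consumed from
  epoch exports, never synthesised from raw signal.
- Model archives serialise the fitted learners with R's native
  serialisation plus XGBoost's portable raw format; they are
  versioned, but cross-major-version compatibility of the forest
  object follows the `ranger` package's own guarantees.
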