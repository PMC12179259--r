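# wristmet

Energy-expenditure estimation from raw wrist-worn IMU streams for
physical-activity research, built for populations — such as adults with
obesity — in which hip-worn actigraphy count equations are least
reliable. The package estimates metabolic equivalents of task (METs,
multiples of the resting oxygen uptake of 3.5 ml·kg⁻¹·min⁻¹) per
sliding window of 20 Hz accelerometer + gyroscope data, and ships the
complete apparatus around the estimator: indirect-calorimetry ground
truth, a leave-one-participant-out evaluation harness, published
comparator equations, Bland–Altman agreement analysis, and a synthetic
multi-participant session generator so the whole pipeline runs without
any recorded data.

## The model

Estimation is a two-stage classify-then-regress pipeline over
fixed-length windows (5–90 s, 50 % overlap):

1. **Sedentary gate.** A gradient-boosted decision-tree classifier
   (XGBoost) labels each window sedentary / non-sedentary from 42
   descriptive statistics — {median, mean, max, min, range, sd, rms} ×
   {ax, ay, az, gx, gy, gz}. Sedentary windows are assigned 1.0 MET.
2. **Intensity regression.** Non-sedentary windows are L2-normalised
   per channel, and a random-forest regressor predicts METs from three
   signal-intensity features of the accelerometer —

   - the pooled-variance motion estimate
     `Km = sqrt(var(x) + var(y) + var(z))`,
   - the root mean square of successive differences
     `RMSSD = sqrt( Σᵢ [(xᵢ−xᵢ₊₁)² + (yᵢ−yᵢ₊₁)² + (zᵢ−zᵢ₊₁)²] / (n−1) )`,
   - the dominant frequency of the band-passed (Butterworth 0.3–8 Hz,
     zero-phase) acceleration magnitude —

   plus age, sex, weight, height, BMI and all pairwise interactions,
   with greedy-forward wrapper feature selection. Predictions are
   floored at 1.0 MET, the resting rate.

Ground truth comes from breath-by-breath gas exchange via the Weir
equation, `EE (kcal/min) = 3.941·VO2 + 1.106·VCO2` (L/min), converted
to METs by dividing oxygen uptake per kg by 3.5 ml·kg⁻¹·min⁻¹. Models
are compared by intensity-stratified RMSE under leave-one-participant-
out cross-validation (LOPO-CV), repeated-measures ANOVA with
Bonferroni-corrected paired t-tests and Cohen's d, and Bland–Altman
±1.96 SD limits of agreement.

## Worked example

Six synthetic participants perform a 12-activity in-lab protocol; the
model is evaluated by LOPO-CV at the 60-s window:

```r
library(wristmet)

cohort <- generate_cohort(6, seed = 42)
ws     <- windows_from_sessions(cohort$sessions, window_s = 60)
ws
#> <window_set> 360 window(s) of 60s (overlap 0.5, 20 Hz)

fit <- wristmet(ws, cohort$demographics, seed = 42)
fit
#> Two-stage wrist-IMU MET estimator
#>   window: 60s at 20 Hz; trained on 360 windows from 6 participant(s)
#>   stage 1: XGBoost sedentary gate (42 features, 50 rounds)
#>   stage 2: random forest (300 trees) on 1 selected feature(s): rmssd
#>   sedentary MET 1.0, floor 1.0, seed 42

folds <- lopo_evaluate(ws, cohort$demographics, seed = 42)
df    <- lopo_windows(folds)
round(rmse_by_class(df), 3)
#>         sedentary             light moderate_vigorous           overall
#>             0.198             0.051             0.031             0.105
round(classification_metrics(df$stage1_pred, df$sedentary_true), 3)
#> precision    recall        f1
#>     0.989     1.000     0.994
```

The overall RMSE of 0.105 MET says held-out participants' windows are
predicted within about a tenth of a MET on this synthetic cohort
(per-breath ground-truth noise is 0.1 MET). The sedentary stratum is
the largest error because gated windows are pinned to exactly 1.0 MET
while measured sedentary activity varies around 1.0–1.3.

Free-living agreement between two minute-level MET series, with
disagreement excursions flagged beyond the ±1.96 SD limits:

```r
pair <- generate_free_living_pair(2000, seed = 42, sigma = 0.2,
                                  excursion_idx = c(100, 900, 1500))
bland_altman(pair$a$met, pair$b$met)
#> Bland-Altman agreement
#>   mean difference: 0.0061 (SD 0.2083)
#>   limits of agreement: [-0.4022, 0.4143]
#>   95.90% of 2000 window(s) within limits (40 over, 42 under)
```

A command-line wrapper around the same functions lives at
`inst/cli/wristmet.R` (subcommands `simulate`, `extract-features`,
`train`, `predict`, `evaluate-lopo`, `report`, `compare`,
`bland-altman`); see `?wristmet_cli`.

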