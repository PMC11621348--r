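---
title: "Linking continuous glucose monitoring to bradycardia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking continuous glucose monitoring to bradycardia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bradyglucose)
```

## The problem

Insulin-treated patients with diabetes and chronic kidney disease carry an
elevated risk of bradyarrhythmias, and hypoglycemia has long been suspected
as a trigger. `bradyglucose` implements an analysis pipeline for paired
7-day recordings of beat-to-beat RR intervals (from Holter ECG) and
interstitial glucose (CGM, 5-minute reporting grid): it detects bradycardia
episodes, extracts short-term heart-rate-variability (HRV) features,
assigns each patient *personalized relative glucose tertiles*, quantifies
when and at which relative glucose levels bradycardia is enriched, and
evaluates whether the pre-episode state is forecastable.

Because raw patient data of this kind cannot be shared, the package ships a
synthetic cohort generator with known ground truth; every downstream stage
is validated against it and against independent oracle implementations.

## Episode detection

A bradycardia episode is a maximal run of **more than 4 consecutive beats**
whose instantaneous heart rate `60000 / RR(ms)` is **strictly below
45 bpm** — equivalently RR > 1333.3 ms. Two conventions are fixed here and
exposed in `analysis_config()`:

* strict inequality at the threshold (a beat at exactly 45 bpm breaks a
  run), following the "fewer than 45" definition;
* detection runs on the *raw* RR stream, before the feature-stage artifact
  cleaning, so long (slow) intervals are never filtered out of the
  phenomenon under study.

Episodes closer than 5 minutes (end to next start, strict) are merged into
*episode groups* by single-linkage chaining (`group_episodes()`), reducing
the otherwise heavy-tailed per-patient episode counts.

## Windowing and the 29 HRV features

Recordings are tiled into non-overlapping half-open 5-minute windows
(matching the CGM grid, so each window carries exactly one glucose sample).
Within each window, intervals outside 300–3000 ms are treated as artifacts
and dropped; a window is valid only if the retained intervals span at least
half the window and at least 10 intervals remain. These cleaning rules are
package conventions (the clinical workflow's own denoising rules are not
public) and are deliberately conservative: 3000 ms comfortably exceeds the
bradycardia threshold, so cleaning cannot delete slow beats that detection
(which ran earlier, on the raw stream) has already seen.

Per valid window the package computes:

* **14 time-domain features** — RR dispersion (SDNN with the sample SD,
  pNN50/pNN20, RMSSD) and instantaneous-HR statistics (mean, median, SD,
  max, min, peak-to-peak, excess kurtosis, skewness, median absolute
  successive change, normalized zero-crossing rate of the mean-centered HR).
  Kurtosis is *excess* kurtosis (normal = 0) and skewness the standardized
  third moment; both use population moments.
* **9 frequency-domain features** — the unevenly sampled tachogram is
  interpolated with a cubic spline onto a 4-Hz grid over the window,
  mean-removed, Hann-tapered, and the one-sided periodogram integrated
  trapezoidally over VLF (0.0033–0.04 Hz), LF (0.04–0.15 Hz) and HF
  (0.15–0.40 Hz); total power spans 0.0033–0.4 Hz, normalized LF/HF powers
  are relative to LF + HF (in percent, so they sum to 100), band peaks are
  the frequency of maximal density, and the LF/HF ratio is in percent.
  VLF from a 5-minute window is shorter than the conventional VLF
  requirement and should be read as low-reliability; it is retained because
  the feature battery defines it.
* **6 nonlinear features** — Poincaré SD1/SD2 with *population* variances
  (so SD1 = RMSSD/√2 holds exactly for zero-mean successive differences),
  ellipse area π·SD1·SD2 (ms², the dimensionally consistent unit),
  SD1/SD2, sample entropy (m = 2, Chebyshev tolerance 0.2 × window SD,
  template counting over i < j pairs), and permutation entropy (order 3,
  lag 1, normalized by log 3! to [0, 1], ties broken by order of
  appearance).

Time of day enters as the continuous clock pair `c24_sin`, `c24_cos`
(period 24 h). CGM gaps up to 15 minutes are linearly interpolated; longer
gaps stay missing. Feature extraction is deterministic.

## Personalized relative glucose tertiles

Rather than absolute hypoglycemia cutoffs, each patient's observed glucose
range is split into three **equal-width** levels (low/medium/high), one
range per patient over the whole recording by default. The phrase "range
over a day" is ambiguous between one range per recording and one per
calendar day; both are implemented (`tertile_mode = "per_day"`), with the
recording-wide range as default because a patient's characteristic range is
the more stable personalization target. Bins are left-closed, the maximum is
included in "high", out-of-range values clamp to the nearest extreme level,
and equal-count (quantile) tertiles are intentionally *not* the default —
the construction is explicitly equal-width on the range.

## Statistical battery

* `mannwhitney_tertile_comparison()` — pairwise two-sided U tests of
  per-patient bradycardia frequencies across tertiles; exact null up to a
  combined n of 20 (without ties), normal approximation with tie correction
  beyond.
* `fisher_signed()` — the signed enrichment statistic: two-sided Fisher
  exact p of the 2×2 table (bradycardia vs non-bradycardia windows ×
  in-tertile vs not), reported as `-log10(p)` and signed by the deviation
  of the observed count from its fixed-margin expectation
  `row1·col1/total`. The hypergeometric two-sided p is computed in-package
  (summing point probabilities no larger than the observed one, with the
  customary 1e-7 relative tolerance) and is cross-checked against
  `stats::fisher.test` and an independent enumeration oracle in the tests.
* `bootstrap_fisher_by_timeband()` — for each 3-hour clock band and each
  extreme tertile, the band's windows are resampled with replacement at
  original size 100 times; each replicate contributes one signed statistic.
  The window is the resampling unit because bands of windows are the units
  the enrichment claim is about. Bands with fewer than 20 usable windows
  are flagged unreliable.
* `wilcoxon_hrv_bootstrap()` — rank-sum tests of each HRV feature between
  bradycardia and non-bradycardia windows; since the classes are heavily
  imbalanced, 100 iterations each draw 200 windows per class without
  replacement. The statistic is `-log10(p)` signed by the difference of
  class means. (An alternative convention multiplies the p value by the raw
  mean difference rather than its sign; that mixes units across features,
  so this package uses the signed `-log10 p` form for both the band
  enrichment and the feature test, putting the two on one scale.)
* `hourly_hr_glucose_correlation()` — Pearson correlation of the 24-point
  daily profiles of mean heart rate and mean glucose, averaged first within
  patient-hours and then across patients, with per-hour 95% CIs.
* No multiple-testing correction is applied anywhere; stratum counts are
  reported so users can adjust externally.

## Forecasting

Windows *containing* an episode are excluded (predicting them has no
forecasting value). The non-excluded window ending within 5 minutes before
an episode-group start is the **risk** zone (one window per group by
default; longer leads via `risk_lead_s`). **Normal** windows must clear
every group by more than 5 minutes on both sides (`normal_buffer_s`);
near-but-not-risk windows are dropped from both classes to prevent label
leakage. Features are z-scored per patient by default — tree ensembles do
not require scaling, but pooling patients with very different baselines
benefits from it, and `zscore = FALSE` disables it — while clock features
are exempt.

Class imbalance is handled by balanced bootstrap: each of 50 iterations
draws a normal-window sample of the risk-class size without replacement and
evaluates a Random Forest (500 trees, √p features per split — conventional
defaults, recorded in the report) by stratified 5-fold cross-validation.
Metrics are fold means aggregated as mean ± SD across iterations;
impurity importances are normalized per iteration. The precision–recall
curve is computed on the out-of-fold scores pooled across folds *and*
iterations in a single threshold sweep — a standard average-precision
estimator chosen over per-iteration curve averaging for simplicity; both
agree in expectation since iterations are exchangeable.

## The synthetic cohort generator

`simulate_cohort()` emulates the structure the analysis relies on, with
per-patient parameters drawn from `cohort_param_ranges()`:

* circadian cosine glucose (mesor 120–210 mg/dL, amplitude 15–45 mg/dL,
  acrophase 13:00–18:00) with stationary AR(1) noise (φ = 0.8 per 5-min
  step, marginal SD 5–12 mg/dL), giving realistic cohort marginals (mean
  glucose ≈ 165 ± 40 mg/dL) and CGM autocorrelation;
* RR streams from a circadian heart-rate profile (mesor 60–88 bpm,
  amplitude 5–12 bpm) plus sinusoidal LF (0.1 Hz) and HF (0.25 Hz)
  modulation and beat-to-beat Gaussian noise;
* bradycardia runs injected at a per-hour intensity =
  base rate × tertile multiplier × nocturnal multiplier, *replacing* beats
  within a fixed time span so the glucose alignment is preserved; defaults:
  ~22% of patients affected, low-tertile odds 3, nocturnal (00:00–06:00)
  excess 2;
* an optional pre-episode heart-rate drift (default 15 bpm over the 10
  minutes before onset, saturating a quarter of the way in). Drift beats
  carry the same circadian/LF/HF/noise structure as ordinary beats, so the
  injected forecasting signal is a genuinely lower heart rate and not a
  smoothness artifact of the insertion.

What the generator does **not** emulate: meal and insulin
pharmacokinetics, respiration-driven HF variability, ectopy and artifact
bursts, sensor dropouts beyond simple gaps, or the real cohort's
demographics. Passing tests therefore show that the pipeline recovers the
structures it is designed to detect when they are present and stays
calibrated when they are absent — not that the clinical effect sizes
themselves are reproduced.

## Numerical choices and degenerate inputs

* Tertile bounds on a constant glucose series are an error ("degenerate
  glucose range"); fewer than 12 non-missing samples likewise.
* `fisher_signed` returns 0 with a warning on zero-margin tables.
* Sample entropy is missing when no template pairs match; SD1/SD2 ratio is
  missing when SD2 = 0; normalized spectral powers are missing when
  LF + HF = 0.
* All randomness flows through a counter-based seed derivation
  (`derive_seed()`): per-patient and per-stage substreams are independent
  of cohort size, so adding patients never changes existing patients'
  draws, and every stage is bit-reproducible from `(config, seed)`.
* File formats are plain CSV (header, `.` decimal mark, empty field for
  missing) written with 17 significant digits so write → read round-trips
  doubles exactly.

## Problem sizes used in the shipped checks

The test-suite simulations use cohorts of 5–6 patients over 2 days (null
calibration: 20 such cohorts; enrichment recovery: 20 seeds; forecasting:
one drifted and one drift-free cohort), with the bootstrap designs at their
defaults and the cross-validation scaled to 3–10 iterations. The
acceptance script (`scripts/acceptance.R`) analyses a 16-patient × 2-day
cohort under the default study-like generator settings with 10 CV
iterations. These sizes are the package's chosen desk-scale analogue of
week-long multi-patient clinical recordings; all statistics scale to
longer cohorts and recordings unchanged.

## Known limitations

* VLF power from 5-minute windows is reported but unreliable by
  construction.
* The Mann-Whitney comparisons use per-patient frequencies as the sampling
  unit; per-window units would overstate the effective sample size.
* Only bradycardia is considered; other arrhythmias are out of scope.
* The forecaster is evaluated on balanced samples; deployment-grade alarm
  precision on the natural class imbalance would be substantially lower,
  and no calibration or alarm logic is provided.
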