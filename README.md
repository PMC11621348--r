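# bradyglucose

Analysis pipeline linking **continuous glucose monitoring (CGM)** to
**bradycardia** in beat-to-beat RR-interval streams, for researchers
studying arrhythmia risk in insulin-treated patients with diabetes and
chronic kidney disease — and, more generally, for anyone analysing paired
Holter-ECG / CGM recordings.

The pipeline implements, as tested reusable R functions:

1. **Episode detection** — bradycardia = a maximal run of more than 4
   consecutive beats at an instantaneous heart rate below 45 bpm
   (HR = 60000/RR, so the threshold is RR > 60000/45 ≈ 1333.3 ms); nearby
   episodes merge into groups when separated by less than 5 minutes.
2. **Short-term HRV features** — non-overlapping 5-minute windows (matched
   to the CGM grid) with 29 features: 14 time-domain (SDNN, pNN50/20,
   RMSSD, HR statistics), 9 spectral (VLF/LF/HF band powers from a
   Hann-tapered periodogram of the 4-Hz cubic-spline-resampled tachogram,
   normalized powers, band peaks, LF/HF ratio) and 6 nonlinear (Poincaré
   SD1/SD2/area/ratio, sample entropy m = 2, permutation entropy order 3),
   plus glucose and 24-h clock features `sin(2πh/24)`, `cos(2πh/24)`.
3. **Personalized relative glucose tertiles** — each patient's observed
   glucose range split into three equal-width levels (low/medium/high), so
   patients serve as their own controls.
4. **Statistics** — pairwise Mann-Whitney U tests of per-patient
   bradycardia frequencies across tertiles; hourly heart-rate–glucose
   Pearson correlation; the **signed Fisher enrichment statistic**
   `-log10(p) × direction` bootstrapped (100×) within 3-hour clock bands
   for the low/high tertiles; bootstrap Wilcoxon rank-sum tests (100×,
   200 windows per class) of each HRV feature against bradycardia.
5. **Risk forecasting** — the 5-minute window before each episode group is
   a *risk zone*, windows far from events are *normal*, event windows are
   excluded; per-patient z-scoring; balanced bootstrap undersampling with a
   Random-Forest classifier under stratified 5-fold cross-validation
   (50 iterations), with PR curves and impurity feature importances.
6. **Synthetic cohort generator** — circadian glucose (cosine + AR(1)
   noise) and RR streams (circadian HR + 0.1/0.25-Hz modulation + noise)
   with injected, ground-truthed bradycardia runs whose intensity can
   depend on tertile and time of day, plus an optional pre-episode
   heart-rate drift. Every downstream stage is testable without patient
   data.

## Worked example

```r
library(bradyglucose)
cfg <- analysis_config(cv_iterations = 10, rf_num_trees = 200, recording_days = 2)
report <- run_full_analysis(cfg, n_patients = 8, seed = 42, days = 2)
print(report)
```

```
<bg_report> 8 patients, 2 with bradycardia; 4608 feature windows
<cv_report> 10 iterations of balanced 5-fold CV; 140 risk windows vs 4202 normal
    metric  mean       sd
  accuracy 0.982 0.005175
       auc 0.998 0.000779
 precision 0.970 0.007210
    recall 0.997 0.003689
        f1 0.983 0.005028
```

Two of the eight simulated patients developed bradycardia (the generator's
default prevalence is ~22%). The classifier separates pre-episode windows
from normal ones almost perfectly because the default cohort carries a
15-bpm pre-episode heart-rate drift — the learnable signal the forecasting
stage is designed to detect.

```r
round(report$shares$overall_pct, 1)
#>    low medium   high
#>   52.1   28.5   19.4
cat("r =", round(report$correlation$r, 3))
#> r = 0.985
head(report$importances[1:2], 5)
#>     feature     median
#>  RR-hf-peak 0.16128882
#>  RR-lf-peak 0.15125111
#>   HR-median 0.10257158
#>     HR-mean 0.09102060
#>      HR-mad 0.08890694
```

With the default low-tertile odds of 3 (and a 2× nocturnal excess), about
half of all bradycardia windows fall in each patient's *low* relative
glucose tertile, and the daily heart-rate and glucose profiles are strongly
correlated. Among the forecaster's most important features are the windowed
heart-rate median and mean. (With only two affected patients, the spectral
peak features also rank highly — they partly fingerprint *which* patient a
window came from; larger cohorts dilute this.)

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gbp.R", package="bradyglucose"))')" \
    simulate --out cohort/ --seed 1 --patients 5 --days 2
```

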