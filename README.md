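# settledown

Characterizing the pre-sleep **settling-down period** from wrist actigraphy.

Standard actigraphy sleep variables describe the sleep period itself and
miss the stretch before it — the settling-down period, from the
caregiver-reported end of the bedtime routine to actual sleep onset — where
bedtime difficulties of children with tactile sensory sensitivities (SS)
actually show up as movement. `settledown` implements the full analysis
chain for comparing SS children with non-sensitive (NSS) peers on this
window, for sleep researchers working with 60-second epoch actigraphy and
sleep diaries:

1. **IO** — ActiLife-style epoch CSVs (`timestamp,vector_magnitude`), sleep
   diary CSVs (`child_id,night_date,settling_start,reported_sleep_onset`),
   and group-label CSVs, with strict contiguity/validation.
2. **Sleep scoring** — per-epoch Sadeh discriminant
   `PS = 7.601 − 0.065·MW − 1.08·NAT − 0.056·SD6 − 0.703·LG` (sleep iff
   `PS ≥ 0`), Tudor-Locke-style consecutive-epoch rest-period detection
   (5-min sleep onset run, 10-min wake offset run, ≥160 min), the
   30-minute diary reconciliation rule, and sleep onset as the first
   3-epoch sleep run.
3. **Settling extraction** — per-night window `[settling start, onset)`
   (or a diary-free 60-min-before-onset fallback), ≥4-night inclusion rule,
   duration summaries and Hedges' g.
4. **Window features** — rolling windows (default 11 min, stride 1) with
   seven features per window: mean and maximum magnitude, kurtosis,
   skewness, Shannon entropy of count values (bits), SD, IQR.
5. **Classification** — stratified 10-fold cross-validated random forests
   (SS = positive class, vote-fraction scores), Youden-J decision
   thresholds chosen on training folds, window/stride grid sweep, and a
   leakage-safe `grouped` fold mode alongside the window-level `paper`
   mode.
6. **Importance & statistics** — permutation feature importance by hold-out
   AUC decrease (refit per permutation), subject-level aggregates,
   Mann-Whitney U group tests (tie-corrected normal approximation), and
   standardized post-hoc regressions controlling for age and sex.

Because the underlying cohort data are not public, the package includes a
seeded **synthetic cohort generator** whose defaults are calibrated to the
published group statistics (settling durations 52.63 (38.31) vs 26.19
(14.20) min; settling epoch means 2481.27 vs 1964.06 counts/min), so every
stage is testable end to end. See the methods vignette
(`vignettes/settling-down-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(settledown)

cfg <- pipeline_config(
  synthetic = cohort_config(seed = 7),    # calibrated two-group cohort
  rf = rf_params(n_trees = 100), k = 10,
  importance_repeats = 10, seed = 7
)
report <- run_pipeline(cfg)
report
```

```
== settling-down analysis report ==
children included: 35; settling periods: 380; windows: 15779 (W=11, S=1)
  NSS settling duration (per-subject): 36.78 min (SD 12.03, n=18)
  SS settling duration (per-subject): 68.45 min (SD 12.87, n=17)
  Hedges' g (per-subject means): 2.49
cross-validation (10-fold, paper): accuracy 0.788, sensitivity 0.760, specificity 0.847, AUC 0.891
most important feature: max_mag (AUC decrease 0.079)
```

Reading the output: 35 simulated children all pass the ≥4-night rule,
contributing 380 settling periods and 15,779 rolling windows. Extracted
per-subject durations (36.8 vs 68.5 min) sit a few minutes above the
generator's true group means because algorithmic sleep onset trails true
quiescence — an honest property of the Sadeh scorer. The window-level
10-fold cross-validation separates the groups with AUC 0.89 (note this
`paper` fold mode is optimistically biased by within-subject window
overlap; `fold_mode = "grouped"` gives the leakage-free estimate), and
maximum activity magnitude is the most informative feature:

```r
report$importance
#> <settling_importance> hold-out AUC decrease (baseline 0.871)
#>       feature mean_auc_decrease sd_auc_decrease n_repeats
#>       max_mag            0.0786         0.01670        10
#>            sd            0.0438         0.01464        10
#>      kurtosis            0.0404         0.01582        10
#>           iqr            0.0329         0.01460        10
#>      skewness            0.0324         0.01355        10
#>      mean_mag            0.0226         0.01173        10
#>  entropy_bits            0.0106         0.00627        10

report$group_tests
#>            variable  ss_mean  ss_sd nss_mean  nss_sd   U    z  p_value
#>   mean_settling_min    68.45   12.9    36.78   12.03 292 4.59 4.48e-06
#>      mean_magnitude  2268.01  311.7  1679.32  396.78 276 4.06 4.92e-05
#>  mean_max_magnitude 13535.18 1547.5  9832.85 1046.68 305 5.02 5.26e-07
#>     sd_settling_min    47.46   17.7    23.71   22.15 253 3.30 9.65e-04
#>      median_entropy     3.46    0.0     3.13    0.83 196 2.31 2.11e-02
```

SS children move more (higher maximum bouts, higher dispersion) during
settling, and take longer to settle — exactly the structure the generator
encodes. `summary(report)` adds the post-hoc regressions;
`sweep_window_stride()` reproduces the window/stride comparison;
`write_cohort()` / `read_cohort_dir()` round-trip a cohort through the CSV
dialects; `pipeline_config(output_dir = ...)` persists every stage artifact
as CSV plus a JSON manifest.

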