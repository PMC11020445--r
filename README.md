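# ebqr

Endplate Bone Quality (EBQ) scoring and cage-subsidence analysis for the
cervical spine.

After anterior cervical discectomy and fusion (ACDF), the interbody cage can
sink into the adjacent vertebral endplates ("cage subsidence"), losing
segmental height and risking recurrent foraminal stenosis. Whether that
happens depends largely on the quality of the *endplate* bone — which
standard DEXA T-scores, measured at the lumbar spine, capture only
indirectly. The EBQ score reads endplate quality straight off the routine
preoperative MRI: on the mid-sagittal T1-weighted slice,

```
EBQ = ((SI_upper_band + SI_lower_band) / 2) / SI_CSF(T1)
```

where each band is the mean signal of the subchondral bone within 3 mm of
the endplates bounding the operated disc space, and the denominator is the
mean cerebrospinal-fluid signal at the level of T1. Marrow fat is T1-bright,
so **higher EBQ means more fat, less dense bone, and a higher subsidence
risk**.

`ebqr` is for spine researchers who want this measurement, and the analysis
chain built on it, as tested reusable code rather than a PACS workflow:

* **Measurement** — `extract_band()`, `compute_ebq()` (with Schmorl-node
  exclusion and multi-rater reconciliation via `reconcile_raters()`), image
  and annotation I/O (PNG/TIFF/NIfTI + JSON side-cars).
* **Outcome** — `segmental_height()` and `classify_subsidence()` (strict
  2 mm height-loss rule, migration override).
* **Statistics** — `t_ci_mean()`, `compare_groups()` (Shapiro-gated
  Student-t / Mann-Whitney, uncorrected chi-square), `pearson_correlation()`,
  `roc_youden()` (midrank AUC, DeLong CI, specificity-first Youden cutoff),
  `logistic_fit()` (Wald odds ratios), `per_level_summary()`, bundled by
  `analyze_cohort()` / `write_results()`.
* **Synthetic ground truth** — `generate_phantom()` draws a schematic
  sagittal slice whose true EBQ is known by construction;
  `simulate_cohort()` draws patient cohorts calibrated to a reference ACDF
  cohort (n = 158, 14.6% subsidence, EBQ 4.13 vs 5.38 across groups,
  EBQ–height-loss correlation 0.798). Everything downstream is testable
  without clinical data.

## Worked example

Measure a noisy phantom on its ground-truth annotations — the configured
truth is 430/100 = 4.30 at every level:

```r
library(ebqr)
ph <- generate_phantom(phantom_config(noise_sd = 5, seed = 42))
measure_phantom(ph)
#>   level      ebq si_upper si_lower   si_csf n_excluded
#> 1  C3/4 4.303326 430.2169 429.7807 99.92242          0
#> 2  C4/5 4.303173 430.1347 429.8322 99.92242          0
#> 3  C5/6 4.306950 430.4070 430.3148 99.92242          0
#> 4  C6/7 4.306118 430.2269 430.3286 99.92242          0
```

Simulate a calibrated 158-patient cohort and run the full analysis chain:

```r
co  <- simulate_cohort(cohort_config(seed = 42))
analyze_cohort(co)
#> Cohort analysis: n = 158, subsidence 19 (12.03%)
#> EBQ vs height loss: r = 0.803 (p = 7.48e-37)
#> ROC: AUC = 0.766 (95% CI 0.648-0.884), cutoff = 4.86 (sens 78.9%, spec 76.3%), n = 19 pos / 139 neg
#> Logistic regression (n = 158, converged in 7 IRLS iterations)
#>             term         b      se         p       or or_ci_lower or_ci_upper
#>      (Intercept) -5.287000 4.89500 0.2801000 0.005059   3.447e-07      74.250
#>              age -0.009583 0.03134 0.7598000 0.990500   9.315e-01       1.053
#>             sexM -0.960600 0.57260 0.0934100 0.382700   1.246e-01       1.175
#>       smokerTRUE -1.324000 0.82600 0.1089000 0.266000   5.270e-02       1.343
#>              bmi  0.130200 0.10580 0.2184000 1.139000   9.258e-01       1.401
#>  preop_height_mm -0.105600 0.09739 0.2781000 0.899800   7.434e-01       1.089
#>           tscore -0.097520 0.23790 0.6819000 0.907100   5.690e-01       1.446
#>              ebq  1.171000 0.33450 0.0004633 3.226000   1.675e+00       6.214
```

Reading the output: in this draw 19/158 simulated patients subside; EBQ
correlates strongly with segmental height loss (r = 0.803); EBQ separates
subsiders from non-subsiders with AUC 0.766 and a Youden-optimal cutoff of
4.86; and in the multivariate model only EBQ is a significant risk factor
(OR 3.23 per EBQ unit, p < 0.001) — single draws of n = 158 scatter around
the calibration targets, which is exactly the sampling variability the
simulator exists to exhibit.

Confidence intervals from printed summary rows use the t convention:

```r
round(t_ci_mean(-1.62, 1.34, 23), 2)
#> lower upper
#> -2.20 -1.04
```

## Design notes

The methods vignette (`vignettes/ebq-methods.Rmd`) documents the band
geometry, the CI/test/ROC conventions and their rationale, the phantom and
cohort generative models, the calibration algebra, and known limitations.
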