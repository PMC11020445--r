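---
title: "Endplate bone quality scoring: models, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endplate bone quality scoring: models, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebqr)
```

## The measurement model

The Endplate Bone Quality (EBQ) score quantifies, on a mid-sagittal
T1-weighted MRI slice, how fat-replaced the subchondral bone of the two
endplates bounding an operated cervical disc space is. Marrow fat is
T1-bright while dense bone is dark, so weak, fat-infiltrated endplates show
a high signal relative to a fat-free reference tissue. The score is

$$\mathrm{EBQ} \;=\; \frac{(\,\overline{SI}_{\text{upper band}} +
\overline{SI}_{\text{lower band}}\,)/2}{\overline{SI}_{\text{CSF, T1}}},$$

where each band is the subchondral bone within 3 mm of the traced endplate
and the denominator is the mean cerebrospinal-fluid signal at the
cranio-caudal level of T1. Being a ratio of means from the same image, EBQ
is invariant under global intensity rescaling (gain, windowing) but **not**
under additive offsets; `ebqr` tests both properties rather than pretending
offset invariance it does not have.

Two numerator conventions are possible when the two bands have different
pixel counts: averaging the two per-band means (each endplate contributes
equally) or pooling all band pixels into one mean (larger bands dominate).
`compute_ebq()` defaults to the per-band average, which matches the verbal
definition of the score as the average of the two endplate signals; pooling
is available via `combine = "pooled"` and is deliberately non-default.

### Band extraction

Annotations live in continuous millimetre coordinates; the centre of pixel
$(i, j)$ (1-based, row 1 at the top) is at $((j-\tfrac12)s,
(i-\tfrac12)s)$ for spacing $s$. A pixel belongs to an endplate band iff
its centre projects perpendicularly onto some segment of the traced
polyline within the band depth, **and** lies on the vertebral-body side of
the line. The side is the sign of the 2-D cross product against the
nearest segment, anchored by a user-supplied hint point; centres exactly on
the line belong to neither side. Two consequences worth stating:

* the band has *flat ends* — a straight 10 mm endplate with a 3 mm depth
  yields exactly the 10 × 3 mm rectangle, with no semicircular caps past
  the endpoints. Caps would sample tissue beyond the traced endplate
  (osteophytes, cortex of the uncinate) that the rater never intended to
  include;
* distances are exact point-to-segment computations, not a discrete
  distance transform. Bands are small, so exactness costs little and makes
  the extraction checkable pixel-for-pixel against a brute-force oracle,
  which the test suite does on every phantom fixture.

At interior joints of a curved polyline the perpendicular strips of
adjacent segments overlap on the inner side of a bend and leave a thin
wedge on the outer side; with the gentle curvatures of cervical endplates
(the phantom's default amplitude is 0–1 mm over a ~14 mm endplate) the
wedge is below pixel resolution.

Schmorl nodes are excluded by annotation, never by automatic detection:
the exclusion is a polygon (or an exact pixel mask, when the phantom
generator provides one) subtracted from the band before averaging, and the
measurement records how many pixels it removed.

### Rater reconciliation

Two primary raters measure independently; if their EBQ values differ by at
most the discrepancy threshold the final score is their mean, otherwise a
third rater's confirmatory re-measurement is required and becomes final.
The threshold defaults to 2.0 *EBQ units* — the unit is not fixed by
convention anywhere we know of, so it is a parameter (`threshold`) rather
than a constant.

## Subsidence classification

Segmental height is the Euclidean distance, on a calibrated lateral
radiograph, between the superior-endplate midpoint of the upper vertebra
and the inferior-endplate midpoint of the lower vertebra. Subsidence is a
height loss *strictly exceeding* 2 mm between the week-1 film and final
follow-up, or reader-adjudicated migration of the cage into an endplate.
Ties at exactly 2 mm are non-subsidence ("exceeding" is strict), apparent
height *gain* is retained rather than clamped (it happens with measurement
noise and must flow into group means), and migration alone suffices
regardless of height change. Magnification correction is assumed to have
happened upstream: the classifier consumes millimetre coordinates.

## Cohort statistics

* **Group confidence intervals** use the $t$ quantile with $n-1$ degrees
  of freedom, $\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$. This convention was
  identified by reverse-engineering published group bounds from their
  printed mean/SD/$n$: the $t$ interval reproduces them after 2-decimal
  rounding, a normal-quantile interval does not.
* **Two-group comparisons** gate each group through Shapiro–Wilk at
  $\alpha = 0.05$; both normal → pooled-variance Student $t$ (Welch behind
  a flag), otherwise Mann–Whitney U with the normal approximation and tie
  correction. Categorical variables use Pearson chi-square *without*
  continuity correction. The chosen test is always reported. For groups
  above Shapiro's size limit a deterministic systematic subsample of 5000
  is tested. Zero-variance groups route to the rank test, and fully tied
  data return $p = 1$.
* **ROC analysis** is oriented so higher EBQ predicts subsidence.
  Thresholds are the midpoints between consecutive distinct scores plus
  $\pm\infty$ sentinels; the AUC is the midrank (Mann–Whitney) estimator,
  so ties count one half and the AUC equals the concordant-pair
  probability exactly; the 95% CI is DeLong's. The reported cutoff
  maximises Youden's $J$; ties on $J$ break toward higher specificity and
  then lower threshold — the specificity-first rule reflects the screening
  use of the score, where a specific operating point is the published
  convention.
* **Logistic regression** is the binomial GLM fitted by IRLS with a tight
  convergence tolerance (`epsilon = 1e-12`, so the score equations vanish
  to numerical precision), Wald standard errors from the inverse observed
  information, odds ratios $e^B$ with $e^{B \pm 1.96\,\mathrm{se}}$ CIs.
  Rank-deficient designs error naming the collinear columns; coefficients
  exceeding 15 per covariate-SD unit are treated as complete separation
  and error rather than returning meaningless Wald intervals.
* **No multiplicity correction** is applied anywhere, matching the
  analysis style this package reproduces; users comparing many variables
  should adjust downstream.

## The phantom generator

`generate_phantom()` rasterizes a schematic cervical sagittal slice:
`length(levels) + 1` vertebral bodies separated by disc spaces, a
posterior CSF column spanning all levels, and a subchondral band of the
configured depth against each endplate. Its purpose is narrow — to give the
EBQ estimator a target whose truth is known by construction — and two
design choices serve that purpose:

* the bands are painted through *the same* point-in-band predicate that
  `extract_band()` measures with, and the CSF through the same polygon
  test, so at zero noise the measured EBQ equals
  `tissue_means["endplate_band"] / tissue_means["csf"]` with no
  rasterization slack (the tests assert equality at `1e-12`);
* pixel values are per-tissue Gaussians plus additive Gaussian noise
  clipped at zero. Real T1W magnitude noise is Rician; at the
  signal-to-noise ratios of interest the Gaussian approximation is
  adequate for validating a ratio of means, and the clipped-Gaussian model
  keeps every moment analytic. The config records the noise model so a
  Rician variant could be added without changing the schema.

Default spacing is 0.5 mm/px, making the 3 mm band 6 px deep — coarse
enough that a whole phantom rasterizes in milliseconds, fine enough that
band geometry is non-trivial. Endplates are straight by default with an
optional sinusoidal bow (`curvature_amp_mm`), since nothing pins down a
canonical endplate shape. Schmorl lesions are half-discs indenting an
endplate; the ground truth keeps both the exact lesion pixel mask (used by
in-memory measurements) and a 64-gon outline (used by annotation files,
exact to within boundary pixels). One integer seed drives a single random
stream per phantom; identical config + seed is bit-identical.

## The cohort simulator and its calibration

`simulate_cohort()` draws, per patient: covariates (age, BMI, sex,
smoking, disc level), EBQ from a normal with optional per-level mean
shifts, then three dependent variables —

* **T-score** $= \alpha_t + \beta_t\,\mathrm{EBQ} + \varepsilon$, with a
  negative $\beta_t$ encoding the inverse EBQ–bone-density relation;
* **height loss** $= \alpha_h + \beta_h\,\mathrm{EBQ} + \varepsilon$;
* **subsidence** $\sim$ Bernoulli$(\mathrm{logit}^{-1}(a +
  b\,\mathrm{EBQ} + c\,T))$, with the latent probability returned
  alongside the outcome.

The defaults are calibrated once, in closed form or by
`calibrate_outcome_model()`, to a reference single-level ACDF cohort of
158 patients: marginal EBQ $4.31 \pm 1.15$, subsidence prevalence
$23/158$, subsided-group EBQ mean $5.38$, group T-scores $-0.84 / -1.62$
with marginal $-0.95 \pm 1.40$, and height loss $1.31 \pm 0.66$ mm with an
EBQ–loss correlation of $0.798$. The calibration solves two integral
equations (marginal prevalence and case mean) by nested root finding; the
linear models then follow algebraically from the target moments. Two
self-consistency facts make these defaults coherent rather than tuned:
the implied non-subsided EBQ mean, $(4.31 - p \cdot 5.38)/(1-p) = 4.128$,
matches the reference group, and the implied $P(\text{loss} > 2\,\text{mm})
= 0.148$ essentially equals the configured prevalence, so classifying the
simulated radiographic heights reproduces the logistic prevalence without
any coupling between the two mechanisms.

Default choices that the reference moments do not pin down: the outcome
model's T-score coefficient is 0 (its group contrast flows entirely
through EBQ; set `tscore_coef` to study direct effects), per-level EBQ
shifts are 0 (no published per-level distribution for subsided patients
exists to anchor them), preoperative segmental height is $38 \pm 3$ mm (a
typical two-body-plus-disc cervical span), and 10% of subsided patients
additionally show migration.

What the simulator deliberately does **not** reproduce: the group-specific
height-loss moments ($1.05 \pm 0.47$ vs $2.82 \pm 0.31$ mm). Height loss
here is linear in EBQ with homoscedastic noise — the model the correlation
target dictates — whereas the reference group moments imply loss depends
on the outcome beyond EBQ. One linear model cannot match the marginal
distribution, the correlation, *and* both group means; we keep the first
two and document the third as out of reach. Likewise the published AUC
(0.806), cutoff (4.70) and fitted ORs are patient-level quantities that
cannot be recomputed without the original cohort; simulated cohorts land
near them (the acceptance script reports the Monte-Carlo means) but tests
assert only oracle equivalence, parameter recovery, and direction.

## Numerical and testing choices

Problem sizes were chosen so the full suite runs in well under a minute of
useful work per property: phantoms are 64 × 64 px single-level for oracle
comparisons, noise recovery uses 100 phantom replicates, cohort
calibration and correlation recovery use 200 replicates of $n = 158$, and
logistic parameter recovery uses 200 replicates of $n = 5000$ with a
covariate design giving a balanced outcome (so the maximum-likelihood
small-sample bias is negligible against the Monte-Carlo standard error of
the replicate mean). Brute-force oracles — the per-pixel band test and the
$O(n_0 n_1)$ concordant-pair AUC — are written as deliberately naive loops
sharing no code with the implementation.

Degenerate inputs error early and name the offending object: empty band
masks, fully excluded ROIs, zero CSF signal, coincident landmarks,
single-class outcomes, rank-deficient designs, geometry that does not fit
the phantom canvas. Reporting precision is 2 decimals for EBQ in printed
output only; every stored or returned value is full precision.

## Known limitations

* 2-D only: mid-sagittal slice selection from a volume, and any
  through-plane partial-volume behaviour, are upstream of this package.
* No MRI physics: no bias fields, no Rician noise, no coil profiles; the
  phantom validates geometry and estimator algebra, not scanner realism.
* Whether the CSF reference polygon must lie posterior to T1's body or
  merely at that cranio-caudal station is not standardised; any annotated
  CSF polygon is accepted.
* The rater-discrepancy threshold's unit (EBQ units here) is a convention,
  not a standard; it is configurable.
* Passing tests on simulated cohorts demonstrate the statistical machinery
  and the generator's calibration, not clinical validity on real MRI data.
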