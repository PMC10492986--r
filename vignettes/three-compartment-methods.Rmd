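---
title: "Methods: segmentation, hemodynamics and the three-compartment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, hemodynamics and the three-compartment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodycomp3)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic-data tests establish.

## 1. Adipose segmentation

The segmentation follows the standard in-house recipe for fat/water-separated
neck-to-knee stacks: background removal on the combined fat/water image, fat
thresholding on the fat-fraction image, and a radial trace of the
subcutaneous ring.

Assumptions: the body cross-section is a single connected component and is
*star-convex about its centroid* — every centroid-anchored ray crosses the
subcutaneous ring once. Radial tracing from the image edge toward the
centroid is equivalent to tracing "from the edges of the image to the center"
for star-convex bodies and is better behaved when the body is off-center.
Lobed (non-convex in the ordinary sense, but still star-convex) inner
boundaries are handled and are exercised by the phantom generator.

Parameters, defaults and rationale:

| parameter | default | units | why |
|---|---|---|---|
| combined-signal threshold | Otsu | a.u. | bimodal body/background histogram; no threshold is specified by the upstream method description |
| `ff_threshold` | 0.5 | fat fraction | midpoint of a bimodal fat/water histogram |
| `max_hole_area` | 1000 | px | fills signal dropouts inside the body without closing the lung-scale cavities |
| `n_rays` | 360 | — | 1° angular resolution; boundary error is then dominated by pixel size |
| `step` | 0.5 | px | Nyquist for nearest-pixel sampling along a ray |
| `min_run` | 2 | samples | a single noisy pixel neither opens nor closes a boundary |
| `min_hit_frac` | 0.5 | — | below this the slice has no credible subcutaneous ring and is flagged |

Tie-break convention: the inner boundary is *open* for VAT and *closed* for
SAT — a fat pixel exactly on the inner contour is subcutaneous. Rays that
hit no fat are linearly interpolated in angle (wrapping at 2π). Degenerate
inputs return *flagged results*, not errors: an all-background slice, an
empty fat mask, or a fat mask with no visceral cavity (inner boundary
collapsed to the centroid) all propagate flags into the run report. Manual
contour editing in the original workflow is replaced by these QC flags; no
interactive editing is provided.

Volumes are voxel counts × voxel volume, summed over slices, in liters.
`NAT = total − SAT − VAT` is an identity, so compartment additivity is exact
up to floating-point associativity (~1e-16 relative).

## 2. QA-method pulse wave velocity

During reflection-free early systole, area tracks flow linearly,
`A(t) = A0 + Q(t)/PWV`, so PWV is the ratio of the time-gradients of Q and A.
With Q in mL/s and A in mm² the ratio is numerically m/s
(1 mL/s per mm² = 1000 mm³/s per mm² = 1 m/s); no further unit conversion is
needed.

The upstream description leaves two things open; both are explicit,
configurable choices here:

* **Robust regression flavor** — Huber loss with tuning constant 1.345
  (`MASS::rlm`), the standard robust default, degrading gracefully to OLS
  (`method = "ols"` available).
* **"Initial linear segment"** — expanding window from the upstroke foot
  (first sample ≥ 5% of peak flow), grown while both Q-on-t and A-on-t OLS
  fits keep R² ≥ 0.98; minimum 4 samples, maximum 40% of systole. The
  4-sample minimum is always used even when noise pushes R² below the
  criterion (the window is then flagged `low_linearity`) — a noisy cycle
  still yields an estimate rather than an error. One rule is applied to
  ascending- and descending-aorta curves alike.

Degenerate inputs: flat or non-positive flow raises an estimation error
("no upstroke"); an area excursion below `min_delta_a` (1e-6 mm²) raises an
"incompressible segment" error. A least-squares slope is linear in the
responses, so when `A = A0 + Q/PWV` holds exactly over the window the
estimator is exact regardless of the curvature of Q(t) itself — this is why
the noise-free recovery tolerance is 1e-6 rather than "small".

Mean blood pressure may be measured or derived as `DBP + PP/3`; derived
values are flagged (`mbp_derived`) because oscillometric MBP and the
one-third rule differ systematically.

## 3. Anthropometry

LMS z-scores use the standard closed form with the L→0 logarithmic limit
(cut at |L| < 1e-7) and linear interpolation of L, M, S in age within sex —
the usual LMS practice, giving z continuous in age. The inverse transform is
exact to round-off (round-trip tested at 1e-9 relative).

The bundled reference (`lms_synthetic.csv`, also constructible in code via
`synthetic_lms_reference()`) is *synthetic*: smooth L/M/S curves over ages
10–22 whose magnitudes are plausible for adolescents, calibrated once so
that the default synthetic cohort splits roughly half normal-weight and half
overweight/obese. It is not a growth standard, carries no epidemiological
meaning, and exists so the computation is fully testable offline. Published
WHO/waist references drop in as CSVs with the same schema
(`measure, sex, age_years, L, M, S`).

Weight-status boundaries are exactly as printed: z ≤ −2 out-of-range
(flagged), −2 < z ≤ 1 normal, z > 1 overweight/obese.

## 4. The three-compartment statistical model

**Zero-skewness log transform.** `lnskew0(x)` finds k with
`skewness(ln(x − k)) = 0` by root-finding (bisection bracket
`[min(x) − 1e6·range, min(x) − 1e-9·range]`, then Newton polishing to
|skewness| < 1e-8). Negative skew uses the mirrored form `ln(k − x)`. For a
sample already zero-skew to tolerance no finite root exists (the criterion
function is one-sided), so the shift is taken far enough that the transform
is numerically affine, choosing among candidate magnitudes the one that best
preserves zero skewness. The transform is triggered automatically when
|sample skewness| > 0.5 — the upstream description says only "any
nonparametrically distributed data", so the trigger is an explicit choice,
overridable per call (`transform = "always"/"never"`).

**Residualization order.** Following the lipid-spillover hypothesis (lipids
fill SAT first, spilling into VAT when SAT capacity is exceeded):
`rSAT = resid(SAT | NAT)`, then `rVAT = resid(VAT | NAT, rSAT)`. OLS
residuals are orthogonal to the regressors and the constant by the normal
equations, so NAT, rSAT, rVAT are pairwise uncorrelated to machine precision
on every valid input — this is a construction property, not a sampling one.
The residualizing regressions deliberately contain *only* tissue terms (the
literal reading of "after nonadipose tissue was accounted for"); age and sex
enter the final association models instead. Including age/sex in the
residualization is a one-line change (`residualize`'s covariate set) kept
available for sensitivity analyses.

**Standardized associations.** Outcomes and continuous predictors are
z-scored before fitting; binary sex is centered only, so its coefficient
remains interpretable per category. The reported `r` is by default the
*standardized coefficient* in the joint model. Whether published tables of
this kind report standardized slopes or partial correlations is genuinely
ambiguous; both are implemented (`r_type = "std_beta"` / `"partial_r"`,
the latter via the Frisch–Waugh residual-correlation construction), they
coincide for a single predictor without covariates, and the default is the
standardized slope because it reproduces |r| ≤ 1 behavior in the joint
model. p values are two-sided from the t distribution with residual degrees
of freedom; no multiplicity correction beyond the fixed P<0.01 significance
threshold (0.01 ≤ p < 0.05 is reported as "trend"). Missingness is handled
by listwise deletion.

## 5. What the synthetic generators do and do not establish

The generators define the package's *stated world*:

* **Phantoms** are ellipses (default semiaxes 160×120 mm, ring 25–30 mm,
  3×3×10 mm voxels as in the imaging protocol) with optional asymmetric ring
  thickness, lobed inner boundaries and circular visceral blobs. Ground
  truth is counted from the drawn masks, so recovery error measures the
  algorithm, not rasterization. They contain no coil shading, chemical-shift
  artifacts, bones, organs or arms — a green recovery test says the tracer
  finds star-convex boundaries under Gaussian fat-fraction noise (sd 0.05),
  not that it segments a real abdomen.
* **Waveforms** enforce `A = A0 + Q/PWV` exactly before the reflection
  onset (default half of a 300 ms systole, 9.6 ms sampling as acquired) and
  then add a raised-cosine area bump (35% of the systolic excursion). Only
  the *existence* of the post-onset nonlinearity matters: it verifies the
  window stops in time. Real reflected waves also distort Q, arrive
  dispersed, and vary beat to beat.
* **Cohorts** draw latent standardized compartment scores from a correlated
  trivariate normal (NAT–SAT 0.5, NAT–VAT 0.35, SAT–VAT 0.6), plant a
  standardized effect matrix on the latent scale with residual variance
  chosen for unit outcome variance, and map to raw scales anchored to
  magnitudes typical of an adolescent neck-to-knee cohort (e.g. NAT
  34 ± 6.5 L, SAT median ≈ 15 L as a 2 L-shifted lognormal, SBP 113 ± 8
  mm Hg). Age is uniform on 13–18 years per the recruitment range; sex is
  binary with 44% female; the 3 obesity-clinic recruits are the highest-BMI-z
  subjects. The default effect matrix plants the qualitative sign pattern of
  the published 3-compartment analysis (NAT→LV mass +0.8, SAT→E/A −0.48,
  VAT→nothing, etc.); it is an emulation for testing, not a reproduction —
  the original cohort data are not public, so no generated number should be
  read as a reimplementation of the published coefficients. Skewed variables
  are shifted lognormals so the `lnskew0` stage has a known closed-form
  answer (shift recovery is the test).

Because pulse pressure and mean BP are derived from generated SBP/DBP, the
pressure identities hold exactly in every cohort; the effect matrix
addresses SBP and DBP directly.

## 6. Numerical tolerances in the test suite

* Compartment orthogonality and Gram–Schmidt equivalence: 1e-10.
* `lnskew0` transformed skewness: 1e-6 (criterion met by root-finding at
  1e-8).
* Noise-free PWV recovery: 1e-6; formula operations: 1e-12 relative.
* Phantom volume recovery: 5% noise-free, 10% at fat-fraction noise sd 0.05;
  rotation by 30° changes volumes < 2% (tested at 3 mm pixels — at coarser
  resolution, small-blob VAT rasterization jitter alone can exceed this).
* Type-I calibration of the P<0.01 rule: 1% ± 1% over 500 null replicates of
  n = 5000; planted effects ±0.05 at n = 2000 (averaged over 5 replicate
  cohorts to keep the check insensitive to the particular seed).

## 7. Known limitations

* The segmentation assumes star-convexity about the centroid; a deeply
  folded panniculus or a body touching the image border violates it.
* No DICOM ingestion and no T2* fitting: inputs are already-reconstructed
  fat-fraction and combined-signal stacks (NIfTI-1 or in-memory arrays; the
  NIfTI reader/writer is minimal and little-endian only).
* The LMS reference shipped is synthetic; real analyses must supply
  published tables.
* Association models are cross-sectional OLS with age/sex adjustment — no
  mixed models, mediation, or causal claims, and no allometric scaling of
  cardiovascular outcomes (deliberately, matching the source methodology).
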