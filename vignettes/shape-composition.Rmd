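---
title: "Modelling 3D body shape from body composition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling 3D body shape from body composition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecomp)
```

## The problem

Body-image research needs stimuli whose size and shape are *biometrically
valid*: a body presented as "X kg of fat, Y kg of muscle" should look like
bodies that actually have that composition. BMI-indexed body scales cannot
deliver this, because BMI collapses adiposity and muscularity into one
number. `shapecomp` implements the statistical machinery for two-dimensional
composition-calibrated shape models, and a synthetic-data engine rich enough
to exercise every stage of the pipeline end to end.

## The shape model and its assumptions

The core model is linear throughout:

1. **Correspondence** is assumed given: each cohort shares a mesh topology
   in which vertex *i* is the same anatomical point on every identity.
   Establishing correspondence (template wrapping, landmarking) is outside
   the package's scope.
2. **Rigid alignment.** Every shape is fitted to the cohort consensus by
   translation and proper rotation only. Scaling is *not* removed: size is
   part of the signal when shape is to be predicted from mass. Reflections
   are excluded (bodies must not mirror), so the orthogonal-Procrustes SVD
   solution is corrected by flipping the smallest singular direction
   whenever its determinant is negative.
3. **PCA.** Aligned, flattened shape vectors are mean-centred (no
   per-coordinate rescaling — all coordinates share units, cm) and
   decomposed by SVD. With *c* identities the centred matrix has rank at
   most *c* − 1, and all nonzero-variance dimensions are retained by
   default. Variance-fraction truncation exists (`var_fraction`) but is off:
   dropping low-variance dimensions is an efficiency device, not part of
   the model.
4. **Per-dimension OLS.** Identity scores on each principal dimension are
   regressed (with intercept) on the chosen predictors — fat and muscle
   mass in kg, or BMI alone; the BMI comparator is the identical code path
   with one predictor. Coefficients are deliberately *not* standardized
   (slopes are cm of shape change per kg) and no significance filter is
   applied: an unrelated dimension simply gets near-zero slopes.

The key assumption is linearity of shape in composition over the observed
range. The model refuses to assert anything outside the training range: the
default prediction policy clamps out-of-range predictor values to the
observed min/max with a warning (`clamp = "refuse"` and `"allow"` are
available for stricter or exploratory use).

### Morphing individuals

Predicting a *change* for a specific person applies the score difference
between target and current composition to the individual's own shape
vector. Because the map is affine, morphing is exactly additive and
invertible, and morphing the mean shape from the predictor means coincides
with direct prediction — both properties are tested.

## Evaluation by leave-one-out

Model comparison refits everything — consensus, PCA, regressions — on each
fold's *n* − 1 training identities for both predictor sets, so no
information from the held-out scan leaks into either model. The held-out
scan is aligned to the fold's own consensus mean (a `heldout_align =
"full_mean"` switch exists for the cheaper variant; strict fold hygiene is
the default). Error is the mean straight-line 3D distance over torso
vertices only: arm and leg placement varies idiosyncratically between scans
and would otherwise dominate the error. The paired comparison reports
t on `error_B − error_A` (positive t favours model A), two-tailed p, and
Cohen's d_z = t/√n; if the two error vectors are identical the degenerate
result is defined as t = 0, p = 1. Per-vertex error heatmaps normalise both
models' errors by their *shared* maximum for an identity (all-zero maps when
both predictions are exact), and can be written into PLY files as a
per-vertex `error_prop` property.

## Psychophysics outcome model

The 2D method-of-adjustment task is summarised per dimension by the mean of
the accepted settings (PSE) and their sample SD (DL, *n* − 1 denominator —
the choice matters slightly for the shape of the precision curve and is
fixed and documented). The trial simulator is the minimal classical
assumption: settings are bivariate Gaussian around the internal PSE;
recorded start points are inert, since anchoring is not modelled.
`dl_variability_curve()` maps the precision of the DL estimate against
trial count by pure Monte Carlo (defaults: target DLs 0.5/1/2 kg, 5–90
trials, 10,000 resamples). For normal data the sample SD has known moments
— mean σ·c4(n), SD σ·√(1 − c4(n)²) — which the tests use as an independent
closed-form oracle; the implementation itself stays simulation-based.

## Multivariate outcome analysis

Because measured fat and muscle are correlated (0.45 in men, 0.38 in women
in the reference cohorts), the two outcome dimensions are analysed jointly
in the multivariate linear model Y = XB + E. Per-predictor MANOVA uses a
single-row Type III contrast: H = (LB̂)ᵀ(L(XᵀX)⁻¹Lᵀ)⁻¹(LB̂),
Λ = det(E)/det(E + H); for a one-row contrast Rao's F transform of Λ is
exact, so no approximation error enters. Only Wilks' Λ is provided. p
values are two-tailed and uncorrected. `shift_vectors()` produces the
measured→predicted arrow table; when inputs are z-scored the arrows are in
z-score units, the fit itself being scale-free.

## Measurement statistics

The composition-validation helpers follow standard kinanthropometric
practice: the ISAK repeat rule (mean of two skinfold measures, median of
three when the first two differ by ≥ 5%; the package evaluates the relative
difference against their mean, a choice that had to be fixed since the rule
itself does not name a denominator), the four-site skinfold equations,
Bland–Altman limits of agreement with the multiplier fixed at 1.96, and the
intraclass correlation. The ICC variant is two-way, absolute-agreement,
single-measurement — the natural choice for same-device test–retest — with
the consistency variant available as an option.

## The synthetic-data engine

The generator is the package's study-condition definition, not a tuning
knob; its defaults were fixed once, as follows.

**Composition.** (fat, muscle) pairs are bivariate normal, truncated at
physiological floors (fat ≥ 2 kg, muscle ≥ 15 kg). Naively sampling with
the target parameters and rejecting below-floor draws would bias the output
(with male parameters the fat mean shifts by ≈ +0.7 kg and the fat–muscle
correlation drops from 0.45 to ≈ 0.41), so the sampler moment-matches: it
solves — by semi-analytic truncated-moment integrals and BFGS — for latent
parameters whose *truncated* distribution has the configured means, SDs and
correlation. Defaults are the published adult reference values (women: fat
17.65 ± 7.92 kg, muscle 26.34 ± 2.79 kg, height 164.63 ± 6.29 cm, r = 0.38;
men: fat 14.53 ± 7.39 kg, muscle 39.55 ± 5.61 kg, height 179.41 ± 6.80 cm,
r = 0.45). Weight is fat + muscle + a residual mass affine in height (slope
0.30 kg/cm, noise SD 1.5 kg), with intercepts (20.57 kg women, 27.52 kg
men) chosen so mean BMI reproduces the reference means; BMI is then
computed, never drawn.

**Meshes.** A deterministic, stylised body (elliptical torso with
shoulder/waist profile, cylindrical limbs) defines the correspondence. Each
identity is `base + FATM·d_fat + SMM·d_muscle + noise`, then a small random
rigid transform (±5°, ±2 cm by default) simulating pose variation. The
displacement fields are smooth radial fields: fat loads mainly on the torso
with a waist emphasis (0.085 cm/kg peak scale), muscle on limbs and
shoulder girdle (0.12 cm/kg). Surface noise is 0.3 cm SD per coordinate,
comparable to a realistic correspondence error and well below
between-identity shape variation. Two presets exist: `small` (600 retained
vertices — 280 torso, 4 × 80 limbs) for tests, and `full` (79,522 raw
vertices; 26,665 retained of which 12,697 torso) matching the
full-resolution layout, so a retained shape flattens to 79,995 numbers.

What the generator does **not** emulate: anatomically realistic body
surfaces, nonlinear or depot-specific fat deposition, sex- or age-specific
deposition patterns, pose articulation beyond rigid jitter, and
correspondence error beyond i.i.d. noise. Passing tests therefore
demonstrate the correctness of the *pipeline* under the model's own linear
assumptions — not that real bodies are linear in composition, nor that
real-scan error magnitudes are reproduced.

**Scenarios.** The toy outcome scenarios encode their true coefficient
matrices exactly (self-estimate: intercepts 1, unit self-mapping, 0.5
psychometric effect on the muscle estimate; ideal: intercepts −2.5/+2.5,
own-body slopes 0.1), with standardized predictors (fat–muscle covariance
0.45, independent psychometric score) and residual SD 0.4 — a value giving
realistically noisy but clearly recoverable structure; n defaults to 100,
with n = 20,000 used for parameter-recovery checks.

**Simpson demo.** The BMI-stratified cohort draws height and BMI, converts
to weight, splits the non-residual mass by a noisy fat fraction (mean 0.28,
SD 0.09) with muscle as a fraction (0.75 ± 0.02) of the remainder, and
rejection-samples 100 men into each of the five BMI bands 15–19 … 31–35. At
fixed BMI the disposable mass is nearly fixed, so a larger fat share
directly takes from muscle (negative within-band association), while across
bands both grow with total mass (positive marginal association). The split
fractions were set, once, at design time so the sign pattern is stable
across seeds; exact covariances behind the published version of this
illustration are not available, so only the qualitative inversion is
asserted.

## Numerical choices

* PCA signs are fixed by making each component's largest-magnitude loading
  positive — determinism for tests; any sign convention is statistically
  equivalent.
* Rank is decided at singular values above `1e-10 ×` the largest.
* The consensus procedure defaults to a single centre/average/align pass;
  full generalized-Procrustes iteration (tolerance 1e-6 cm, cap via
  `iterations`) is available but changes results only marginally for
  well-posed cohorts. Whether to iterate is genuinely open; the single-pass
  default matches the simplest published description of the procedure.
* Flattening interleaves (x, y, z) per vertex in ascending index order, so
  one vertex's error is a contiguous triple; the convention is arbitrary
  but fixed, and flatten/unflatten are bit-exact inverses.
* Degenerate cases are defined, not left to NaN: identical error vectors
  give t = 0, p = 1; an all-exact heatmap is all zeros; a single adjustment
  trial yields an NA DL with a warning; zero between-subject variance makes
  the ICC NA with a warning.
* Mesh I/O supports ASCII OBJ and ASCII/binary-little-endian PLY with an
  optional `error_prop` float property; region labels travel in a sidecar
  CSV because neither format has a standard per-vertex tag channel.

## Problem sizes in the test suite

The suite runs the full pipeline at deliberately modest scale: LOO
comparison on a 60-identity, 600-vertex male cohort; parameter recovery at
n = 20,000; composition calibration at n = 50,000; DL curves at 10,000
resamples; the full-resolution preset is built once to verify the
structural constants (79,522 / 26,665 / 12,697 / 79,995). These sizes give
sampling error comfortably inside each check's tolerance while keeping the
suite quick.

## Known limitations

* Linearity is assumed, not tested, at the extremes; the model clamps
  rather than extrapolates by default.
* No segmental (per-limb) composition predictors; no nonlinear mappings.
* The rigid-alignment step can leave a small rotation between an identity
  and the consensus even for noiseless linear cohorts (alignment optimises
  fit, not linearity); reconstruction through the aligned pipeline is
  therefore exact only to alignment precision (~1e-4 cm RMS at test scale),
  while the unaligned fit is exact to machine precision.
* Wilks-only MANOVA; no mixed-model or repeated-measures extensions.
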