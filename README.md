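# shapecomp

Statistical models of 3D body shape, calibrated for body composition.

Most body-image assessment tools show observers a sequence of bodies that
vary along a single axis — body mass index. But BMI confounds two distinct
components of body composition, adiposity and muscularity: two people with
identical BMI can have very different bodies, and across a population the
fat–muscle relationship even reverses sign once you condition on BMI
(Simpson's paradox). `shapecomp` implements the full analysis pipeline for
building and evaluating *two-dimensional* body-shape models in which 3D
shape is predicted jointly from total fat mass (FATM, kg) and skeletal
muscle mass (SMM, kg), for researchers in body-image psychophysics,
eating-disorder assessment and anthropometrics.

## The model

Given a cohort of c corresponded body meshes (identical vertex count and
ordering) and per-identity composition measures:

1. **Alignment.** Each shape is rigidly fitted (translation + proper
   rotation only, no scaling — size carries shape information) to the
   cohort's consensus mean by partial Procrustes superimposition.
2. **PCA + regressions.** Aligned shapes are flattened to vectors (26,665
   retained points × 3 coordinates = 79,995 numbers at full resolution) and
   decomposed by PCA into a subspace of c − 1 dimensions. For each
   dimension *separately*, the identity scores are regressed on the
   predictors by OLS:

   score_j = β0_j + β1_j · FATM + β2_j · SMM + ε

   All dimensions are kept regardless of significance; a shape for any
   (FATM, SMM) pair is reconstructed as mean + Σ_j scorê_j · PC_j, and an
   individual's own scan can be morphed by applying the predicted score
   *change* between two composition states.
3. **Evaluation.** Leave-one-out: the held-out scan is predicted from its
   measured composition by a model refit on the remaining identities, and
   compared against a BMI-only model via the mean straight-line 3D error
   over the torso, with a paired t test and Cohen's d_z = t/√n.
4. **Outcome analysis.** The 2D method-of-adjustment task yields per-trial
   (fat, muscle) settings; their mean estimates the point of subjective
   equality (PSE) and their SD the difference limen (DL). Outcomes are
   analysed with the multivariate linear model Y = XB + E and per-predictor
   Wilks' Λ = det(E)/det(E + H) MANOVA tests.

A synthetic-data engine generates corresponded mesh cohorts whose geometry
varies linearly in known fat/muscle displacement fields, with composition
distributions calibrated to published adult reference values (fat–muscle
correlations 0.45 in men, 0.38 in women), so every stage of the pipeline can
be exercised and verified without access to scan data.

## Worked example

```r
library(shapecomp)

# a synthetic male cohort: 40 identities, 600-vertex meshes
coh <- generate_cohort(synth_config("male", n = 40, preset = "small", seed = 2024))

# does the FATM/SMM model predict shape better than BMI?
loo_compare(coh$meshes, coh$records, model_a = c("fatm", "smm"), model_b = "bmi")
#> <loo_result: n = 40>
#>   model A [fatm+smm]: M = 0.497, SD = 0.018 cm
#>   model B [bmi]: M = 0.606, SD = 0.178 cm
#>   paired t(39) = 4.088, p = 0.00021, Cohen's d_z = 0.65
```

The composition model's mean torso error (0.497 cm) is significantly below
the BMI model's (0.606 cm): positive t favours the two-predictor model.

```r
# method-of-adjustment outcomes: PSE = mean setting, DL = SD of settings
est <- estimate_adjustment(
  simulate_adjustment(true_pse = c(14.5, 39.6), true_dl = c(2, 1.5),
                      trial_corr = 0.45, n_trials = 40, seed = 3))
est
#> <adjustment_estimate (40 trials): PSE fat 14.39 kg, muscle 39.61 kg;
#>  DL fat 1.67 kg, muscle 1.43 kg>

# toy self-estimate scenario: multivariate regression recovers the truth
d <- scenario_data(scenario_spec("self_estimate", n = 20000, seed = 1))
fit <- fit_mvlm(d$X, d$Y)
round(fit$B_hat, 3)
#>             est_fat est_muscle
#> (Intercept)   1.001      0.999
#> fat           1.003     -0.003
#> muscle        0.001      1.003
#> psych         0.003      0.504
wilks_test(fit, "psych")
#> <wilks_test 'psych': lambda = 0.3856, F(2, 19995) = 15926.271, p = 0>
```

The recovered coefficients match the simulation (overestimation of both
masses by 1 unit; a 0.5 psychometric contribution to the muscle estimate),
and the psychometric covariate is — as designed — strongly significant in
the self-estimate scenario.

Measurement-validation utilities are included: `isak_value()` (skinfold
repeat consolidation), `jackson_pollock_bodyfat()` (four-site equations,
e.g. male, S = 50 mm, age 30 → 12.38 %), `bland_altman()` and
`icc_agreement()`.

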