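Package: shapecomp
Title: Biometrically Calibrated Statistical Models of 3D Body Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds statistical models of corresponded 3D body-shape meshes as a
    function of body composition (total fat mass and skeletal muscle mass).
    Provides rigid (translation + rotation, size-preserving) Procrustes alignment
    to a consensus shape, PCA-plus-regression shape synthesis and individual
    morphing, leave-one-out comparison of composition-based versus BMI-based
    shape prediction with paired statistics and per-vertex error maps, a
    method-of-adjustment psychophysics outcome model (point of subjective
    equality and difference limen) with Monte Carlo precision curves,
    multivariate multiple regression with Wilks' lambda tests for
    two-dimensional body-composition outcomes, body-composition measurement
    statistics (four-site skinfold equations, ISAK repeat consolidation,
    Bland-Altman agreement, intraclass correlation), and a synthetic-data
    engine generating corresponded mesh cohorts with known fat/muscle
    displacement fields plus toy-scenario and Simpson's-paradox simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
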