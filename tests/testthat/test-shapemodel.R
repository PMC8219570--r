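# shared small fixture: aligned noiseless cohort with linear ground truth
fixture_model <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) {
      cc <- noiseless_cohort(n = 12)
      cons <- build_consensus(cc$meshes)
      shapes <- flatten_cohort(cons$aligned)
      coh <<- list(cohort = cc, cons = cons, shapes = shapes,
                   model = fit_shape_model(shapes, cc$records))
    }
    coh
  }
})

test_that("the PCA subspace has at most c - 1 dimensions and conserves variance", {
  fx <- fixture_model()
  model <- fx$model
  expect_lte(ncol(model$basis), nrow(fx$cohort$records) - 1)
  expect_equal(crossprod(model$basis), diag(ncol(model$basis)),
               tolerance = 1e-8, ignore_attr = TRUE)
  Xc <- sweep(unclass(fx$shapes), 2, colMeans(fx$shapes))
  expect_equal(sum(model$singular_values^2), sum(Xc^2), tolerance = 1e-6)
})

test_that("PCA scores and loadings match a brute-force eigendecomposition", {
  set.seed(31)
  meshes <- lapply(1:7, function(i) random_mesh(10, paste0("id", i)))
  shapes <- flatten_cohort(meshes)
  comp <- data.frame(fatm = rnorm(7, 15, 5), smm = rnorm(7, 30, 4))
  model <- fit_shape_model(shapes, comp)
  Xc <- sweep(unclass(shapes), 2, colMeans(shapes))
  eig <- eigen(crossprod(Xc), symmetric = TRUE)
  k <- ncol(model$basis)
  expect_equal(model$singular_values^2, eig$values[1:k], tolerance = 1e-8)
  for (j in 1:k)     # loadings agree up to sign
    expect_equal(abs(sum(model$basis[, j] * eig$vectors[, j])), 1,
                 tolerance = 1e-8)
  # scores are the centred data in the basis
  expect_equal(model$scores, Xc %*% model$basis, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a noiseless linear cohort is reproduced exactly from composition", {
  fx <- fixture_model()
  rec <- fx$cohort$records
  # jitter-free meshes need no alignment: fit on the raw cohort, where the
  # composition -> shape map is exactly linear
  model <- fit_shape_model(flatten_cohort(fx$cohort$meshes), rec)
  for (i in c(1, 5, 12)) {
    pred <- predict_shape(model, c(rec$fatm[i], rec$smm[i]), clamp = "allow")
    rms <- sqrt(mean((pred$vertices - fx$cohort$meshes[[i]]$vertices)^2))
    expect_lt(rms, 1e-6)
  }
  # after consensus alignment the same reproduction holds to alignment
  # precision
  for (i in c(1, 12)) {
    pred <- predict_shape(fx$model, c(rec$fatm[i], rec$smm[i]), clamp = "allow")
    rms <- sqrt(mean((pred$vertices - fx$cons$aligned[[i]]$vertices)^2))
    expect_lt(rms, 1e-4)
  }
  # reconstructing a training identity from its own scores is exact
  v <- fx$model$mean_vector + drop(fx$model$basis %*% fx$model$scores[3, ])
  expect_equal(v, flatten_mesh_for_test(fx$cons$aligned[[3]], fx$model$topology),
               tolerance = 1e-8)
})

test_that("prediction at the predictor means returns the mean shape", {
  fx <- fixture_model()
  rec <- fx$cohort$records
  pred <- predict_shape(fx$model, c(mean(rec$fatm), mean(rec$smm)),
                        clamp = "allow")
  mean_mesh <- unflatten(fx$model$mean_vector, fx$model$topology)
  expect_equal(pred$vertices, mean_mesh$vertices, tolerance = 1e-9)
  # and equals the brute-force mean of the per-identity scores route
  expect_equal(drop(c(1, mean(rec$fatm), mean(rec$smm)) %*% fx$model$coefficients),
               colMeans(fx$model$scores), tolerance = 1e-8)
})

test_that("prediction is linear in the predictors and honours clamp policies", {
  fx <- fixture_model()
  model <- fx$model
  rg <- model$training_ranges
  a <- rg["min", ] * 0.7 + rg["max", ] * 0.3
  b <- rg["min", ] * 0.2 + rg["max", ] * 0.8
  al <- 0.35
  lhs <- predict_shape(model, al * a + (1 - al) * b, clamp = "allow")$vertices
  rhs <- al * predict_shape(model, a, clamp = "allow")$vertices +
    (1 - al) * predict_shape(model, b, clamp = "allow")$vertices
  expect_equal(lhs, rhs, tolerance = 1e-9)
  beyond <- rg["max", ] + c(10, 10)
  expect_warning(out <- predict_shape(model, beyond), "clamp")
  at_max <- predict_shape(model, rg["max", ], clamp = "allow")
  expect_equal(out$vertices, at_max$vertices, tolerance = 1e-12)
  expect_error(predict_shape(model, beyond, clamp = "refuse"), "range error")
})

test_that("degenerate model inputs raise informative errors", {
  set.seed(32)
  meshes <- lapply(1:5, function(i) random_mesh(8, paste0("id", i)))
  shapes <- flatten_cohort(meshes)
  comp <- data.frame(fatm = rnorm(5, 15, 4), smm = rep(30, 5))
  expect_error(fit_shape_model(shapes, comp, c("fatm", "smm")),
               "collinearity")
  expect_error(fit_shape_model(shapes[1:3, ], comp[1:3, ], c("fatm", "smm")),
               "insufficient-data|rows")
  expect_error(fit_shape_model(shapes, comp, character(0)), "nonempty")
})

test_that("a BMI-only model runs through the same code path", {
  fx <- fixture_model()
  model <- fit_shape_model(fx$shapes, fx$cohort$records, predictors = "bmi")
  expect_identical(model$predictor_names, "bmi")
  expect_equal(nrow(model$coefficients), 2)
  pred <- predict_shape(model, mean(fx$cohort$records$bmi), clamp = "allow")
  expect_equal(pred$vertices, unflatten(model$mean_vector, model$topology)$vertices,
               tolerance = 1e-9)
})

test_that("morphing applies shape change relative to the individual", {
  fx <- fixture_model()
  model <- fx$model
  indiv <- fx$cons$aligned[[2]]
  rec <- fx$cohort$records[2, ]
  cur <- c(rec$fatm, rec$smm)
  # target = current: identity
  same <- morph_individual(model, indiv, cur, cur)
  expect_equal(same$vertices, indiv$vertices, tolerance = 1e-12)
  # morph there and back: identity
  tgt <- cur + c(5, -2)
  back <- morph_individual(model,
                           morph_individual(model, indiv, cur, tgt, clamp = "allow"),
                           tgt, cur, clamp = "allow")
  expect_equal(back$vertices, indiv$vertices, tolerance = 1e-9)
  # morphing the mean shape from the predictor means equals direct prediction
  mean_mesh <- unflatten(model$mean_vector, model$topology)
  mm <- c(mean(fx$cohort$records$fatm), mean(fx$cohort$records$smm))
  via_morph <- morph_individual(model, mean_mesh, mm, tgt, clamp = "allow")
  direct <- predict_shape(model, tgt, clamp = "allow")
  expect_equal(via_morph$vertices, direct$vertices, tolerance = 1e-9)
  wrong <- random_mesh(10)
  expect_error(morph_individual(model, wrong, cur, tgt), "correspondence")
})

test_that("held-out reconstruction error approaches the noise floor", {
  noise_sd <- 0.25
  coh <- generate_cohort(synth_config("male", n = 40, noise_sd = noise_sd,
                                      jitter_rot_deg = 0, jitter_trans_cm = 0,
                                      seed = 33))
  cons <- build_consensus(coh$meshes)
  shapes <- flatten_cohort(cons$aligned)
  rms <- vapply(1:5, function(i) {
    model <- fit_shape_model(shapes[-i, ], coh$records[-i, ])
    rec <- coh$records[i, ]
    pred <- predict_shape(model, c(rec$fatm, rec$smm), clamp = "allow")
    sqrt(mean(rowSums((pred$vertices - cons$aligned[[i]]$vertices)^2)))
  }, 1.0)
  # per-point RMS error of pure coordinate noise is noise_sd * sqrt(3)
  expect_gt(mean(rms), noise_sd * sqrt(3) * 0.9)
  expect_lt(mean(rms), noise_sd * sqrt(3) * 1.35)
})
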