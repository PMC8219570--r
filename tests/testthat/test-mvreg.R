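test_that("multivariate OLS recovers exact coefficients and matches lm at r = 1", {
  set.seed(51)
  n <- 40
  X <- cbind(1, matrix(rnorm(n * 2), n, 2))
  colnames(X) <- c("(Intercept)", "a", "b")
  B0 <- rbind(c(1, -2), c(0.5, 3), c(-1, 0))
  Y <- X %*% B0
  fit <- fit_mvlm(X, Y)
  expect_equal(fit$B_hat, B0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(max(abs(fit$E_sscp)), 1e-18)
  # normal equations hold
  expect_equal(crossprod(X) %*% fit$B_hat, crossprod(X, Y), tolerance = 1e-8,
               ignore_attr = TRUE)
  # r = 1 equals the univariate lm oracle including SE, t, p
  y <- Y[, 1] + rnorm(n)
  f1 <- fit_mvlm(X, matrix(y, ncol = 1))
  or <- summary(lm(y ~ X[, 2] + X[, 3]))$coefficients
  expect_equal(unname(f1$B_hat[, 1]), unname(or[, "Estimate"]), tolerance = 1e-10)
  expect_equal(unname(f1$se[, 1]), unname(or[, "Std. Error"]), tolerance = 1e-10)
  expect_equal(unname(f1$t_values[, 1]), unname(or[, "t value"]), tolerance = 1e-10)
  expect_equal(unname(f1$p_values[, 1]), unname(or[, "Pr(>|t|)"]), tolerance = 1e-10)
  expect_equal(unname(f1$sigma_hat[1, 1]), summary(lm(y ~ X[, -1]))$sigma^2,
               tolerance = 1e-10)
  # rank deficiency is a collinearity error naming the column
  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_mvlm(Xbad, Y), "collinearity")
})

test_that("fitting is invariant to outcome ordering", {
  set.seed(52)
  n <- 30
  X <- cbind(1, rnorm(n), rnorm(n))
  Y <- cbind(y1 = rnorm(n), y2 = rnorm(n))
  f12 <- fit_mvlm(X, Y)
  f21 <- fit_mvlm(X, Y[, c(2, 1)])
  expect_equal(unname(f12$B_hat[, c(2, 1)]), unname(f21$B_hat), tolerance = 1e-12)
  expect_equal(unname(f12$E_sscp[c(2, 1), c(2, 1)]), unname(f21$E_sscp),
               tolerance = 1e-10)
})

test_that("Wilks' lambda matches a determinant oracle and car::Anova", {
  set.seed(53)
  n <- 12
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "a", "b")
  Y <- cbind(X %*% c(1, 0.8, 0) + rnorm(n, sd = 0.7),
             X %*% c(0, 0.3, -0.5) + rnorm(n, sd = 0.7))
  fit <- fit_mvlm(X, Y)
  wt <- wilks_test(fit, "a")
  # oracle 1: assemble SSCPs explicitly from full and reduced fits
  E_full <- crossprod(Y - X %*% solve(crossprod(X), crossprod(X, Y)))
  Xr <- X[, c(1, 3)]
  E_red <- crossprod(Y - Xr %*% solve(crossprod(Xr), crossprod(Xr, Y)))
  lambda_oracle <- det(E_full) / det(E_full + (E_red - E_full))
  expect_equal(wt$lambda, lambda_oracle, tolerance = 1e-10)
  expect_gt(wt$lambda, 0)
  expect_lte(wt$lambda, 1)
  # oracle 2: stats::anova.mlm model comparison on the same data
  d <- data.frame(a = X[, 2], b = X[, 3])
  mod <- lm(Y ~ a + b, data = d)
  an <- anova(mod, lm(Y ~ b, data = d), test = "Wilks")
  expect_equal(wt$lambda, an$Wilks[2], tolerance = 1e-8)
  expect_equal(wt$F, an$`approx F`[2], tolerance = 1e-8)
  expect_equal(wt$p, an$`Pr(>F)`[2], tolerance = 1e-8)
  expect_error(wilks_test(fit, "(Intercept)"), "unsupported-contrast")
  expect_error(wilks_test(fit, "nope"), "not found")
})

test_that("a null predictor yields lambda near 1 and a flat p-value", {
  set.seed(54)
  n <- 20000
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "real", "null")
  Y <- cbind(X[, "real"] + rnorm(n), 0.5 * X[, "real"] + rnorm(n))
  fit <- fit_mvlm(X, Y)
  wn <- wilks_test(fit, "null")
  expect_gt(wn$lambda, 0.999)
  expect_gt(wn$p, 0.01)
  expect_lt(wilks_test(fit, "real")$p, 1e-10)
})

test_that("independent outcomes factorize the two-outcome lambda", {
  set.seed(55)
  n <- 50000
  X <- cbind(1, rnorm(n))
  colnames(X) <- c("(Intercept)", "x")
  Y <- cbind(0.02 * X[, 2] + rnorm(n), -0.015 * X[, 2] + rnorm(n))
  fit <- fit_mvlm(X, Y)
  l2 <- wilks_test(fit, "x")$lambda
  l_uni <- vapply(1:2, function(j)
    wilks_test(fit_mvlm(X, Y[, j, drop = FALSE]), "x")$lambda, 1.0)
  expect_equal(l2, prod(l_uni), tolerance = 1e-4)
})

test_that("shift vectors join measured composition to model predictions", {
  set.seed(56)
  n <- 200
  meas <- cbind(fat = rnorm(n), muscle = rnorm(n))
  X <- cbind(`(Intercept)` = 1, meas)
  # identity mapping: all arrows have zero length
  fit0 <- fit_mvlm(X, meas)
  sv0 <- shift_vectors(fit0, meas)
  expect_lt(max(abs(sv0$end_fat - sv0$start_fat)), 1e-10)
  expect_lt(max(abs(sv0$end_muscle - sv0$start_muscle)), 1e-10)
  expect_error(shift_vectors(fit_mvlm(X, meas[, 1, drop = FALSE]), meas),
               "dimensionality")
})

test_that("toy scenarios reproduce their designed response patterns", {
  # self-estimates: arrows displace by ~(+1, +1) on average
  d1 <- scenario_data(scenario_spec("self_estimate", n = 20000, seed = 57))
  f1 <- fit_mvlm(d1$X, d1$Y)
  sv1 <- shift_vectors(f1, d1$X[, c("fat", "muscle")])
  expect_equal(mean(sv1$end_fat - sv1$start_fat), 1, tolerance = 0.05)
  expect_equal(mean(sv1$end_muscle - sv1$start_muscle), 1, tolerance = 0.05)
  # ideal: arrow ends cluster near (-2.5, +2.5) regardless of start
  d2 <- scenario_data(scenario_spec("ideal", n = 20000, seed = 58))
  f2 <- fit_mvlm(d2$X, d2$Y)
  sv2 <- shift_vectors(f2, d2$X[, c("fat", "muscle")])
  expect_equal(mean(sv2$end_fat), -2.5, tolerance = 0.05)
  expect_equal(mean(sv2$end_muscle), 2.5, tolerance = 0.05)
  expect_lt(sd(sv2$end_fat), 0.25)
  # psych matters for self-estimates but not for the ideal
  expect_lt(wilks_test(f1, "psych")$p, 1e-6)
  expect_gt(wilks_test(f2, "psych")$p, 0.01)
})
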