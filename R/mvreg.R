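#' Fit a multivariate multiple regression Y = XB + E
#'
#' Ordinary least squares for the standard multivariate linear model: `Y` is
#' an n x r matrix of response variables (here, the two-dimensional body
#' composition chosen in the adjustment task), `X` an n x p design whose
#' first column is the intercept, `B` a p x r coefficient matrix and the
#' error rows i.i.d. normal with covariance Sigma. The coefficient matrix is
#' the normal-equations solution; the residual sums-of-squares-and-cross-
#' products matrix `E = (Y - XB)'(Y - XB)` and `sigma_hat = E / (n - p)`
#' drive per-coefficient t tests and the MANOVA tests of [wilks_test()].
#'
#' @param X n x p numeric design matrix, intercept in the first column.
#' @param Y n x r numeric outcome matrix.
#' @return object of class `mvlm_fit` with `B_hat`, `E_sscp`, `sigma_hat`,
#'   `se`, `t_values`, `p_values` (each p x r), plus `X`, `Y`, `xtx_inv`,
#'   `n`, `p`, `r`.
#' @export
fit_mvlm <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- storage.mode(Y) <- "double"
  n <- nrow(X); p <- ncol(X); r <- ncol(Y)
  if (nrow(Y) != n) stopf("X has %d rows but Y has %d", n, nrow(Y))
  if (n <= p) stopf("insufficient-data error: n = %d must exceed p = %d", n, p)
  if (is.null(colnames(X))) colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(r))
  qx <- qr(X)
  if (qx$rank < p) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):p]]
    stopf("collinearity error: design is rank-deficient (column(s): %s)",
          paste(dropped, collapse = ", "))
  }
  xtx_inv <- chol2inv(qr.R(qx))
  B <- xtx_inv %*% crossprod(X, Y)
  dimnames(B) <- list(colnames(X), colnames(Y))
  resid <- Y - X %*% B
  E <- crossprod(resid)
  sigma <- E / (n - p)
  se <- sqrt(outer(diag(xtx_inv), diag(sigma)))
  dimnames(se) <- dimnames(B)
  tmat <- B / se
  pmat <- 2 * stats::pt(-abs(tmat), df = n - p)
  structure(list(B_hat = B, E_sscp = E, sigma_hat = sigma,
                 se = se, t_values = tmat, p_values = pmat,
                 X = X, Y = Y, xtx_inv = xtx_inv,
                 n = n, p = p, r = r),
            class = "mvlm_fit")
}

#' @export
print.mvlm_fit <- function(x, ...) {
  cat(sprintf("<mvlm_fit: n = %d, p = %d predictors, r = %d outcomes>\n",
              x$n, x$p, x$r))
  cat("Coefficients (B_hat):\n")
  print(round(x$B_hat, 4))
  invisible(x)
}

#' Wilks' lambda MANOVA test for one predictor
#'
#' Tests whether a predictor's coefficients on all outcomes are jointly zero,
#' using the single-row contrast `L` selecting that predictor's row of `B`:
#' the hypothesis SSCP is `H = (LB)' (L (X'X)^-1 L')^-1 (LB)` and
#' `lambda = det(E) / det(E + H)`. For a one-row contrast Rao's F transform
#' is exact: `F = ((1 - lambda)/lambda) * (n - p - r + 1)/r` on
#' `(r, n - p - r + 1)` degrees of freedom.
#'
#' @param fit a [fit_mvlm()] result.
#' @param predictor name (or index) of a non-intercept design column.
#' @return object of class `wilks_test`: `predictor`, `lambda`, `F`, `df1`,
#'   `df2`, `p`.
#' @export
wilks_test <- function(fit, predictor) {
  stopifnot(inherits(fit, "mvlm_fit"))
  j <- if (is.character(predictor)) match(predictor, colnames(fit$X))
       else as.integer(predictor)
  if (is.na(j) || j < 1L || j > fit$p)
    stopf("predictor '%s' not found in the design", predictor)
  if (j == 1L)
    stopf("unsupported-contrast error: the intercept cannot be tested")
  LB <- fit$B_hat[j, , drop = FALSE]                  # 1 x r
  H <- crossprod(LB) / fit$xtx_inv[j, j]              # r x r
  E <- fit$E_sscp
  lambda <- det(E) / det(E + H)
  ve <- fit$n - fit$p
  r <- fit$r
  df1 <- r
  df2 <- ve - r + 1
  Fstat <- (1 - lambda) / lambda * df2 / df1
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(predictor = colnames(fit$X)[j], lambda = lambda,
                 F = Fstat, df1 = df1, df2 = df2, p = p),
            class = "wilks_test")
}

#' @export
print.wilks_test <- function(x, ...) {
  cat(sprintf("<wilks_test '%s': lambda = %.4f, F(%d, %d) = %.3f, p = %.3g>\n",
              x$predictor, x$lambda, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Measured-to-predicted shift vectors for 2D composition outcomes
#'
#' For each individual, an arrow from their measured (fat, muscle) pair to
#' the model-predicted outcome pair (the fitted values `X B_hat`). When the
#' pipeline operates in z-scores the arrows are in z-score units too: the fit
#' itself is scale-agnostic.
#'
#' @param fit a [fit_mvlm()] result with exactly 2 outcomes.
#' @param measured n x 2 matrix of measured (fat, muscle) values.
#' @return data frame with columns `start_fat`, `start_muscle`, `end_fat`,
#'   `end_muscle`.
#' @export
shift_vectors <- function(fit, measured) {
  stopifnot(inherits(fit, "mvlm_fit"))
  if (fit$r != 2L)
    stopf("dimensionality error: shift vectors need r = 2 outcomes, fit has %d",
          fit$r)
  measured <- as.matrix(measured)
  if (nrow(measured) != fit$n || ncol(measured) != 2L)
    stopf("measured must be an n x 2 matrix (n = %d)", fit$n)
  ends <- fit$X %*% fit$B_hat
  data.frame(start_fat = measured[, 1], start_muscle = measured[, 2],
             end_fat = ends[, 1], end_muscle = ends[, 2])
}
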