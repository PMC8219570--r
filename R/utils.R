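# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Draw from a multivariate normal distribution
#'
#' Cholesky-based sampler used by the synthetic-data generators. Uses the
#' current RNG state (callers are responsible for seeding).
#'
#' @param n number of draws.
#' @param mean mean vector of length d.
#' @param sigma d x d positive semidefinite covariance matrix.
#' @return an n x d matrix of draws.
#' @keywords internal
rmvn <- function(n, mean, sigma) {
  d <- length(mean)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
  sweep(z %*% L, 2L, mean, `+`)
}

# rotation matrix about a unit axis (Rodrigues' formula); angle in radians
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# set.seed only when a seed is supplied
maybe_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stopf("seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}
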