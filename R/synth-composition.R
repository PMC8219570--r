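#' Default body-composition population parameters
#'
#' Sex-specific means and SDs of fat mass, skeletal muscle mass and height,
#' the fat-muscle correlation, physiological floors, and the parameters of
#' the residual (non-fat, non-muscle) mass model. Defaults describe the
#' reference adult cohorts the package emulates: women fat 17.65 +/- 7.92 kg,
#' muscle 26.34 +/- 2.79 kg, height 164.63 +/- 6.29 cm, r = 0.38; men fat
#' 14.53 +/- 7.39 kg, muscle 39.55 +/- 5.61 kg, height 179.41 +/- 6.80 cm,
#' r = 0.45.
#'
#' @param sex `"male"` or `"female"`.
#' @return a named list of parameters accepted by [sample_composition()].
#' @export
composition_params <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (sex == "female")
    list(fat_mean = 17.65, fat_sd = 7.92,
         muscle_mean = 26.34, muscle_sd = 2.79,
         fat_muscle_cor = 0.38,
         height_mean = 164.63, height_sd = 6.29,
         age_mean = 29.14, age_sd = 8.18,
         # residual mass: weight minus fat minus muscle; intercept chosen so
         # mean weight reproduces the reference mean BMI of 23.82
         residual_intercept = 20.57, residual_slope = 0.30, residual_sd = 1.5,
         floors = c(fat = 2, muscle = 15))
  else
    list(fat_mean = 14.53, fat_sd = 7.39,
         muscle_mean = 39.55, muscle_sd = 5.61,
         fat_muscle_cor = 0.45,
         height_mean = 179.41, height_sd = 6.80,
         age_mean = 28.84, age_sd = 7.99,
         residual_intercept = 27.52, residual_slope = 0.30, residual_sd = 1.5,
         floors = c(fat = 2, muscle = 15))
}

# ---- truncated bivariate normal moments -----------------------------------
# For (Zf, Zm) standard bivariate normal with correlation rho, truncated to
# Zf >= a, Zm >= b: moments computed by 1D quadrature over Zf with the
# closed-form conditional truncated-normal moments of Zm | Zf.

# inverse Mills ratio, numerically stable in the upper tail
mills <- function(t) exp(stats::dnorm(t, log = TRUE) -
                           stats::pnorm(t, lower.tail = FALSE, log.p = TRUE))

tbn_moments <- function(rho, a, b) {
  s <- sqrt(1 - rho^2)
  f <- function(x, order_x, which_y) {
    t <- (b - rho * x) / s
    Q <- stats::pnorm(t, lower.tail = FALSE)       # P(Zm >= b | Zf = x)
    base <- stats::dnorm(x) * x^order_x
    if (which_y == 0) return(base * Q)
    lam <- mills(t)
    m1 <- rho * x + s * lam                        # E[Zm | Zf = x, Zm >= b]
    if (which_y == 1) return(base * Q * m1)
    v <- s^2 * (1 + t * lam - lam^2)
    base * Q * (v + m1^2)
  }
  qu <- function(order_x, which_y)
    stats::integrate(f, lower = a, upper = Inf, order_x = order_x,
                     which_y = which_y, rel.tol = 1e-10,
                     stop.on.error = FALSE)$value
  P <- qu(0, 0)
  if (P <= 0) stopf("parameter error: truncation region has zero probability")
  list(P = P,
       ex = qu(1, 0) / P, ex2 = qu(2, 0) / P,
       ey = qu(0, 1) / P, ey2 = qu(0, 2) / P,
       exy = qu(1, 1) / P)
}

# moments (mean/sd/cor) of the truncated distribution given latent params
truncated_summary <- function(mu1, sd1, mu2, sd2, rho, floor1, floor2) {
  a <- (floor1 - mu1) / sd1
  b <- (floor2 - mu2) / sd2
  m <- tbn_moments(rho, a, b)
  v1 <- m$ex2 - m$ex^2; v2 <- m$ey2 - m$ey^2
  cv <- m$exy - m$ex * m$ey
  list(mean1 = mu1 + sd1 * m$ex, sd1 = sd1 * sqrt(v1),
       mean2 = mu2 + sd2 * m$ey, sd2 = sd2 * sqrt(v2),
       cor = cv / sqrt(v1 * v2), accept = m$P)
}

# Solve for latent bivariate-normal parameters whose floor-truncated
# distribution has the target means/SDs/correlation. Moment matching keeps
# the generator's output calibrated to the configured population values even
# when the floors trim an appreciable tail.
calibrate_truncated <- function(target, floors) {
  obj <- function(par) {
    mu1 <- par[1]; sd1 <- exp(par[2]); mu2 <- par[3]; sd2 <- exp(par[4])
    rho <- tanh(par[5])
    s <- truncated_summary(mu1, sd1, mu2, sd2, rho, floors[1], floors[2])
    sum(((s$mean1 - target$fat_mean) / target$fat_sd)^2,
        ((s$sd1 - target$fat_sd) / target$fat_sd)^2,
        ((s$mean2 - target$muscle_mean) / target$muscle_sd)^2,
        ((s$sd2 - target$muscle_sd) / target$muscle_sd)^2,
        (s$cor - target$fat_muscle_cor)^2)
  }
  start <- c(target$fat_mean, log(target$fat_sd),
             target$muscle_mean, log(target$muscle_sd),
             atanh(target$fat_muscle_cor))
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  if (fit$value > 1e-6)
    warnf("truncation calibration converged imperfectly (objective %.2e)", fit$value)
  list(mu1 = fit$par[1], sd1 = exp(fit$par[2]),
       mu2 = fit$par[3], sd2 = exp(fit$par[4]),
       rho = tanh(fit$par[5]))
}

#' Sample a synthetic body-composition cohort
#'
#' Draws (fat mass, skeletal muscle mass) pairs from a bivariate normal
#' truncated at physiological floors (fat >= 2 kg, muscle >= 15 kg by
#' default). The latent parameters are moment-matched so that the
#' *truncated* output reproduces the configured means, SDs and fat-muscle
#' correlation. Height is normal; weight is fat + muscle + a residual mass
#' affine in height plus noise; BMI is computed from weight and height; age
#' is normal truncated to 18-45; `psych` is a standard-normal psychometric
#' score.
#'
#' @param sex `"male"` or `"female"` (selects default parameters).
#' @param n number of identities (>= 0).
#' @param params parameter list, see [composition_params()].
#' @param seed optional RNG seed.
#' @return data frame of composition records with columns
#'   `id, sex, fatm, smm, height, weight, bmi, age, psych`.
#' @export
sample_composition <- function(sex = c("female", "male"), n,
                               params = composition_params(sex), seed = NULL) {
  sex <- match.arg(sex)
  if (n < 0) stopf("n must be >= 0")
  fl <- params$floors
  if (fl["fat"] > params$fat_mean + 5 * params$fat_sd ||
      fl["muscle"] > params$muscle_mean + 5 * params$muscle_sd)
    stopf("parameter error: floor above mean + 5 SD; truncation infeasible")
  empty <- data.frame(id = character(), sex = character(), fatm = numeric(),
                      smm = numeric(), height = numeric(), weight = numeric(),
                      bmi = numeric(), age = numeric(), psych = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  maybe_seed(seed)
  cal <- calibrate_truncated(params, fl)
  sigma <- matrix(c(cal$sd1^2, cal$rho * cal$sd1 * cal$sd2,
                    cal$rho * cal$sd1 * cal$sd2, cal$sd2^2), 2L)
  fat <- muscle <- numeric(0)
  tries <- 0L
  while (length(fat) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stopf("rejection sampling failed to fill the cohort")
    batch <- rmvn(max(2L * n, 100L), c(cal$mu1, cal$mu2), sigma)
    ok <- batch[, 1] >= fl["fat"] & batch[, 2] >= fl["muscle"]
    fat <- c(fat, batch[ok, 1]); muscle <- c(muscle, batch[ok, 2])
  }
  fat <- fat[seq_len(n)]; muscle <- muscle[seq_len(n)]
  height <- stats::rnorm(n, params$height_mean, params$height_sd)
  resid <- params$residual_intercept +
    params$residual_slope * (height - params$height_mean) +
    stats::rnorm(n, sd = params$residual_sd)
  resid <- pmax(resid, 1)    # residual mass must stay positive
  weight <- fat + muscle + resid
  bmi <- weight / (height / 100)^2
  age <- pmin(45, pmax(18, stats::rnorm(n, params$age_mean, params$age_sd)))
  data.frame(id = sprintf("%s%04d", substr(sex, 1L, 1L), seq_len(n)),
             sex = sex, fatm = fat, smm = muscle, height = height,
             weight = weight, bmi = bmi, age = age,
             psych = stats::rnorm(n), stringsAsFactors = FALSE)
}
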