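#' Toy-scenario specification for the 2D adjustment-outcome analysis
#'
#' Two canned scenarios describe the kinds of responses the 2D method-of-
#' adjustment task might produce in men, as true coefficient matrices for
#' outcomes (estimated fat, estimated muscle) on predictors (intercept,
#' measured fat, measured muscle, psychometric score), all in z-score units:
#'
#' * `self_estimate`: participants report their own composition but
#'   overestimate both masses by 1 unit on average, and higher psychometric
#'   scores add to the muscle estimate (coefficient 0.5).
#'   B = rbind(est_fat = c(1, 1, 0, 0), est_muscle = c(1, 0, 1, 0.5)).
#' * `ideal`: everyone converges on a common low-fat, high-muscle ideal
#'   nearly regardless of their own body:
#'   B = rbind(est_fat = c(-2.5, 0.1, 0, 0), est_muscle = c(2.5, 0, 0.1, 0)).
#'
#' Predictors are standardized with fat-muscle covariance 0.45 and an
#' independent psychometric score.
#'
#' @param name `"self_estimate"` or `"ideal"`.
#' @param n number of simulated participants (> 8).
#' @param residual_sd SD of the independent outcome residuals (z-score
#'   units).
#' @param seed optional RNG seed.
#' @return a named list of class `scenario_spec` with the true 4 x 2
#'   coefficient matrix `B_true` (rows intercept/fat/muscle/psych, columns
#'   est_fat/est_muscle) and the predictor covariance matrix.
#' @export
scenario_spec <- function(name = c("self_estimate", "ideal"), n = 100L,
                          residual_sd = 0.4, seed = NULL) {
  name <- match.arg(name)
  if (n <= 8L) stopf("n must be > 8")
  if (residual_sd < 0) stopf("residual_sd must be >= 0")
  B <- if (name == "self_estimate")
    cbind(est_fat = c(1, 1, 0, 0), est_muscle = c(1, 0, 1, 0.5))
  else
    cbind(est_fat = c(-2.5, 0.1, 0, 0), est_muscle = c(2.5, 0, 0.1, 0))
  rownames(B) <- c("(Intercept)", "fat", "muscle", "psych")
  pred_cov <- matrix(c(1, 0.45, 0, 0.45, 1, 0, 0, 0, 1), 3L, 3L,
                     dimnames = list(c("fat", "muscle", "psych"),
                                     c("fat", "muscle", "psych")))
  if (min(eigen(pred_cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stopf("parameter error: predictor covariance is not positive definite")
  structure(list(name = name, n = as.integer(n), B_true = B,
                 pred_cov = pred_cov, residual_sd = residual_sd, seed = seed),
            class = "scenario_spec")
}

#' Simulate toy adjustment-outcome data for a scenario
#'
#' Draws standardized predictors from the scenario's covariance, then
#' `Y = X B_true + noise` with independent Gaussian residuals.
#'
#' @param spec a [scenario_spec()].
#' @return list with `X` (n x 4 design, intercept first), `Y` (n x 2
#'   outcomes) and `truth` (the spec).
#' @export
scenario_data <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  maybe_seed(spec$seed)
  Z <- rmvn(spec$n, c(0, 0, 0), spec$pred_cov)
  colnames(Z) <- c("fat", "muscle", "psych")
  X <- cbind(`(Intercept)` = 1, Z)
  Y <- X %*% spec$B_true
  if (spec$residual_sd > 0)
    Y <- Y + matrix(stats::rnorm(spec$n * 2L, sd = spec$residual_sd), spec$n, 2L)
  list(X = X, Y = Y, truth = spec)
}

#' Configuration for the Simpson's-paradox composition simulation
#'
#' @param n_per_band identities per BMI band (>= 2).
#' @param band_edges increasing BMI band edges; default five bands
#'   15-19, 19-23, 23-27, 27-31, 31-35 kg/m^2.
#' @param height_mean,height_sd stature distribution (cm).
#' @param bmi_mean,bmi_sd BMI distribution of the underlying population.
#' @param fat_frac_mean,fat_frac_sd distribution of the fat share of the
#'   disposable (non-residual) mass; its spread is what makes composition
#'   vary at fixed BMI.
#' @param muscle_frac_mean,muscle_frac_sd muscle share of the remaining
#'   disposable mass.
#' @param seed optional RNG seed.
#' @return a named list of class `simpson_config`.
#' @export
simpson_config <- function(n_per_band = 100L,
                           band_edges = c(15, 19, 23, 27, 31, 35),
                           height_mean = 179.41, height_sd = 6.80,
                           bmi_mean = 25, bmi_sd = 4.5,
                           fat_frac_mean = 0.28, fat_frac_sd = 0.09,
                           muscle_frac_mean = 0.75, muscle_frac_sd = 0.02,
                           seed = NULL) {
  if (n_per_band < 2L) stopf("n_per_band must be >= 2")
  if (length(band_edges) < 2L || any(diff(band_edges) <= 0))
    stopf("band_edges must be increasing with >= 2 values")
  structure(list(n_per_band = as.integer(n_per_band), band_edges = band_edges,
                 height_mean = height_mean, height_sd = height_sd,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 fat_frac_mean = fat_frac_mean, fat_frac_sd = fat_frac_sd,
                 muscle_frac_mean = muscle_frac_mean,
                 muscle_frac_sd = muscle_frac_sd, seed = seed),
            class = "simpson_config")
}

#' Simulate the Simpson's-paradox relationship between fat and muscle mass
#'
#' Draws men from a joint (height, BMI, composition split) model and keeps
#' exactly `n_per_band` whose BMI falls in each half-open band
#' `[edge_i, edge_{i+1})`, by rejection. In the model both fat and muscle
#' grow with total mass, so they are positively correlated across the whole
#' sample; but at (nearly) fixed BMI the disposable mass is fixed and a
#' larger fat share directly takes from muscle, so within narrow BMI bands
#' the association inverts.
#'
#' @param config a [simpson_config()].
#' @return data frame with columns `fat`, `muscle`, `bmi`, `band` (factor),
#'   `n_per_band * (length(band_edges) - 1)` rows; band edges kept as
#'   attribute `band_edges`.
#' @export
simpson_cohort <- function(config = simpson_config()) {
  stopifnot(inherits(config, "simpson_config"))
  maybe_seed(config$seed)
  edges <- config$band_edges
  nb <- length(edges) - 1L
  labels <- sprintf("%g-%g", edges[-length(edges)], edges[-1])
  need <- rep(config$n_per_band, nb)
  got <- vector("list", nb)
  for (b in seq_len(nb)) got[[b]] <- list()
  tries <- 0L
  while (any(vapply(seq_len(nb), function(b) length(got[[b]]), 1L) <
             config$n_per_band)) {
    tries <- tries + 1L
    if (tries > 200L)
      stopf("infeasible-band error: could not fill all BMI bands after %d batches", tries)
    m <- 5000L
    h <- stats::rnorm(m, config$height_mean, config$height_sd)
    bmi <- stats::rnorm(m, config$bmi_mean, config$bmi_sd)
    weight <- bmi * (h / 100)^2
    residual <- 0.30 * h - 26 + stats::rnorm(m, sd = 1)
    pool <- pmax(weight - residual, 5)
    pfat <- pmin(0.55, pmax(0.08, stats::rnorm(m, config$fat_frac_mean,
                                               config$fat_frac_sd)))
    fat <- pfat * pool
    mfrac <- stats::rnorm(m, config$muscle_frac_mean, config$muscle_frac_sd)
    muscle <- mfrac * (pool - fat)
    band <- findInterval(bmi, edges, rightmost.closed = FALSE)
    for (b in seq_len(nb)) {
      sel <- which(band == b)
      if (!length(sel)) next
      have <- length(got[[b]])
      take <- sel[seq_len(min(length(sel), config$n_per_band - have))]
      if (length(take))
        got[[b]] <- c(got[[b]], lapply(take, function(i)
          c(fat = fat[i], muscle = muscle[i], bmi = bmi[i])))
    }
  }
  rows <- do.call(rbind, lapply(seq_len(nb), function(b)
    do.call(rbind, got[[b]])))
  out <- data.frame(fat = rows[, "fat"], muscle = rows[, "muscle"],
                    bmi = rows[, "bmi"],
                    band = factor(rep(labels, each = config$n_per_band),
                                  levels = labels))
  attr(out, "band_edges") <- edges
  out
}

#' Overall and per-band OLS slopes of muscle mass on fat mass
#'
#' The regression of muscle on fat across the whole sample, and separately
#' within each BMI band — the comparison that exposes Simpson's paradox when
#' the overall slope is positive but every within-band slope is negative.
#'
#' @param table a [simpson_cohort()] data frame (or any data frame with
#'   `fat`, `muscle` and `band` columns).
#' @return list with `overall` (slope) and `by_band` (named vector of
#'   slopes).
#' @export
simpson_slopes <- function(table) {
  if (nrow(table) < 2L) stopf("insufficient-data error: need >= 2 points")
  slope <- function(d) {
    if (nrow(d) < 2L) stopf("insufficient-data error: empty band")
    unname(stats::coef(stats::lm(muscle ~ fat, data = d))[2])
  }
  by_band <- vapply(split(table, table$band), slope, 1.0)
  list(overall = slope(table), by_band = by_band)
}
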