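#' Simulate a 2D method-of-adjustment session
#'
#' In the adjustment task an observer tunes the fat and muscle mass of a CGI
#' body until it matches an internal standard; each accepted setting is one
#' trial. The response model here is the minimal classical-psychophysics
#' assumption: settings are bivariate Gaussian around the observer's internal
#' point of subjective equality (PSE), with componentwise SDs equal to the
#' difference limens (DLs) and a configurable fat-muscle trial correlation.
#' Start points are drawn uniformly from `start_box`, recorded, and inert —
#' anchoring effects are not modelled.
#'
#' @param true_pse length-2 numeric, internal (fat, muscle) PSE in kg.
#' @param true_dl length-2 nonnegative numeric, internal (fat, muscle) DL in kg.
#' @param trial_corr correlation of the two settings across trials, in
#'   `[-1, 1]`.
#' @param n_trials number of trials (>= 1).
#' @param seed optional RNG seed; same seed reproduces the set bit-exactly.
#' @param start_box 2x2 matrix of per-dimension start ranges (rows fat,
#'   muscle; columns min, max), kg.
#' @return object of class `trial_set` with `trials` and `start` (n x 2
#'   matrices, columns fat/muscle), plus the simulation truth.
#' @export
simulate_adjustment <- function(true_pse, true_dl, trial_corr = 0,
                                n_trials = 30L, seed = NULL,
                                start_box = rbind(fat = c(2, 50),
                                                  muscle = c(15, 62))) {
  if (length(true_pse) != 2L || length(true_dl) != 2L)
    stopf("true_pse and true_dl must each have 2 components (fat, muscle)")
  if (any(true_dl < 0)) stopf("parameter error: true_dl must be >= 0")
  if (abs(trial_corr) > 1)
    stopf("parameter error: |trial_corr| must be <= 1, got %g", trial_corr)
  if (n_trials < 1L) stopf("need at least 1 trial")
  maybe_seed(seed)
  z1 <- stats::rnorm(n_trials)
  z2 <- if (abs(trial_corr) == 1) sign(trial_corr) * z1
        else trial_corr * z1 + sqrt(1 - trial_corr^2) * stats::rnorm(n_trials)
  trials <- cbind(fat = true_pse[1] + true_dl[1] * z1,
                  muscle = true_pse[2] + true_dl[2] * z2)
  start <- cbind(fat = stats::runif(n_trials, start_box[1, 1], start_box[1, 2]),
                 muscle = stats::runif(n_trials, start_box[2, 1], start_box[2, 2]))
  structure(list(trials = trials, start = start, true_pse = true_pse,
                 true_dl = true_dl, trial_corr = trial_corr, seed = seed),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set: %d trials, true PSE (%.2f, %.2f) kg, true DL (%.2f, %.2f) kg>\n",
              nrow(x$trials), x$true_pse[1], x$true_pse[2],
              x$true_dl[1], x$true_dl[2]))
  invisible(x)
}

#' Estimate PSE and DL from method-of-adjustment trials
#'
#' The per-dimension mean of the chosen settings estimates the point of
#' subjective equality; their per-dimension sample standard deviation
#' (n - 1 denominator) estimates the difference limen, the task's precision.
#'
#' @param trials a [simulate_adjustment()] result, or an n x 2 matrix of
#'   (fat, muscle) settings in kg.
#' @return object of class `adjustment_estimate` with `pse`, `dl` (each a
#'   named length-2 vector, kg) and `n_trials`. With a single trial the DL is
#'   undefined (`NA`) with a warning.
#' @export
estimate_adjustment <- function(trials) {
  m <- if (inherits(trials, "trial_set")) trials$trials else as.matrix(trials)
  if (ncol(m) != 2L) stopf("trials must have 2 columns (fat, muscle)")
  n <- nrow(m)
  if (n < 1L) stopf("need at least 1 trial")
  pse <- colMeans(m)
  if (n < 2L) {
    warnf("DL undefined with a single trial")
    dl <- c(fat = NA_real_, muscle = NA_real_)
  } else {
    dl <- apply(m, 2L, stats::sd)
  }
  names(pse) <- names(dl) <- c("fat", "muscle")
  structure(list(pse = pse, dl = dl, n_trials = n),
            class = "adjustment_estimate")
}

#' @export
print.adjustment_estimate <- function(x, ...) {
  cat(sprintf("<adjustment_estimate (%d trials): PSE fat %.2f kg, muscle %.2f kg; DL fat %.2f kg, muscle %.2f kg>\n",
              x$n_trials, x$pse["fat"], x$pse["muscle"],
              x$dl["fat"], x$dl["muscle"]))
  invisible(x)
}

#' Monte Carlo precision of DL estimates versus trial count
#'
#' How many adjustment trials are needed for a stable difference-limen
#' estimate? For each (target DL, trial count) combination, `resamples`
#' independent trial sets are drawn from a normal with SD equal to the target
#' DL; each set's sample SD is one DL estimate. The table reports the SD of
#' those estimates (the estimate's variability) and their mean (which is
#' biased low by the classical c4(n) factor). Variability decays with trial
#' count with an elbow around 20-60 trials.
#'
#' @param target_dls target DL values (kg).
#' @param trial_counts numbers of trials per session (each >= 2).
#' @param resamples Monte Carlo resamples per combination.
#' @param seed optional RNG seed; the curve is bit-reproducible given a seed.
#' @return data frame with columns `target_dl`, `n_trials`, `dl_sd`
#'   (variability of the DL estimate) and `dl_mean`.
#' @export
dl_variability_curve <- function(target_dls = c(0.5, 1, 2),
                                 trial_counts = c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90),
                                 resamples = 10000L, seed = NULL) {
  if (any(target_dls <= 0)) stopf("parameter error: target DLs must be > 0")
  if (any(trial_counts < 2L)) stopf("trial counts must be >= 2")
  if (resamples < 1L) stopf("resamples must be >= 1")
  maybe_seed(seed)
  out <- expand.grid(target_dl = target_dls, n_trials = trial_counts,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$target_dl, out$n_trials), ]
  rownames(out) <- NULL
  out$dl_sd <- out$dl_mean <- NA_real_
  for (i in seq_len(nrow(out))) {
    n <- out$n_trials[i]
    x <- matrix(stats::rnorm(resamples * n, sd = out$target_dl[i]),
                nrow = resamples)
    # row-wise sample SDs without apply()
    s <- sqrt(pmax(0, (rowSums(x^2) - rowSums(x)^2 / n) / (n - 1)))
    out$dl_sd[i] <- stats::sd(s)
    out$dl_mean[i] <- mean(s)
  }
  out[, c("target_dl", "n_trials", "dl_sd", "dl_mean")]
}
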