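#' Mean straight-line 3D point error between corresponded meshes
#'
#' The mean Euclidean distance between each original vertex and its predicted
#' location, over the requested regions. Shape-prediction accuracy is by
#' default assessed on the torso only, excluding arms and legs whose
#' positioning varies idiosyncratically between scans.
#'
#' @param predicted,original corresponded [body_mesh()] objects.
#' @param regions region subset over which to average.
#' @return mean point error (cm).
#' @export
mean_point_error <- function(predicted, original, regions = "torso") {
  check_corresponded(predicted, original, "predicted and original")
  idx <- which(original$regions %in% regions)
  if (!length(idx))
    stopf("empty-mask error: no vertices in regions {%s}",
          paste(regions, collapse = ", "))
  d <- predicted$vertices[idx, , drop = FALSE] -
    original$vertices[idx, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Leave-one-out comparison of two shape-prediction models
#'
#' For each identity in turn, its scan is removed, the consensus, PCA and
#' per-dimension regressions are refit on the remaining `n - 1` identities
#' for both predictor sets, the held-out scan is rigidly aligned to the
#' fold's consensus mean, and both models predict its shape from its own
#' measured predictor values. Prediction error is the mean straight-line
#' point distance over `regions` (torso by default). The two per-identity
#' error vectors are compared with a paired two-tailed t test on
#' `error_b - error_a` (so positive t favours model A), and the paired
#' effect size is Cohen's d_z = mean(diff) / SD(diff) = t / sqrt(n).
#'
#' @param meshes list of corresponded [body_mesh()] objects (raw, unaligned).
#' @param composition data frame of composition records, one row per mesh in
#'   the same order, containing every predictor named below.
#' @param model_a,model_b character predictor sets for the two competing
#'   models (defaults: fat + muscle mass vs BMI alone).
#' @param regions regions over which prediction error is averaged.
#' @param fit_regions regions used to build the shape matrix the models are
#'   fit on.
#' @param iterations consensus iterations per fold (see [build_consensus()]).
#' @param heldout_align `"fold_mean"` (strict leave-one-out: align the
#'   held-out scan to the fold's own consensus) or `"full_mean"` (align all
#'   scans to the full-sample consensus once).
#' @return object of class `loo_result`: per-identity errors, per-model mean
#'   and SD, paired `t`, `df`, `p`, `cohen_dz`.
#' @export
loo_compare <- function(meshes, composition,
                        model_a = c("fatm", "smm"), model_b = "bmi",
                        regions = "torso",
                        fit_regions = c("torso", "arm", "leg"),
                        iterations = 1L,
                        heldout_align = c("fold_mean", "full_mean")) {
  heldout_align <- match.arg(heldout_align)
  n <- length(meshes)
  if (nrow(composition) != n)
    stopf("composition has %d rows for %d meshes", nrow(composition), n)
  needed <- max(length(model_a), length(model_b))
  if (n < needed + 3L)
    stopf("insufficient-data error: %d identities, need >= %d", n, needed + 3L)

  full_mean <- if (heldout_align == "full_mean")
    build_consensus(meshes, iterations = iterations)$mean else NULL

  err <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("a", "b")))
  for (i in seq_len(n)) {
    cons <- build_consensus(meshes[-i], iterations = iterations)
    shapes <- flatten_cohort(cons$aligned, regions = fit_regions)
    comp_train <- composition[-i, , drop = FALSE]
    ref <- if (heldout_align == "fold_mean") cons$mean else full_mean
    held <- align_to_reference(meshes[[i]], ref)$aligned
    for (m in c("a", "b")) {
      preds <- if (m == "a") model_a else model_b
      fit <- fit_shape_model(shapes, comp_train, predictors = preds)
      vals <- as.numeric(composition[i, preds])
      pred <- predict_shape(fit, vals, clamp = "allow")
      held_sub <- unflatten(flatten_mesh(held, fit$topology), fit$topology)
      err[i, m] <- mean_point_error(pred, held_sub, regions = regions)
    }
  }
  paired_result(err[, "a"], err[, "b"],
                model_a = paste(model_a, collapse = "+"),
                model_b = paste(model_b, collapse = "+"),
                ids = vapply(meshes, function(m) m$id, ""))
}

# paired t summary (on error_b - error_a: positive t favours model A), with
# the degenerate zero-variance case defined as t=0, p=1
paired_result <- function(err_a, err_b, model_a, model_b, ids) {
  n <- length(err_a)
  diffs <- err_b - err_a
  if (stats::sd(diffs) == 0) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(err_b, err_a, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  structure(
    list(errors = data.frame(id = ids, error_a = err_a, error_b = err_b),
         model_a = model_a, model_b = model_b,
         mean_a = mean(err_a), sd_a = stats::sd(err_a),
         mean_b = mean(err_b), sd_b = stats::sd(err_b),
         t = t_stat, df = n - 1L, p = p,
         cohen_dz = cohen_dz_from_t(t_stat, n), n = n),
    class = "loo_result")
}

#' Paired Cohen's d from a t statistic
#'
#' For a paired design, d_z = mean(diff)/SD(diff) = t / sqrt(n). This is the
#' effect size reported alongside paired model comparisons.
#'
#' @param t paired t statistic.
#' @param n number of pairs.
#' @return Cohen's d_z.
#' @export
cohen_dz_from_t <- function(t, n) t / sqrt(n)

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result: n = %d>\n", x$n))
  cat(sprintf("  model A [%s]: M = %.3f, SD = %.3f cm\n", x$model_a, x$mean_a, x$sd_a))
  cat(sprintf("  model B [%s]: M = %.3f, SD = %.3f cm\n", x$model_b, x$mean_b, x$sd_b))
  cat(sprintf("  paired t(%d) = %.3f, p = %.3g, Cohen's d_z = %.2f\n",
              x$df, x$t, x$p, x$cohen_dz))
  invisible(x)
}

#' Max-normalized per-vertex error maps for two competing predictions
#'
#' For one identity, per-vertex prediction errors of two models are expressed
#' as proportions of the *shared* maximum error across both models, so the
#' two heatmaps are on the same scale and exactly one vertex (ties permitted)
#' attains 1. If both predictions are exact the maximum is 0 and all
#' proportions are defined as 0.
#'
#' @param original the identity's scan ([body_mesh()]).
#' @param predicted_a,predicted_b the two corresponded model predictions.
#' @return list with `prop_a`, `prop_b` (per-vertex proportions in `[0, 1]`)
#'   and `max_error` (cm). Suitable as the `scalar` channel of
#'   [write_mesh()].
#' @export
error_proportion_map <- function(original, predicted_a, predicted_b) {
  check_corresponded(original, predicted_a, "original and prediction A")
  check_corresponded(original, predicted_b, "original and prediction B")
  da <- sqrt(rowSums((predicted_a$vertices - original$vertices)^2))
  db <- sqrt(rowSums((predicted_b$vertices - original$vertices)^2))
  mx <- max(da, db)
  if (mx == 0) list(prop_a = da, prop_b = db, max_error = 0)
  else list(prop_a = da / mx, prop_b = db / mx, max_error = mx)
}
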