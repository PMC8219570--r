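#' Fit a PCA + regressions shape model
#'
#' The central mapping from body composition to 3D shape. The aligned shape
#' vectors are mean-centred (no per-coordinate rescaling) and decomposed by
#' PCA via SVD; with `c` identities the subspace has at most `c - 1`
#' dimensions, all of which are retained. For every principal dimension
#' separately, the identities' scores are regressed by ordinary least squares
#' (with intercept) on the chosen predictors — typically fat mass and
#' skeletal muscle mass in kg, or BMI alone. No significance filtering is
#' applied: a dimension unrelated to composition simply receives near-zero
#' slopes and contributes almost nothing to predicted shape change.
#'
#' @param shapes a `shape_matrix` from [flatten_cohort()] of *aligned* shapes
#'   (see [build_consensus()]).
#' @param composition data frame of composition records, one row per shape
#'   row, in the same order.
#' @param predictors character vector of predictor column names, e.g.
#'   `c("fatm", "smm")` or `"bmi"`.
#' @param var_fraction optional fraction of total variance to retain
#'   (components are truncated after reaching it); default keeps all `c - 1`.
#' @return object of class `shape_model` with elements `mean_vector`,
#'   `basis` (orthonormal columns), `coefficients` ((1 + k) x n_pc matrix of
#'   intercepts and per-predictor slopes), `predictor_names`,
#'   `training_ranges`, `c`, `scores`, `singular_values`, `topology`.
#' @export
fit_shape_model <- function(shapes, composition, predictors = c("fatm", "smm"),
                            var_fraction = 1) {
  if (!inherits(shapes, "shape_matrix"))
    stopf("shapes must be a shape_matrix from flatten_cohort()")
  n <- nrow(shapes)
  if (nrow(composition) != n)
    stopf("composition has %d rows for %d shapes", nrow(composition), n)
  if (!length(predictors)) stopf("predictors must be nonempty")
  missing <- setdiff(predictors, names(composition))
  if (length(missing))
    stopf("predictor(s) not in composition records: %s",
          paste(missing, collapse = ", "))
  if (n < length(predictors) + 2L)
    stopf("insufficient-data error: %d identities for %d predictor(s)",
          n, length(predictors))
  P <- as.matrix(composition[, predictors, drop = FALSE])
  storage.mode(P) <- "double"
  const <- predictors[apply(P, 2L, function(x) stats::sd(x) == 0)]
  if (length(const))
    stopf("collinearity error: predictor(s) constant across identities: %s",
          paste(const, collapse = ", "))

  mu <- colMeans(shapes)
  Xc <- sweep(unclass(shapes), 2L, mu)
  sv <- svd(Xc, nu = n, nv = min(n, ncol(Xc)))
  tol <- max(sv$d) * 1e-10
  ncomp <- min(n - 1L, sum(sv$d > tol))
  if (var_fraction < 1) {
    v <- cumsum(sv$d[seq_len(ncomp)]^2) / sum(sv$d[seq_len(ncomp)]^2)
    ncomp <- which(v >= var_fraction)[1]
  }
  basis <- sv$v[, seq_len(ncomp), drop = FALSE]
  # deterministic sign: largest-magnitude loading of each PC is positive
  for (j in seq_len(ncomp)) {
    k <- which.max(abs(basis[, j]))
    if (basis[k, j] < 0) basis[, j] <- -basis[, j]
  }
  scores <- Xc %*% basis                                   # n x ncomp
  M <- cbind(`(Intercept)` = 1, P)
  coefficients <- solve(crossprod(M), crossprod(M, scores))
  if (!all(is.finite(coefficients)))
    stopf("collinearity error: regression coefficients are not finite")
  ranges <- apply(P, 2L, range)
  rownames(ranges) <- c("min", "max")
  structure(
    list(mean_vector = mu, basis = basis, coefficients = coefficients,
         predictor_names = predictors, training_ranges = ranges,
         c = n, scores = scores,
         singular_values = sv$d[seq_len(ncomp)],
         topology = attr(shapes, "topology")),
    class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model: %d identities, %d principal dimensions, predictors [%s]>\n",
              x$c, ncol(x$basis), paste(x$predictor_names, collapse = ", ")))
  rg <- x$training_ranges
  for (p in x$predictor_names)
    cat(sprintf("  %s in [%.2f, %.2f]\n", p, rg["min", p], rg["max", p]))
  invisible(x)
}

# clamp predictor values per policy; returns possibly clamped values
apply_clamp <- function(model, values, clamp) {
  rg <- model$training_ranges
  lo <- rg["min", ]; hi <- rg["max", ]
  out_of_range <- values < lo | values > hi
  if (any(out_of_range)) {
    msg <- paste(sprintf("%s = %.3g outside training range [%.3g, %.3g]",
                         model$predictor_names[out_of_range],
                         values[out_of_range], lo[out_of_range],
                         hi[out_of_range]), collapse = "; ")
    if (clamp == "refuse") stopf("range error: %s", msg)
    if (clamp == "clamp_warn") {
      warnf("clamping to training range: %s", msg)
      values <- pmin(pmax(values, lo), hi)
    }
  }
  values
}

# predicted PC scores at given predictor values
predict_scores <- function(model, values, clamp = "allow") {
  k <- length(model$predictor_names)
  if (length(values) != k)
    stopf("expected %d predictor value(s) [%s], got %d",
          k, paste(model$predictor_names, collapse = ", "), length(values))
  if (!all(is.finite(values))) stopf("predictor values must be finite")
  values <- apply_clamp(model, values, clamp)
  drop(c(1, values) %*% model$coefficients)
}

#' Predict 3D body shape from composition values
#'
#' Each principal dimension's predicted score is its regression intercept
#' plus the slope-weighted predictor values; the shape is the model mean plus
#' the basis combination of those scores. The model is only trusted inside
#' the composition range it was trained on, so values outside
#' `training_ranges` are by default clamped to the range with a warning
#' (`"refuse"` raises an error, `"allow"` extrapolates linearly).
#'
#' @param model a [fit_shape_model()] result.
#' @param values numeric vector, one value per model predictor (kg, or kg/m^2
#'   for BMI).
#' @param clamp out-of-range policy: `"clamp_warn"`, `"refuse"` or `"allow"`.
#' @param fill optional donor mesh for non-retained regions (see
#'   [unflatten()]).
#' @return the predicted [body_mesh()].
#' @export
predict_shape <- function(model, values,
                          clamp = c("clamp_warn", "refuse", "allow"),
                          fill = NULL) {
  clamp <- match.arg(clamp)
  scores <- predict_scores(model, values, clamp)
  vec <- model$mean_vector + drop(model$basis %*% scores)
  unflatten(vec, model$topology,
            id = sprintf("predicted(%s)",
                         paste(sprintf("%s=%.4g", model$predictor_names, values),
                               collapse = ",")),
            fill = fill)
}

#' Morph an individual's shape to a new body composition
#'
#' Applies the model's predicted shape *change* between two composition
#' states to a specific person's mesh: the individual's own shape is the
#' starting point in the model space, and the displacement
#' `basis %*% (scores(target) - scores(current))` is added to it. With
#' `target == current` the mesh is returned unchanged.
#'
#' @param model a [fit_shape_model()] result.
#' @param individual a [body_mesh()] corresponded with the model topology
#'   (full vertex set).
#' @param current,target numeric predictor values (one per model predictor)
#'   describing the individual's measured and desired composition.
#' @param clamp out-of-range policy, as in [predict_shape()].
#' @return the morphed [body_mesh()].
#' @export
morph_individual <- function(model, individual, current, target,
                             clamp = c("clamp_warn", "refuse", "allow")) {
  clamp <- match.arg(clamp)
  tp <- model$topology
  if (n_vertices(individual) != tp$n_vertices)
    stopf("correspondence error: individual has %d vertices, model topology expects %d",
          n_vertices(individual), tp$n_vertices)
  delta <- predict_scores(model, target, clamp) -
    predict_scores(model, current, clamp)
  vec <- flatten_mesh(individual, tp) + drop(model$basis %*% delta)
  unflatten(vec, tp, id = sprintf("%s(morphed)", individual$id),
            fill = individual)
}
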