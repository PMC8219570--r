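#' Rigidly align a corresponded shape to a reference
#'
#' Finds the translation and proper rotation (no scaling, no reflection)
#' minimising the sum of squared distances between corresponding vertices —
#' partial Procrustes superimposition. Size is deliberately preserved:
#' scaling carries the shape information of interest (a heavier body *is*
#' bigger), so only position and orientation are removed.
#'
#' The optimal rotation is the orthogonal-Procrustes SVD solution with
#' reflection correction (the sign of the smallest singular direction is
#' flipped if the determinant would be -1).
#'
#' @param shape,reference corresponded [body_mesh()] objects.
#' @return a list of class `alignment_result` with elements `rotation`
#'   (3x3, det +1; applied on the right to row vectors), `translation`
#'   (length-3, cm), `aligned` (the transformed [body_mesh()]) and
#'   `residual` (root-mean-square point distance to the reference, cm).
#' @export
align_to_reference <- function(shape, reference) {
  check_corresponded(shape, reference, "shape and reference")
  Y <- reference$vertices
  if (max(apply(Y, 2, stats::sd)) < .Machine$double.eps * 10)
    stopf("degeneracy error: reference vertices are all identical")
  X <- shape$vertices
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- sweep(X, 2L, xc); Yc <- sweep(Y, 2L, yc)
  C <- crossprod(Xc, Yc)                  # 3x3
  sv <- svd(C)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    # flip the smallest singular direction: proper rotation, no mirroring
    u <- sv$u; u[, 3L] <- -u[, 3L]
    R <- u %*% t(sv$v)
  }
  translation <- yc - drop(xc %*% R)
  aligned_V <- sweep(X %*% R, 2L, translation, `+`)
  aligned <- mesh_with_vertices(shape, aligned_V)
  residual <- sqrt(mean(rowSums((aligned_V - Y)^2)))
  structure(list(rotation = R, translation = translation,
                 aligned = aligned, residual = residual),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<alignment_result: rotation %.2f deg, |translation| %.2f cm, RMS residual %.4f cm>\n",
              ang, sqrt(sum(x$translation^2)), x$residual))
  invisible(x)
}

mesh_with_vertices <- function(mesh, V) {
  out <- mesh
  colnames(V) <- c("x", "y", "z")
  out$vertices <- V
  out
}

#' Consensus (mean) shape of a corresponded cohort
#'
#' Centres every shape at its centroid, averages them coordinate-wise, and
#' rigidly fits each shape to this average ([align_to_reference()]). With
#' `iterations = 1` (the default) this is the single-pass centre / average /
#' align procedure; larger values re-average the aligned shapes and re-align
#' until the mean moves less than `tol` (generalized Procrustes iteration).
#'
#' @param meshes list of corresponded [body_mesh()] objects, length >= 2.
#' @param iterations maximum average/align cycles (>= 1).
#' @param tol convergence threshold on the maximum mean-shape point movement
#'   (cm) between iterations.
#' @return list with `mean` (the consensus [body_mesh()]), `aligned` (list of
#'   aligned meshes), `transforms` (list of [align_to_reference()] results)
#'   and `iterations_run`.
#' @export
build_consensus <- function(meshes, iterations = 1L, tol = 1e-6) {
  if (length(meshes) < 2L)
    stopf("insufficient-data error: consensus needs >= 2 shapes, got %d",
          length(meshes))
  if (iterations < 1L) stopf("iterations must be >= 1")
  ref <- meshes[[1]]
  for (m in meshes[-1]) check_corresponded(ref, m, "cohort meshes")
  centred <- lapply(meshes, function(m)
    sweep(m$vertices, 2L, colMeans(m$vertices)))
  mean_V <- Reduce(`+`, centred) / length(centred)
  iterations_run <- 0L
  transforms <- NULL
  repeat {
    iterations_run <- iterations_run + 1L
    mean_mesh <- body_mesh(mean_V, id = "consensus", faces = ref$faces,
                           regions = ref$regions)
    transforms <- lapply(meshes, align_to_reference, reference = mean_mesh)
    aligned_V <- lapply(transforms, function(tr) tr$aligned$vertices)
    new_mean <- Reduce(`+`, aligned_V) / length(aligned_V)
    movement <- max(sqrt(rowSums((new_mean - mean_V)^2)))
    if (iterations_run >= iterations || movement < tol) break
    mean_V <- new_mean
  }
  list(mean = body_mesh(mean_V, id = "consensus", faces = ref$faces,
                        regions = ref$regions),
       aligned = lapply(transforms, `[[`, "aligned"),
       transforms = transforms,
       iterations_run = iterations_run)
}

#' Centroid size of a mesh
#'
#' Square root of the sum of squared distances of the vertices from their
#' centroid; invariant under the rigid alignment used here (size is
#' preserved by design).
#'
#' @param mesh a [body_mesh()].
#' @return centroid size (cm).
#' @export
centroid_size <- function(mesh) {
  V <- sweep(mesh$vertices, 2L, colMeans(mesh$vertices))
  sqrt(sum(V^2))
}
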