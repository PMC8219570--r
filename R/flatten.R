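#' Flatten a corresponded mesh cohort into a shape matrix
#'
#' Each mesh is converted to one row: the retained vertices (those whose
#' region label is in `regions`) are concatenated in ascending vertex-index
#' order as interleaved (x, y, z) triples, so row length is 3 times the
#' retained vertex count. A cohort of meshes with the standard 26,665
#' retained points therefore flattens to rows of 79,995 numbers. The mapping
#' back to mesh positions is stored as the `"topology"` attribute and
#' inverted bit-exactly by [unflatten()].
#'
#' @param meshes list of corresponded [body_mesh()] objects.
#' @param regions character subset of `c("torso","arm","leg","excluded")`.
#' @return a numeric matrix of class `shape_matrix` (one row per identity,
#'   rownames = identity ids) with attribute `topology`.
#' @export
flatten_cohort <- function(meshes, regions = c("torso", "arm", "leg")) {
  if (!length(meshes)) stopf("empty cohort")
  if (inherits(meshes, "body_mesh")) meshes <- list(meshes)
  if (!length(regions)) stopf("regions must be nonempty")
  ref <- meshes[[1]]
  for (m in meshes[-1]) {
    check_corresponded(ref, m, "cohort meshes")
    if (!identical(ref$regions, m$regions))
      stopf("correspondence error: cohort meshes differ in region labels")
  }
  topology <- mesh_topology(ref, regions)
  rows <- t(vapply(meshes, function(m) flatten_mesh(m, topology),
                   numeric(3L * length(topology$indices))))
  rownames(rows) <- vapply(meshes, function(m) m$id, "")
  structure(rows, topology = topology, class = c("shape_matrix", "matrix"))
}

# vertex-index map from a reference mesh and a region subset
mesh_topology <- function(mesh, regions = c("torso", "arm", "leg")) {
  idx <- which(mesh$regions %in% regions)
  if (!length(idx))
    stopf("empty-mask error: no vertices in regions {%s}",
          paste(regions, collapse = ", "))
  # faces entirely within the retained set, remapped to retained indexing
  faces <- NULL
  if (!is.null(mesh$faces) && nrow(mesh$faces)) {
    keep <- matrix(mesh$faces %in% idx, ncol = 3L)
    f <- mesh$faces[rowSums(keep) == 3L, , drop = FALSE]
    if (nrow(f)) {
      remap <- integer(n_vertices(mesh)); remap[idx] <- seq_along(idx)
      faces <- matrix(remap[f], ncol = 3L)
    }
  }
  structure(list(indices = idx, n_vertices = n_vertices(mesh),
                 regions_full = mesh$regions, regions = regions,
                 faces = faces),
            class = "mesh_topology")
}

# one mesh -> interleaved (x,y,z) vector over the topology's retained vertices
flatten_mesh <- function(mesh, topology) {
  if (n_vertices(mesh) != topology$n_vertices)
    stopf("correspondence error: mesh has %d vertices, topology expects %d",
          n_vertices(mesh), topology$n_vertices)
  as.vector(t(mesh$vertices[topology$indices, , drop = FALSE]))
}

#' Rebuild a mesh from a flattened shape vector
#'
#' Exact inverse of the flattening performed by [flatten_cohort()]. When
#' `fill` is supplied (a corresponded donor mesh, e.g. the cohort mean), the
#' vertices outside the retained regions are taken from it and the result has
#' the full vertex set; otherwise the result contains the retained vertices
#' only.
#'
#' @param vec numeric shape vector of length `3 * length(topology$indices)`.
#' @param topology a topology object from [flatten_cohort()] (its
#'   `"topology"` attribute).
#' @param id identity label for the rebuilt mesh.
#' @param fill optional donor [body_mesh()] supplying excluded-region
#'   vertices.
#' @return a [body_mesh()].
#' @export
unflatten <- function(vec, topology, id = "reconstruction", fill = NULL) {
  if (inherits(vec, "shape_matrix") && is.null(dim(vec))) vec <- as.numeric(vec)
  m <- length(topology$indices)
  if (length(vec) != 3L * m)
    stopf("dimension error: vector length %d, topology expects %d",
          length(vec), 3L * m)
  V <- matrix(vec, ncol = 3L, byrow = TRUE)
  if (!is.null(fill)) {
    if (n_vertices(fill) != topology$n_vertices)
      stopf("correspondence error: fill mesh has %d vertices, topology expects %d",
            n_vertices(fill), topology$n_vertices)
    full <- fill$vertices
    full[topology$indices, ] <- V
    body_mesh(full, id = id, faces = fill$faces, regions = topology$regions_full)
  } else {
    body_mesh(V, id = id, faces = topology$faces,
              regions = topology$regions_full[topology$indices])
  }
}

#' @export
`[.shape_matrix` <- function(x, i, j, ..., drop = TRUE) {
  y <- unclass(x)
  if (missing(j)) {
    out <- y[i, , drop = drop]
    if (is.matrix(out))
      out <- structure(out, topology = attr(x, "topology"),
                       class = c("shape_matrix", "matrix"))
    out
  } else {
    y[i, j, drop = drop]
  }
}

#' @export
print.shape_matrix <- function(x, ...) {
  tp <- attr(x, "topology")
  cat(sprintf("<shape_matrix: %d identities x %d (= 3 x %d vertices; regions %s)>\n",
              nrow(x), ncol(x), length(tp$indices),
              paste(tp$regions, collapse = "+")))
  invisible(x)
}
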