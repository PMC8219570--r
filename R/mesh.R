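#' Corresponded 3D body mesh
#'
#' A `body_mesh` holds an ordered set of 3D vertices (in centimetres), an
#' optional triangle list, and a per-vertex region label. Meshes in a cohort
#' are *corresponded*: vertex `i` denotes the same anatomical location on
#' every identity, so all meshes of a cohort must share vertex count,
#' ordering and face list.
#'
#' @param vertices numeric matrix with one row per vertex and columns x, y, z
#'   (units: cm). All coordinates must be finite.
#' @param id identity label (single string).
#' @param faces optional integer matrix of triangles (one row per face, three
#'   1-based vertex indices), or `NULL`.
#' @param regions character vector of per-vertex region tags, one of
#'   `"torso"`, `"arm"`, `"leg"`, `"excluded"`. Defaults to all-torso.
#' @return an object of class `body_mesh`.
#' @seealso [read_mesh()], [write_mesh()], [flatten_cohort()]
#' @export
body_mesh <- function(vertices, id = "mesh", faces = NULL, regions = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 3L)
    stopf("vertices must have 3 columns, got %d", ncol(vertices))
  storage.mode(vertices) <- "double"
  if (!all(is.finite(vertices)))
    stopf("mesh '%s': all vertex coordinates must be finite", id)
  n <- nrow(vertices)
  regions <- regions %||% rep("torso", n)
  if (length(regions) != n)
    stopf("mesh '%s': %d region labels for %d vertices", id, length(regions), n)
  bad <- setdiff(unique(regions), c("torso", "arm", "leg", "excluded"))
  if (length(bad))
    stopf("mesh '%s': unknown region label(s): %s", id, paste(bad, collapse = ", "))
  if (!is.null(faces)) {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
    if (ncol(faces) != 3L)
      stopf("faces must be a 3-column triangle index matrix")
    if (nrow(faces) && (min(faces) < 1L || max(faces) > n))
      stopf("mesh '%s': face indices outside 1..%d", id, n)
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(
    list(id = as.character(id), vertices = vertices, faces = faces,
         regions = as.character(regions)),
    class = "body_mesh"
  )
}

#' @export
print.body_mesh <- function(x, ...) {
  tab <- table(factor(x$regions, levels = c("torso", "arm", "leg", "excluded")))
  cat(sprintf("<body_mesh '%s': %d vertices (%s), %s faces>\n",
              x$id, nrow(x$vertices),
              paste(sprintf("%d %s", as.integer(tab), names(tab))[tab > 0],
                    collapse = ", "),
              if (is.null(x$faces)) "no" else nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# check two meshes share topology (vertex count + faces); index correspondence
# is by construction
check_corresponded <- function(a, b, what = "meshes") {
  if (n_vertices(a) != n_vertices(b))
    stopf("correspondence error: %s have %d vs %d vertices",
          what, n_vertices(a), n_vertices(b))
  fa <- a$faces; fb <- b$faces
  if (xor(is.null(fa), is.null(fb)) ||
      (!is.null(fa) && !identical(dim(fa), dim(fb))))
    stopf("correspondence error: %s differ in face list", what)
  invisible(TRUE)
}

#' Read a mesh from an OBJ or PLY file
#'
#' Vertex order is preserved exactly as in the file; coordinates are taken as
#' centimetres unless `scale` is given (e.g. `scale = 0.1` for mm input).
#' Region labels are read from a sidecar CSV (`vertex_index,label`) when
#' `labels` is supplied, otherwise every vertex is tagged `"torso"`.
#'
#' @param path file to read.
#' @param format `"obj"` or `"ply"`; defaults to the file extension.
#' @param id identity label; defaults to the file base name.
#' @param labels optional path to a region-label sidecar CSV.
#' @param expected_vertices optional vertex count for cohort-topology
#'   checking; a mismatch is a correspondence error.
#' @param scale multiplicative factor applied to coordinates (to cm).
#' @return a [body_mesh()]. PLY per-vertex `error_prop` scalars, if present,
#'   are attached as attribute `"scalar"`.
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply"), id = NULL,
                      labels = NULL, expected_vertices = NULL, scale = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("obj", "ply"))
    stopf("unsupported mesh format '%s'", format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  id <- id %||% tools::file_path_sans_ext(basename(path))
  parsed <- if (format == "obj") parse_obj(path) else parse_ply(path)
  verts <- parsed$vertices * scale
  if (!is.null(expected_vertices) && nrow(verts) != expected_vertices)
    stopf("correspondence error: %s has %d vertices, expected %d",
          path, nrow(verts), expected_vertices)
  regions <- NULL
  if (!is.null(labels)) regions <- read_region_labels(labels, nrow(verts))
  mesh <- body_mesh(verts, id = id, faces = parsed$faces, regions = regions)
  if (!is.null(parsed$scalar)) attr(mesh, "scalar") <- parsed$scalar
  mesh
}

parse_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vsel <- grepl("^v\\s", lines)
  fsel <- grepl("^f\\s", lines)
  vl <- lines[vsel]
  verts <- matrix(NA_real_, length(vl), 3L)
  for (i in seq_along(vl)) {
    parts <- strsplit(trimws(vl[i]), "\\s+")[[1]][-1L]
    xyz <- suppressWarnings(as.numeric(parts[1:3]))
    if (length(parts) < 3L || anyNA(xyz))
      stopf("parse error in %s at line %d: malformed vertex record",
            path, which(vsel)[i])
    verts[i, ] <- xyz
  }
  faces <- NULL
  if (any(fsel)) {
    fl <- lines[fsel]
    faces <- matrix(NA_integer_, length(fl), 3L)
    for (i in seq_along(fl)) {
      parts <- strsplit(trimws(fl[i]), "\\s+")[[1]][-1L]
      idx <- suppressWarnings(as.integer(sub("/.*$", "", parts)))
      if (length(idx) != 3L || anyNA(idx))
        stopf("parse error in %s at line %d: only triangular faces supported",
              path, which(fsel)[i])
      faces[i, ] <- idx
    }
  }
  list(vertices = verts, faces = faces, scalar = NULL)
}

parse_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stopf("parse error in %s: unterminated PLY header", path)
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply")
    stopf("parse error in %s at line 1: not a PLY file", path)
  fmt_line <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt_line[1])
  if (!binary && !grepl("ascii", fmt_line[1]))
    stopf("parse error in %s: unsupported PLY format '%s'", path, fmt_line[1])

  # parse element/property declarations
  elements <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
                 ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
                 int32 = 4, uint32 = 4, float = 4, float32 = 4,
                 double = 8, float64 = 8)
  read_bin_scalar <- function(type, n = 1L) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64"))
      readBin(con, "double", n = n, size = sz, endian = "little")
    else
      readBin(con, "integer", n = n, size = sz, endian = "little",
              signed = !(sz < 4 && grepl("^u", type)))
  }

  verts <- NULL; faces <- NULL; scalar <- NULL
  if (binary) {
    for (el in elements) {
      if (!any(vapply(el$props, `[[`, TRUE, "list"))) {
        pn <- vapply(el$props, `[[`, "", "name")
        # fixed-size rows: read property-wise per row
        dat <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count))
          for (j in seq_along(el$props))
            dat[i, j] <- read_bin_scalar(el$props[[j]]$type)
        colnames(dat) <- pn
        if (el$name == "vertex") {
          verts <- dat[, c("x", "y", "z"), drop = FALSE]
          if ("error_prop" %in% pn) scalar <- dat[, "error_prop"]
        }
      } else if (el$name == "face") {
        faces <- matrix(NA_integer_, el$count, 3L)
        p <- el$props[[1]]
        for (i in seq_len(el$count)) {
          k <- read_bin_scalar(p$count_type)
          idx <- read_bin_scalar(p$type, n = k)
          if (k != 3L) stopf("parse error in %s: only triangular faces supported", path)
          faces[i, ] <- idx + 1L
        }
      }
    }
  } else {
    body <- readLines(con)
    pos <- 0L
    for (el in elements) {
      rows <- body[pos + seq_len(el$count)]
      pos <- pos + el$count
      if (el$name == "vertex") {
        pn <- vapply(el$props, `[[`, "", "name")
        dat <- do.call(rbind, lapply(seq_along(rows), function(i) {
          v <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
          if (length(v) < length(pn) || anyNA(v[seq_along(pn)]))
            stopf("parse error in %s: malformed vertex row %d", path, i)
          v[seq_along(pn)]
        }))
        colnames(dat) <- pn
        verts <- dat[, c("x", "y", "z"), drop = FALSE]
        if ("error_prop" %in% pn) scalar <- dat[, "error_prop"]
      } else if (el$name == "face") {
        faces <- do.call(rbind, lapply(seq_along(rows), function(i) {
          v <- suppressWarnings(as.integer(strsplit(trimws(rows[i]), "\\s+")[[1]]))
          if (anyNA(v) || v[1] != 3L)
            stopf("parse error in %s: malformed face row %d (triangles only)", path, i)
          v[2:4] + 1L
        }))
      }
    }
  }
  if (is.null(verts)) stopf("parse error in %s: no vertex element", path)
  list(vertices = unname(verts), faces = faces, scalar = unname(scalar))
}

#' Write a mesh to an OBJ or PLY file
#'
#' PLY output can carry an optional per-vertex scalar in `[0, 1]` (stored as a
#' float property named `error_prop`), used for prediction-error heatmaps.
#' OBJ has no standard per-vertex scalar channel, so `scalar` is ignored there
#' with a warning.
#'
#' @param mesh a [body_mesh()].
#' @param path output file.
#' @param format `"obj"` or `"ply"`; defaults to the file extension.
#' @param scalar optional numeric vector, one value per vertex.
#' @param binary write binary little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"),
                       scalar = NULL, binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!format %in% c("obj", "ply"))
    stopf("unsupported mesh format '%s'", format)
  if (!is.null(scalar) && length(scalar) != n_vertices(mesh))
    stopf("scalar must have one value per vertex (%d), got %d",
          n_vertices(mesh), length(scalar))
  V <- mesh$vertices
  F <- mesh$faces
  if (format == "obj") {
    if (!is.null(scalar))
      warnf("OBJ output has no per-vertex scalar channel; scalar dropped")
    lines <- sprintf("v %.6f %.6f %.6f", V[, 1], V[, 2], V[, 3])
    if (!is.null(F) && nrow(F))
      lines <- c(lines, sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]))
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(e) FALSE)
    if (!ok) stopf("I/O error: cannot write %s", path)
  } else {
    header <- c("ply",
                if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
                sprintf("element vertex %d", nrow(V)),
                "property double x", "property double y", "property double z",
                if (!is.null(scalar)) "property float error_prop",
                if (!is.null(F)) sprintf("element face %d", nrow(F)),
                if (!is.null(F)) "property list uchar int vertex_indices",
                "end_header")
    con <- tryCatch(file(path, "wb"), error = function(e) NULL)
    if (is.null(con)) stopf("I/O error: cannot write %s", path)
    on.exit(close(con))
    writeLines(header, con)
    if (binary) {
      for (i in seq_len(nrow(V))) {
        writeBin(as.double(V[i, ]), con, size = 8, endian = "little")
        if (!is.null(scalar))
          writeBin(as.double(scalar[i]), con, size = 4, endian = "little")
      }
      if (!is.null(F)) for (i in seq_len(nrow(F))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
      }
    } else {
      rows <- sprintf("%.6f %.6f %.6f", V[, 1], V[, 2], V[, 3])
      if (!is.null(scalar)) rows <- paste(rows, sprintf("%.6f", scalar))
      writeLines(rows, con)
      if (!is.null(F) && nrow(F))
        writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
    }
  }
  invisible(path)
}

#' Read or write a region-label sidecar file
#'
#' Region labels (torso/arm/leg/excluded) travel in a two-column CSV
#' `vertex_index,label` with 1-based indices, since OBJ/PLY have no standard
#' tag channel.
#'
#' @param path CSV file.
#' @param n_vertices expected number of vertices.
#' @return character vector of labels in vertex order.
#' @export
read_region_labels <- function(path, n_vertices) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df)))
    stopf("label sidecar %s must have columns vertex_index,label", path)
  out <- rep("torso", n_vertices)
  idx <- as.integer(df$vertex_index)
  if (any(idx < 1L | idx > n_vertices))
    stopf("label sidecar %s: vertex_index outside 1..%d", path, n_vertices)
  out[idx] <- df$label
  out
}

#' @rdname read_region_labels
#' @param mesh a [body_mesh()] whose labels are written.
#' @export
write_region_labels <- function(mesh, path) {
  utils::write.csv(
    data.frame(vertex_index = seq_len(n_vertices(mesh)), label = mesh$regions),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
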