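#' Mesh resolution presets
#'
#' `"small"` is a 600-vertex test-scale body (280 torso, 2 x 80 arm, 2 x 80
#' leg vertices, no excluded regions). `"full"` reproduces the standard
#' full-resolution layout: 79,522 raw vertices of which 26,665 are retained
#' (12,697 torso, 6,984 arm, 6,984 leg) and 52,857 carry the `excluded` tag
#' (head, neck, hands, feet) — so flattening the retained regions yields a
#' 79,995-vector.
#'
#' @param name `"small"` or `"full"`.
#' @return a named list of per-region vertex counts and grid parameters.
#' @export
mesh_preset <- function(name = c("small", "full")) {
  name <- match.arg(name)
  if (name == "small")
    list(name = "small", torso = 280L, arm = 80L, leg = 80L, excluded = 0L,
         torso_nc = 14L, limb_nc = 5L, faces = TRUE)
  else
    list(name = "full", torso = 12697L, arm = 3492L, leg = 3492L,
         excluded = 52857L, torso_nc = 113L, limb_nc = 36L, faces = FALSE)
}

# points on a (possibly partial) cylindrical grid: count points, nc around the
# circumference, z from z0 to z1, radius a function of z and angle
cylinder_points <- function(count, nc, z0, z1, radius_fun, cx = 0, cy = 0) {
  i <- seq_len(count) - 1L
  row <- i %/% nc
  col <- i %% nc
  nrows <- max(row) + 1L
  z <- z0 + (z1 - z0) * if (nrows > 1L) row / (nrows - 1L) else 0.5
  theta <- 2 * pi * col / nc + 0.5 * pi * row / max(1L, nrows)  # slight twist
  r <- radius_fun(z, theta)
  cbind(x = cx + r * cos(theta), y = cy + 0.8 * r * sin(theta), z = z)
}

# deterministic quasi-uniform sphere points (Fibonacci lattice)
sphere_points <- function(count, centre, radius) {
  i <- seq_len(count) - 0.5
  phi <- acos(1 - 2 * i / count)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = centre[1] + radius * sin(phi) * cos(theta),
        y = centre[2] + radius * sin(phi) * sin(theta),
        z = centre[3] + radius * cos(phi))
}

# triangle faces for the first `count` points of an nc-wide grid
grid_faces <- function(count, nc, offset = 0L) {
  nrows <- ceiling(count / nc)
  out <- list()
  for (r in seq_len(nrows - 1L) - 1L) {
    for (c in seq_len(nc) - 1L) {
      a <- r * nc + c + 1L
      b <- r * nc + (c + 1L) %% nc + 1L
      d <- a + nc; e <- b + nc
      if (max(a, b, d, e) <= count)
        out[[length(out) + 1L]] <- rbind(c(a, b, d), c(b, e, d))
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out) + offset
}

#' Deterministic base body mesh for a preset
#'
#' A stylised, smooth human body built from cylindrical parts (elliptical
#' torso with shoulder/waist/hip profile, two arms, two legs) plus, in the
#' full preset, excluded head/hand/feet point clouds. Coordinates are in cm,
#' z up, and the construction is fully deterministic, so the mesh defines the
#' cohort correspondence. The `sex` argument scales overall stature and
#' base widths.
#'
#' @param preset `"small"` or `"full"`, or a [mesh_preset()] list.
#' @param sex `"female"` or `"male"`.
#' @return a [body_mesh()] with region labels set.
#' @export
base_body_mesh <- function(preset = "small", sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (is.character(preset)) preset <- mesh_preset(preset)
  hscale <- if (sex == "male") 1.0 else 164.63 / 179.41
  wscale <- if (sex == "male") 1.0 else 0.93
  torso_r <- function(z, theta) {
    zn <- (z - 70) / 60
    wscale * (13 + 2.5 * sin(pi * zn)^2 + 1.5 * zn - 2 * exp(-((zn - 0.45) / 0.22)^2))
  }
  limb_r <- function(base) function(z, theta) wscale * base
  parts <- list(
    torso = cylinder_points(preset$torso, preset$torso_nc,
                            70 * hscale, 130 * hscale, torso_r),
    arm_l = cylinder_points(preset$arm, preset$limb_nc, 75 * hscale,
                            128 * hscale, limb_r(4.2), cx = -22 * wscale),
    arm_r = cylinder_points(preset$arm, preset$limb_nc, 75 * hscale,
                            128 * hscale, limb_r(4.2), cx = 22 * wscale),
    leg_l = cylinder_points(preset$leg, preset$limb_nc, 2 * hscale,
                            68 * hscale, limb_r(6.5), cx = -9 * wscale),
    leg_r = cylinder_points(preset$leg, preset$limb_nc, 2 * hscale,
                            68 * hscale, limb_r(6.5), cx = 9 * wscale))
  regions <- rep(c("torso", "arm", "arm", "leg", "leg"),
                 times = vapply(parts, nrow, 1L))
  V <- do.call(rbind, parts)
  faces <- NULL
  if (isTRUE(preset$faces)) {
    offs <- cumsum(c(0L, vapply(parts, nrow, 1L)))
    ncs <- c(preset$torso_nc, rep(preset$limb_nc, 4L))
    fl <- Map(function(count, nc, off) grid_faces(count, nc, off),
              vapply(parts, nrow, 1L), ncs, offs[1:5])
    faces <- do.call(rbind, fl[!vapply(fl, is.null, TRUE)])
  }
  if (preset$excluded > 0L) {
    nh <- round(preset$excluded * 0.38)
    nhand <- round(preset$excluded * 0.155)
    nfoot1 <- round(preset$excluded * 0.155)
    nfoot2 <- preset$excluded - nh - 2L * nhand - nfoot1
    ex <- rbind(
      sphere_points(nh, c(0, 0, 142 * hscale), 9.5 * wscale),            # head+neck
      sphere_points(nhand, c(-22 * wscale, 0, 70 * hscale), 4 * wscale), # hands
      sphere_points(nhand, c(22 * wscale, 0, 70 * hscale), 4 * wscale),
      sphere_points(nfoot1, c(-9 * wscale, 4, 1), 5 * wscale),           # feet
      sphere_points(nfoot2, c(9 * wscale, 4, 1), 5 * wscale))
    V <- rbind(V, ex)
    regions <- c(regions, rep("excluded", preset$excluded))
  }
  body_mesh(V, id = sprintf("base_%s_%s", preset$name, sex),
            faces = faces, regions = regions)
}

# per-vertex unit radial direction (in xy) away from the owning part's axis
radial_directions <- function(mesh) {
  V <- mesh$vertices
  axis_x <- numeric(nrow(V))
  arm <- mesh$regions == "arm"; leg <- mesh$regions == "leg"
  axis_x[arm] <- sign(V[arm, 1]) * mean(abs(V[arm, 1]))
  axis_x[leg] <- sign(V[leg, 1]) * mean(abs(V[leg, 1]))
  dx <- V[, 1] - axis_x
  dy <- V[, 2]
  nrm <- sqrt(dx^2 + dy^2)
  nrm[nrm < 1e-9] <- 1
  cbind(dx / nrm, dy / nrm, 0)
}

#' Fat and muscle displacement fields for a base mesh
#'
#' Smooth per-vertex displacement directions (cm per kg) describing how the
#' body surface moves as fat or muscle mass increases. Fat deposits
#' preferentially on the torso with a waist/belly emphasis; muscle develops
#' preferentially on the limbs and shoulder girdle. Excluded regions do not
#' move. These fields are the generator's ground truth: generated cohorts
#' vary linearly in them.
#'
#' @param base a [base_body_mesh()].
#' @return list with `d_fat` and `d_muscle`, each an n x 3 matrix (cm/kg).
#' @export
displacement_fields <- function(base) {
  V <- base$vertices
  u <- radial_directions(base)
  z <- V[, 3]
  zr <- (z - min(z)) / max(1e-9, diff(range(z)))
  fat_w <- numeric(nrow(V))
  mus_w <- numeric(nrow(V))
  torso <- base$regions == "torso"; arm <- base$regions == "arm"
  leg <- base$regions == "leg"
  fat_w[torso] <- 1 + 0.8 * exp(-((zr[torso] - 0.55) / 0.18)^2)
  fat_w[arm] <- 0.20
  fat_w[leg] <- 0.35
  mus_w[torso] <- 0.25 + 0.55 * exp(-((zr[torso] - 0.92) / 0.12)^2)  # shoulders
  mus_w[arm] <- 1.0
  mus_w[leg] <- 0.9
  list(d_fat = 0.085 * fat_w * u, d_muscle = 0.12 * mus_w * u)
}

#' Synthetic cohort configuration
#'
#' @param sex `"female"` or `"male"`.
#' @param n number of identities.
#' @param preset mesh resolution preset name (see [mesh_preset()]).
#' @param params composition parameters (see [composition_params()]).
#' @param noise_sd per-coordinate Gaussian surface noise SD (cm).
#' @param jitter_rot_deg maximum random rigid rotation per identity (deg).
#' @param jitter_trans_cm maximum random translation per identity (cm).
#' @param seed optional RNG seed.
#' @return a named list of class `synth_config`.
#' @export
synth_config <- function(sex = c("female", "male"), n = 20L, preset = "small",
                         params = composition_params(sex), noise_sd = 0.3,
                         jitter_rot_deg = 5, jitter_trans_cm = 2,
                         seed = NULL) {
  sex <- match.arg(sex)
  if (n < 0) stopf("n must be >= 0")
  if (noise_sd < 0 || jitter_rot_deg < 0 || jitter_trans_cm < 0)
    stopf("noise and jitter magnitudes must be >= 0")
  structure(list(sex = sex, n = as.integer(n), preset = preset,
                 params = params, noise_sd = noise_sd,
                 jitter_rot_deg = jitter_rot_deg,
                 jitter_trans_cm = jitter_trans_cm, seed = seed),
            class = "synth_config")
}

#' Generate a corresponded synthetic body-mesh cohort
#'
#' Each identity's surface is `base + fatm * d_fat + smm * d_muscle + noise`,
#' followed by a small random rigid transform (simulating pose/position
#' variation between scans). Composition comes from [sample_composition()];
#' the linear ground truth (base mesh, displacement fields, per-identity
#' rigid transforms) is returned for parameter-recovery testing.
#'
#' @param config a [synth_config()].
#' @return list with `meshes` (list of [body_mesh()]), `records`
#'   (composition data frame) and `truth` (list: `base`, `d_fat`,
#'   `d_muscle`, `rotations`, `translations`).
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  maybe_seed(config$seed)
  records <- sample_composition(config$sex, config$n, config$params, seed = NULL)
  base <- base_body_mesh(config$preset, config$sex)
  fields <- displacement_fields(base)
  nv <- n_vertices(base)
  meshes <- vector("list", config$n)
  rotations <- vector("list", config$n)
  translations <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    V <- base$vertices +
      records$fatm[i] * fields$d_fat +
      records$smm[i] * fields$d_muscle
    if (config$noise_sd > 0)
      V <- V + matrix(stats::rnorm(nv * 3L, sd = config$noise_sd), nv, 3L)
    R <- diag(3)
    tr <- c(0, 0, 0)
    if (config$jitter_rot_deg > 0) {
      axis <- stats::rnorm(3)
      angle <- stats::runif(1, -config$jitter_rot_deg, config$jitter_rot_deg) * pi / 180
      R <- rotation_about_axis(axis, angle)
    }
    if (config$jitter_trans_cm > 0)
      tr <- stats::runif(3, -config$jitter_trans_cm, config$jitter_trans_cm)
    V <- sweep(V %*% R, 2L, tr, `+`)
    meshes[[i]] <- body_mesh(V, id = records$id[i], faces = base$faces,
                             regions = base$regions)
    rotations[[i]] <- R
    translations[[i]] <- tr
  }
  list(meshes = meshes, records = records,
       truth = list(base = base, d_fat = fields$d_fat,
                    d_muscle = fields$d_muscle,
                    rotations = rotations, translations = translations))
}
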