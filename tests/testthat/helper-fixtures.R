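# in-code fixtures shared across test files

make_tetra <- function(id = "tetra") {
  body_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
            id = id,
            faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)))
}

random_mesh <- function(n = 50, id = "rand", regions = NULL) {
  body_mesh(matrix(rnorm(n * 3, sd = 10), n, 3), id = id, regions = regions)
}

random_rotation <- function() {
  axis <- rnorm(3)
  shapecomp:::rotation_about_axis(axis, runif(1, 0, pi))
}

# direct access to the internal flattening for oracle comparisons
flatten_mesh_for_test <- function(mesh, topology)
  shapecomp:::flatten_mesh(mesh, topology)

# small noiseless, jitter-free cohort with exact linear ground truth
noiseless_cohort <- function(n = 12, sex = "male", seed = 11) {
  generate_cohort(synth_config(sex, n = n, preset = "small",
                               noise_sd = 0, jitter_rot_deg = 0,
                               jitter_trans_cm = 0, seed = seed))
}
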