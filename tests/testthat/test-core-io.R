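test_that("OBJ files round-trip with vertex order and coordinates preserved", {
  tet <- make_tetra()
  path <- withr::local_tempfile(fileext = ".obj")
  write_mesh(tet, path)
  back <- read_mesh(path)
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$faces, tet$faces)
  # file order is preserved exactly: permute and check it stays permuted
  perm <- tet
  perm$vertices <- tet$vertices[c(3, 1, 4, 2), ]
  perm$faces <- NULL
  write_mesh(perm, path)
  expect_equal(read_mesh(path)$vertices[1, ], c(x = 0, y = 1, z = 0))
})

test_that("PLY round-trips in ascii and binary, with the scalar channel", {
  set.seed(4)
  mesh <- make_tetra()
  scalar <- c(0, 0.25, 0.5, 1)
  for (binary in c(FALSE, TRUE)) {
    path <- withr::local_tempfile(fileext = ".ply")
    write_mesh(mesh, path, scalar = scalar, binary = binary)
    back <- read_mesh(path)
    expect_equal(back$vertices, mesh$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_identical(back$faces, mesh$faces)
    expect_equal(attr(back, "scalar"), scalar, tolerance = 1e-6)
  }
  # all-zero scalar is stored, not dropped
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(mesh, path, scalar = rep(0, 4))
  expect_equal(attr(read_mesh(path), "scalar"), rep(0, 4))
  # OBJ has no scalar channel
  path2 <- withr::local_tempfile(fileext = ".obj")
  expect_warning(write_mesh(mesh, path2, scalar = scalar), "scalar")
})

test_that("malformed mesh files and topology mismatches raise parse errors", {
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 bad 0"), path)
  expect_error(read_mesh(path), "line 2")
  writeLines(c("v 0 0 0", "v 1 0 0"), path)
  expect_error(read_mesh(path, expected_vertices = 4), "correspondence")
})

test_that("region label sidecars round-trip and drive region assignment", {
  mesh <- body_mesh(matrix(rnorm(12), 4, 3),
                    regions = c("torso", "arm", "leg", "excluded"))
  obj <- withr::local_tempfile(fileext = ".obj")
  lab <- withr::local_tempfile(fileext = ".csv")
  write_mesh(mesh, obj)
  write_region_labels(mesh, lab)
  back <- read_mesh(obj, labels = lab)
  expect_identical(back$regions, mesh$regions)
})

test_that("flatten and unflatten are mutually inverse, interleaving (x,y,z)", {
  set.seed(2)
  regions <- sample(c("torso", "arm", "leg"), 30, replace = TRUE)
  meshes <- lapply(1:4, function(i) random_mesh(30, paste0("id", i), regions))
  sm <- flatten_cohort(meshes)
  expect_equal(ncol(sm), 90)
  expect_identical(sm[2, 1:3],
                   unname(meshes[[2]]$vertices[1, ]))  # interleaved triples
  tp <- attr(sm, "topology")
  for (i in seq_along(meshes)) {
    back <- unflatten(sm[i, ], tp)
    expect_identical(back$vertices, meshes[[i]]$vertices)
  }
  # region subsetting: torso-only rows, filled back via donor mesh
  sm_t <- flatten_cohort(meshes, regions = "torso")
  expect_equal(ncol(sm_t), 3 * sum(regions == "torso"))
  back <- unflatten(sm_t[1, ], attr(sm_t, "topology"), fill = meshes[[1]])
  expect_identical(back$vertices, meshes[[1]]$vertices)
  expect_error(unflatten(sm_t[1, 1:5], attr(sm_t, "topology")), "dimension")
  # two-vertex mesh flattens to a length-6 row
  expect_equal(ncol(flatten_cohort(list(random_mesh(2)))), 6)
})

test_that("flattened mean shape equals the coordinate-wise cohort mean", {
  set.seed(3)
  meshes <- lapply(1:6, function(i) random_mesh(25, paste0("id", i)))
  sm <- flatten_cohort(meshes)
  mean_mesh <- unflatten(colMeans(sm), attr(sm, "topology"))
  brute <- Reduce(`+`, lapply(meshes, `[[`, "vertices")) / 6
  expect_equal(mean_mesh$vertices, brute, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("composition tables are validated row by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "id,sex,fatm_kg,smm_kg,height_cm,weight_kg,bmi,age,psych",
    "ok1,female,17.65,26.34,164.63,64.55,23.8156,29,0.1",
    "bad_fat,male,-1,30,180,80,24.7,30,0",
    "bad_bmi,male,15,40,180,80,30.0,30,0",
    "bad_sum,male,50,40,85,85,26.2,30,0",
    "ok2,male,14.5,39.6,179.41,81.6,25.35,28,-0.2"), path)
  expect_warning(df <- read_composition_table(path), "row 2")
  expect_identical(df$id, c("ok1", "ok2"))
  # bmi is recomputed from weight/height: hand oracle 64.55 / 1.6463^2
  expect_equal(df$bmi[1], 64.55 / 1.6463^2, tolerance = 1e-9)
  # empty table: empty records plus a warning
  writeLines("id,sex,fatm_kg,smm_kg", path)
  expect_warning(empty <- read_composition_table(path), "empty")
  expect_equal(nrow(empty), 0)
  # missing mandatory column is a schema error
  writeLines(c("id,sex,fatm_kg", "a,male,10"), path)
  expect_error(read_composition_table(path), "schema")
})

test_that("composition tables round-trip through the canonical dialect", {
  rec <- sample_composition("female", 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_composition_table(rec, path)
  back <- read_composition_table(path)
  expect_equal(back$fatm, rec$fatm, tolerance = 1e-6)
  expect_equal(back$bmi, rec$bmi, tolerance = 1e-4)
})
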