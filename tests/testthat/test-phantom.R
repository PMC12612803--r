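test_that("sphere voxelization uses strict centre-distance inclusion", {
  spec <- phantom_spec(0.3, 0.1, extent = c(0.8, 0.8, 0.8), seed = 1)
  # a sphere of diameter 2 dx centred on a voxel centre covers only that voxel:
  # the face neighbours sit exactly at r and the inequality is strict
  ctr <- c(0.425, 0.425, 0.425)   # centre of voxel (9, 9, 9)
  idx <- rasterize_sphere(ctr, 2 * 0.05, spec)
  expect_equal(nrow(idx), 1L)
  expect_equal(unname(idx[1, ]), c(9L, 9L, 9L))
  expect_equal(nrow(idx), brute_force_sphere_count(ctr, 0.1, spec))
})

test_that("voxelized sphere volume matches the brute-force lattice count", {
  spec <- phantom_spec(0.6, 0.1, extent = c(1.6, 1.6, 1.6), seed = 1)
  ctr <- c(0.775, 0.775, 0.775)   # a voxel centre well inside the grid
  idx <- rasterize_sphere(ctr, 0.6, spec)
  expect_equal(nrow(idx), brute_force_sphere_count(ctr, 0.6, spec))
  # within 5% of the continuum volume (4/3) pi 6^3 ~ 905 voxel volumes
  expect_lt(abs(nrow(idx) - 4 / 3 * pi * 6^3), 0.05 * 4 / 3 * pi * 6^3)
  # off-centre placement still matches brute force
  ctr2 <- ctr + c(0.013, -0.021, 0.007)
  expect_equal(nrow(rasterize_sphere(ctr2, 0.6, spec)),
               brute_force_sphere_count(ctr2, 0.6, spec))
})

test_that("degenerate sphere inputs are rejected", {
  spec <- phantom_spec(0.3, 0.1, extent = c(0.8, 0.8, 0.8))
  expect_error(rasterize_sphere(c(0.4, 0.4, 0.4), 0, spec), "positive")
  expect_error(rasterize_sphere(c(0.4, 0.4, 0.4), -1, spec), "positive")
  expect_error(phantom_spec(0, 0.1), "positive")
  expect_error(phantom_spec(0.05, 0.1), "twice the voxel size")
  expect_error(phantom_spec(0.3, 1.0), "\\[0, 1\\)")
  expect_error(phantom_spec(0.3, 0.1, extent = c(0.83, 0.8, 0.8)),
               "integer multiple")
})

test_that("porosity is the marrow-voxel fraction", {
  lab <- array(FALSE, c(4, 4, 4))
  expect_equal(measure_porosity(lab), 0)
  lab[] <- TRUE
  expect_equal(measure_porosity(lab), 1)
  lab[] <- rep(c(TRUE, FALSE), 32)
  expect_equal(measure_porosity(lab), 0.5)
  expect_error(measure_porosity(array(logical(0), c(0, 1, 1))), "empty")
})

test_that("generation hits the porosity target and records provenance", {
  # the full-scale 3D geometry with 0.3 mm pores at 25% porosity
  spec <- phantom_spec(0.3, 0.25, seed = 7)
  ph <- generate_phantom(spec)
  expect_lte(abs(measure_porosity(ph) - 0.25), 0.005)
  expect_equal(ph$achieved_porosity, measure_porosity(ph))
  expect_gt(ph$n_spheres_placed, 0)
})

test_that("a zero-porosity target yields an untouched cortical block", {
  ph <- generate_phantom(phantom_spec(0.3, 0, extent = c(0.8, 0.8, 0.8)))
  expect_equal(ph$n_spheres_placed, 0L)
  expect_false(any(ph$labels))
  expect_equal(ph$achieved_porosity, 0)
})

test_that("generation is bit-reproducible for a fixed spec and seed", {
  spec <- phantom_spec(0.2, 0.3, extent = c(1.6, 1.6, 1.6),
                       dimensionality = 2, seed = 42,
                       porosity_tolerance = 0.02)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$n_spheres_placed, b$n_spheres_placed)
  # a different seed gives a different arrangement
  spec2 <- phantom_spec(0.2, 0.3, extent = c(1.6, 1.6, 1.6),
                        dimensionality = 2, seed = 43,
                        porosity_tolerance = 0.02)
  expect_false(identical(generate_phantom(spec2)$labels, a$labels))
})

test_that("overlapping placement is bounded by the single-sphere volume", {
  spec <- phantom_spec(0.3, 0.4, extent = c(1.6, 1.6, 1.6),
                       dimensionality = 2, seed = 5,
                       porosity_tolerance = 0.05)
  ph <- generate_phantom(spec)
  single <- nrow(rasterize_sphere(c(0.8, 0, 0.8), 0.3, spec))
  total <- prod(spec$dims)
  expect_lte(ph$achieved_porosity,
             ph$n_spheres_placed * single / total + 1e-12)
})

test_that("finer pores overshoot the target less, on average over seeds", {
  overshoot <- function(d, seed) {
    spec <- phantom_spec(d, 0.25, extent = c(1.6, 1.6, 1.6),
                         dimensionality = 2, seed = seed,
                         porosity_tolerance = 0.2)
    generate_phantom(spec)$achieved_porosity - 0.25
  }
  fine <- vapply(1:20, function(s) overshoot(0.2, s), numeric(1))
  coarse <- vapply(1:20, function(s) overshoot(0.6, s), numeric(1))
  expect_true(all(fine >= 0) && all(coarse >= 0))  # stop at first crossing
  expect_lt(mean(fine), mean(coarse))
})

test_that("phantoms round-trip through NIfTI with their sidecar", {
  ph <- generate_phantom(phantom_spec(0.3, 0.2, extent = c(0.8, 0.8, 0.8),
                                      seed = 3, porosity_tolerance = 0.05))
  path <- withr::local_tempfile(fileext = ".nii")
  write_phantom(ph, path)
  img <- RNifti::readNifti(path)
  expect_equal(array(as.logical(img), dim = dim(ph$labels)), ph$labels)
  side <- jsonlite::read_json(sub("\\.nii$", ".json", path))
  expect_equal(side$achieved_porosity, ph$achieved_porosity)
  expect_equal(side$seed, 3L)
})
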