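test_that("zero-noise rendering round-trips the injected series exactly", {
  set.seed(1)
  vals <- matrix(rnorm(20), ncol = 2)
  grid <- volume_grid(c(16, 16, 16), voxel_size_mm = 2)
  rois <- list(roi_spec("a", c(-6, 0, 0), 4), roi_spec("b", c(6, 0, 0), 4))
  rv <- render_volumes(vals, rois, grid, baseline = 100,
                       observation_noise_sd = 0)
  s <- extract_mean_series(rv$volumes, rv$masks, 2)
  expect_equal(unname(s$values), vals + 100, tolerance = 1e-12)
})

test_that("extraction error of a noisy 81-voxel sphere has sd near 1/9", {
  grid <- volume_grid(c(17, 17, 17), voxel_size_mm = 2)
  roi <- list(roi_spec("a", c(0, 0, 0), 5))
  n_t <- 400
  vals <- matrix(0, n_t, 1)
  rv <- render_volumes(vals, roi, grid, baseline = 0,
                       observation_noise_sd = 1, seed = 9)
  expect_length(rv$masks$a, 81L)
  s <- extract_mean_series(rv$volumes, rv$masks, 2)
  # mean of 81 i.i.d. N(0,1) draws has sd 1/9
  expect_equal(sd(s$values[, 1]), 1 / 9, tolerance = 0.05)
})

test_that("ill-posed renderings are rejected", {
  grid <- volume_grid(c(32, 32, 32), voxel_size_mm = 2)
  mid <- roi_spec("mid", c(0, 0, 0), 10)
  corner <- roi_spec("corner", c(-31, -31, -31), 10)
  expect_silent(render_volumes(matrix(0, 2, 1), list(mid), grid))
  expect_error(render_volumes(matrix(0, 2, 1), list(corner), grid),
               "fit inside")
  overlapping <- list(roi_spec("a", c(0, 0, 0), 6),
                      roi_spec("b", c(4, 0, 0), 6))
  expect_error(render_volumes(matrix(0, 2, 2), overlapping, grid),
               "overlap")
})

test_that("NIfTI write/read preserves data and affine", {
  set.seed(2)
  arr <- array(rnorm(10 * 10 * 8 * 3), c(10, 10, 8, 3))
  grid <- volume_grid(c(10, 10, 8), voxel_size_mm = 2,
                      origin_mm = c(-9, -9, -7))
  f <- tempfile(fileext = ".nii.gz")
  write_volumes_nifti(arr, grid$affine, f)
  back <- read_volumes_nifti(f)
  expect_equal(back$volumes, arr, tolerance = 1e-6)
  expect_equal(matrix(as.numeric(back$grid$affine), 4, 4),
               matrix(as.numeric(grid$affine), 4, 4), tolerance = 1e-5)
})

test_that("simulate_run chains paradigm, VAR, HRF and rendering", {
  cfg <- one_way_config(seed = 3, n_nodes = 2)
  par <- generate_paradigm(2, 10, 20, "task", 2, seed = 3)
  grid <- volume_grid(c(16, 16, 16), voxel_size_mm = 2)
  rois <- list(roi_spec("a", c(-6, 0, 0), 4), roi_spec("b", c(6, 0, 0), 4))
  run <- simulate_run(cfg, par, rois, grid, render = TRUE)
  expect_equal(dim(run$volumes)[4], par$n_volumes)
  expect_equal(nrow(run$series$values), par$n_volumes)
  expect_identical(run$series$condition_labels, condition_labels(par))
  expect_named(run$ground_truth$adjacency)
})
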