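test_that("sphere mask matches brute-force lattice enumeration", {
  # 5 mm radius on a 2 mm grid, centre on a voxel centre: enumerate all
  # lattice offsets with squared distance <= 25 mm^2
  brute <- 0L
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    if ((2 * i)^2 + (2 * j)^2 + (2 * k)^2 <= 25) brute <- brute + 1L
  }
  grid <- volume_grid(c(33, 33, 33), voxel_size_mm = 2)
  mask <- build_sphere_mask(roi_spec("m1", c(0, 0, 0), 5), grid)
  expect_equal(length(mask), brute)
  expect_equal(length(mask), 81L)
})

test_that("degenerate and failing spheres behave as specified", {
  grid <- volume_grid(c(11, 11, 11), voxel_size_mm = 2)
  tiny <- build_sphere_mask(roi_spec("pt", c(0, 0, 0), 0.1), grid)
  expect_length(tiny, 1L)
  expect_error(
    build_sphere_mask(roi_spec("far", c(500, 0, 0), 5), grid),
    "far")
})

test_that("the four seed-node spheres are pairwise disjoint on a head grid", {
  # whole-head grid: 2 mm voxels spanning +-90 mm left-right and similar
  grid <- volume_grid(c(91, 109, 91), voxel_size_mm = 2,
                      origin_mm = c(-90, -126, -72))
  rois <- list(roi_spec("A1_2_3ulhf_l", c(-29, -7, 64), 10),
               roi_spec("A9_46v_l", c(-48, 63, 28), 5),
               roi_spec("A1_2_3ulhf_r", c(18, -3, 64), 10),
               roi_spec("A9_46v_r", c(35, 67, 32), 5))
  masks <- lapply(rois, build_sphere_mask, grid = grid)
  all_idx <- unlist(masks)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_true(all(lengths(masks) > 0L))
})

test_that("mask size is monotone in radius and symmetric under reflection", {
  grid <- volume_grid(c(21, 21, 21), voxel_size_mm = 2)
  sizes <- sapply(c(2, 4, 6, 8), function(r)
    length(build_sphere_mask(roi_spec("s", c(0, 0, 0), r), grid)))
  expect_true(all(diff(sizes) >= 0))
  m1 <- build_sphere_mask(roi_spec("l", c(-6, 2, 0), 5), grid)
  m2 <- build_sphere_mask(roi_spec("r", c(6, 2, 0), 5), grid)
  # reflect voxel x-index through the grid midplane
  idx <- arrayInd(m1, grid$shape)
  idx[, 1] <- grid$shape[1] + 1L - idx[, 1]
  m1_reflected <- sort(idx[, 1] + (idx[, 2] - 1L) * grid$shape[1] +
                         (idx[, 3] - 1L) * prod(grid$shape[1:2]))
  expect_equal(m1_reflected, sort(m2))
})

test_that("mean extraction is exact for single-voxel and constant fields", {
  grid <- volume_grid(c(8, 8, 8), voxel_size_mm = 2)
  vols <- array(7, dim = c(8, 8, 8, 3))
  mask <- build_sphere_mask(roi_spec("a", c(0, 0, 0), 3), grid)
  s <- extract_mean_series(vols, list(a = mask), tr_seconds = 2)
  expect_equal(unname(s$values[, 1]), rep(7, 3))
  # single-voxel mask returns the raw voxel time course
  set.seed(1)
  vols[] <- rnorm(length(vols))
  single <- which(array(seq_len(8^3), c(8, 8, 8)) == 100)
  s2 <- extract_mean_series(vols, list(v = 100L), 2)
  flat <- matrix(vols, 8^3, 3)
  expect_equal(unname(s2$values[, 1]), flat[100, ])
})

test_that("mean extraction is linear in the volume data", {
  set.seed(2)
  v1 <- array(rnorm(6^3 * 4), c(6, 6, 6, 4))
  v2 <- array(rnorm(6^3 * 4), c(6, 6, 6, 4))
  grid <- volume_grid(c(6, 6, 6), voxel_size_mm = 2)
  mask <- list(m = build_sphere_mask(roi_spec("m", c(0, 0, 0), 4), grid))
  lhs <- extract_mean_series(2 * v1 - 3 * v2, mask, 2)$values
  rhs <- 2 * extract_mean_series(v1, mask, 2)$values -
    3 * extract_mean_series(v2, mask, 2)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("activation feature is the task-minus-rest BOLD difference", {
  vals <- matrix(c(100, 103, 100, 100, 101, 99), ncol = 2)
  s <- roi_series(vals, 2, c("a", "b"), c("rest", "MIL", "rest"))
  act <- compute_active(s, c(a = 100, b = 100))
  expect_equal(unname(act[2, "a"]), 3)
  expect_equal(unname(act[1, "a"]), 0)
  expect_error(compute_active(s, c(a = 100)), "missing")
  # baseline from labeled rest volumes equals the direct mean-difference
  set.seed(3)
  vals2 <- matrix(rnorm(60, mean = 100), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  labels <- rep(c("rest", "MIL", "rest"), each = 10)
  s2 <- roi_series(vals2, 2, c("a", "b"), labels)
  base <- rest_baseline(s2, n_transition = 0)
  direct <- colMeans(vals2[labels == "rest", ])
  expect_equal(base, direct)
  expect_equal(compute_active(s2, base),
               sweep(vals2, 2, direct, "-"))
})

test_that("initial-volume discarding preserves order and guards bounds", {
  s <- roi_series(matrix(1:150, ncol = 1), 2, "a",
                  rep(c("rest", "MIL"), 75))
  expect_identical(discard_initial(s, 0), s)
  s10 <- discard_initial(s, 10)
  expect_equal(nrow(s10$values), 140)
  expect_equal(unname(s10$values[1, 1]), 11)
  expect_equal(s10$condition_labels[1], s$condition_labels[11])
  expect_error(discard_initial(s, 150), "smaller")
})

test_that("transition trimming drops the first volumes of every run", {
  labels <- rep(c("rest", "MIL", "rest"), c(10, 5, 10))
  stable <- trim_transitions(labels, 4)
  # the 5-volume task block keeps exactly one stable volume
  expect_equal(sum(labels[stable] == "MIL"), 1L)
  expect_equal(stable[labels[stable] == "MIL"], 15L)
  expect_equal(trim_transitions(labels, 0), seq_along(labels))
  # a run no longer than the trim contributes nothing
  labels4 <- rep(c("rest", "MIL"), c(10, 4))
  expect_equal(sum(trim_transitions(labels4, 4) > 10), 0L)
  # returned indices always carry their own run's label
  set.seed(4)
  rand <- sample(c("a", "b", "rest"), 200, replace = TRUE)
  idx <- trim_transitions(rand, 2)
  runs <- rle(rand)
  run_of <- rep(seq_along(runs$lengths), runs$lengths)
  for (i in idx) expect_identical(rand[i], runs$values[run_of[i]])
})

test_that("ROI series CSV round-trips values and labels", {
  set.seed(5)
  s <- roi_series(matrix(rnorm(40), ncol = 2), 2, c("x", "y"),
                  rep(c("rest", "MIL"), 10))
  f <- tempfile(fileext = ".csv")
  write_roi_series(s, f)
  s2 <- read_roi_series(f, 2)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_identical(s2$condition_labels, s$condition_labels)
})
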