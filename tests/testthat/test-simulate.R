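test_that("latent VAR matches an independently coded recursion", {
  cfg <- one_way_config(coupling = 0.8, base_ar = 0.5, seed = 7)
  labels <- rep(c("rest", "task"), each = 50)
  sim <- simulate_latent_signals(cfg, labels)
  # brute-force two-line recursion with the same seeded innovations
  set.seed(7)
  eps <- matrix(rnorm(2 * 100), nrow = 2)
  x <- matrix(0, 2, 100)
  x[, 1] <- eps[, 1]
  for (t in 2:100) {
    c12 <- if (labels[t] == "task") 0.8 else 0
    x[1, t] <- 0.5 * x[1, t - 1] + eps[1, t]
    x[2, t] <- 0.5 * x[2, t - 1] + c12 * x[1, t - 1] + eps[2, t]
  }
  expect_equal(sim$latent, x)
})

test_that("same seed gives bit-identical simulations", {
  cfg <- one_way_config(seed = 11)
  a <- simulate_latent_signals(cfg, rep("task", 200))
  b <- simulate_latent_signals(cfg, rep("task", 200))
  expect_identical(a$latent, b$latent)
})

test_that("zero coupling leaves nodes uncorrelated at lag 1", {
  cfg <- simulation_config(2, 0.5, list(), seed = 2)
  sim <- simulate_latent_signals(cfg, rep("rest", 2000))
  r <- cor(sim$latent[1, -2000], sim$latent[2, -1])
  expect_lt(abs(r), 0.1)
})

test_that("condition-switched coupling raises lag-1 cross-correlation in task", {
  cfg <- one_way_config(coupling = 0.8, seed = 5)
  labels <- rep(rep(c("rest", "task"), each = 50), 20)
  sim <- simulate_latent_signals(cfg, labels)
  x <- sim$latent
  lag1 <- function(keep) {
    idx <- which(keep[-1])
    cor(x[1, idx], x[2, idx + 1])
  }
  expect_gt(lag1(labels == "task"), lag1(labels == "rest") + 0.2)
})

test_that("unstable condition systems are rejected before simulation", {
  cpl <- matrix(c(0, 0.8, 0.8, 0), 2, 2)
  expect_error(simulation_config(2, 0.5, list(task = cpl)),
               "unstable")
  # accepted configs have spectral radius < 1 in every condition
  cfg <- one_way_config(coupling = 0.9, base_ar = 0.6)
  A <- dwgcfmri:::transition_matrix(cfg, "task")
  expect_lt(max(Mod(eigen(A)$values)), 1)
})

test_that("double-gamma kernel peaks 2-6 s after an impulse", {
  y <- apply_hrf(c(1, rep(0, 29)), tr_seconds = 1)
  peak_idx <- which.max(y) - 1L   # seconds post-impulse at tr = 1
  expect_gte(peak_idx, 2L)
  expect_lte(peak_idx, 6L)
})

test_that("hemodynamic convolution is causal, linear and unit-gain", {
  expect_equal(apply_hrf(rep(0, 40), 2), rep(0, 40))
  # constant input converges to the constant (unit-sum kernel)
  y <- apply_hrf(rep(3, 60), 1)
  expect_equal(tail(y, 1), 3, tolerance = 1e-10)
  # hand convolution oracle on 10 samples
  h <- hrf_kernel(2)
  x <- c(1, -2, 0.5, 3, 0, 0, 1, -1, 2, 0.25)
  manual <- sapply(seq_along(x), function(t)
    sum(h[1:t] * x[t:1]))
  expect_equal(apply_hrf(x, 2)[seq_along(x)], manual, tolerance = 1e-12)
  expect_error(apply_hrf(c(1, NA, 2), 1), "finite")
})

test_that("variance-matched noise keeps node variances flat under coupling", {
  cpl <- matrix(0, 3, 3)
  cpl[1, 2] <- 0.7
  sds <- variance_matched_noise(0.4, cpl, 1)
  # independent route: iterate the discrete Lyapunov recursion
  A <- diag(0.4, 3) + t(cpl)
  Q <- diag(sds^2, 3)
  Sigma <- Q
  for (i in 1:2000) Sigma <- A %*% Sigma %*% t(A) + Q
  expect_equal(diag(Sigma), rep(1 / (1 - 0.4^2), 3), tolerance = 1e-8)
  expect_error(variance_matched_noise(0.3, {
    m <- matrix(0, 2, 2); m[1, 2] <- 2; m
  }, 1), "unstable|too strong")
})
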