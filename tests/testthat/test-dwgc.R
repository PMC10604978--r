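test_that("window predictors match the textbook normal-equations oracle", {
  cfg <- one_way_config(coupling = 0.6, seed = 21)
  sim <- simulate_latent_signals(cfg, rep("task", 200))
  src <- sim$latent[1, ]
  tgt <- sim$latent[2, ]
  spec <- ar_model_spec(order_p = 1, train_span = 40)
  fit <- fit_window_predictors(src, tgt, t = 100, spec)
  u <- 60:99
  Xr <- cbind(1, tgt[u - 1])
  Xf <- cbind(Xr, src[u - 1])
  br <- solve(crossprod(Xr), crossprod(Xr, tgt[u]))
  bf <- solve(crossprod(Xf), crossprod(Xf, tgt[u]))
  expect_equal(unname(fit$coefficients$restricted), drop(br),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients$full), drop(bf), tolerance = 1e-8)
  expect_equal(fit$restricted(100), drop(c(1, tgt[99]) %*% br),
               tolerance = 1e-10)
})

test_that("nested-model identities hold in degenerate cases", {
  set.seed(1)
  # constant target: restricted predictor is exact, in-window MSE 0
  w <- window_gc(rnorm(100), rep(5, 100), t = 50, k = 4)
  expect_equal(w$L1, 0, tolerance = 1e-15)
  # all-zero source: full predictor equals restricted, L1 = L2
  w0 <- window_gc(rep(0, 150), rnorm(150), t = 60, k = 4)
  expect_equal(w0$L1, w0$L2, tolerance = 1e-8)
})

test_that("independent white noise yields median F near 1", {
  set.seed(2)
  conn <- dwgc_sequence(cbind(a = rnorm(400), b = rnorm(400)),
                        ar_model_spec(), k = 4)
  expect_equal(median(conn$F), 1, tolerance = 0.1)
})

test_that("noise-free perfect coupling saturates the epsilon floor", {
  set.seed(3)
  x <- rnorm(200)
  y <- c(0, head(x, -1))    # y(t) = x(t-1) exactly
  w <- window_gc(x, y, t = 60, k = 4, epsilon = 1e-12)
  expect_true(w$saturated)
  expect_equal(w$F, w$L1 / 1e-12)
})

test_that("window-level direction agrees with a full-series Granger test", {
  skip_if_not_installed("lmtest")
  frac <- numeric(3)
  for (s in 1:3) {
    cfg <- one_way_config(coupling = 0.8, seed = 30 + s)
    sim <- simulate_latent_signals(cfg, rep("task", 600))
    x <- t(sim$latent)
    conn <- dwgc_sequence(x, ar_model_spec(), 4)
    frac[s] <- mean(conn$F[, "roi1->roi2"] > conn$F[, "roi2->roi1"])
    gt_true <- lmtest::grangertest(x[, 2] ~ x[, 1], order = 1)$F[2]
    gt_rev <- lmtest::grangertest(x[, 1] ~ x[, 2], order = 1)$F[2]
    expect_gt(gt_true, gt_rev)
  }
  expect_true(all(frac > 0.7))
})

test_that("window count follows the admissibility arithmetic", {
  set.seed(4)
  x <- cbind(a = rnorm(100), b = rnorm(100))
  spec <- ar_model_spec(order_p = 1, train_span = 40)
  conn <- dwgc_sequence(x, spec, k = 4, stride = 1)
  # first start needs train_span + p volumes of history; last window must
  # fit: (100 - 4 + 1) - (40 + 1 + 1) + 1 windows
  expect_equal(length(conn$window_starts), 56L)
  expect_equal(conn$window_starts[1], 42L)
  expect_equal(ncol(conn$F), 2L)
  expect_error(window_gc(x[, 1], x[, 2], t = 98, k = 4), "overruns")
  expect_error(window_gc(x[, 1], x[, 2], t = 10, k = 4), "history")
  expect_error(dwgc_sequence(x[, 1, drop = FALSE], spec, 4), "2 nodes")
})

test_that("F is invariant to common offset and positive rescaling", {
  set.seed(5)
  x <- rnorm(200)
  y <- 0.4 * c(0, head(x, -1)) + rnorm(200)
  w1 <- window_gc(x, y, 60, 4)
  w2 <- window_gc(3 + 2 * x, 3 + 2 * y, 60, 4)
  expect_equal(w1$F, w2$F, tolerance = 1e-10)
})

test_that("thresholding keeps the statistic iff it reaches omega", {
  expect_equal(apply_threshold(2.0, 1.5), 2.0)
  expect_equal(apply_threshold(1.0, 1.5), 0)
  expect_equal(apply_threshold(1.5, 1.5), 1.5)   # boundary inclusive
  expect_equal(apply_threshold(c(0.5, 3), 1), c(0, 3))
})

test_that("surrogate threshold calibration is seeded and monotone in alpha", {
  set.seed(6)
  x <- matrix(rnorm(600 * 2), ncol = 2)
  spec <- ar_model_spec()
  om1 <- calibrate_threshold(x, spec, 4, alpha = 0.05, seed = 9)
  om2 <- calibrate_threshold(x, spec, 4, alpha = 0.05, seed = 9)
  expect_identical(om1, om2)
  om_loose <- calibrate_threshold(x, spec, 4, alpha = 0.9, seed = 9)
  expect_true(all(om_loose[!is.na(om_loose)] < om1[!is.na(om1)]))
  expect_error(calibrate_threshold(x, spec, 4, alpha = 1.5), "alpha")
  expect_error(calibrate_threshold(x[1:30, ], spec, 4), "short")
})

test_that("full model nests the restricted one in in-sample mode", {
  spec_is <- ar_model_spec(train_span = 30, fit_mode = "in_sample")
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(120)
    y <- 0.3 * c(0, head(x, -1)) + rnorm(120)
    conn <- dwgc_sequence(cbind(x = x, y = y), spec_is, 4)
    expect_true(all(conn$L2 <= conn$L1 + 1e-12))
  }
  # out-of-sample: holds on long-run averages when coupling is real
  cfg <- one_way_config(coupling = 0.8, seed = 40)
  sim <- simulate_latent_signals(cfg, rep("task", 800))
  conn <- dwgc_sequence(t(sim$latent), ar_model_spec(), 4)
  expect_gt(mean(conn$L1[, "roi1->roi2"]), mean(conn$L2[, "roi1->roi2"]))
})

test_that("connectivity export produces aligned long CSV plus sidecar", {
  set.seed(7)
  conn <- dwgc_sequence(cbind(a = rnorm(120), b = rnorm(120)),
                        ar_model_spec(), 4, omega = 1.5)
  df <- as.data.frame(conn)
  expect_equal(nrow(df), length(conn$window_starts) * 2L)
  expect_true(all(df$F_thresholded %in% c(0, df$F)))
  f <- tempfile(fileext = ".csv")
  write_connectivity(conn, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", ".json", f)))
  side <- jsonlite::read_json(sub("\\.csv$", ".json", f))
  expect_equal(side$k, 4L)
})
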