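stream_fixture <- function(seed = 1, n_blocks = 6, mode = "dwgc") {
  cfg <- one_way_config(coupling = 0.8, seed = seed, n_nodes = 2)
  cfg$coupling_schedule <- list(MIL = cfg$coupling_schedule$task)
  par <- generate_paradigm(2, 10, 20, "MIL", n_blocks, seed = seed)
  run <- simulate_run(cfg, par)
  config <- pipeline_config(n_discard = 10, mode = mode, alpha = NULL,
                            omega = 1.2)
  pipe <- train_pipeline(run$series, config,
                         classifier_spec("gaussian_nb"), seed = seed)
  list(series = run$series, pipe = pipe, paradigm = par)
}

test_that("streaming replay reproduces batch decoding bit-for-bit", {
  fx <- stream_fixture(seed = 2)
  batch <- batch_decode(fx$series, fx$pipe)
  stream <- stream_replay(fx$series, fx$pipe)
  merged <- merge(batch, stream$decisions, by = "volume")
  expect_gt(nrow(merged), 40)
  expect_identical(merged$predicted.x, merged$predicted.y)
})

test_that("stream/batch equality also holds with activation features", {
  fx <- stream_fixture(seed = 3, mode = "both")
  batch <- batch_decode(fx$series, fx$pipe)
  stream <- stream_replay(fx$series, fx$pipe)
  merged <- merge(batch, stream$decisions, by = "volume")
  expect_gt(nrow(merged), 30)
  expect_identical(merged$predicted.x, merged$predicted.y)
})

test_that("decision count matches warm-up arithmetic", {
  fx <- stream_fixture(seed = 4)
  stream <- stream_replay(fx$series, fx$pipe)
  n_total <- nrow(fx$series$values)
  spec <- fx$pipe$config$ar_spec
  # decisions start once n_discard + train_span + p + k - 1 volumes passed
  warmup <- fx$pipe$config$n_discard + spec$train_span + spec$order_p +
    fx$pipe$config$k - 1L
  expect_equal(nrow(stream$decisions), n_total - warmup)
  expect_equal(stream$volumes_processed, n_total)
  expect_true(all(diff(stream$decisions$volume) == 1L))
  expect_true(all(c("t_feature_s", "t_classify_s", "t_total_s") %in%
                    names(stream$decisions)))
})

test_that("decisions are causal: later volumes never change earlier ones", {
  fx <- stream_fixture(seed = 5)
  full <- stream_replay(fx$series, fx$pipe)
  altered <- fx$series
  cut <- nrow(altered$values) - 20L
  altered$values[(cut + 1L):nrow(altered$values), ] <- 999
  alt <- stream_replay(altered, fx$pipe)
  keep <- full$decisions$volume <= cut - fx$pipe$config$n_discard -
    fx$pipe$config$k
  expect_identical(full$decisions$predicted[keep],
                   alt$decisions$predicted[seq_len(sum(keep))])
})

test_that("a truncated volume feed stops gracefully with a partial log", {
  fx <- stream_fixture(seed = 6)
  mat <- fx$series$values
  labels <- fx$series$condition_labels
  feed <- function(v) if (v <= 100) mat[v, ] else NULL
  out <- stream_replay(feed, fx$pipe, labels = labels, n_volumes = 500)
  expect_equal(out$volumes_processed, 100L)
  expect_gt(nrow(out$decisions), 0)
  expect_lt(nrow(out$decisions), 100)
})

test_that("feature-layout mismatches are caught", {
  fx <- stream_fixture(seed = 7)
  wide <- roi_series(cbind(fx$series$values, extra = 0), 2,
                     c("roi1", "roi2", "extra"),
                     fx$series$condition_labels)
  expect_error(stream_replay(wide, fx$pipe), "mismatch")
})
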