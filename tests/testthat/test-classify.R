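make_conn <- function(n_nodes = 4, n_t = 120, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n_t * n_nodes), ncol = n_nodes,
              dimnames = list(NULL, paste0("node", seq_len(n_nodes))))
  dwgc_sequence(x, ar_model_spec(), 4)
}

test_that("feature assembly yields the documented column counts", {
  conn <- make_conn()
  labels <- rep(c("rest", "MIL", "MIR"), length.out = 120)
  fd <- assemble_features(conn, NULL, labels, "dwgc")
  expect_equal(ncol(fd$x), 4 * 3)
  act <- matrix(rnorm(120 * 4), ncol = 4,
                dimnames = list(NULL, paste0("node", 1:4)))
  fb <- assemble_features(conn, act, labels, "both")
  expect_equal(ncol(fb$x), 12 + 4)
  expect_equal(fb$provenance, c(rep("dwgc", 12), rep("activation", 4)))
  # rows align across modes
  fa <- assemble_features(conn, act, labels, "activation")
  expect_identical(fa$volume, fd$volume)
  expect_identical(fa$labels, fd$labels)
  expect_error(assemble_features(conn, NULL, labels[1:20], "dwgc"),
               "windows extend")
  expect_error(assemble_features(conn, NULL, labels, "both"), "required")
})

test_that("hemodynamic lag correction shifts labels, not features", {
  conn <- make_conn()
  labels <- rep(c("rest", "MIL"), each = 10, length.out = 120)
  f0 <- assemble_features(conn, NULL, labels, "dwgc")
  f2 <- assemble_features(conn, NULL, labels, "dwgc", label_lag = 2)
  expect_identical(f0$x, f2$x)
  expect_identical(f0$volume, f2$volume)
  expect_identical(f2$labels, labels[pmax(f2$volume - 2L, 1L)])
})

test_that("Cohen's kappa follows the chance-corrected formula", {
  expect_equal(cohen_kappa(matrix(c(40, 10, 10, 40), 2)), 0.6)
  expect_equal(cohen_kappa(diag(c(30, 20, 10))), 1)
  expect_equal(cohen_kappa(matrix(25, 2, 2)), 0)
  expect_warning(k <- cohen_kappa(matrix(c(10, 0, 0, 0), 2)), "degenerate")
  expect_equal(k, 0)
  expect_error(cohen_kappa(matrix(0, 2, 2)), "positive")
})

test_that("perfectly separable data scores accuracy and kappa of 1", {
  fm <- separable_features()
  rep_ <- kfold_evaluate(fm, classifier_spec("svm_rbf"), K = 5, seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
  expect_equal(sum(rep_$confusion), nrow(fm$x))
  expect_equal(sum(rep_$confusion[upper.tri(rep_$confusion)],
                   rep_$confusion[lower.tri(rep_$confusion)]), 0)
})

test_that("evaluation is deterministic given the seed and block-grouped", {
  fm <- separable_features(seed = 2)
  a <- kfold_evaluate(fm, classifier_spec("gaussian_nb"), 5, seed = 7)
  b <- kfold_evaluate(fm, classifier_spec("gaussian_nb"), 5, seed = 7)
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$predictions, b$predictions)
  # all samples of one block land in the same fold
  fold_of <- tapply(a$predictions$fold, fm$block_id[
    match(a$predictions$volume, fm$volume)], function(z) length(unique(z)))
  expect_true(all(fold_of == 1))
  expect_error(kfold_evaluate(fm, K = 1), "K")
})

test_that("gradient-boosting family runs behind the same interface", {
  skip_if_not_installed("xgboost")
  fm <- separable_features(seed = 3)
  rep_ <- kfold_evaluate(fm, classifier_spec("gbdt_xg", n_estimators = 30),
                         K = 3, seed = 1)
  expect_gt(rep_$accuracy, 0.95)
})

test_that("decoding-accuracy curve counts per-position hits", {
  labels <- rep(c("rest", "MIL", "rest", "MIR", "rest"),
                c(10, 5, 10, 5, 10))
  # all predictions correct
  vols <- which(labels != "rest")
  preds <- data.frame(volume = vols, predicted = labels[vols])
  curve <- decoding_accuracy_curve(preds, labels)
  expect_length(curve, 5L)
  expect_equal(as.numeric(curve), rep(1, 5))
  # correct only from the third volume of each block onward
  wrong <- preds
  runs <- rle(labels)
  pos <- unlist(lapply(runs$lengths[runs$values != "rest"], seq_len))
  wrong$predicted[pos <= 2] <- "rest"
  c2 <- decoding_accuracy_curve(wrong, labels)
  expect_equal(as.numeric(c2), c(0, 0, 1, 1, 1))
  # ragged task blocks are rejected
  bad <- rep(c("rest", "MIL", "rest", "MIR"), c(5, 5, 5, 4))
  vb <- which(bad != "rest")
  expect_error(decoding_accuracy_curve(
    data.frame(volume = vb, predicted = bad[vb]), bad), "unequal")
})

test_that("paired feature-set comparison handles identity and degeneracy", {
  fm <- separable_features(seed = 4)
  cmp <- compare_feature_sets(fm, fm, classifier_spec("gaussian_nb"),
                              K = 4, n_repeats = 3, seed = 2)
  expect_equal(cmp$mean_difference, 0)
  expect_equal(cmp$t_statistic, 0)
  one <- compare_feature_sets(fm, fm, classifier_spec("gaussian_nb"),
                              K = 4, n_repeats = 1, seed = 2)
  expect_true(is.na(one$t_statistic))
  fm2 <- separable_features(seed = 5)
  fm2$volume <- fm2$volume + 1L
  expect_error(compare_feature_sets(fm, fm2), "identical")
})

test_that("pooled runs keep blocks distinct and layouts checked", {
  conn <- make_conn(seed = 6)
  labels <- rep(c("rest", "MIL"), each = 10, length.out = 120)
  f1 <- assemble_features(conn, NULL, labels, "dwgc")
  f2 <- assemble_features(make_conn(seed = 7), NULL, labels, "dwgc")
  pooled <- pool_features(list(f1, f2), n_volumes = c(120L, 120L))
  expect_equal(nrow(pooled$x), 2 * nrow(f1$x))
  expect_equal(length(intersect(pooled$block_id[pooled$run == 1],
                                pooled$block_id[pooled$run == 2])), 0L)
  expect_equal(pooled$volume[pooled$run == 2][1], f2$volume[1] + 120L)
  f3 <- f2
  f3$feature_names <- rev(f3$feature_names)
  expect_error(pool_features(list(f1, f3)), "layout")
})
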