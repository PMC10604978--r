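#' Assemble per-volume feature vectors for decoding
#'
#' Turns the window-level connectivity stream (and optionally the per-ROI
#' activation stream) into a labeled feature matrix, one row per window.
#' A row is timestamped at the window's *start* volume — the moment the
#' window's F value describes, and the index of the connectivity tensor —
#' and labeled with that volume's condition. (The window closes, and the
#' feature becomes available to a real-time loop, `k - 1` volumes later;
#' the streaming replay accounts for that latency.)
#'
#' @param connectivity a [dwgc_sequence()] result.
#' @param activation optional `T x R` activation matrix from
#'   [compute_active()], aligned on volume index.
#' @param labels per-volume condition labels for the full run.
#' @param mode `"dwgc"` (directed-pair F values only), `"activation"`
#'   (per-ROI activation only), or `"both"`.
#' @param log_f if `TRUE`, connectivity columns enter as `log(F)` (floored
#'   at machine epsilon so thresholded zeros stay finite). The F statistic
#'   is a ratio of mean squared errors with a heavy right tail; the log
#'   stabilizes its variance, which helps margin-based classifiers.
#' @param label_lag hemodynamic lag correction in volumes: a row at window
#'   start `t` is labeled (and block-grouped) by the condition at
#'   `t - label_lag`, because the BOLD signal inside the window expresses
#'   neural activity from roughly that long before. 0 (default) labels by
#'   the concurrent condition; 2 volumes (4 s at TR 2 s) matches the HRF
#'   rise.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `labels`,
#'   `volume` (decision volume per row), `block_id` (label-run id per row,
#'   used for leakage-free fold grouping), `feature_names`, `provenance`.
#' @export
assemble_features <- function(connectivity, activation = NULL, labels,
                              mode = c("dwgc", "activation", "both"),
                              log_f = FALSE, label_lag = 0L) {
  mode <- match.arg(mode)
  label_lag <- as.integer(label_lag)
  stopifnot(inherits(connectivity, "connectivity_sequence"))
  if (length(connectivity$window_starts) == 0L) {
    stop("connectivity sequence is empty", call. = FALSE)
  }
  volumes <- connectivity$window_starts
  labels <- as.character(labels)
  if (max(volumes) > length(labels)) {
    stop(sprintf("labels cover %d volumes but windows extend to volume %d",
                 length(labels), max(volumes)), call. = FALSE)
  }
  if (mode %in% c("activation", "both")) {
    if (is.null(activation)) {
      stop("activation matrix required for mode = \"", mode, "\"",
           call. = FALSE)
    }
    activation <- as.matrix(activation)
    if (nrow(activation) < max(volumes)) {
      stop(sprintf(
        "activation has %d rows but windows extend to volume %d",
        nrow(activation), max(volumes)), call. = FALSE)
    }
    if (is.null(colnames(activation))) {
      colnames(activation) <- paste0("roi", seq_len(ncol(activation)))
    }
  }
  fmat <- connectivity$F_thresholded
  if (log_f) fmat <- log(pmax(fmat, .Machine$double.eps))
  x <- switch(mode,
    dwgc = fmat,
    activation = activation[volumes, , drop = FALSE],
    both = cbind(fmat, activation[volumes, , drop = FALSE]))
  prov <- switch(mode,
    dwgc = rep("dwgc", ncol(connectivity$F_thresholded)),
    activation = rep("activation", ncol(activation)),
    both = c(rep("dwgc", ncol(connectivity$F_thresholded)),
             rep("activation", ncol(activation))))
  colnames(x) <- make.unique(colnames(x))
  runs <- rle(labels)
  block_of_volume <- rep(seq_along(runs$lengths), runs$lengths)
  label_vol <- pmax(volumes - label_lag, 1L)
  structure(list(x = x, labels = labels[label_vol], volume = volumes,
                 block_id = block_of_volume[label_vol],
                 feature_names = colnames(x), provenance = prov),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d samples x %d features (%s); classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(unique(x$provenance), collapse = "+"),
              paste(sort(unique(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Keep a subset of feature-matrix rows
#'
#' @param features a `feature_matrix`.
#' @param idx row indices (or logical mask) to keep.
#' @export
subset_features <- function(features, idx) {
  stopifnot(inherits(features, "feature_matrix"))
  out <- list(x = features$x[idx, , drop = FALSE],
              labels = features$labels[idx],
              volume = features$volume[idx],
              block_id = features$block_id[idx],
              feature_names = features$feature_names,
              provenance = features$provenance)
  if (!is.null(features$run)) out$run <- features$run[idx]
  structure(out, class = "feature_matrix")
}

#' Pool feature matrices from several runs
#'
#' Stacks per-run feature matrices into one training set, keeping task
#' blocks distinct across runs (block ids and volume indices are offset
#' per run) so block-stratified folds never mix runs within a block.
#'
#' @param feature_list list of `feature_matrix` objects with identical
#'   feature layouts.
#' @param n_volumes optional per-run volume counts used as volume-index
#'   offsets, so pooled volume indices align with concatenated per-run
#'   label vectors; defaults to each run's last window start.
#' @return A single pooled `feature_matrix`; the originating run of each
#'   row is recorded in `run`.
#' @export
pool_features <- function(feature_list, n_volumes = NULL) {
  stopifnot(length(feature_list) >= 1L,
            all(vapply(feature_list, inherits, logical(1L), "feature_matrix")))
  layouts <- vapply(feature_list, function(f)
    paste(f$feature_names, collapse = "|"), character(1L))
  if (length(unique(layouts)) != 1L) {
    stop("feature matrices have different feature layouts", call. = FALSE)
  }
  block_off <- 0L
  vol_off <- 0L
  out <- list()
  for (u in seq_along(feature_list)) {
    f <- feature_list[[u]]
    out[[u]] <- data.frame(run = u, volume = f$volume + vol_off,
                           block_id = f$block_id + block_off)
    block_off <- block_off + max(f$block_id)
    vol_off <- vol_off + if (is.null(n_volumes)) max(f$volume)
                         else as.integer(n_volumes[u])
  }
  meta <- do.call(rbind, out)
  structure(list(x = do.call(rbind, lapply(feature_list, `[[`, "x")),
                 labels = unlist(lapply(feature_list, `[[`, "labels")),
                 volume = meta$volume, block_id = meta$block_id,
                 run = meta$run,
                 feature_names = feature_list[[1L]]$feature_names,
                 provenance = feature_list[[1L]]$provenance),
            class = "feature_matrix")
}

#' Classifier specifications for the decoding suite
#'
#' Families and their stock hyperparameters: `gaussian_nb` (Gaussian naive
#' Bayes), `svm_poly` (polynomial-kernel SVM, exponent 1), `svm_rbf`
#' (RBF-kernel SVM, `C = 19`, gamma set automatically from the feature
#' variance), `gbdt_light` (gradient-boosted trees, depth 5, learning rate
#' 0.8, 1000 rounds) and `gbdt_xg` (depth 8, learning rate 0.08, 1000
#' rounds). Both boosting families are backed by the xgboost package.
#' Any preset can be overridden through `...`.
#'
#' @param family one of `"gaussian_nb"`, `"svm_poly"`, `"svm_rbf"`,
#'   `"gbdt_light"`, `"gbdt_xg"`.
#' @param ... hyperparameter overrides (`cost`, `gamma`, `degree`,
#'   `max_depth`, `learning_rate`, `n_estimators`).
#' @export
classifier_spec <- function(family = c("svm_rbf", "svm_poly", "gaussian_nb",
                                       "gbdt_light", "gbdt_xg"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    gaussian_nb = list(),
    svm_poly = list(degree = 1L, cost = 1, coef0 = 0),
    svm_rbf = list(cost = 19, gamma = "scale"),
    gbdt_light = list(max_depth = 5L, learning_rate = 0.8,
                      n_estimators = 1000L),
    gbdt_xg = list(max_depth = 8L, learning_rate = 0.08,
                   n_estimators = 1000L))
  override <- list(...)
  bad <- setdiff(names(override), c(names(defaults), "cost", "gamma"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown hyperparameter(s) for %s: %s", family,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  params <- utils::modifyList(defaults, override)
  structure(list(family = family, params = params), class = "classifier_spec")
}

# fit one classifier on (already standardized) features
fit_family <- function(x, y, spec, seed = 1L) {
  y <- factor(y)
  if (spec$family %in% c("gbdt_light", "gbdt_xg")) {
    if (!requireNamespace("xgboost", quietly = TRUE)) {
      stop("gradient-boosting families require the xgboost package",
           call. = FALSE)
    }
    p <- spec$params
    booster <- with_seed(seed, xgboost::xgboost(
      x, y, nrounds = p$n_estimators, max_depth = p$max_depth,
      learning_rate = p$learning_rate, nthreads = 1L, verbosity = 0))
    return(list(kind = "xgb", model = booster, levels = levels(y)))
  }
  model <- switch(spec$family,
    # train and predict both via as.data.frame so column-name mangling of
    # "src->tgt" feature names is applied consistently
    gaussian_nb = e1071::naiveBayes(as.data.frame(x), y),
    svm_poly = e1071::svm(x, y, kernel = "polynomial",
                          degree = spec$params$degree,
                          coef0 = spec$params$coef0,
                          cost = spec$params$cost, scale = FALSE),
    svm_rbf = {
      g <- spec$params$gamma
      if (identical(g, "scale")) {
        v <- stats::var(as.vector(x))
        g <- if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      }
      e1071::svm(x, y, kernel = "radial", cost = spec$params$cost,
                 gamma = g, scale = FALSE)
    })
  list(kind = spec$family, model = model, levels = levels(y))
}

predict_family <- function(fit, x) {
  if (fit$kind == "xgb") {
    raw <- stats::predict(fit$model, x)
    if (is.matrix(raw)) {
      idx <- max.col(raw, ties.method = "first")
      lev <- colnames(raw) %||% fit$levels
      return(factor(lev[idx], levels = fit$levels))
    }
    return(factor(fit$levels[as.integer(raw > 0.5) + 1L],
                  levels = fit$levels))
  }
  if (fit$kind == "gaussian_nb") {
    return(stats::predict(fit$model, as.data.frame(x)))
  }
  stats::predict(fit$model, x)
}

#' Train a decoder on a full feature matrix
#'
#' Standardizes features (training statistics are stored with the model)
#' and fits the requested classifier family; the returned object predicts
#' labels for new feature rows with [predict_decoder()].
#'
#' @param features a `feature_matrix` from [assemble_features()].
#' @param spec a [classifier_spec()].
#' @param seed integer seed (used by stochastic families).
#' @export
train_decoder <- function(features, spec = classifier_spec(), seed = 1L) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(spec, "classifier_spec"))
  ctr <- colMeans(features$x)
  scl <- apply(features$x, 2L, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- scale(features$x, center = ctr, scale = scl)
  fit <- fit_family(xs, features$labels, spec, seed)
  structure(list(fit = fit, center = ctr, scale = scl, spec = spec,
                 feature_names = features$feature_names),
            class = "decoder")
}

#' @rdname train_decoder
#' @param decoder a trained `decoder`.
#' @param x feature rows (matrix or `feature_matrix`) in the training
#'   column layout.
#' @return Factor of predicted labels.
#' @export
predict_decoder <- function(decoder, x) {
  stopifnot(inherits(decoder, "decoder"))
  if (inherits(x, "feature_matrix")) x <- x$x
  x <- matrix(x, ncol = length(decoder$feature_names),
              dimnames = list(NULL, decoder$feature_names))
  xs <- scale(x, center = decoder$center, scale = decoder$scale)
  predict_family(decoder$fit, xs)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with
#' `p_o = trace / N` and `p_e = sum_c row_c * col_c / N^2`.
#'
#' @param confusion square count matrix (rows = truth, columns = predicted).
#' @return Kappa in `[-1, 1]`; a degenerate single-cell matrix
#'   (`p_e = 1`) returns 0 with a warning.
#' @examples
#' cohen_kappa(matrix(c(40, 10, 10, 40), 2))  # 0.6
#' @export
cohen_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  n <- sum(confusion)
  if (n <= 0) stop("confusion matrix must have positive total count",
                   call. = FALSE)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warning("degenerate confusion matrix (chance agreement = 1); kappa set to 0")
    return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

# deal each class's blocks round-robin to K folds under the seed, so every
# fold sees every class and no task block straddles the train/test split
make_block_folds <- function(labels, block_id, K, seed) {
  blocks <- unique(block_id)
  block_class <- vapply(blocks, function(b)
    labels[match(b, block_id)], character(1L))
  fold_of_block <- stats::setNames(integer(length(blocks)), blocks)
  with_seed(seed, {
    offset <- 0L
    for (cls in sample(unique(block_class))) {
      b_cls <- sample(blocks[block_class == cls])
      fold_of_block[as.character(b_cls)] <-
        ((seq_along(b_cls) - 1L + offset) %% K) + 1L
      offset <- offset + length(b_cls)
    }
  })
  unname(fold_of_block[as.character(block_id)])
}

#' K-fold cross-validated evaluation of a decoder
#'
#' Folds are grouped by task block (all samples of one block share a fold)
#' to prevent temporal leakage between training and test sets, and dealt
#' round-robin per class so folds stay stratified. The K held-out
#' confusion matrices are aggregated into one report.
#'
#' @param features a `feature_matrix`.
#' @param spec a [classifier_spec()].
#' @param K number of folds (default 5).
#' @param seed integer seed controlling fold assignment (and stochastic
#'   families).
#' @param predict_features optional second `feature_matrix` over the same
#'   run (e.g. all windows including hemodynamic transition volumes, while
#'   `features` holds only the stable training rows): every row whose task
#'   block is held out in a fold is predicted by that fold's model and
#'   included in `predictions`. Metrics are always computed on `features`
#'   rows only. Defaults to `features`.
#' @return An `evaluation_report`: `confusion` (truth x predicted),
#'   `accuracy`, `kappa`, `per_fold` data frame, `predictions` (one row
#'   per held-out sample: `volume`, `truth`, `predicted`, `fold`), `K`,
#'   `seed`.
#' @export
kfold_evaluate <- function(features, spec = classifier_spec(), K = 5L,
                           seed = 1L, predict_features = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  classes <- sort(unique(features$labels))
  counts <- table(features$labels)
  if (any(counts < K)) {
    stop(sprintf("class \"%s\" has fewer samples than K = %d",
                 names(counts)[which.min(counts)], K), call. = FALSE)
  }
  fold <- make_block_folds(features$labels, features$block_id, K, seed)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, predicted = classes))
  per_fold <- vector("list", K)
  preds <- vector("list", K)
  extra <- !is.null(predict_features)
  if (extra) stopifnot(inherits(predict_features, "feature_matrix"))
  for (f in seq_len(K)) {
    tr <- fold != f
    te <- !tr
    if (!all(classes %in% features$labels[tr])) {
      stop(sprintf(
        "fold %d leaves a class absent from the training set; use more data or a smaller K",
        f), call. = FALSE)
    }
    dec <- train_decoder(subset_features(features, tr), spec,
                         seed = seed + f)
    yhat <- as.character(predict_decoder(dec, features$x[te, , drop = FALSE]))
    truth <- features$labels[te]
    cm <- table(factor(truth, classes), factor(yhat, classes))
    confusion <- confusion + as.matrix(cm)
    per_fold[[f]] <- data.frame(
      fold = f, n = sum(te),
      accuracy = mean(yhat == truth),
      kappa = if (sum(cm) > 0) cohen_kappa(cm) else NA_real_)
    if (extra) {
      held_blocks <- unique(features$block_id[te])
      pe <- predict_features$block_id %in% held_blocks
      yh <- as.character(predict_decoder(
        dec, predict_features$x[pe, , drop = FALSE]))
      preds[[f]] <- data.frame(volume = predict_features$volume[pe],
                               truth = predict_features$labels[pe],
                               predicted = yh, fold = f,
                               stringsAsFactors = FALSE)
    } else {
      preds[[f]] <- data.frame(volume = features$volume[te], truth = truth,
                               predicted = yhat, fold = f,
                               stringsAsFactors = FALSE)
    }
  }
  predictions <- do.call(rbind, preds)
  predictions <- predictions[order(predictions$volume), ]
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 kappa = cohen_kappa(confusion),
                 per_fold = do.call(rbind, per_fold),
                 predictions = predictions, K = K, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold evaluation: accuracy %.3f, kappa %.3f (%d samples)\n",
              x$K, x$accuracy, x$kappa, sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Per-TR decoding-accuracy curve
#'
#' Measures how quickly within a task block the decoder recognizes the
#' state: position m's accuracy is the fraction of task blocks whose m-th
#' volume was classified correctly. With 10-s blocks at a TR of 2 s the
#' curve has five points.
#'
#' @param predictions data frame with columns `volume` and `predicted`
#'   (e.g. the `predictions` element of [kfold_evaluate()] or the decision
#'   log of [stream_replay()]).
#' @param labels per-volume true condition labels of the run (or a
#'   `paradigm`, from which labels are derived).
#' @param incomplete how to treat task blocks only partially covered by
#'   predictions (e.g. blocks straddling the warm-up boundary):
#'   `"error"` (default) or `"drop"`.
#' @return A `da_curve`: numeric vector (one accuracy per in-block volume
#'   position) with attribute `n_blocks`. Blocks with no predicted volume
#'   are always dropped; task blocks of unequal length are an error.
#' @export
decoding_accuracy_curve <- function(predictions, labels,
                                    incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (inherits(labels, "paradigm")) labels <- condition_labels(labels)
  labels <- as.character(labels)
  stopifnot(is.data.frame(predictions),
            all(c("volume", "predicted") %in% names(predictions)))
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  task <- which(runs$values != "rest")
  if (length(task) == 0L) stop("no task blocks in the labels", call. = FALSE)
  len <- unique(runs$lengths[task])
  if (length(len) != 1L) {
    stop("task blocks have unequal lengths; the per-position curve is undefined",
         call. = FALSE)
  }
  pred_of_volume <- rep(NA_character_, length(labels))
  pred_of_volume[predictions$volume] <- as.character(predictions$predicted)
  hits <- matrix(NA, nrow = 0L, ncol = len)
  for (b in task) {
    vols <- starts[b]:ends[b]
    pv <- pred_of_volume[vols]
    if (all(is.na(pv))) next
    if (anyNA(pv)) {
      if (incomplete == "drop") next
      stop(sprintf("block starting at volume %d is only partially covered by predictions",
                   starts[b]), call. = FALSE)
    }
    hits <- rbind(hits, pv == runs$values[b])
  }
  if (nrow(hits) == 0L) stop("no task block is covered by the predictions",
                             call. = FALSE)
  structure(colMeans(hits), n_blocks = nrow(hits), class = "da_curve")
}

#' @export
print.da_curve <- function(x, ...) {
  cat(sprintf("DA curve over %d blocks: %s\n", attr(x, "n_blocks"),
              paste(sprintf("%.2f", unclass(x)), collapse = " ")))
  invisible(x)
}

#' Paired comparison of two feature sets
#'
#' Repeats K-fold evaluation `n_repeats` times with different fold seeds,
#' using the *same* folds for both feature sets in each repeat, and
#' applies a paired t-test to the per-repeat accuracies. This is the
#' standard way to ask whether connectivity features beat activation
#' features on the same data.
#'
#' @param features_a,features_b two `feature_matrix` objects over the same
#'   sample rows (same volumes and labels).
#' @param spec a [classifier_spec()].
#' @param K folds per repeat.
#' @param n_repeats number of repeats (the paired t-test needs >= 2).
#' @param seed base seed; repeat r uses `seed + r`.
#' @return List with `accuracy_a`, `accuracy_b` (per repeat),
#'   `mean_difference` (a minus b), `t_statistic`, `p_value` (one-sided,
#'   a > b), `n_repeats`.
#' @export
compare_feature_sets <- function(features_a, features_b,
                                 spec = classifier_spec(), K = 5L,
                                 n_repeats = 20L, seed = 1L) {
  stopifnot(inherits(features_a, "feature_matrix"),
            inherits(features_b, "feature_matrix"))
  if (nrow(features_a$x) != nrow(features_b$x) ||
      !identical(features_a$volume, features_b$volume) ||
      !identical(features_a$labels, features_b$labels)) {
    stop("the two feature sets must cover identical sample rows",
         call. = FALSE)
  }
  acc_a <- acc_b <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    acc_a[r] <- kfold_evaluate(features_a, spec, K, seed = seed + r)$accuracy
    acc_b[r] <- kfold_evaluate(features_b, spec, K, seed = seed + r)$accuracy
  }
  d <- acc_a - acc_b
  if (n_repeats < 2L) {
    t_stat <- NA_real_
    p <- NA_real_
  } else if (stats::sd(d) < 1e-15) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) > 0) 0 else 1
  } else {
    tt <- stats::t.test(acc_a, acc_b, paired = TRUE,
                        alternative = "greater")
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(accuracy_a = acc_a, accuracy_b = acc_b, mean_difference = mean(d),
       t_statistic = t_stat, p_value = p, n_repeats = n_repeats)
}
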