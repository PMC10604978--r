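#' Decoding pipeline configuration
#'
#' Bundles every tunable of the volume-by-volume decoding chain: volume
#' discards, transition trimming, the autoregressive window model, window
#' length and threshold calibration, feature mode and classifier.
#'
#' @param n_discard leading volumes dropped for magnetization settling
#'   (default 10).
#' @param n_transition hemodynamic transition volumes trimmed from each
#'   condition run when building training sets and baselines (default 4).
#' @param ar_spec an [ar_model_spec()].
#' @param k causality window length in volumes (default 4).
#' @param alpha nominal false-positive level used to calibrate the
#'   detection threshold when `omega` is not supplied.
#' @param omega optional precomputed threshold (scalar or matrix); `NULL`
#'   means calibrate from the training series.
#' @param mode feature mode: `"dwgc"`, `"activation"`, or `"both"`.
#' @param baseline_mode `"first_rest_block"` freezes the rest baseline
#'   after the first completed rest period (as a real-time session must);
#'   `"all_rest"` uses every stable rest volume.
#' @param stride window stride for batch feature extraction.
#' @param epsilon floor on the full-model MSE.
#' @export
pipeline_config <- function(n_discard = 10L, n_transition = 4L,
                            ar_spec = ar_model_spec(), k = 4L,
                            alpha = 0.05, omega = NULL,
                            mode = c("dwgc", "activation", "both"),
                            baseline_mode = c("first_rest_block", "all_rest"),
                            stride = 1L, epsilon = 1e-12) {
  structure(list(n_discard = as.integer(n_discard),
                 n_transition = as.integer(n_transition),
                 ar_spec = ar_spec, k = as.integer(k), alpha = alpha,
                 omega = omega, mode = match.arg(mode),
                 baseline_mode = match.arg(baseline_mode),
                 stride = as.integer(stride), epsilon = epsilon),
            class = "pipeline_config")
}

# rest baseline per config: either the stable volumes of the first rest
# run only (causally available early in a session) or all stable rest
# volumes; indices are post-discard
compute_baseline <- function(series, config) {
  labels <- series$condition_labels
  if (config$baseline_mode == "all_rest") {
    return(rest_baseline(series, config$n_transition))
  }
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rest_runs <- which(runs$values == "rest" &
                       runs$lengths > config$n_transition)
  if (length(rest_runs) == 0L) {
    stop("no rest run longer than n_transition volumes: cannot form a baseline",
         call. = FALSE)
  }
  b <- rest_runs[1L]
  idx <- (starts[b] + config$n_transition):ends[b]
  structure(colMeans(series$values[idx, , drop = FALSE]),
            frozen_at_volume = ends[b])
}

# features for every admissible window of a (post-discard) series
pipeline_features <- function(series, config, omega) {
  active <- NULL
  if (config$mode != "dwgc") {
    base <- compute_baseline(series, config)
    active <- compute_active(series, base)
  }
  conn <- dwgc_sequence(series, config$ar_spec, config$k, omega,
                        config$stride, config$epsilon)
  assemble_features(conn, active, series$condition_labels, config$mode)
}

#' Train the full decoding pipeline on a labeled run
#'
#' Discards initial volumes, calibrates the causality threshold from
#' circular-shift surrogates of the training series (unless a threshold is
#' supplied), extracts features for every window, restricts the training
#' set to hemodynamically stable volumes, and fits the classifier.
#'
#' @param series an [roi_series()] with per-volume condition labels.
#' @param config a [pipeline_config()].
#' @param classifier a [classifier_spec()].
#' @param seed integer seed (threshold surrogates, folds, stochastic fits).
#' @return An `mi_pipeline`: list with `decoder`, `omega`, `config`,
#'   `features` (the stable training rows) and `series_used`.
#' @export
train_pipeline <- function(series, config = pipeline_config(),
                           classifier = classifier_spec(), seed = 1L) {
  stopifnot(inherits(series, "roi_series"),
            inherits(config, "pipeline_config"))
  series <- discard_initial(series, config$n_discard)
  omega <- config$omega
  if (is.null(omega) && !is.null(config$alpha)) {
    omega <- calibrate_threshold(series, config$ar_spec, config$k,
                                 alpha = config$alpha, seed = seed)
  }
  feats <- pipeline_features(series, config, omega)
  stable <- trim_transitions(series$condition_labels, config$n_transition)
  keep <- feats$volume %in% stable
  training <- subset_features(feats, keep)
  decoder <- train_decoder(training, classifier, seed = seed)
  structure(list(decoder = decoder, omega = omega, config = config,
                 features = training, all_features = feats,
                 n_volumes_trained = nrow(series$values)),
            class = "mi_pipeline")
}

#' Batch decoding of a run with a trained pipeline
#'
#' Runs the identical feature chain as [stream_replay()] but over the
#' whole run at once; used for training-set construction and as the
#' reference the streaming path must reproduce bit-for-bit.
#'
#' @param series an [roi_series()] for the full run (pre-discard).
#' @param pipeline an `mi_pipeline` from [train_pipeline()].
#' @return Data frame with `volume` (post-discard index of the decision
#'   volume), `predicted`.
#' @export
batch_decode <- function(series, pipeline) {
  stopifnot(inherits(pipeline, "mi_pipeline"))
  config <- pipeline$config
  series <- discard_initial(series, config$n_discard)
  feats <- pipeline_features(series, config, pipeline$omega)
  pred <- predict_decoder(pipeline$decoder, feats)
  data.frame(volume = feats$volume, predicted = as.character(pred),
             stringsAsFactors = FALSE)
}

#' Replay a run volume-by-volume through the trained pipeline
#'
#' Emulates the per-TR real-time loop: volumes arrive one at a time, the
#' ROI buffer grows, and once enough history exists each new volume closes
#' a causality window, yields a feature vector, and is classified. Every
#' decision depends only on volumes already seen, and the emitted label
#' sequence is bit-identical to [batch_decode()] on the same input.
#' Per-stage wall-clock times are logged per volume.
#'
#' @param source the volume feed: an [roi_series()], a `T x R` matrix, or
#'   a function `f(v)` returning the v-th per-ROI row (`NULL` once the
#'   feed is exhausted, which stops the replay gracefully).
#' @param pipeline a trained `mi_pipeline`.
#' @param labels per-volume condition labels (the cue sequence, known in
#'   real time); required for activation-based feature modes and for the
#'   decision log's truth column. Optional for pure-dwgc mode.
#' @param n_volumes expected run length when `source` is a function.
#' @return List with `decisions` (data frame: `volume`, the post-discard
#'   index of the *window-start* volume the decision describes — the
#'   decision is emitted `k - 1` volumes later, when its window closes —
#'   plus `predicted`, `truth`, `t_feature_s`, `t_classify_s`,
#'   `t_total_s`) and `volumes_processed`.
#' @export
stream_replay <- function(source, pipeline, labels = NULL,
                          n_volumes = NULL) {
  stopifnot(inherits(pipeline, "mi_pipeline"))
  config <- pipeline$config
  spec <- config$ar_spec
  k <- config$k
  if (inherits(source, "roi_series")) {
    if (is.null(labels)) labels <- source$condition_labels
    mat <- source$values
    n_volumes <- nrow(mat)
    feed <- function(v) if (v <= n_volumes) mat[v, ] else NULL
    roi_names <- source$roi_names
  } else if (is.matrix(source)) {
    n_volumes <- nrow(source)
    feed <- function(v) if (v <= n_volumes) source[v, ] else NULL
    roi_names <- colnames(source)
  } else if (is.function(source)) {
    if (is.null(n_volumes)) n_volumes <- .Machine$integer.max
    feed <- source
    roi_names <- NULL
  } else {
    stop("unsupported volume source", call. = FALSE)
  }
  n_pairs_expected <- length(pipeline$decoder$feature_names)
  need_active <- config$mode != "dwgc"
  if (need_active && is.null(labels)) {
    stop("activation features need per-volume condition labels", call. = FALSE)
  }

  n_discard <- config$n_discard
  buffer <- NULL          # post-discard ROI rows seen so far
  buf_labels <- character(0)
  baseline <- NULL
  decisions <- list()
  v <- 0L
  processed <- 0L
  warm <- first_window_start(spec) + k - 1L   # first decidable buffer index
  repeat {
    v <- v + 1L
    if (v > n_volumes) break
    row <- feed(v)
    if (is.null(row)) break                    # truncated feed: stop cleanly
    processed <- processed + 1L
    if (v <= n_discard) next
    t0 <- proc.time()[["elapsed"]]
    buffer <- rbind(buffer, row)
    bi <- nrow(buffer)                         # post-discard volume index
    if (!is.null(labels)) buf_labels <- c(buf_labels, labels[v])

    if (need_active && is.null(baseline)) {
      # freeze the baseline once the first qualifying rest run (longer
      # than n_transition) has fully elapsed; matches compute_baseline()
      runs <- rle(buf_labels)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      qual <- which(runs$values == "rest" &
                      runs$lengths > config$n_transition)
      qual <- qual[qual < length(runs$lengths)]   # run must be complete
      if (length(qual) > 0L) {
        b <- qual[1L]
        idx <- (starts[b] + config$n_transition):ends[b]
        baseline <- colMeans(buffer[idx, , drop = FALSE])
      }
    }
    if (bi < warm) next
    if (need_active && is.null(baseline)) next

    t_start <- bi - k + 1L
    n_r <- ncol(buffer)
    fvec <- numeric(0)
    if (config$mode != "activation") {
      q <- 0L
      fvec <- numeric(n_r * (n_r - 1L))
      for (i in seq_len(n_r)) for (j in seq_len(n_r)) if (i != j) {
        q <- q + 1L
        res <- window_gc_engine(buffer[, i], buffer[, j], spec, k, t_start,
                                config$epsilon)
        om <- if (is.null(pipeline$omega)) 0
              else if (is.matrix(pipeline$omega)) pipeline$omega[i, j]
              else pipeline$omega
        fvec[q] <- apply_threshold(res$F, om)
      }
    }
    if (need_active) {
      fvec <- c(fvec, buffer[t_start, ] - baseline)
    }
    if (length(fvec) != n_pairs_expected) {
      stop(sprintf(
        "feature layout mismatch: stream produces %d features, decoder expects %d",
        length(fvec), n_pairs_expected), call. = FALSE)
    }
    t1 <- proc.time()[["elapsed"]]
    pred <- as.character(predict_decoder(pipeline$decoder,
                                         matrix(fvec, nrow = 1L)))
    t2 <- proc.time()[["elapsed"]]
    decisions[[length(decisions) + 1L]] <- data.frame(
      volume = t_start, predicted = pred,
      truth = if (is.null(labels))
        NA_character_ else labels[t_start + n_discard],
      t_feature_s = t1 - t0, t_classify_s = t2 - t1, t_total_s = t2 - t0,
      stringsAsFactors = FALSE)
  }
  list(decisions = if (length(decisions) > 0L) do.call(rbind, decisions)
                   else data.frame(volume = integer(0),
                                   predicted = character(0)),
       volumes_processed = processed)
}
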