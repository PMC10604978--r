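#' Autoregressive predictor specification for window-level causality
#'
#' Each directed pair is scored by comparing two one-step-ahead predictors
#' of the target series: a restricted model regressing the target's next
#' value on its own last `order_p` (basis-expanded) values, and a full
#' model that additionally uses the source's last `order_p` values. Both
#' are fitted by least squares on the `train_span` samples immediately
#' before the evaluation window, so window errors are out-of-sample by
#' default.
#'
#' @param order_p autoregressive order (number of lags, >= 1).
#' @param basis `"linear"` for raw lags, `"polynomial"` for per-lag powers
#'   `1..degree` (a simple nonlinear autoregression).
#' @param degree polynomial degree (ignored for the linear basis).
#' @param train_span number of past samples used to fit coefficients; must
#'   be at least twice the number of predictor terms of the full model.
#' @param fit_mode `"out_of_sample"` (default: fit strictly before the
#'   window, evaluate on the window) or `"in_sample"` (fit and evaluate on
#'   the training span extended through the window; guarantees the nesting
#'   inequality L1 >= L2 and is used for oracle cross-checks).
#' @return An `ar_model_spec` object.
#' @export
ar_model_spec <- function(order_p = 1L, basis = c("linear", "polynomial"),
                          degree = 2L, train_span = 40L,
                          fit_mode = c("out_of_sample", "in_sample")) {
  basis <- match.arg(basis)
  fit_mode <- match.arg(fit_mode)
  order_p <- as.integer(order_p)
  degree <- as.integer(degree)
  train_span <- as.integer(train_span)
  if (order_p < 1L) stop("order_p must be >= 1", call. = FALSE)
  if (basis == "polynomial" && degree < 1L) stop("degree must be >= 1",
                                                 call. = FALSE)
  d <- if (basis == "polynomial") degree else 1L
  n_terms_full <- 1L + 2L * order_p * d
  if (train_span < 2L * n_terms_full) {
    stop(sprintf(
      "train_span (%d) must be at least twice the %d predictor terms of the full model",
      train_span, n_terms_full), call. = FALSE)
  }
  structure(list(order_p = order_p, basis = basis, degree = d,
                 train_span = train_span, fit_mode = fit_mode),
            class = "ar_model_spec")
}

# lagged-value matrix: row u holds y[u-1], ..., y[u-p] (NA where undefined)
lag_matrix <- function(y, p) {
  n <- length(y)
  out <- matrix(NA_real_, n, p)
  for (l in seq_len(p)) {
    out[(l + 1L):n, l] <- y[1L:(n - l)]
  }
  out
}

# per-lag power expansion (no cross terms); linear basis is degree 1
basis_expand <- function(L, spec) {
  if (spec$basis == "linear" || spec$degree == 1L) return(L)
  do.call(cbind, lapply(seq_len(spec$degree), function(d) L^d))
}

# least-squares fit with a tiny-ridge fallback on rank deficiency
fit_ls <- function(X, y, ridge = 1e-8) {
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  beta <- tryCatch({
    R <- chol(XtX)
    backsolve(R, forwardsolve(t(R), Xty))
  }, error = function(e) NULL)
  if (is.null(beta)) {
    vlog("rank-deficient design: falling back to ridge (lambda = %g)", ridge)
    beta <- solve(XtX + diag(ridge, ncol(X)), Xty)
    attr(beta, "ridge") <- TRUE
  }
  beta
}

# first admissible window start for a series of length n_t
first_window_start <- function(spec) spec$train_span + spec$order_p + 1L
last_window_start <- function(spec, n_t, k) n_t - k + 1L

# Core engine: window-level restricted-vs-full MSE comparison for one
# directed pair over a set of window starts. Standardization of the target
# over the training span enters as a variance rescaling of both MSEs
# (predictions themselves are invariant to affine rescaling because every
# design contains an intercept and per-lag power terms).
window_gc_engine <- function(source, target, spec, k, starts,
                             epsilon = 1e-12) {
  p <- spec$order_p
  span <- spec$train_span
  n_t <- length(target)
  Zy <- basis_expand(lag_matrix(target, p), spec)
  Zx <- basis_expand(lag_matrix(source, p), spec)
  n_w <- length(starts)
  L1 <- L2 <- numeric(n_w)
  sat <- logical(n_w)
  for (w in seq_len(n_w)) {
    t0 <- starts[w]
    if (spec$fit_mode == "out_of_sample") {
      fit_rows <- (t0 - span):(t0 - 1L)
      eval_rows <- t0:(t0 + k - 1L)
    } else {
      fit_rows <- (t0 - span):(t0 + k - 1L)
      eval_rows <- fit_rows
    }
    Xr_fit <- cbind(1, Zy[fit_rows, , drop = FALSE])
    Xf_fit <- cbind(Xr_fit, Zx[fit_rows, , drop = FALSE])
    y_fit <- target[fit_rows]
    br <- fit_ls(Xr_fit, y_fit)
    bf <- fit_ls(Xf_fit, y_fit)
    Xr_ev <- cbind(1, Zy[eval_rows, , drop = FALSE])
    Xf_ev <- cbind(Xr_ev, Zx[eval_rows, , drop = FALSE])
    y_ev <- target[eval_rows]
    # training-span variance of the target = standardization scale
    s2 <- stats::var(target[(t0 - span - p):(t0 - 1L)])
    if (!is.finite(s2) || s2 < epsilon) s2 <- 1
    L1[w] <- mean((y_ev - Xr_ev %*% br)^2) / s2
    L2[w] <- mean((y_ev - Xf_ev %*% bf)^2) / s2
    sat[w] <- L2[w] < epsilon
  }
  F_stat <- L1 / pmax(L2, epsilon)
  list(L1 = L1, L2 = L2, F = F_stat, saturated = sat, starts = starts)
}

#' Fit the restricted and full window predictors
#'
#' Fits, on the `train_span` samples strictly before volume `t`, the two
#' nested least-squares predictors compared by window-level Granger
#' causality: target-past-only (restricted) and target-plus-source past
#' (full). Rank-deficient designs fall back to a tiny ridge penalty
#' (lambda = 1e-8).
#'
#' @param source,target numeric series (source candidate cause, target
#'   candidate effect).
#' @param t window start index (1-based); training uses samples
#'   `t - train_span, ..., t - 1`.
#' @param spec an [ar_model_spec()].
#' @return List of two functions, `restricted(v)` and `full(v)`, each
#'   returning one-step-ahead predictions of the target at the requested
#'   time indices (using observed lags), plus the fitted `coefficients`.
#' @export
fit_window_predictors <- function(source, target, t, spec = ar_model_spec()) {
  stopifnot(inherits(spec, "ar_model_spec"))
  p <- spec$order_p
  span <- spec$train_span
  if (t - span - p < 1L) {
    stop(sprintf(
      "window start %d needs %d training samples plus %d lags of history",
      t, span, p), call. = FALSE)
  }
  Zy <- basis_expand(lag_matrix(target, p), spec)
  Zx <- basis_expand(lag_matrix(source, p), spec)
  fit_rows <- (t - span):(t - 1L)
  Xr <- cbind(1, Zy[fit_rows, , drop = FALSE])
  Xf <- cbind(Xr, Zx[fit_rows, , drop = FALSE])
  y <- target[fit_rows]
  br <- fit_ls(Xr, y)
  bf <- fit_ls(Xf, y)
  list(
    restricted = function(v) drop(cbind(1, Zy[v, , drop = FALSE]) %*% br),
    full = function(v) drop(cbind(1, Zy[v, , drop = FALSE],
                                  Zx[v, , drop = FALSE]) %*% bf),
    coefficients = list(restricted = drop(br), full = drop(bf))
  )
}

#' Window-level Granger causality for one directed pair and window
#'
#' Computes, for the sliding window `[t, t + k - 1]`, the mean squared
#' one-step prediction error of the restricted predictor (`L1`) and of the
#' full predictor (`L2`), and their ratio `F = L1 / max(L2, epsilon)`.
#' `F` substantially above 1 means the source's past improved prediction of
#' the target within this window. When `L2` falls below `epsilon` (e.g.
#' noise-free perfect coupling) the ratio is reported at the epsilon-capped
#' value and flagged `saturated`.
#'
#' @inheritParams fit_window_predictors
#' @param k window length in volumes (default 4).
#' @param epsilon floor applied to `L2` before division.
#' @param omega optional detection threshold; filled into `F_thresholded`.
#' @return A `window_gc_value`: list with `source`, `target` (if named),
#'   `window_start_t`, `window_len_k`, `L1`, `L2`, `F`, `F_thresholded`,
#'   `saturated`.
#' @export
window_gc <- function(source, target, t, k = 4L, spec = ar_model_spec(),
                      epsilon = 1e-12, omega = 0) {
  stopifnot(inherits(spec, "ar_model_spec"))
  k <- as.integer(k)
  if (k < 1L) stop("window length k must be >= 1", call. = FALSE)
  n_t <- length(target)
  if (length(source) != n_t) stop("source and target lengths differ",
                                  call. = FALSE)
  if (t < first_window_start(spec)) {
    stop(sprintf("window start %d leaves too little history (need >= %d)",
                 t, first_window_start(spec)), call. = FALSE)
  }
  if (t + k - 1L > n_t) {
    stop(sprintf("window [%d, %d] overruns the series end (%d)",
                 t, t + k - 1L, n_t), call. = FALSE)
  }
  res <- window_gc_engine(source, target, spec, k, t, epsilon)
  structure(list(window_start_t = t, window_len_k = k,
                 L1 = res$L1, L2 = res$L2, F = res$F,
                 F_thresholded = apply_threshold(res$F, omega),
                 saturated = res$saturated),
            class = "window_gc_value")
}

#' Threshold an F statistic
#'
#' Detection rule for window-level causality: the statistic is kept iff it
#' reaches the calibrated threshold, otherwise set to exactly zero
#' (boundary inclusive).
#'
#' @param F_stat F statistic(s), >= 0.
#' @param omega threshold(s), >= 0; recycled.
#' @return `F_stat` where `F_stat >= omega`, else 0.
#' @export
apply_threshold <- function(F_stat, omega) {
  ifelse(F_stat >= omega, F_stat, 0)
}

#' Calibrate the detection threshold from circular-shift surrogates
#'
#' Destroys cross-lag structure while preserving each series'
#' autocorrelation by circularly shifting the source series by random
#' offsets, recomputes window-level F on the surrogates, and sets the
#' threshold to the empirical `1 - alpha` quantile of the pooled surrogate
#' F values. Calibrated per ordered pair by default; `scope = "global"`
#' pools all pairs into a single threshold.
#'
#' @param series an [roi_series()] or numeric `T x R` matrix (R >= 2).
#' @param spec an [ar_model_spec()].
#' @param k window length.
#' @param alpha nominal false-positive rate of the detection rule.
#' @param n_surrogates number of circular-shift draws per pair (>= 100).
#' @param windows_per_surrogate window starts evaluated per draw (pooled).
#' @param seed integer seed; same seed gives an identical threshold.
#' @param scope `"per_pair"` (matrix of thresholds) or `"global"` (scalar).
#' @param epsilon floor on `L2`.
#' @return `scope = "per_pair"`: an R x R matrix `omega[source, target]`
#'   with `NA` diagonal; `scope = "global"`: a single number.
#' @export
calibrate_threshold <- function(series, spec = ar_model_spec(), k = 4L,
                                alpha = 0.05, n_surrogates = 500L,
                                windows_per_surrogate = 5L, seed = 1L,
                                scope = c("per_pair", "global"),
                                epsilon = 1e-12) {
  scope <- match.arg(scope)
  x <- if (inherits(series, "roi_series")) series$values else as.matrix(series)
  n_t <- nrow(x)
  n_r <- ncol(x)
  if (n_r < 2L) stop("need at least 2 series", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_surrogates < 100L) stop("use at least 100 surrogates", call. = FALSE)
  t_min <- first_window_start(spec)
  t_max <- last_window_start(spec, n_t, k)
  if (t_max < t_min) stop("series too short for any window", call. = FALSE)
  p <- spec$order_p
  min_shift <- k + p + 1L
  if (n_t - 2L * min_shift <= 0L) stop("series too short for surrogate shifts",
                                       call. = FALSE)
  nodes <- colnames(x) %||% paste0("roi", seq_len(n_r))
  omega <- matrix(NA_real_, n_r, n_r, dimnames = list(nodes, nodes))
  pooled <- list()
  pair_id <- 0L
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_r)) {
      if (i == j) next
      pair_id <- pair_id + 1L
      f_vals <- with_seed(seed + pair_id, {
        shifts <- sample(min_shift:(n_t - min_shift), n_surrogates,
                         replace = TRUE)
        starts_pool <- t_min:t_max
        unlist(lapply(seq_len(n_surrogates), function(s) {
          src <- x[((seq_len(n_t) - 1L + shifts[s]) %% n_t) + 1L, i]
          st <- if (length(starts_pool) <= windows_per_surrogate) starts_pool
                else sort(sample(starts_pool, windows_per_surrogate))
          window_gc_engine(src, x[, j], spec, k, st, epsilon)$F
        }))
      })
      if (scope == "per_pair") {
        omega[i, j] <- stats::quantile(f_vals, 1 - alpha, names = FALSE)
      } else {
        pooled[[pair_id]] <- f_vals
      }
    }
  }
  if (scope == "global") {
    return(stats::quantile(unlist(pooled), 1 - alpha, names = FALSE))
  }
  omega
}

#' Dynamic window-level Granger causality over a whole run
#'
#' Slides a window of length `k` over the run and computes, for every
#' ordered node pair, the window-level F statistic and its thresholded
#' value. The resulting time-indexed directed-F tensor is the effective
#' connectivity feature stream fed to the classifiers.
#'
#' @param series an [roi_series()] or numeric `T x R` matrix (R >= 2).
#' @param spec an [ar_model_spec()].
#' @param k window length in volumes (default 4).
#' @param omega threshold: `NULL` or 0 for none, a scalar shared by all
#'   pairs, or a `source x target` matrix from [calibrate_threshold()].
#' @param stride step between successive window starts.
#' @param epsilon floor on `L2`.
#' @return A `connectivity_sequence`: list with `window_starts`, `nodes`,
#'   `k`, `omega`, and `n_windows x n_pairs` matrices `L1`, `L2`, `F`,
#'   `F_thresholded`, `saturated`, columns named `"source->target"`.
#'   Convert with [as.data.frame()] for the long form.
#' @export
dwgc_sequence <- function(series, spec = ar_model_spec(), k = 4L,
                          omega = NULL, stride = 1L, epsilon = 1e-12) {
  x <- if (inherits(series, "roi_series")) series$values else as.matrix(series)
  n_t <- nrow(x)
  n_r <- ncol(x)
  if (n_r < 2L) stop("dynamic causality needs at least 2 nodes", call. = FALSE)
  k <- as.integer(k)
  stride <- as.integer(stride)
  if (k < 1L || stride < 1L) stop("k and stride must be >= 1", call. = FALSE)
  t_min <- first_window_start(spec)
  t_max <- last_window_start(spec, n_t, k)
  if (t_max < t_min) {
    stop(sprintf(
      "series of %d volumes is too short: first window needs %d volumes of history plus k = %d",
      n_t, t_min - 1L, k), call. = FALSE)
  }
  starts <- seq.int(t_min, t_max, by = stride)
  nodes <- colnames(x) %||% paste0("roi", seq_len(n_r))
  pairs <- list()
  for (i in seq_len(n_r)) for (j in seq_len(n_r)) if (i != j) {
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  pair_names <- vapply(pairs, function(pr)
    paste0(nodes[pr[1L]], "->", nodes[pr[2L]]), character(1L))
  n_w <- length(starts)
  F_mat <- L1_mat <- L2_mat <- matrix(
    NA_real_, n_w, length(pairs), dimnames = list(NULL, pair_names))
  sat_mat <- matrix(FALSE, n_w, length(pairs),
                    dimnames = list(NULL, pair_names))
  omega_vec <- pair_threshold_vector(omega, nodes, pairs, pair_names)
  thr_mat <- F_mat
  for (q in seq_along(pairs)) {
    i <- pairs[[q]][1L]; j <- pairs[[q]][2L]
    res <- window_gc_engine(x[, i], x[, j], spec, k, starts, epsilon)
    F_mat[, q] <- res$F
    L1_mat[, q] <- res$L1
    L2_mat[, q] <- res$L2
    sat_mat[, q] <- res$saturated
    thr_mat[, q] <- apply_threshold(res$F, omega_vec[q])
  }
  structure(list(window_starts = starts, nodes = nodes, k = k,
                 omega = omega_vec, stride = stride, spec = spec,
                 L1 = L1_mat, L2 = L2_mat, F = F_mat,
                 F_thresholded = thr_mat, saturated = sat_mat),
            class = "connectivity_sequence")
}

# normalize the threshold argument to one value per ordered pair
pair_threshold_vector <- function(omega, nodes, pairs, pair_names) {
  if (is.null(omega)) {
    out <- rep(0, length(pairs))
  } else if (is.matrix(omega)) {
    out <- vapply(pairs, function(pr) omega[pr[1L], pr[2L]], numeric(1L))
    if (any(!is.finite(out))) {
      stop("threshold matrix lacks entries for some ordered pairs",
           call. = FALSE)
    }
  } else if (length(omega) == 1L) {
    out <- rep(as.numeric(omega), length(pairs))
  } else {
    stop("omega must be NULL, a scalar, or a source x target matrix",
         call. = FALSE)
  }
  names(out) <- pair_names
  out
}

#' @export
print.connectivity_sequence <- function(x, ...) {
  cat(sprintf(
    "Window-level causality: %d windows (k = %d, stride = %d), %d nodes, %d directed pairs\n",
    length(x$window_starts), x$k, x$stride, length(x$nodes), ncol(x$F)))
  invisible(x)
}

#' @export
as.data.frame.connectivity_sequence <- function(x, ...) {
  n_w <- length(x$window_starts)
  pair_names <- colnames(x$F)
  src <- sub("->.*$", "", pair_names)
  tgt <- sub("^.*->", "", pair_names)
  data.frame(
    window_start = rep(x$window_starts, times = length(pair_names)),
    source = rep(src, each = n_w),
    target = rep(tgt, each = n_w),
    L1 = as.vector(x$L1), L2 = as.vector(x$L2), F = as.vector(x$F),
    F_thresholded = as.vector(x$F_thresholded),
    stringsAsFactors = FALSE
  )
}

#' Write a connectivity sequence as long CSV plus a JSON sidecar
#'
#' @param conn a `connectivity_sequence`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
write_connectivity <- function(conn, path) {
  stopifnot(inherits(conn, "connectivity_sequence"))
  utils::write.csv(as.data.frame(conn), path, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(k = conn$k, stride = conn$stride, omega = as.list(conn$omega),
         spec = unclass(conn$spec), nodes = conn$nodes),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
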