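#' Configure a condition-switched latent VAR simulation
#'
#' The latent node dynamics are a first-order vector autoregression whose
#' cross-couplings switch with the experimental condition:
#' `x_i(t) = a_i x_i(t-1) + sum_j c[j,i](cond(t)) x_j(t-1) + drive_i(cond(t)) + e`,
#' with `e ~ N(0, noise_sd^2)`. Couplings model condition-dependent directed
#' (Granger) influence; the per-condition additive `amplitude_schedule`
#' models condition-dependent activation level. Both knobs default to off
#' except where supplied, so a study can modulate coupling, amplitude, or
#' both.
#'
#' @param n_nodes number of latent nodes (>= 2).
#' @param base_ar_coeffs per-node self-regression coefficients, recycled to
#'   `n_nodes`; each must satisfy `|a| < 1`.
#' @param coupling_schedule named list mapping condition label to an
#'   `n_nodes x n_nodes` matrix whose `[j, i]` entry is the directed
#'   coupling j -> i (dimensionless weight on `x_j(t-1)` in node i's
#'   update). Conditions missing from the list get zero coupling.
#' @param amplitude_schedule named list mapping condition label to a
#'   per-node additive drive (recycled); conditions missing get zero.
#' @param noise_sd innovation standard deviation of the latent VAR.
#' @param noise_schedule optional named list mapping condition label to a
#'   per-node innovation standard deviation (recycled); conditions missing
#'   fall back to `noise_sd`. Use [variance_matched_noise()] to keep each
#'   node's marginal variance flat across conditions while its coupling
#'   changes, so that only the directed dependence — not the signal
#'   amplitude — distinguishes conditions.
#' @param hrf_params hemodynamic response parameters, see [hrf_kernel()].
#' @param observation_noise_sd i.i.d. voxelwise noise added when rendering
#'   volumes ([render_volumes()]).
#' @param seed integer; fully determines every random draw.
#' @return A `simulation_config` list, validated for stability: each
#'   condition's transition matrix must have spectral radius < 1.
#' @examples
#' cpl <- matrix(0, 2, 2); cpl[1, 2] <- 0.8
#' cfg <- simulation_config(n_nodes = 2,
#'                          coupling_schedule = list(MIL = cpl))
#' @export
simulation_config <- function(n_nodes = 4,
                              base_ar_coeffs = 0.5,
                              coupling_schedule = list(),
                              amplitude_schedule = list(),
                              noise_sd = 1,
                              noise_schedule = list(),
                              hrf_params = hrf_parameters(),
                              observation_noise_sd = 1,
                              seed = 1L) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 2) {
    stop("`n_nodes` must be an integer >= 2", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  a <- rep_len(as.numeric(base_ar_coeffs), n_nodes)
  if (any(abs(a) >= 1)) {
    stop("all base_ar_coeffs must satisfy |a| < 1", call. = FALSE)
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  stopifnot_scalar_number(observation_noise_sd, "observation_noise_sd")
  if (observation_noise_sd < 0) stop("observation_noise_sd must be >= 0",
                                     call. = FALSE)
  coupling_schedule <- lapply(coupling_schedule, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == n_nodes)) {
      stop("each coupling matrix must be n_nodes x n_nodes", call. = FALSE)
    }
    storage.mode(m) <- "double"
    m
  })
  cfg <- structure(
    list(n_nodes = n_nodes, base_ar_coeffs = a,
         coupling_schedule = coupling_schedule,
         amplitude_schedule = lapply(amplitude_schedule, function(v)
           rep_len(as.numeric(v), n_nodes)),
         noise_sd = noise_sd,
         noise_schedule = lapply(noise_schedule, function(v) {
           v <- rep_len(as.numeric(v), n_nodes)
           if (any(v <= 0)) stop("noise_schedule sds must be positive",
                                 call. = FALSE)
           v
         }),
         hrf_params = hrf_params,
         observation_noise_sd = observation_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  for (cond in names(coupling_schedule)) {
    rho <- spectral_radius(transition_matrix(cfg, cond))
    if (rho >= 1) {
      stop(sprintf(
        "condition \"%s\" yields an unstable VAR (spectral radius %.3f >= 1)",
        cond, rho), call. = FALSE)
    }
  }
  cfg
}

# x(t) = A x(t-1) + noise with A = diag(a) + t(coupling): node i receives
# coupling[j, i] * x_j(t-1)
transition_matrix <- function(config, condition) {
  A <- diag(config$base_ar_coeffs, config$n_nodes)
  cpl <- config$coupling_schedule[[condition]]
  if (!is.null(cpl)) A <- A + t(cpl)
  A
}

spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Simulate latent node signals under a paradigm
#'
#' Runs the condition-switched VAR of [simulation_config()] over the
#' per-volume condition sequence of `paradigm` and returns both the latent
#' matrix and the ground truth needed to score downstream causality
#' recovery.
#'
#' @param config a [simulation_config()].
#' @param paradigm a [generate_paradigm()] object, or a character vector of
#'   per-volume condition labels.
#' @return List with `latent` (`n_nodes x T` matrix), and `ground_truth`:
#'   per-volume `labels` plus `adjacency`, the per-condition logical matrix
#'   of true nonzero directed couplings (`[j, i]` = j -> i).
#' @export
simulate_latent_signals <- function(config, paradigm) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- if (inherits(paradigm, "paradigm")) condition_labels(paradigm)
            else as.character(paradigm)
  n_t <- length(labels)
  if (n_t < 2L) stop("paradigm must span at least 2 volumes", call. = FALSE)
  # conditions without a schedule entry get zero coupling / zero drive
  n <- config$n_nodes
  A_by_cond <- lapply(unique(labels), function(cond) transition_matrix(config, cond))
  names(A_by_cond) <- unique(labels)
  drive_by_cond <- lapply(unique(labels), function(cond) {
    d <- config$amplitude_schedule[[cond]]
    if (is.null(d)) numeric(n) else d
  })
  names(drive_by_cond) <- unique(labels)

  sd_by_cond <- lapply(unique(labels), function(cond) {
    s <- config$noise_schedule[[cond]]
    if (is.null(s)) rep(config$noise_sd, n) else s
  })
  names(sd_by_cond) <- unique(labels)
  x <- matrix(0, nrow = n, ncol = n_t)
  with_seed(config$seed, {
    eps <- matrix(stats::rnorm(n * n_t), nrow = n)
    for (cond in unique(labels)) {
      eps[, labels == cond] <- eps[, labels == cond] * sd_by_cond[[cond]]
    }
    x[, 1L] <- eps[, 1L] + drive_by_cond[[labels[1L]]]
    for (t in 2:n_t) {
      x[, t] <- A_by_cond[[labels[t]]] %*% x[, t - 1L] +
        drive_by_cond[[labels[t]]] + eps[, t]
    }
  })
  adjacency <- lapply(unique(labels), function(cond) {
    cpl <- config$coupling_schedule[[cond]]
    if (is.null(cpl)) matrix(FALSE, n, n) else cpl != 0
  })
  names(adjacency) <- unique(labels)
  list(latent = x,
       ground_truth = list(labels = labels, adjacency = adjacency))
}

#' Innovation noise that keeps node variances flat under coupling
#'
#' Directed coupling feeds extra variance into its target node, so a
#' coupled condition would be distinguishable from rest by signal
#' amplitude alone. This helper computes per-node innovation standard
#' deviations for a coupled condition such that the stationary marginal
#' variance of every node equals its rest (uncoupled) value: solving the
#' discrete Lyapunov equation `Sigma = A Sigma A' + Q`, the stationary
#' variances are linear in the innovation variances `q`, so the matching
#' `q` solves a small linear system. Use the result as a
#' `noise_schedule` entry to simulate conditions that differ *only* in
#' their directed dependence structure.
#'
#' @param base_ar_coeffs per-node self-regression coefficients.
#' @param coupling `n x n` coupling matrix (`[j, i]` = j -> i) of the
#'   condition to match.
#' @param noise_sd innovation sd of the uncoupled (rest) condition.
#' @param hrf_kernel optional sampled hemodynamic kernel (from
#'   [hrf_kernel()]). When given, the *convolved* (BOLD-level) variances
#'   are matched instead of the latent ones — hemodynamic filtering
#'   reweights the autocovariance, so latent-variance matching alone
#'   still leaks an amplitude cue into the observed signal.
#' @return Per-node innovation standard deviations for the coupled
#'   condition.
#' @export
variance_matched_noise <- function(base_ar_coeffs, coupling, noise_sd = 1,
                                   hrf_kernel = NULL) {
  n <- nrow(coupling)
  a <- rep_len(as.numeric(base_ar_coeffs), n)
  A <- diag(a, n) + t(coupling)
  if (spectral_radius(A) >= 1) stop("coupled system is unstable",
                                    call. = FALSE)
  A0 <- diag(a, n)
  # filtered variance of node i: sum_l c_h(l) gamma_ii(l), with c_h the
  # kernel's lag autocorrelation (c_h = 1 at lag 0 only for no filter)
  # and gamma(l) = A^l Sigma; Sigma and hence every gamma_ii(l) is linear
  # in the innovation variances q, so matching is a linear solve.
  ch <- if (is.null(hrf_kernel)) 1 else {
    L <- length(hrf_kernel)
    vapply(0:(L - 1L), function(l)
      sum(hrf_kernel[seq_len(L - l)] * hrf_kernel[(1L + l):L]), numeric(1L))
  }
  filtered_var <- function(A, Q) {
    # stationary Sigma solving Sigma = A Sigma A' + Q
    Sigma <- matrix(solve(diag(n * n) - kronecker(A, A), as.vector(Q)), n, n)
    v <- ch[1L] * diag(Sigma)
    if (length(ch) > 1L) {
      G <- Sigma
      for (l in 2:length(ch)) {
        G <- A %*% G
        v <- v + 2 * ch[l] * diag(G)
      }
    }
    v
  }
  target <- filtered_var(A0, diag(noise_sd^2, n))
  M <- vapply(seq_len(n), function(j) {
    Q <- matrix(0, n, n)
    Q[j, j] <- 1
    filtered_var(A, Q)
  }, numeric(n))
  q <- solve(M, target)
  if (any(q <= 0)) {
    stop("coupling too strong to match variances with positive innovation noise",
         call. = FALSE)
  }
  sqrt(drop(q))
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The BOLD response to a brief neural event rises over a few seconds,
#' peaks at roughly 5 s, and undershoots near 15 s before returning to
#' baseline. The kernel is the standard difference of two gamma densities,
#' sampled at the TR, truncated at `duration_s`, and normalized to unit sum
#' so that a sustained input converges to its own level.
#'
#' @param peak_s time-to-peak of the positive lobe in seconds.
#' @param undershoot_s time-to-trough of the undershoot in seconds.
#' @param ratio relative amplitude of the undershoot.
#' @param duration_s truncation point of the kernel in seconds.
#' @return `hrf_parameters()` returns the parameter list; `hrf_kernel()`
#'   returns the sampled, unit-sum kernel (first sample at lag 0).
#' @export
hrf_parameters <- function(peak_s = 5, undershoot_s = 15, ratio = 1 / 6,
                           duration_s = 30) {
  list(peak_s = peak_s, undershoot_s = undershoot_s, ratio = ratio,
       duration_s = duration_s)
}

#' @rdname hrf_parameters
#' @param tr_seconds sampling interval of the kernel.
#' @param params an [hrf_parameters()] list.
#' @export
hrf_kernel <- function(tr_seconds, params = hrf_parameters()) {
  stopifnot_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  t <- seq(0, params$duration_s, by = tr_seconds)
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = params$peak_s + 1, rate = 1) -
    params$ratio * stats::dgamma(t, shape = params$undershoot_s + 1, rate = 1)
  peak_t <- t[which.max(h)]
  if (peak_t < 0 || peak_t > 30) {
    warning(sprintf("HRF kernel peaks at %g s, outside [0, 30] s", peak_t))
  }
  h / sum(h)
}

#' Convolve latent signals with the hemodynamic response
#'
#' Applies a causal, truncated convolution of every node's latent series
#' with the double-gamma kernel, emulating the hemodynamic lag that delays
#' BOLD expression of neural events by 2-6 s.
#'
#' @param latent_matrix `n_nodes x T` latent matrix (or a numeric vector).
#' @param tr_seconds sampling interval in seconds.
#' @param hrf_params an [hrf_parameters()] list.
#' @return Matrix (or vector) of the same shape: `y(t) = sum_m h(m) x(t - m)`
#'   with `x` taken as zero before the first sample.
#' @export
apply_hrf <- function(latent_matrix, tr_seconds, hrf_params = hrf_parameters()) {
  vec_in <- is.null(dim(latent_matrix))
  x <- if (vec_in) matrix(latent_matrix, nrow = 1L) else as.matrix(latent_matrix)
  if (!all(is.finite(x))) stop("latent matrix contains non-finite values",
                               call. = FALSE)
  h <- hrf_kernel(tr_seconds, hrf_params)
  n_t <- ncol(x)
  out <- t(apply(x, 1L, function(row) {
    full <- stats::convolve(row, rev(h), type = "open")
    full[seq_len(n_t)]
  }))
  if (vec_in) drop(out) else out
}
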