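#' Render ROI series into a synthetic 4D volume stack
#'
#' Paints each ROI's per-volume signal onto the voxels of its sphere, adds a
#' constant background baseline, and overlays i.i.d. Gaussian observation
#' noise, producing a stack that round-trips through mask building and mean
#' extraction. ROI spheres must be pairwise disjoint so the ground truth of
#' every voxel is unambiguous.
#'
#' @param roi_series_values `T x R` matrix of per-volume ROI signals (or an
#'   [roi_series()] object).
#' @param roi_specs list of [roi_spec()] objects, one per column.
#' @param grid a [volume_grid()]; all spheres must fit inside it.
#' @param baseline background (and additive ROI) offset in BOLD units.
#' @param observation_noise_sd voxelwise noise standard deviation.
#' @param seed integer seed for the noise draw.
#' @return List with `volumes` (4D array), `affine`, `masks` (named list of
#'   linear indices) and `grid`.
#' @export
render_volumes <- function(roi_series_values, roi_specs, grid,
                           baseline = 100, observation_noise_sd = 0,
                           seed = 1L) {
  vals <- if (inherits(roi_series_values, "roi_series"))
    roi_series_values$values else as.matrix(roi_series_values)
  stopifnot(inherits(grid, "volume_grid"))
  if (length(roi_specs) != ncol(vals)) {
    stop("need one roi_spec per series column", call. = FALSE)
  }
  if (observation_noise_sd < 0) stop("observation_noise_sd must be >= 0",
                                     call. = FALSE)
  masks <- lapply(roi_specs, build_sphere_mask, grid = grid)
  names(masks) <- vapply(roi_specs, `[[`, character(1L), "name")
  # spheres that leave the grid would silently lose voxels: require the
  # full brute-force sphere volume to be present
  centers <- voxel_centers_mm(grid)
  lo <- apply(centers, 2L, min); hi <- apply(centers, 2L, max)
  for (i in seq_along(roi_specs)) {
    r <- roi_specs[[i]]
    pad <- r$radius_mm
    if (any(r$center_mm - pad < lo - 1e-9) || any(r$center_mm + pad > hi + 1e-9)) {
      stop(sprintf("ROI \"%s\" (radius %g mm) does not fit inside the grid",
                   r$name, r$radius_mm), call. = FALSE)
    }
  }
  all_idx <- unlist(masks)
  if (anyDuplicated(all_idx)) {
    stop("ROI spheres overlap: ground truth would be ambiguous", call. = FALSE)
  }
  n_t <- nrow(vals)
  nvox <- prod(grid$shape)
  flat <- matrix(baseline, nrow = nvox, ncol = n_t)
  for (r in seq_along(masks)) {
    flat[masks[[r]], ] <- rep(baseline + vals[, r], each = length(masks[[r]]))
  }
  if (observation_noise_sd > 0) {
    flat <- flat + with_seed(seed, matrix(
      stats::rnorm(nvox * n_t, sd = observation_noise_sd), nrow = nvox))
  }
  list(volumes = array(flat, dim = c(grid$shape, n_t)),
       affine = grid$affine, masks = masks, grid = grid)
}

#' Write / read a 4D volume stack as NIfTI-1
#'
#' @param volumes 4D array.
#' @param affine 4x4 voxel-index-to-mm affine (RAS+), stored as the sform.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volumes_nifti <- function(volumes, affine, path) {
  img <- RNifti::asNifti(unclass(volumes))
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volumes_nifti
#' @return `read_volumes_nifti` returns a list with `volumes` (4D array)
#'   and `grid` (a [volume_grid()] carrying the stored affine).
#' @export
read_volumes_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  d <- dim(arr)
  if (length(d) == 3L) dim(arr) <- c(d, 1L)
  list(volumes = arr,
       grid = volume_grid(dim(arr)[1:3], affine = unclass(aff)))
}

#' Simulate a complete synthetic motor-imagery run
#'
#' Convenience wrapper chaining paradigm, latent VAR, hemodynamic
#' convolution and (optionally) volume rendering, returning everything a
#' downstream pipeline or test needs, with ground truth.
#'
#' @param config a [simulation_config()].
#' @param paradigm a [generate_paradigm()] object.
#' @param roi_specs optional list of [roi_spec()]; required with
#'   `render = TRUE`.
#' @param grid optional [volume_grid()] for rendering.
#' @param render if `TRUE`, also render 4D volumes.
#' @return List with `series` (an [roi_series()] of the HRF-convolved node
#'   signals, labeled by condition), `latent`, `ground_truth`, and, when
#'   rendered, `volumes`/`affine`/`masks`.
#' @export
simulate_run <- function(config, paradigm, roi_specs = NULL, grid = NULL,
                         render = FALSE) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(paradigm, "paradigm"))
  sim <- simulate_latent_signals(config, paradigm)
  bold <- apply_hrf(sim$latent, paradigm$tr_seconds, config$hrf_params)
  roi_names <- if (!is.null(roi_specs)) {
    vapply(roi_specs, `[[`, character(1L), "name")
  } else paste0("node", seq_len(config$n_nodes))
  series <- roi_series(t(bold), paradigm$tr_seconds, roi_names,
                       sim$ground_truth$labels)
  out <- list(series = series, latent = sim$latent,
              ground_truth = sim$ground_truth)
  if (render) {
    if (is.null(roi_specs) || is.null(grid)) {
      stop("rendering requires roi_specs and a volume grid", call. = FALSE)
    }
    rv <- render_volumes(series, roi_specs, grid,
                         observation_noise_sd = config$observation_noise_sd,
                         seed = config$seed + 1000L)
    out <- c(out, rv[c("volumes", "affine", "masks")])
  }
  out
}
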