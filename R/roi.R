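#' ROI and volume-grid constructors
#'
#' An ROI is a named sphere in scanner millimetre space; a volume grid is a
#' voxel lattice with an invertible affine mapping 0-based voxel indices to
#' mm coordinates. Typical seed-node ROIs in motor-imagery work are 5 mm
#' spheres in prefrontal cortex and 10 mm spheres over sensorimotor cortex.
#'
#' @param name ROI label, unique within a set.
#' @param center_mm numeric length-3, sphere centre in mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @export
roi_spec <- function(name, center_mm, radius_mm) {
  stopifnot(is.character(name), length(name) == 1L)
  center_mm <- as.numeric(center_mm)
  if (length(center_mm) != 3L || !all(is.finite(center_mm))) {
    stop("center_mm must be a finite (x, y, z) triple", call. = FALSE)
  }
  stopifnot_scalar_number(radius_mm, "radius_mm", positive = TRUE)
  structure(list(name = name, center_mm = center_mm, radius_mm = radius_mm),
            class = "roi_spec")
}

#' @rdname roi_spec
#' @param shape integer (nx, ny, nz) grid dimensions.
#' @param voxel_size_mm isotropic voxel edge length, used when `affine` is
#'   not given.
#' @param origin_mm mm coordinate of voxel (0, 0, 0); defaults to centring
#'   the grid on the mm origin.
#' @param affine optional full 4x4 voxel-index-to-mm affine (RAS+);
#'   overrides `voxel_size_mm`/`origin_mm`.
#' @export
volume_grid <- function(shape, voxel_size_mm = 2, origin_mm = NULL,
                        affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    if (is.null(origin_mm)) {
      origin_mm <- -voxel_size_mm * (shape - 1L) / 2
    }
    affine <- diag(c(rep(voxel_size_mm, 3L), 1))
    affine[1:3, 4L] <- origin_mm
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible", call. = FALSE)
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

# mm coordinates of all voxel centres, as an (nvox x 3) matrix in the
# grid's linear (column-major) voxel order
voxel_centers_mm <- function(grid) {
  idx <- as.matrix(expand.grid(i = 0:(grid$shape[1L] - 1L),
                               j = 0:(grid$shape[2L] - 1L),
                               k = 0:(grid$shape[3L] - 1L)))
  hom <- cbind(idx, 1) %*% t(grid$affine)
  hom[, 1:3, drop = FALSE]
}

#' Build a spherical ROI voxel mask
#'
#' A voxel belongs to the mask iff the Euclidean distance from its centre
#' (its affine-mapped index) to the ROI centre is at most the radius
#' (closed ball).
#'
#' @param roi an [roi_spec()].
#' @param grid a [volume_grid()].
#' @return Integer vector of linear (column-major, 1-based) voxel indices.
#' @export
build_sphere_mask <- function(roi, grid) {
  stopifnot(inherits(roi, "roi_spec"), inherits(grid, "volume_grid"))
  centers <- voxel_centers_mm(grid)
  d2 <- (centers[, 1L] - roi$center_mm[1L])^2 +
        (centers[, 2L] - roi$center_mm[2L])^2 +
        (centers[, 3L] - roi$center_mm[3L])^2
  mask <- which(d2 <= roi$radius_mm^2 + 1e-9)
  if (length(mask) == 0L) {
    stop(sprintf("ROI \"%s\" does not intersect the volume grid", roi$name),
         call. = FALSE)
  }
  mask
}

#' Construct an ROI time-series matrix
#'
#' The container for per-volume mean BOLD values of every ROI, together
#' with the TR and the per-volume condition labels.
#'
#' @param values numeric `T x R` matrix, volumes in rows, ROIs in columns.
#' @param tr_seconds repetition time.
#' @param roi_names column names (length R).
#' @param condition_labels per-volume labels (length T).
#' @export
roi_series <- function(values, tr_seconds, roi_names = colnames(values),
                       condition_labels = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("series values must be finite", call. = FALSE)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(ncol(values)))
  stopifnot(length(roi_names) == ncol(values))
  if (is.null(condition_labels)) condition_labels <- rep(NA_character_, nrow(values))
  if (length(condition_labels) != nrow(values)) {
    stop("condition_labels length must equal the number of volumes", call. = FALSE)
  }
  colnames(values) <- roi_names
  structure(list(values = values, tr_seconds = tr_seconds,
                 roi_names = roi_names,
                 condition_labels = as.character(condition_labels)),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("ROI series: %d volumes x %d ROIs (TR = %g s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_series <- function(x) dim(x$values)

#' Extract per-volume ROI mean series from a 4D volume stack
#'
#' Entry (t, r) is the arithmetic mean of volume t over the voxels of
#' mask r — the per-TR "average activation value" of the ROI.
#'
#' @param volumes 4D array (nx, ny, nz, T) or an RNifti image.
#' @param masks named list of linear voxel index vectors
#'   (from [build_sphere_mask()]).
#' @param tr_seconds repetition time stored on the result.
#' @param condition_labels optional per-volume labels.
#' @return An [roi_series()].
#' @export
extract_mean_series <- function(volumes, masks, tr_seconds = 2,
                                condition_labels = NULL) {
  volumes <- unclass(volumes)
  d <- dim(volumes)
  if (length(d) != 4L) stop("`volumes` must be a 4D (x, y, z, t) array",
                            call. = FALSE)
  nvox <- prod(d[1:3])
  flat <- matrix(volumes, nrow = nvox, ncol = d[4L])
  bad <- vapply(masks, function(m) any(m < 1L | m > nvox), logical(1L))
  if (any(bad)) {
    stop(sprintf("mask(s) %s index outside the volume grid",
                 paste(names(masks)[bad], collapse = ", ")), call. = FALSE)
  }
  vals <- vapply(masks, function(m) colMeans(flat[m, , drop = FALSE]),
                 numeric(d[4L]))
  if (d[4L] == 1L) vals <- matrix(vals, nrow = 1L)
  roi_series(vals, tr_seconds,
             roi_names = names(masks) %||% paste0("roi", seq_along(masks)),
             condition_labels = condition_labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-ROI rest baseline of an ROI series
#'
#' The mean BOLD of each ROI over rest-labeled volumes, after excluding the
#' first `n_transition` volumes of every label run (hemodynamic
#' transitions). This is the `BOLDrest` reference that activation features
#' subtract.
#'
#' @param series an [roi_series()] with condition labels.
#' @param n_transition transition volumes to trim from each run (default 4).
#' @return Named numeric vector, one baseline per ROI.
#' @export
rest_baseline <- function(series, n_transition = 4L) {
  stopifnot(inherits(series, "roi_series"))
  stable <- trim_transitions(series$condition_labels, n_transition)
  rest_idx <- stable[series$condition_labels[stable] == "rest"]
  if (length(rest_idx) == 0L) {
    stop("no stable rest-labeled volumes to form a baseline", call. = FALSE)
  }
  colMeans(series$values[rest_idx, , drop = FALSE])
}

#' Per-volume activation feature (task-minus-rest BOLD)
#'
#' The activation feature of ROI r at volume t is the ROI's current mean
#' BOLD minus its rest baseline: `ACTIVE[t, r] = BOLD[t, r] - baseline[r]`,
#' updated once per volume.
#'
#' @param series an [roi_series()].
#' @param baseline named per-ROI baseline, e.g. from [rest_baseline()].
#' @return `T x R` matrix of activation values (same units as BOLD).
#' @export
compute_active <- function(series, baseline) {
  stopifnot(inherits(series, "roi_series"))
  if (is.null(names(baseline))) names(baseline) <- series$roi_names
  missing <- setdiff(series$roi_names, names(baseline))
  if (length(missing) > 0L) {
    stop(sprintf("baseline missing for ROI(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!all(is.finite(baseline))) stop("baseline must be finite", call. = FALSE)
  sweep(series$values, 2L, baseline[series$roi_names], "-")
}

#' Discard initial volumes of a run
#'
#' Early volumes of a BOLD sequence are acquired before magnetization
#' reaches steady state and are conventionally dropped (10 volumes here).
#'
#' @param series an [roi_series()].
#' @param n_discard number of leading volumes to remove.
#' @return The shortened [roi_series()], order preserved.
#' @export
discard_initial <- function(series, n_discard = 10L) {
  stopifnot(inherits(series, "roi_series"))
  n_discard <- as.integer(n_discard)
  n <- nrow(series$values)
  if (n_discard < 0L) stop("n_discard must be >= 0", call. = FALSE)
  if (n_discard >= n) {
    stop(sprintf("n_discard (%d) must be smaller than the %d available volumes",
                 n_discard, n), call. = FALSE)
  }
  if (n_discard == 0L) return(series)
  keep <- (n_discard + 1L):n
  roi_series(series$values[keep, , drop = FALSE], series$tr_seconds,
             series$roi_names, series$condition_labels[keep])
}

#' Indices of hemodynamically stable volumes
#'
#' BOLD needs roughly 2-6 s to follow a state change, so the first
#' `n_transition` volumes of every maximal constant-label run are excluded
#' when building training sets. Runs no longer than `n_transition`
#' contribute no indices.
#'
#' @param condition_labels per-volume labels.
#' @param n_transition volumes to drop at the start of each run (default 4).
#' @return Increasing integer vector of stable 1-based volume indices.
#' @export
trim_transitions <- function(condition_labels, n_transition = 4L) {
  n_transition <- as.integer(n_transition)
  if (n_transition < 0L) stop("n_transition must be >= 0", call. = FALSE)
  labels <- as.character(condition_labels)
  n <- length(labels)
  if (n == 0L) return(integer(0))
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- unlist(lapply(seq_along(starts), function(i) {
    first <- starts[i] + n_transition
    if (first > ends[i]) integer(0) else first:ends[i]
  }))
  as.integer(idx)
}

#' Read / write ROI series as CSV
#'
#' One row per volume, one column per ROI, plus a trailing `condition`
#' label column.
#'
#' @param series an [roi_series()].
#' @param path CSV path.
#' @export
write_roi_series <- function(series, path) {
  stopifnot(inherits(series, "roi_series"))
  df <- as.data.frame(series$values)
  df$condition <- series$condition_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_series
#' @param tr_seconds repetition time of the stored run.
#' @export
read_roi_series <- function(path, tr_seconds = 2) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"condition" %in% names(df)) {
    stop("ROI series CSV must have a `condition` column", call. = FALSE)
  }
  labels <- df$condition
  df$condition <- NULL
  roi_series(as.matrix(df), tr_seconds, names(df), labels)
}

#' Read ROI specifications from a config file
#'
#' Accepts a CSV with columns `name, x, y, z, radius` (mm) or a YAML file
#' with a `rois:` list of the same fields.
#'
#' @param path file path (`.csv` or `.yaml`/`.yml`).
#' @return List of [roi_spec()] objects.
#' @export
read_roi_specs <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML ROI specs requires the yaml package", call. = FALSE)
    }
    cfg <- yaml::read_yaml(path)
    rois <- cfg$rois %||% cfg
    return(lapply(rois, function(r)
      roi_spec(r$name, c(r$x, r$y, r$z), r$radius)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "radius")
  if (!all(need %in% names(df))) {
    stop("ROI spec CSV must have columns name, x, y, z, radius", call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i)
    roi_spec(df$name[i], c(df$x[i], df$y[i], df$z[i]), df$radius[i]))
}
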