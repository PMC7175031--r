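# 4D volume containers, masking, smoothing: the subject-level I/O layer.

#' Construct a 4D volume series
#'
#' A subject's scan: a 4D intensity array stored in the native R/NIfTI axis
#' order `x, y, z, t` (the last margin indexes the K time points), together
#' with the voxel-to-world affine and the repetition time.
#'
#' @param data 4D numeric array `x * y * z * t` with `K = dim(data)[4] >= 2`.
#' @param affine invertible 4x4 voxel-to-world transform.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `volume_series`.
#' @export
volume_series <- function(data, affine = diag(4), tr_seconds = 0.72) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)", call. = FALSE)
  if (dim(data)[4] < 2L)
    stop("a volume series needs at least K = 2 time points", call. = FALSE)
  if (any(dim(data)[1:3] < 1L))
    stop("spatial dimensions must be >= 1", call. = FALSE)
  affine <- unclass(as.matrix(affine))[1:4, 1:4]
  if (abs(det(affine)) < 1e-12)
    stop("`affine` must be invertible", call. = FALSE)
  structure(list(data = data, affine = affine,
                 tr_seconds = as.numeric(tr_seconds)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d grid, K = %d time points, TR = %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

n_timepoints <- function(series) dim(series$data)[4]

#' Load a 4D NIfTI file as a volume series
#'
#' Reads a NIfTI-1 volume series and discards the leading frames (magnetic
#' saturation volumes; the customary count is 5).
#'
#' @param path path to a 4D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param n_discard number of initial frames to drop; must be smaller than
#'   the number of stored frames.
#' @return a [volume_series].
#' @export
load_volume_series <- function(path, n_discard = 5L) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "cannot read '%s' as NIfTI: %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(dim(img)) != 4L)
    stop(sprintf("'%s' is not a 4D volume series", path), call. = FALSE)
  k <- dim(img)[4]
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L || n_discard >= k)
    stop(sprintf("n_discard = %d out of range for K = %d frames", n_discard, k),
         call. = FALSE)
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  data <- unclass(img)[, , , (n_discard + 1L):k, drop = FALSE]
  volume_series(data, affine = RNifti::xform(img), tr_seconds = tr)
}

#' Discard leading frames of an in-memory series
#'
#' @param series a [volume_series].
#' @param n_discard frames to drop from the front.
#' @return the truncated [volume_series].
#' @export
discard_frames <- function(series, n_discard) {
  k <- n_timepoints(series)
  n_discard <- as.integer(n_discard)
  if (n_discard < 0L || n_discard >= k)
    stop(sprintf("n_discard = %d out of range for K = %d frames", n_discard, k),
         call. = FALSE)
  if (n_discard == 0L) return(series)
  series$data <- series$data[, , , (n_discard + 1L):k, drop = FALSE]
  series
}

#' Write a 3D map (or stack of maps) as NIfTI
#'
#' @param data 3D array, or list of 3D arrays written as one 4D file.
#' @param affine 4x4 voxel-to-world transform to attach.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(data, affine, path) {
  if (is.list(data)) {
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)))
  }
  img <- RNifti::asNifti(data)
  affine <- unclass(as.matrix(affine))
  RNifti::qform(img) <- structure(affine, code = 2L)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (length(dim(img)) > 3L)
    pd <- c(pd, rep(1, length(dim(img)) - 3L))
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1D zero-padded convolution along one margin of an nd array.
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - 1L - half
    lo <- max(1L, 1L + off); hi <- min(n, n + off)
    if (lo > hi) next
    src <- seq.int(lo, hi)
    out[src - off, ] <- out[src - off, ] + kernel[k] * m[src, , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Gaussian smoothing of every frame
#'
#' Convolves each 3D frame with an isotropic Gaussian of the stated full
#' width at half maximum. The kernel standard deviation is
#' `FWHM / (2 sqrt(2 log 2))`, converted to voxels per axis from the affine;
#' the separable kernel is normalized to unit sum so the image sum is
#' preserved up to zero-padding truncation at the grid boundary.
#'
#' @param series a [volume_series].
#' @param fwhm_mm kernel FWHM in millimetres; 0 returns the series unchanged.
#' @return the smoothed [volume_series].
#' @export
smooth_gaussian <- function(series, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("`fwhm_mm` must be a single non-negative number", call. = FALSE)
  if (fwhm_mm == 0) return(series)
  vox <- sqrt(colSums(series$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox
  data <- series$data
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s < 1e-8) next
    r <- max(1L, ceiling(4 * s))
    kern <- dnorm(seq.int(-r, r), sd = s)
    kern <- kern / sum(kern)
    data <- convolve_axis(data, kern, axis)
  }
  series$data <- data
  series
}

#' Construct a brain mask
#'
#' @param mask 3D logical array.
#' @return an object of class `brain_mask` with the voxel count `L` and the
#'   column-to-coordinate map `voxel_index` (x-fastest order, 1-based).
#' @export
brain_mask <- function(mask) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim(mask))
  L <- sum(mask)
  if (L < 1L) stop("mask is empty: no in-brain voxels", call. = FALSE)
  structure(list(mask = mask, L = L,
                 voxel_index = which(mask, arr.ind = TRUE)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %s grid, L = %d in-mask voxels\n",
              paste(dim(x$mask), collapse = " x "), x$L))
  invisible(x)
}

#' Build a group brain mask by temporal-mean thresholding
#'
#' A voxel enters the mask iff, in every subject, its temporal-mean
#' intensity exceeds `threshold_fraction` times the mean over voxels with
#' positive temporal mean; the per-subject masks are intersected.
#'
#' @param series_list list of [volume_series] on one common grid.
#' @param threshold_fraction fraction of the positive-voxel mean intensity.
#' @return a [brain_mask].
#' @export
build_group_mask <- function(series_list, threshold_fraction = 0.5) {
  if (length(series_list) < 1L) stop("need at least one subject", call. = FALSE)
  dims <- dim(series_list[[1]]$data)[1:3]
  acc <- array(TRUE, dims)
  for (s in series_list) {
    if (!identical(dim(s$data)[1:3], dims))
      stop_shape("subjects are not on a common grid")
    tm <- rowMeans(matrix(s$data, nrow = prod(dims)))
    pos <- tm > 0
    if (!any(pos)) stop("subject has no positive-mean voxels", call. = FALSE)
    thr <- threshold_fraction * mean(tm[pos])
    acc <- acc & array(tm > thr, dims)
  }
  if (!any(acc))
    stop("group mask is empty after intersection", call. = FALSE)
  brain_mask(acc)
}

#' Extract the K x L in-mask data matrix of a subject
#'
#' @param series a [volume_series].
#' @param mask a [brain_mask] on the same grid.
#' @return a `subject_matrix`: time points in rows, in-mask voxels in
#'   columns, sharing the mask's `voxel_index` column order.
#' @export
mask_series <- function(series, mask) {
  dims <- dim(series$data)
  if (!identical(dims[1:3], dim(mask$mask)))
    stop_shape("series grid does not match mask grid")
  flat <- matrix(series$data, nrow = prod(dims[1:3]))
  subject_matrix(t(flat[as.vector(mask$mask), , drop = FALSE]),
                 voxel_index = mask$voxel_index)
}

#' Reconstruct 3D images from the rows of an in-mask matrix
#'
#' Inverse of masking: each row is scattered back onto the mask support,
#' out-of-mask voxels are zero.
#'
#' @param x matrix with `L` columns (e.g. a [pca_reduce] result's `values`),
#'   or a `reduced_matrix`.
#' @param mask the [brain_mask] that defined the column order.
#' @return list of 3D arrays, one per row.
#' @export
rows_to_volumes <- function(x, mask) {
  vals <- if (inherits(x, "reduced_matrix") || inherits(x, "subject_matrix"))
    x$values else as.matrix(x)
  if (ncol(vals) != mask$L)
    stop_shape(sprintf("matrix has %d columns but mask has L = %d voxels",
                       ncol(vals), mask$L))
  sel <- as.vector(mask$mask)
  lapply(seq_len(nrow(vals)), function(m) {
    out <- numeric(length(sel))
    out[sel] <- vals[m, ]
    array(out, dim(mask$mask))
  })
}
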