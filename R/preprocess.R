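# Temporal cleaning and PCA reduction of subject matrices.

#' Construct a subject data matrix
#'
#' @param values K x L numeric matrix: temporal evolution of L in-mask
#'   voxels at K time points.
#' @param voxel_index L x 3 matrix mapping columns to grid coordinates.
#' @return an object of class `subject_matrix`.
#' @export
subject_matrix <- function(values, voxel_index = NULL) {
  values <- as.matrix(values)
  if (!is.null(voxel_index) && nrow(voxel_index) != ncol(values))
    stop_shape("voxel_index rows must match matrix columns")
  structure(list(values = values, voxel_index = voxel_index),
            class = "subject_matrix")
}

#' Linearly detrend and standardize voxel time series
#'
#' Per column (voxel): the least-squares linear trend over time is removed,
#' then the residual is scaled to zero mean and unit sample variance.
#' Columns that are constant (zero residual variance) are mapped to
#' all-zero with a warning, keeping L stable across subjects.
#'
#' @param x a [subject_matrix] with K >= 3 time points.
#' @return the detrended, standardized [subject_matrix].
#' @export
detrend_standardize <- function(x) {
  v <- x$values
  K <- nrow(v)
  if (K < 3L) stop("detrending needs K >= 3 time points", call. = FALSE)
  t0 <- seq_len(K) - (K + 1) / 2              # centered time axis
  denom <- sum(t0^2)
  ctr <- sweep(v, 2, colMeans(v))
  slope <- colSums(t0 * ctr) / denom
  resid <- ctr - outer(t0, slope)
  resid <- sweep(resid, 2, colMeans(resid))   # numerically re-center
  sdv <- sqrt(colSums(resid^2) / (K - 1))
  const <- sdv < 1e-12
  if (any(const)) {
    warning(sprintf("%d constant voxel column(s) set to zero", sum(const)),
            call. = FALSE)
    sdv[const] <- 1
    resid[, const] <- 0
  }
  x$values <- sweep(resid, 2, sdv, "/")
  x
}

#' PCA reduction by singular value decomposition
#'
#' Removes the row mean (per-time-point mean across voxels), takes the SVD
#' `X = U D V'` of the centered matrix, and projects onto the `M` leading
#' left singular vectors: `X_M = U_M' X`. Each singular vector's sign is
#' fixed so its largest-magnitude loading is positive, removing the SVD
#' sign ambiguity.
#'
#' @param x a [subject_matrix].
#' @param M number of components to retain, `M <= min(K, L)`.
#' @return an object of class `reduced_matrix` with fields `values`
#'   (M x L scores), `basis` (K x M orthonormal), `singular_values`,
#'   `var_retained` and the inherited `voxel_index`.
#' @export
pca_reduce <- function(x, M) {
  v <- x$values
  M <- as.integer(M)
  if (M < 1L || M > min(dim(v)))
    stop(sprintf("M = %d must lie in [1, min(K, L) = %d]", M, min(dim(v))),
         call. = FALSE)
  ctr <- v - rowMeans(v)
  sv <- svd(ctr, nu = M, nv = 0)
  U <- sv$u
  scores <- t(U) %*% ctr
  # Resolve the SVD sign ambiguity on the component's spatial map: the
  # largest-magnitude voxel value is made positive. Anchoring the sign
  # spatially keeps component polarity comparable across subjects, which
  # the later cross-subject matching of mode maps relies on.
  for (j in seq_len(M)) {
    i0 <- which.max(abs(scores[j, ]))
    if (scores[j, i0] < 0) {
      U[, j] <- -U[, j]
      scores[j, ] <- -scores[j, ]
    }
  }
  structure(list(values = scores,
                 basis = U,
                 singular_values = sv$d,
                 var_retained = sum(sv$d[seq_len(M)]^2) / sum(sv$d^2),
                 voxel_index = x$voxel_index),
            class = "reduced_matrix")
}

#' @export
print.reduced_matrix <- function(x, ...) {
  cat(sprintf("<reduced_matrix> %d components x %d voxels (%.1f%% variance retained)\n",
              nrow(x$values), ncol(x$values), 100 * x$var_retained))
  invisible(x)
}
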