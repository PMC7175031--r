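# Cross-subject matching of intrinsic modes and group reference averaging.

#' Correlation cost matrix between reference and subject modes
#'
#' Entry `(i, j)` is `1 - rho(R_i, V_j)`, the Pearson-correlation cost of
#' assigning subject mode `j` to reference row `i`; zero-variance rows
#' correlate 0 by convention, so entries lie in `[0, 2]`.
#'
#' @param ref reference rows: a `reference_set`, `vimf_matrix` or M x L
#'   matrix.
#' @param vimf subject rows of identical shape.
#' @param absolute if `TRUE`, use `1 - |rho|` so anticorrelated modes can
#'   match (polarity is re-aligned afterwards by the caller).
#' @return M x M numeric cost matrix.
#' @export
correlation_cost <- function(ref, vimf, absolute = FALSE) {
  a <- row_values(ref); b <- row_values(vimf)
  if (!all(dim(a) == dim(b)))
    stop_shape("reference and subject matrices must have identical shape")
  za <- standardize_rows(a, on_constant = "zero")
  zb <- standardize_rows(b, on_constant = "zero")
  rho <- tcrossprod(za, zb) / ncol(za)
  if (absolute) 1 - abs(rho) else 1 - rho
}

row_values <- function(x) {
  if (is.list(x) && !is.null(x$values)) as.matrix(x$values) else as.matrix(x)
}

#' Minimum-cost assignment (Hungarian / Munkres method)
#'
#' Solves the linear sum assignment problem with the Jonker-Volgenant
#' shortest-augmenting-path formulation of the Hungarian method, O(M^3);
#' ties are broken deterministically by the lowest-index augmenting path.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer permutation `perm` minimizing
#'   `sum(cost[cbind(seq_len(M), perm)])`; `perm[i]` is the column assigned
#'   to row `i`.
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square", call. = FALSE)
  if (!all(is.finite(cost))) stop("cost matrix must be finite", call. = FALSE)

  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)        # p[j + 1]: row assigned to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      idx <- free + 1L
      cur <- cost[i0, free] - u[i0 + 1L] - v[idx]
      better <- cur < minv[idx]
      if (any(better)) {
        minv[idx[better]] <- cur[better]
        way[idx[better]] <- j0
      }
      k <- which.min(minv[idx])
      delta <- minv[idx][k]
      j1 <- free[k]
      u[p[used] + 1L] <- u[p[used] + 1L] + delta
      v[used] <- v[used] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  perm <- integer(n)
  perm[p[-1L]] <- seq_len(n)
  perm
}

#' Build group reference maps from subject VIMF matrices
#'
#' Sequential scheme: the reference starts as subject 1's VIMF matrix; for
#' each further subject the rows are reordered by the minimum-cost
#' assignment against the current reference
#' (`1 - rho` cost, [hungarian_assign]) and merged by the incremental mean
#' `R <- ((s - 1) / s) R + (1 / s) V~`. Finally every reference row is
#' standardized to zero mean, unit variance.
#'
#' @param vimf_list list of `vimf_matrix` (or M x L matrices), one per
#'   subject, consistent in shape. Merge order is the input order.
#' @param absolute match on `|rho|` and re-align the sign of matched
#'   subject rows before merging; the default matches the signed
#'   correlation cost.
#' @return object of class `reference_set`: standardized `values` (M x L),
#'   the pre-standardization running mean `values_raw`, `n_subjects_merged`
#'   and the per-subject `assignment_log`.
#' @export
build_references <- function(vimf_list, absolute = FALSE) {
  if (length(vimf_list) < 1L) stop("need at least one subject", call. = FALSE)
  mats <- lapply(vimf_list, row_values)
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == dims), logical(1))))
    stop_shape("subject VIMF matrices differ in shape")

  R <- mats[[1]]
  log_ <- list(seq_len(dims[1]))
  if (length(mats) > 1L) {
    for (s in 2L:length(mats)) {
      cost <- correlation_cost(R, mats[[s]], absolute = absolute)
      perm <- hungarian_assign(cost)
      vt <- mats[[s]][perm, , drop = FALSE]
      if (absolute) {
        rho <- 1 - correlation_cost(R, vt)    # signed rho of matched rows
        sgn <- ifelse(diag(rho) < 0, -1, 1)
        vt <- vt * sgn
      }
      R <- ((s - 1) / s) * R + (1 / s) * vt
      log_[[s]] <- perm
    }
  }
  zvar <- sqrt(rowMeans((R - rowMeans(R))^2)) < 1e-300
  if (any(zvar))
    stop(sprintf("degenerate reference row(s) with zero variance: %s",
                 paste(which(zvar), collapse = ", ")), call. = FALSE)
  structure(list(values = standardize_rows(R),
                 values_raw = R,
                 n_subjects_merged = length(mats),
                 assignment_log = log_,
                 voxel_index = if (is.list(vimf_list[[1]]))
                   vimf_list[[1]]$voxel_index else NULL),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d references x %d voxels, merged from %d subject(s)\n",
              nrow(x$values), ncol(x$values), x$n_subjects_merged))
  invisible(x)
}
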