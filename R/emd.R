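# Bidimensional ensemble EMD with tension-spline envelopes (BEEMD):
# slice sifting, mode extraction and volumetric assembly.

#' EMD parameter set
#'
#' Defaults follow the standard configuration for slice-wise decomposition
#' of reduced fMRI component images: six modes (five BIMFs plus residuum),
#' five sifting passes per mode, assisting noise amplitude 0.2, one
#' antithetic noise pair (the ensemble consists of the `+noise` and
#' `-noise` realizations), and initial tension 0.9.
#'
#' @param n_modes total mode count J, residuum included.
#' @param n_sift sifting iterations per mode.
#' @param noise_amplitude assisting-noise amplitude relative to the slice
#'   standard deviation.
#' @param ensemble_pairs number of antithetic noise pairs.
#' @param t1 initial tension, in `[0, 1)`.
#' @param seed integer seed for the ensemble noise; `NULL` uses the current
#'   RNG state.
#' @param max_extrema cap on extrema per kind before envelope
#'   interpolation; larger sets are subsampled (seeded) to bound the
#'   cubic solve cost.
#' @return an object of class `emd_params`.
#' @export
emd_params <- function(n_modes = 6L, n_sift = 5L, noise_amplitude = 0.2,
                       ensemble_pairs = 1L, t1 = 0.9, seed = NULL,
                       max_extrema = 2000L) {
  stopifnot(n_modes >= 2L, n_sift >= 1L, noise_amplitude >= 0,
            ensemble_pairs >= 1L, t1 >= 0, t1 < 1, max_extrema >= 10L)
  structure(list(n_modes = as.integer(n_modes), n_sift = as.integer(n_sift),
                 noise_amplitude = noise_amplitude,
                 ensemble_pairs = as.integer(ensemble_pairs),
                 t1 = t1, seed = seed, max_extrema = as.integer(max_extrema)),
            class = "emd_params")
}

#' Tension schedule across modes
#'
#' The tension starts at `t1` for the first mode and is reduced by `1/J`
#' after each extracted BIMF: `T_{j+1} = T_j - 1/J`, clipped to `[0, 1)`.
#' With `t1 = 0.9` and `J = 6` this gives 0.9, 0.7333..., 0.5666..., 0.4,
#' 0.2333... for the five sifted modes.
#'
#' @param t1 initial tension.
#' @param j_max total mode count J (residuum included).
#' @return numeric vector of length `j_max - 1`, one tension per sifted mode.
#' @export
tension_schedule <- function(t1 = 0.9, j_max = 6L) {
  ts <- t1 - (seq_len(j_max - 1L) - 1L) / j_max
  pmin(pmax(ts, 0), 1 - 1e-12)
}

#' Local extrema of a 2D slice
#'
#' A pixel is a maximum iff it is strictly greater than all of its existing
#' 8-connected neighbours (boundary pixels are compared against their
#' available neighbours only); minima symmetrically. Plateaus -- 4-connected
#' components of two or more equal-valued pixels whose outside 8-neighbours
#' are all strictly lower (higher) -- contribute their centroid-nearest
#' pixel once. A constant slice has no extrema.
#'
#' @param slice numeric matrix, at least 3 x 3.
#' @return list with `maxima` and `minima`, each an n x 3 matrix of
#'   `(x, y, value)` rows.
#' @export
find_local_extrema <- function(slice) {
  v <- as.matrix(slice)
  if (nrow(v) < 3L || ncol(v) < 3L)
    stop("slice must be at least 3 x 3", call. = FALSE)
  mx <- extrema_one_sign(v)
  mn <- extrema_one_sign(-v)
  list(maxima = cbind(mx[, 1:2, drop = FALSE], value = v[mx[, 1:2, drop = FALSE]]),
       minima = cbind(mn[, 1:2, drop = FALSE], value = v[mn[, 1:2, drop = FALSE]]))
}

# Maxima of v (call with -v for minima). Returns matrix with columns x, y.
extrema_one_sign <- function(v) {
  nx <- nrow(v); ny <- ncol(v)
  nb_max <- matrix(-Inf, nx, ny)     # max over existing 8-neighbours
  eq_any <- matrix(FALSE, nx, ny)    # any neighbour equal
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sx <- seq.int(max(1, 1 + dx), min(nx, nx + dx))
    sy <- seq.int(max(1, 1 + dy), min(ny, ny + dy))
    nb <- v[sx, sy, drop = FALSE]
    tx <- sx - dx; ty <- sy - dy
    cur <- nb_max[tx, ty, drop = FALSE]
    nb_max[tx, ty] <- pmax(cur, nb)
    eq_any[tx, ty] <- eq_any[tx, ty, drop = FALSE] | (nb == v[tx, ty, drop = FALSE])
  }
  strict <- v > nb_max
  out <- which(strict, arr.ind = TRUE)
  # Plateau handling is only needed where a pixel ties its neighbourhood
  # maximum through an equal neighbour; generic continuous data never
  # reaches this branch.
  cand <- which(eq_any & v >= nb_max & is.finite(nb_max))
  if (length(cand)) {
    reps <- plateau_representatives(v, cand)
    if (length(reps))
      out <- rbind(out, which(array(seq_along(v) %in% reps, dim(v)),
                              arr.ind = TRUE))
  }
  colnames(out) <- c("x", "y")
  out[order(out[, 2], out[, 1]), , drop = FALSE]
}

# BFS over 4-connected equal-valued components seeded at candidate pixels;
# a component counts as a plateau extremum iff every outside 8-neighbour is
# strictly lower. Returns linear indices of centroid-nearest representatives.
plateau_representatives <- function(v, cand) {
  nx <- nrow(v); ny <- ncol(v)
  visited <- logical(length(v))
  reps <- integer(0)
  for (start in cand) {
    if (visited[start]) next
    val <- v[start]
    comp <- integer(0); queue <- start; visited[start] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        px <- cx + d[1]; py <- cy + d[2]
        if (px < 1L || px > nx || py < 1L || py > ny) next
        idx <- (py - 1L) * nx + px
        if (!visited[idx] && v[idx] == val) {
          visited[idx] <- TRUE
          queue <- c(queue, idx)
        }
      }
    }
    if (length(comp) < 2L) next      # singletons are covered by the strict rule
    ok <- TRUE; has_outside <- FALSE
    inset <- logical(length(v)); inset[comp] <- TRUE
    for (cur in comp) {
      cx <- (cur - 1L) %% nx + 1L; cy <- (cur - 1L) %/% nx + 1L
      for (dx in -1:1) for (dy in -1:1) {
        if (dx == 0 && dy == 0) next
        px <- cx + dx; py <- cy + dy
        if (px < 1L || px > nx || py < 1L || py > ny) next
        idx <- (py - 1L) * nx + px
        if (inset[idx]) next
        has_outside <- TRUE
        if (v[idx] >= val) ok <- FALSE
      }
      if (!ok) break
    }
    if (ok && has_outside) {
      cxs <- (comp - 1L) %% nx + 1L; cys <- (comp - 1L) %/% nx + 1L
      d2 <- (cxs - mean(cxs))^2 + (cys - mean(cys))^2
      reps <- c(reps, comp[order(d2, comp)[1]])
    }
  }
  reps
}

# Sentinel returned when a slice has too few extrema to continue sifting.
exhausted_sentinel <- function() structure(list(), class = "emd_exhausted")

#' @keywords internal
is_exhausted <- function(x) inherits(x, "emd_exhausted")

#' Mean extrema envelope of a slice
#'
#' Interpolates the maxima into an upper envelope and the minima into a
#' lower envelope with [greens_tension_interpolate], after augmenting each
#' extrema set with the four slice corners valued by their nearest
#' extremum (bounding envelope blow-up at the edges), and returns the
#' pointwise average. With fewer than 3 maxima or minima (or a degenerate
#' collinear geometry) the sifting signal is exhausted and a sentinel is
#' returned telling the caller to treat the remaining slice as residuum.
#'
#' @param slice numeric matrix.
#' @param tension envelope tension in `[0, 1)`.
#' @param max_extrema cap per extrema kind; larger sets are subsampled.
#' @return matrix of the mean envelope, or an exhaustion sentinel
#'   (test with `is_exhausted()`).
#' @export
mean_envelope <- function(slice, tension, max_extrema = 2000L) {
  v <- as.matrix(slice)
  ex <- find_local_extrema(v)
  if (nrow(ex$maxima) < 3L || nrow(ex$minima) < 3L)
    return(exhausted_sentinel())
  up <- envelope_surface(v, ex$maxima, tension, max_extrema)
  lo <- envelope_surface(v, ex$minima, tension, max_extrema)
  if (is_exhausted(up) || is_exhausted(lo)) return(exhausted_sentinel())
  (up + lo) / 2
}

envelope_surface <- function(v, extrema, tension, max_extrema) {
  pts <- extrema[, 1:2, drop = FALSE]
  val <- extrema[, 3]
  if (nrow(pts) > max_extrema) {
    keep <- sort(sample.int(nrow(pts), max_extrema))
    pts <- pts[keep, , drop = FALSE]
    val <- val[keep]
  }
  corners <- cbind(c(1, 1, nrow(v), nrow(v)), c(1, ncol(v), 1, ncol(v)))
  have <- paste(pts[, 1], pts[, 2])
  for (i in 1:4) {
    if (paste(corners[i, 1], corners[i, 2]) %in% have) next
    d2 <- (pts[, 1] - corners[i, 1])^2 + (pts[, 2] - corners[i, 2])^2
    pts <- rbind(pts, corners[i, ])
    val <- c(val, val[which.min(d2)])
  }
  tryCatch(
    greens_tension_interpolate(pts, val, tension, dim(v)),
    cicaemd_degenerate_geometry = function(e) exhausted_sentinel())
}

#' Extract one intrinsic mode by sifting
#'
#' Iterates `h_k = h_{k-1} - mean_envelope(h_{k-1})` for `n_sift` passes;
#' the final `h` is the mode and `slice - h` the residual, so mode plus
#' residual reproduce the input exactly. If the extrema are exhausted at
#' any pass the mode is zero and the full slice is returned as residual,
#' with the `exhausted` flag set.
#'
#' @param slice numeric matrix.
#' @param tension envelope tension for this mode.
#' @param n_sift number of sifting passes.
#' @param max_extrema see [mean_envelope].
#' @return list with `bimf`, `residual` and `exhausted`.
#' @export
sift_mode <- function(slice, tension, n_sift, max_extrema = 2000L) {
  v <- as.matrix(slice)
  h <- v
  for (k in seq_len(n_sift)) {
    env <- mean_envelope(h, tension, max_extrema)
    if (is_exhausted(env)) {
      return(list(bimf = array(0, dim(v)), residual = v, exhausted = TRUE))
    }
    h <- h - env
  }
  list(bimf = h, residual = v - h, exhausted = FALSE)
}

#' Ensemble decomposition of a slice into BIMFs
#'
#' For each antithetic pair, white Gaussian noise with standard deviation
#' `noise_amplitude * sd(slice)` is added to and subtracted from the slice;
#' each realization is decomposed independently (`J - 1` sifted modes under
#' the [tension_schedule], the final residual being mode `J`), and
#' corresponding modes are averaged across realizations. The paired noise
#' cancels in the average, so the modes sum to the input slice exactly.
#' Modes are ordered by decreasing dominant spatial frequency, `b_1`
#' highest; a degenerate (constant or too small) slice is returned whole as
#' the residuum.
#'
#' @param slice numeric matrix, at least 4 x 4 for a meaningful
#'   decomposition.
#' @param params an [emd_params].
#' @return object of class `bimf_stack`: list `modes` of J matrices plus
#'   `source_shape`.
#' @export
decompose_slice <- function(slice, params = emd_params()) {
  v <- as.matrix(slice)
  J <- params$n_modes
  zero_stack <- function() {
    modes <- rep(list(array(0, dim(v))), J)
    modes[[J]] <- v
    structure(list(modes = modes, source_shape = dim(v)), class = "bimf_stack")
  }
  if (nrow(v) < 4L || ncol(v) < 4L) return(zero_stack())
  s0 <- sd(as.vector(v))
  if (!is.finite(s0) || s0 < 1e-300) return(zero_stack())

  ts <- tension_schedule(params$t1, J)
  noise_sd <- params$noise_amplitude * s0
  acc <- rep(list(array(0, dim(v))), J)
  n_real <- 0L

  run_one <- function(input) {
    modes <- vector("list", J)
    rem <- input
    for (j in seq_len(J - 1L)) {
      res <- sift_mode(rem, ts[j], params$n_sift, params$max_extrema)
      modes[[j]] <- res$bimf
      rem <- res$residual
      if (res$exhausted) {
        for (jj in seq.int(j, J - 1L)) modes[[jj]] <- array(0, dim(v))
        break
      }
    }
    modes[[J]] <- rem
    modes
  }

  with_seed(params$seed, {
    for (pair in seq_len(params$ensemble_pairs)) {
      eta <- if (noise_sd > 0) array(rnorm(length(v), sd = noise_sd), dim(v))
             else array(0, dim(v))
      for (signed in list(v + eta, v - eta)) {
        modes <- run_one(signed)
        for (j in seq_len(J)) acc[[j]] <- acc[[j]] + modes[[j]]
        n_real <- n_real + 1L
      }
    }
  })
  structure(list(modes = lapply(acc, function(m) m / n_real),
                 source_shape = dim(v)),
            class = "bimf_stack")
}

#' @export
print.bimf_stack <- function(x, ...) {
  cat(sprintf("<bimf_stack> %d modes on a %s slice\n", length(x$modes),
              paste(x$source_shape, collapse = " x ")))
  invisible(x)
}

#' Slice-wise EMD of a 3D volume
#'
#' Decomposes every transverse (axial, third-axis) slice of the volume on
#' its full rectangular grid, sums the modes named in `combine` (the
#' customary reference combination is modes 5 and 6, the lowest-frequency
#' BIMF plus the residuum), restacks the slices and applies the mask
#' afterwards, zeroing out-of-mask voxels. All-zero slices are skipped and
#' returned as zero.
#'
#' @param volume 3D array on the mask grid.
#' @param mask a [brain_mask].
#' @param params an [emd_params]; its `seed` spawns one independent noise
#'   substream per slice.
#' @param combine integer set of mode indices to sum, subset of `1..J`.
#' @return 3D array of the combined, masked modes.
#' @export
decompose_volume <- function(volume, mask, params = emd_params(),
                             combine = c(5L, 6L)) {
  if (!identical(dim(volume), dim(mask$mask)))
    stop_shape("volume grid does not match mask grid")
  combine <- as.integer(combine)
  if (length(combine) < 1L || any(combine < 1L | combine > params$n_modes))
    stop(sprintf("`combine` must be a non-empty subset of 1..%d",
                 params$n_modes), call. = FALSE)
  out <- array(0, dim(volume))
  for (z in seq_len(dim(volume)[3])) {
    sl <- volume[, , z]
    if (all(sl == 0)) next
    sp <- params
    if (!is.null(params$seed)) sp$seed <- child_seed(params$seed, z)
    stack <- decompose_slice(sl, sp)
    out[, , z] <- Reduce(`+`, stack$modes[combine])
  }
  out[!mask$mask] <- 0
  out
}

#' Stack in-mask voxels of component images into a VIMF matrix
#'
#' @param images list of M 3D arrays on the mask grid (volume intrinsic
#'   mode functions).
#' @param mask a [brain_mask] defining the shared column order.
#' @return M x L matrix of class `vimf_matrix` carrying the mask's
#'   `voxel_index`.
#' @export
volumes_to_vimf_matrix <- function(images, mask) {
  sel <- mask$mask
  rows <- lapply(images, function(img) {
    if (!identical(dim(img), dim(sel)))
      stop_shape("image grid does not match mask grid")
    img[sel]
  })
  structure(list(values = do.call(rbind, rows), voxel_index = mask$voxel_index),
            class = "vimf_matrix")
}
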