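# Synthetic multi-subject fMRI data and multi-scale test images with known
# ground truth; every pipeline stage is testable without any download.

#' Ellipsoidal brain mask for synthetic grids
#'
#' @param grid `c(nx, ny, nz)` grid dimensions.
#' @param scale semi-axes as a fraction of the half-dimensions.
#' @return a [brain_mask].
#' @export
ellipsoid_mask <- function(grid, scale = 0.85) {
  ctr <- (grid + 1) / 2
  ax <- pmax(scale * (grid - 1) / 2, 0.5)
  x <- (seq_len(grid[1]) - ctr[1]) / ax[1]
  y <- (seq_len(grid[2]) - ctr[2]) / ax[2]
  z <- (seq_len(grid[3]) - ctr[3]) / ax[3]
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  brain_mask(r2 <= 1)
}

# Flat-top ("plateau") blob profile exp(-(d^2 / 2 sigma^2)^2): a
# quasi-binary parcel with a smooth rim. Unlike a Gaussian profile, the
# plateau shape survives voxel-wise temporal variance normalization
# (which compresses graded amplitudes toward a saturated core) nearly
# unchanged, so planted maps remain comparable to extracted maps on the
# scale the pipeline works in.
blob_map <- function(grid, centers, sigmas, amps) {
  out <- array(0, grid)
  xs <- seq_len(grid[1]); ys <- seq_len(grid[2]); zs <- seq_len(grid[3])
  for (b in seq_len(nrow(centers))) {
    d2 <- outer(outer((xs - centers[b, 1])^2, (ys - centers[b, 2])^2, "+"),
                (zs - centers[b, 3])^2, "+")
    out <- out + amps[b] * exp(-0.5 * (d2 / sigmas[b]^2)^2)
  }
  out
}

standardize_in_mask <- function(vol, mask) {
  v <- vol[mask$mask]
  s <- sqrt(mean((v - mean(v))^2))
  if (s < 1e-300) stop("degenerate source map", call. = FALSE)
  out <- array(0, dim(vol))
  out[mask$mask] <- (v - mean(v)) / s
  out
}

#' Generate sparse super-Gaussian spatial source maps
#'
#' Each source is a sum of a few flat-top blobs (quasi-binary parcels with
#' smooth rims) at seeded random in-mask locations, standardized over the
#' mask support (out-of-mask voxels are zero). Sources are redrawn until
#' all pairwise in-mask correlations stay below `max_corr`, mimicking
#' spatially segregated resting-state networks: sparse positive parcels
#' make the map distributions heavy-tailed (super-Gaussian), the regime
#' the extended-Infomax score expects.
#'
#' Networks are drawn with graded spatial extent (an `extent_ramp` scaling
#' the blob widths from the first source, the broadest, to the last, the
#' most compact): networks of distinct extent carry distinct in-mask
#' energy after voxel-wise variance normalization, which is what makes
#' their variance ordering -- and hence their principal-component
#' ordering -- identifiable, as it is for real resting-state networks of
#' different sizes.
#'
#' @param grid `c(nx, ny, nz)`.
#' @param n_sources number of source maps.
#' @param blob_count_range inclusive range of blobs per source.
#' @param blob_sigma_range base range of blob standard deviations (voxels).
#' @param extent_ramp multiplicative blob-width scale of the first and last
#'   source; intermediate sources are interpolated.
#' @param seed integer seed.
#' @param max_corr pairwise correlation bound.
#' @param max_retries redraw budget per source.
#' @return list of class `spatial_sources`: standardized 3D `maps`, the
#'   generating `blobs` (centers/sigmas/amplitudes), the `mask` and the
#'   in-mask source matrix `values` (n_sources x L).
#' @export
generate_spatial_sources <- function(grid, n_sources,
                                     blob_count_range = c(2L, 3L),
                                     blob_sigma_range = c(2.0, 2.4),
                                     extent_ramp = c(1.3, 0.85),
                                     seed = 1L, max_corr = 0.15,
                                     max_retries = 300L) {
  mask <- ellipsoid_mask(grid)
  idx <- mask$voxel_index
  scale_m <- if (n_sources == 1L) mean(extent_ramp) else
    seq(extent_ramp[1], extent_ramp[2], length.out = n_sources)
  with_seed(seed, {
    maps <- vector("list", n_sources)
    blobs <- vector("list", n_sources)
    vals <- matrix(NA_real_, n_sources, mask$L)
    for (m in seq_len(n_sources)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        nb <- sample(seq.int(blob_count_range[1], blob_count_range[2]), 1)
        ctr <- idx[sample.int(nrow(idx), nb), , drop = FALSE]
        sig <- runif(nb, blob_sigma_range[1], blob_sigma_range[2]) * scale_m[m]
        amp <- runif(nb, 0.7, 1.3)
        vol <- standardize_in_mask(blob_map(grid, ctr, sig, amp), mask)
        v <- vol[mask$mask]
        if (m == 1L ||
            all(abs(vals[seq_len(m - 1L), , drop = FALSE] %*% v / mask$L)
                < max_corr)) {
          maps[[m]] <- vol
          blobs[[m]] <- list(centers = ctr, sigmas = sig, amps = amp)
          vals[m, ] <- v
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not draw sufficiently uncorrelated sources; use a larger grid",
             call. = FALSE)
    }
    structure(list(maps = maps, blobs = blobs, mask = mask, values = vals,
                   grid = grid, seed = seed),
              class = "spatial_sources")
  })
}

# Laplace (double-exponential) draws with unit standard deviation.
rlaplace_unit <- function(n) (rexp(n) - rexp(n)) / sqrt(2)

#' Generate a synthetic multi-subject resting-state dataset
#'
#' Emulates a cohort sharing a set of spatial networks: per subject, every
#' group source is displaced by a seeded Gaussian spatial jitter (modelling
#' residual anatomical variability after registration), mixed over K time
#' points by heavy-tailed (Laplace) time courses with per-source scales,
#' and buried in additive Gaussian noise on top of a constant in-brain
#' baseline intensity (so intensity-based masking behaves as on real
#' scans).
#'
#' @param grid `c(nx, ny, nz)` spatial grid.
#' @param n_subjects cohort size S.
#' @param n_timepoints time points K per subject.
#' @param n_sources number of planted networks.
#' @param jitter_sigma spatial displacement scale in voxels.
#' @param noise_sigma additive noise standard deviation.
#' @param mixing_scales per-source time-course standard deviations;
#'   defaults to a decreasing ramp so the networks carry distinct
#'   variances, as resting-state networks do.
#' @param baseline in-brain baseline intensity.
#' @param tr_seconds repetition time attached to the series.
#' @param seed integer seed; the dataset is a pure function of
#'   (parameters, seed).
#' @return list with `subjects` (list of [volume_series]) and `truth`
#'   (group `sources`, per-subject jittered `subject_sources` as
#'   n_sources x L matrices, `mixing` matrices, the `mask` and all
#'   parameters).
#' @export
generate_group_dataset <- function(grid = c(32L, 32L, 8L), n_subjects = 10L,
                                   n_timepoints = 120L, n_sources = 5L,
                                   jitter_sigma = 0.5, noise_sigma = 1,
                                   mixing_scales = NULL, baseline = 100,
                                   tr_seconds = 0.72, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_timepoints >= 2L, n_sources >= 1L,
            jitter_sigma >= 0, noise_sigma >= 0)
  if (is.null(mixing_scales))
    mixing_scales <- 4 * seq(1, 0.5, length.out = n_sources)
  src <- generate_spatial_sources(grid, n_sources, seed = child_seed(seed, 1))
  mask <- src$mask
  affine <- diag(c(2, 2, 2, 1))   # 2 mm isotropic voxels
  nvox <- prod(grid)
  base_vol <- baseline * as.numeric(mask$mask)

  subjects <- vector("list", n_subjects)
  subject_sources <- vector("list", n_subjects)
  mixing <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    with_seed(child_seed(seed, 2, s), {
      smaps <- matrix(NA_real_, n_sources, mask$L)
      full <- matrix(NA_real_, n_sources, nvox)
      for (m in seq_len(n_sources)) {
        shift <- rnorm(3, sd = jitter_sigma)
        b <- src$blobs[[m]]
        ctr <- sweep(b$centers, 2, shift, "+")
        vol <- standardize_in_mask(blob_map(grid, ctr, b$sigmas, b$amps), mask)
        smaps[m, ] <- vol[mask$mask]
        full[m, ] <- as.vector(vol)
      }
      A <- matrix(rlaplace_unit(n_timepoints * n_sources),
                  n_timepoints, n_sources)
      A <- sweep(A, 2, mixing_scales, "*")
      X <- A %*% full
      X <- sweep(X, 2, base_vol, "+")
      X <- X + matrix(rnorm(length(X), sd = noise_sigma),
                      n_timepoints, nvox)
      subjects[[s]] <- volume_series(array(t(X), c(grid, n_timepoints)),
                                     affine = affine,
                                     tr_seconds = tr_seconds)
      subject_sources[[s]] <- smaps
      mixing[[s]] <- A
    })
  }
  list(subjects = subjects,
       truth = list(sources = src$values, source_maps = src$maps,
                    subject_sources = subject_sources, mixing = mixing,
                    mask = mask,
                    params = list(grid = grid, n_subjects = n_subjects,
                                  n_timepoints = n_timepoints,
                                  n_sources = n_sources,
                                  jitter_sigma = jitter_sigma,
                                  noise_sigma = noise_sigma,
                                  mixing_scales = mixing_scales,
                                  baseline = baseline, seed = seed)))
}

#' Multi-band test image for frequency-ordering checks
#'
#' A sum of 2D sinusoids at the listed spatial frequencies (cycles per
#' image width) plus a smooth linear ramp. Each band is a superposition of
#' `waves_per_band` unit sinusoids at seeded random orientations and
#' phases, giving it ring-shaped spectral support; the default band list
#' is a dense geometric comb spanning the scales an image decomposition
#' separates, so every extracted mode is genuinely populated. The
#' per-band components are retained so spectral ordering of extracted
#' modes can be verified band by band.
#'
#' @param grid `c(nx, ny)` image dimensions.
#' @param bands frequencies in cycles per image width, at least 2.
#' @param seed integer seed.
#' @param waves_per_band sinusoids per band.
#' @return matrix of class `multiscale_image` with attributes `components`
#'   (list of per-band matrices) and `ramp`.
#' @export
multiscale_test_image <- function(grid = c(64L, 64L),
                                  bands = 28 * (1 / 1.35)^(0:11), seed = 1L,
                                  waves_per_band = 12L) {
  if (length(bands) < 2L) stop("need at least 2 bands", call. = FALSE)
  nx <- grid[1]; ny <- grid[2]
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  with_seed(seed, {
    comps <- lapply(bands, function(f) {
      acc <- 0
      for (k in seq_len(waves_per_band)) {
        th <- runif(1, 0, 2 * pi)
        ph <- runif(1, 0, 2 * pi)
        acc <- acc + sin(2 * pi * f * (cos(th) * xs + sin(th) * ys) / nx + ph)
      }
      acc / sqrt(waves_per_band)
    })
    dir <- runif(2, -1, 1)
    ramp <- (dir[1] * xs / nx + dir[2] * ys / ny)
  })
  img <- Reduce(`+`, comps) + ramp
  structure(img, class = c("multiscale_image", class(img)),
            components = comps, ramp = ramp, bands = bands)
}

#' Radial spectral centroid of a 2D image
#'
#' The power-weighted mean radial spatial frequency of the discrete
#' Fourier transform (DC term excluded), in cycles per image width on the
#' first axis; used to verify that extracted modes are ordered from high
#' to low spatial frequency. Power (squared magnitude) weighting keeps the
#' centroid anchored to a mode's dominant band rather than to broadband
#' leakage tails.
#'
#' @param img numeric matrix.
#' @return scalar centroid frequency, or `NA` for an (almost) empty image.
#' @export
spectral_centroid <- function(img) {
  img <- unclass(as.matrix(img))
  nx <- nrow(img); ny <- ncol(img)
  F <- stats::fft(img)
  fx <- c(seq.int(0, floor(nx / 2)), seq.int(-ceiling(nx / 2) + 1, -1)) / nx
  fy <- c(seq.int(0, floor(ny / 2)), seq.int(-ceiling(ny / 2) + 1, -1)) / ny
  rad <- sqrt(outer(fx^2, fy^2, "+")) * nx   # cycles per image width (x)
  w <- Mod(F)^2
  w[1, 1] <- 0
  tot <- sum(w)
  if (tot < 1e-12) return(NA_real_)
  sum(w * rad) / tot
}

#' Measure recovery of planted sources from a pipeline result
#'
#' For every subject and threshold, matches the extracted components to
#' that subject's jittered ground-truth maps by minimum-cost assignment on
#' `1 - |rho|` and reports the matched absolute correlations together with
#' the per-component constraint similarities.
#'
#' @param result a `pipeline_result`.
#' @param truth the `truth` element of [generate_group_dataset].
#' @return list per threshold with `rho` (subjects x components matched
#'   absolute correlations), `similarity` (subjects x components),
#'   `converged` (logical per subject).
#' @export
source_recovery <- function(result, truth) {
  mask <- result$mask
  tm <- lapply(truth$subject_sources, function(sm) {
    vols <- rows_to_volumes(sm, truth$mask)
    do.call(rbind, lapply(vols, function(v) v[mask$mask]))
  })
  out <- lapply(result$ica, function(per_thr) {
    S <- length(per_thr)
    M <- nrow(per_thr[[1]]$Y)
    rho <- matrix(NA_real_, S, M)
    sims <- matrix(NA_real_, S, M)
    conv <- logical(S)
    for (s in seq_len(S)) {
      C <- abs(stats::cor(t(per_thr[[s]]$Y), t(tm[[s]])))
      perm <- hungarian_assign(1 - C)
      rho[s, ] <- C[cbind(seq_len(M), perm)]
      sims[s, ] <- per_thr[[s]]$similarity
      conv[s] <- per_thr[[s]]$converged
    }
    list(rho = rho, similarity = sims, converged = conv)
  })
  out
}
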