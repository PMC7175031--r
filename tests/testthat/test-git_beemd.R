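test_that("tension schedule descends by 1/J from the initial value", {
  ts <- tension_schedule(0.9, 6)
  expect_equal(ts, c(0.9, 0.9 - 1/6, 0.9 - 2/6, 0.4, 0.9 - 4/6),
               tolerance = 1e-12)
  expect_true(all(ts >= 0 & ts < 1))
  # clipping at zero for long schedules
  expect_true(all(tension_schedule(0.2, 8) >= 0))
})

test_that("local extrema match an exhaustive scan on continuous slices", {
  # constant slice: no strict extremum exists
  ex <- find_local_extrema(matrix(1, 5, 5))
  expect_equal(nrow(ex$maxima), 0)
  expect_equal(nrow(ex$minima), 0)
  # single interior peak
  v <- matrix(1, 3, 3); v[2, 2] <- 5
  ex <- find_local_extrema(v)
  expect_equal(unname(ex$maxima[, 1:2, drop = FALSE]), matrix(c(2, 2), 1))
  expect_equal(ex$maxima[1, 3], 5, ignore_attr = TRUE)
  # random continuous slices against the brute-force oracle
  set.seed(31)
  for (rep in 1:5) {
    v <- matrix(rnorm(81), 9, 9)
    got <- find_local_extrema(v)
    ref <- extrema_oracle(v)
    expect_equal(unname(got$maxima[, 1:2, drop = FALSE]),
                 unname(ref$maxima[order(ref$maxima[, 2], ref$maxima[, 1]), ,
                                   drop = FALSE]))
    expect_equal(unname(got$minima[, 1:2, drop = FALSE]),
                 unname(ref$minima[order(ref$minima[, 2], ref$minima[, 1]), ,
                                   drop = FALSE]))
  }
})

test_that("plateaus contribute one centroid-nearest representative", {
  v <- matrix(0, 7, 7)
  v[3:4, 3:5] <- 2          # 2x3 flat top above its surroundings
  ex <- find_local_extrema(v)
  expect_equal(nrow(ex$maxima), 1)
  expect_true(ex$maxima[1, 1] %in% 3:4 && ex$maxima[1, 2] %in% 3:5)
})

test_that("mean envelope averages interpolated extrema envelopes", {
  # symmetric egg carton: envelopes cancel in the interior
  n <- 24
  xs <- matrix(seq_len(n), n, n); ys <- t(xs)
  egg <- sin(2 * pi * 4 * xs / n) * sin(2 * pi * 4 * ys / n)
  env <- mean_envelope(egg, 0.5)
  expect_false(is_exhausted(env))
  interior <- env[5:(n - 4), 5:(n - 4)]
  expect_lt(mean(abs(interior)), 0.1)
  # too few extrema signals exhaustion
  flat <- outer(seq_len(6), seq_len(6), function(a, b) a + 2 * b)
  expect_true(is_exhausted(mean_envelope(flat, 0.5)))
})

test_that("sifting splits a slice into mode plus exact residual", {
  set.seed(32)
  v <- matrix(rnorm(20 * 20), 20, 20)
  res <- sift_mode(v, 0.9, 5)
  expect_false(res$exhausted)
  expect_equal(res$bimf + res$residual, v, tolerance = 1e-12)
  # a pure plane has no oscillatory content
  plane <- outer(seq_len(10), seq_len(10), function(a, b) 0.5 * a - b)
  resp <- sift_mode(plane, 0.9, 5)
  expect_true(resp$exhausted)
  expect_equal(resp$bimf, array(0, c(10, 10)))
  expect_equal(resp$residual, plane)
})

test_that("sifted mode tracks the fast scale of a two-scale image", {
  n <- 48
  xs <- matrix(seq_len(n), n, n)
  fast <- sin(2 * pi * 10 * xs / n)
  ramp <- 3 * xs / n
  res <- sift_mode(fast + ramp, 0.9, 5)
  interior <- 9:(n - 8)
  expect_gt(cor(as.vector(res$bimf[interior, interior]),
                as.vector(fast[interior, interior])), 0.9)
})

test_that("ensemble decomposition reconstructs the slice exactly", {
  set.seed(33)
  v <- matrix(rnorm(32 * 32), 32, 32)
  st <- decompose_slice(v, emd_params(seed = 5))
  expect_length(st$modes, 6)
  expect_lt(max(abs(Reduce(`+`, st$modes) - v)), 1e-6)
  # identical seed gives a bit-identical stack
  st2 <- decompose_slice(v, emd_params(seed = 5))
  expect_identical(st, st2)
  # degenerate input goes wholly to the residuum
  zv <- matrix(0, 8, 8)
  stz <- decompose_slice(zv, emd_params(seed = 1))
  expect_equal(stz$modes[[6]], zv)
})

test_that("mode spectral centroids decrease on a multiband fixture", {
  img <- multiscale_test_image(seed = 5)
  st <- decompose_slice(unclass(img), emd_params(seed = 6))
  cen <- sapply(st$modes[1:5], spectral_centroid)
  expect_true(all(diff(cen) < 0))
})

test_that("volume decomposition combines modes linearly and masks afterwards", {
  grid <- c(16, 16, 3)
  mask <- ellipsoid_mask(grid)
  set.seed(34)
  vol <- array(rnorm(prod(grid)), grid)
  p <- emd_params(seed = 9)
  full <- decompose_volume(vol, mask, p, combine = 1:6)
  masked <- vol; masked[!mask$mask] <- 0
  expect_lt(max(abs(full - masked)), 1e-6)
  b5 <- decompose_volume(vol, mask, p, combine = 5)
  b6 <- decompose_volume(vol, mask, p, combine = 6)
  b56 <- decompose_volume(vol, mask, p, combine = c(5, 6))
  expect_equal(b56, b5 + b6, tolerance = 1e-10)
  expect_error(decompose_volume(vol, mask, p, combine = 7), "subset")
  # empty slice returned as zero
  vol2 <- vol; vol2[, , 2] <- 0
  out2 <- decompose_volume(vol2, mask, p, combine = c(5, 6))
  expect_true(all(out2[, , 2] == 0))
})
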