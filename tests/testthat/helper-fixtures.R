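# Shared fixtures and small oracles used across test files.

# Tiny 4D series: deterministic ramp + seeded noise on a boxy "brain".
make_tiny_series <- function(K = 12, grid = c(8, 8, 4), seed = 1,
                             baseline = 50) {
  set.seed(seed)
  brain <- array(FALSE, grid)
  brain[3:6, 3:6, 2:3] <- TRUE
  data <- array(rnorm(prod(grid) * K, sd = 0.5), c(grid, K))
  for (t in seq_len(K)) data[, , , t] <- data[, , , t] + baseline * brain
  volume_series(data, affine = diag(c(2, 2, 2, 1)), tr_seconds = 0.72)
}

# Independent dense biharmonic spline (naive loops, own solver) used as the
# oracle for the tension-0 Green's-function surface.
biharmonic_oracle <- function(points, values, grid_shape) {
  n <- nrow(points)
  g <- function(r) ifelse(r <= 0, 0, r^2 * (log(r) - 1))
  A <- matrix(0, n + 3, n + 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- g(sqrt(sum((points[i, ] - points[j, ])^2)))
    }
    A[i, n + 1] <- A[n + 1, i] <- 1
    A[i, n + 2] <- A[n + 2, i] <- points[i, 1]
    A[i, n + 3] <- A[n + 3, i] <- points[i, 2]
  }
  sol <- solve(A, c(values, 0, 0, 0))
  out <- matrix(0, grid_shape[1], grid_shape[2])
  for (gx in seq_len(grid_shape[1])) {
    for (gy in seq_len(grid_shape[2])) {
      s <- sol[n + 1] + sol[n + 2] * gx + sol[n + 3] * gy
      for (k in seq_len(n)) {
        s <- s + sol[k] * g(sqrt((gx - points[k, 1])^2 + (gy - points[k, 2])^2))
      }
      out[gx, gy] <- s
    }
  }
  out
}

# Brute-force 8-neighbourhood extrema scan (strict rule), the oracle for
# find_local_extrema on continuous-valued slices.
extrema_oracle <- function(v) {
  nx <- nrow(v); ny <- ncol(v)
  mx <- NULL; mn <- NULL
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (i + di >= 1 && i + di <= nx && j + dj >= 1 && j + dj <= ny)
        nb <- c(nb, v[i + di, j + dj])
    }
    if (all(v[i, j] > nb)) mx <- rbind(mx, c(i, j))
    if (all(v[i, j] < nb)) mn <- rbind(mn, c(i, j))
  }
  list(maxima = mx, minima = mn)
}

# Exhaustive minimum-cost assignment by permutation enumeration.
brute_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    tot <- sum(cost[cbind(seq_len(n), perms[i, ])])
    if (tot < best) best <- tot
  }
  best
}

# Minimal permutation enumerator (avoids external dependencies).
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# The synthetic benchmark pipeline is expensive; compute it once and share
# across test files (acceptance checks 7 and 8 and the consistency
# property all use it).
.fixture_cache <- new.env(parent = emptyenv())

benchmark_fixture <- function() {
  if (!is.null(.fixture_cache$benchmark)) return(.fixture_cache$benchmark)
  ds <- generate_group_dataset(seed = 1)
  res <- run_pipeline(ds$subjects, config = synthetic_study_config(seed = 11))
  rec <- source_recovery(res, ds$truth)
  .fixture_cache$benchmark <- list(ds = ds, res = res, rec = rec)
  .fixture_cache$benchmark
}

clone_fixture <- function() {
  if (!is.null(.fixture_cache$clones)) return(.fixture_cache$clones)
  ds <- generate_group_dataset(seed = 2, n_subjects = 1)
  clones <- rep(ds$subjects[1], 4)
  res <- run_pipeline(clones,
                      config = synthetic_study_config(seed = 7,
                                                      thresholds = 0.5))
  .fixture_cache$clones <- res
  .fixture_cache$clones
}
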