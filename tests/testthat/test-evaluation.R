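make_maps <- function(mats) group_maps(mats)

test_that("mean network is the subject average", {
  set.seed(81)
  mats <- lapply(1:4, function(s) matrix(rnorm(2 * 30), 2, 30))
  gm <- make_maps(mats)
  # explicit summation oracle on the standardized maps
  ref <- Reduce(`+`, lapply(1:4, function(s) gm$maps[s, 1, ])) / 4
  expect_equal(mean_network(gm, 1), ref, tolerance = 1e-12)
  # identical subjects: mean equals the common map
  gm2 <- make_maps(rep(mats[1], 3))
  expect_equal(mean_network(gm2, 2), gm2$maps[1, 2, ], tolerance = 1e-12)
  # cancellation
  gm3 <- make_maps(list(mats[[1]], -mats[[1]]))
  expect_lt(max(abs(mean_network(gm3, 1))), 1e-12)
  expect_error(mean_network(gm, 5), "component index")
})

test_that("consistency follows its defining average of correlations", {
  set.seed(82)
  mats <- lapply(1:5, function(s) matrix(rnorm(3 * 50), 3, 50))
  gm <- make_maps(mats)
  for (m in 1:3) {
    mn <- mean_network(gm, m)
    ref <- mean(sapply(1:5, function(s) cor(gm$maps[s, m, ], mn)))
    expect_equal(consistency(gm, m), ref, tolerance = 1e-10)
  }
  # identical cohort: exactly 1
  gmid <- make_maps(rep(mats[1], 4))
  expect_equal(consistency(gmid, 1), 1)
  # cancellation makes the mean degenerate
  gm0 <- make_maps(list(mats[[1]], -mats[[1]]))
  expect_error(consistency(gm0, 1), "zero variance")
})

test_that("two-subject geometry gives the closed-form 1/sqrt(2)", {
  set.seed(83)
  L <- 400
  r <- rnorm(L); r <- (r - mean(r)) / sqrt(mean((r - mean(r))^2))
  q <- rnorm(L); q <- q - mean(q * r) / mean(r^2) * r
  q <- (q - mean(q)) / sqrt(mean((q - mean(q))^2))
  gm <- make_maps(list(matrix(r + q, 1), matrix(r - q, 1)))
  expect_equal(consistency(gm, 1), 1 / sqrt(2), tolerance = 1e-10)
})

test_that("consistency is invariant under common positive rescaling", {
  set.seed(84)
  mats <- lapply(1:4, function(s) matrix(rnorm(2 * 40), 2, 40))
  gm1 <- make_maps(mats)
  gm2 <- make_maps(lapply(mats, function(m) 7.3 * m))
  expect_equal(consistency(gm1, 1), consistency(gm2, 1), tolerance = 1e-12)
})

test_that("independent noise cohorts have near-zero consistency", {
  set.seed(85)
  L <- 4000
  gm <- make_maps(lapply(1:8, function(s) matrix(rnorm(L), 1)))
  expect_lt(abs(consistency(gm, 1)), 3 / sqrt(L) * 8)
})

test_that("one-sample t-maps follow the textbook formula", {
  set.seed(86)
  S <- 10
  mats <- lapply(1:S, function(s) matrix(rnorm(1 * 25), 1, 25))
  gm <- make_maps(mats)
  tmap <- one_sample_tmap(gm, 1)
  y <- sapply(1:S, function(s) gm$maps[s, 1, 7])
  expect_equal(tmap[7], mean(y) / (sd(y) / sqrt(S)), tolerance = 1e-10)
  # zero-variance voxels
  ident <- make_maps(rep(mats[1], 3))
  t2 <- one_sample_tmap(ident, 1)
  pos <- which(ident$maps[1, 1, ] > 0)[1]
  expect_true(is.infinite(t2[pos]) && t2[pos] > 0)
  expect_error(one_sample_tmap(make_maps(mats[1]), 1), "2 subjects")
})

test_that("critical t values match quadrature of the t density", {
  expect_equal(critical_t(0.5, 7), 0, tolerance = 1e-12)
  for (case in list(c(0.001, 9), c(0.01, 15), c(0.05, 3))) {
    tc <- critical_t(case[1], case[2])
    tail <- integrate(function(u) dt(u, case[2]), tc, Inf)$value
    expect_equal(tail, case[1], tolerance = 1e-6)
  }
  expect_error(critical_t(0, 9), "p")
  expect_error(critical_t(0.1, 0), "df")
})

test_that("display thresholding zeroes sub-threshold voxels only", {
  set.seed(87)
  m <- rnorm(100)
  out <- threshold_map(m, 2)
  expect_true(all(out[m <= 2] == 0))
  expect_identical(out[m > 2], m[m > 2])
  expect_identical(threshold_map(m, -1e10), m)
  out15 <- threshold_map(m, 1.5)
  expect_identical(out15 != 0, m > 1.5)
})

test_that("consistency reports serialize to the CSV schema", {
  set.seed(88)
  gm <- make_maps(lapply(1:3, function(s) matrix(rnorm(2 * 20), 2, 20)))
  rep_ <- consistency_report(gm, threshold = 0.5)
  expect_equal(rep_$k_per, sapply(1:2, function(m) consistency(gm, m)),
               tolerance = 1e-12)
  path <- tempfile(fileext = ".csv")
  write_consistency_csv(rep_, path)
  df <- read.csv(path)
  expect_named(df, c("component", "threshold", "k_per",
                     paste0("rho_subject_", 1:3)))
  expect_equal(df$k_per, rep_$k_per, tolerance = 1e-10)
})
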