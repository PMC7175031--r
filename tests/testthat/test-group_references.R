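test_that("correlation cost matches the direct Pearson formula", {
  set.seed(41)
  A <- matrix(rnorm(3 * 50), 3, 50)
  B <- matrix(rnorm(3 * 50), 3, 50)
  C <- correlation_cost(A, B)
  for (i in 1:3) for (j in 1:3) {
    a <- A[i, ] - mean(A[i, ]); b <- B[j, ] - mean(B[j, ])
    rho <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    expect_equal(C[i, j], 1 - rho, tolerance = 1e-10)
  }
  # self-cost has a zero diagonal; anticorrelated rows cost 2
  expect_lt(max(abs(diag(correlation_cost(A, A)))), 1e-12)
  expect_equal(correlation_cost(A[1, , drop = FALSE],
                                -A[1, , drop = FALSE])[1, 1], 2,
               tolerance = 1e-12)
  # zero-variance convention
  Z <- matrix(1, 1, 50)
  expect_equal(correlation_cost(Z, A[1, , drop = FALSE])[1, 1], 1)
})

test_that("assignment cost equals the exhaustive minimum on random matrices", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    perm <- hungarian_assign(cost)
    expect_setequal(perm, seq_len(n))
    got <- sum(cost[cbind(seq_len(n), perm)])
    expect_equal(got, brute_assignment_cost(cost), tolerance = 1e-12)
  }
})

test_that("assignment is equivariant under row relabeling", {
  set.seed(43)
  cost <- matrix(runif(25), 5, 5)
  perm <- hungarian_assign(cost)
  shuffle <- sample(5)
  perm2 <- hungarian_assign(cost[shuffle, ])
  expect_equal(sum(cost[shuffle, ][cbind(1:5, perm2)]),
               sum(cost[cbind(1:5, perm)]), tolerance = 1e-12)
  # identity-favoring matrix
  ident <- matrix(1, 4, 4); diag(ident) <- 0
  expect_equal(hungarian_assign(ident), 1:4)
  expect_error(hungarian_assign(matrix(1, 2, 3)), "square")
  expect_error(hungarian_assign(matrix(c(1, NA, 2, 3), 2, 2)), "finite")
})

test_that("planted permutations are recovered and the merge is a batch mean", {
  set.seed(44)
  M <- 5; L <- 80
  base <- matrix(rnorm(M * L), M, L)
  perms <- list(seq_len(M), sample(M), sample(M))
  vimfs <- lapply(perms, function(p) base[p, ] + rnorm(M * L, sd = 0.1))
  refs <- build_references(vimfs)
  # recovered assignments invert the planted permutations
  for (s in 2:3) {
    realigned <- vimfs[[s]][refs$assignment_log[[s]], ]
    expect_lt(max(abs(realigned - base)), 0.8)   # rows matched to base rows
    expect_equal(perms[[s]][refs$assignment_log[[s]]], seq_len(M))
  }
  # incremental mean equals the batch mean of the realigned matrices
  realigned <- lapply(seq_along(vimfs), function(s)
    vimfs[[s]][refs$assignment_log[[s]], ])
  batch <- Reduce(`+`, realigned) / length(realigned)
  expect_lt(max(abs(refs$values_raw - batch)), 1e-12)
})

test_that("reference rows are standardized and degenerate merges error", {
  set.seed(45)
  v <- matrix(rnorm(4 * 60), 4, 60)
  refs <- build_references(list(v, v, v))
  expect_lt(max(abs(rowMeans(refs$values))), 1e-10)
  expect_lt(max(abs(rowMeans(refs$values^2) - 1)), 1e-8)
  # identical subjects: reference equals the standardized common matrix
  z <- t(scale(t(v))) * sqrt(60 / 59)
  expect_equal(refs$values, z, tolerance = 1e-8, ignore_attr = TRUE)
  # single subject
  refs1 <- build_references(list(v))
  expect_equal(refs1$values, refs$values, tolerance = 1e-10)
  expect_error(build_references(list(rbind(v, 0), rbind(v, 0))),
               "zero variance")
})

test_that("absolute matching re-aligns anticorrelated modes", {
  set.seed(46)
  base <- matrix(rnorm(3 * 50), 3, 50)
  flipped <- base * c(-1, 1, -1)
  refs <- build_references(list(base, flipped), absolute = TRUE)
  rho <- diag(1 - correlation_cost(refs$values, base))
  expect_true(all(rho > 0.99))
})
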