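test_that("1-D projected W2 agrees with brute-force optimal matching", {
  # K=1 point masses at 0 and 1 -> squared distance 1
  expect_equal(sliced_w2(matrix(0), matrix(1), L = 10, seed = 1), 1)
  set.seed(31)
  for (r in 1:50) {
    b <- sample(2:6, 1)
    p <- rnorm(b)
    q <- rnorm(b)
    expect_equal(spaceval:::w2sq_1d(p, q), brute_w2sq_1d(p, q),
                 tolerance = 1e-12)
  }
  # unequal sizes: quantile-function integral against a fine discretization
  for (r in 1:10) {
    p <- rnorm(sample(2:7, 1))
    q <- rnorm(sample(2:7, 1))
    u <- (seq_len(20000) - 0.5) / 20000
    ref <- mean((quantile(p, u, type = 1) - quantile(q, u, type = 1))^2)
    expect_equal(spaceval:::w2sq_1d(p, q), ref, tolerance = 1e-3)
  }
})

test_that("sliced W2 is symmetric, zero on identical multisets, and converges in L", {
  set.seed(33)
  P <- matrix(rnorm(40), 20, 2)
  Q <- matrix(rnorm(40) + 1, 20, 2)
  expect_equal(sliced_w2(P, P, L = 30, seed = 2), 0)
  expect_equal(sliced_w2(P, Q, L = 30, seed = 2),
               sliced_w2(Q, P, L = 30, seed = 2))
  expect_error(sliced_w2(P, matrix(0, 5, 3)), "dimension")

  # estimator variance across projection seeds decays roughly like 1/L
  est <- function(L) vapply(1:40, function(s) sliced_w2(P, Q, L, seed = s),
                            numeric(1))
  v5 <- var(est(5L))
  v80 <- var(est(80L))
  expect_lt(v80, v5 / 4)  # 16-fold expected; 4-fold demanded for stability
})

test_that("the exponential kernel is a decreasing map onto (0, 1]", {
  expect_equal(exp_kernel(0, 10), 1)
  expect_equal(exp_kernel(0.1, 10), exp(-1))
  expect_lt(exp_kernel(0.5, 100), 1e-20)
  expect_true(all(diff(exp_kernel(seq(0, 2, 0.1), 5)) < 0))
  expect_error(exp_kernel(-0.1, 10), "nonnegative")
  expect_error(exp_kernel(0.1, 0), "positive")
})

test_that("the MMD V-statistic has exact identity, symmetry, and bounds", {
  set.seed(35)
  mk <- function(shift) lapply(1:4, function(i) matrix(rnorm(30) + shift,
                                                       15, 2))
  A <- mk(0)
  B <- mk(2)
  cfg <- discrepancy_config(n_batches = 4, batch_size = 15,
                            n_projections = 25, seed = 9)
  expect_identical(mmd_squared(A, A, cfg)$d, 0)
  rab <- mmd_squared(A, B, cfg)
  rba <- mmd_squared(B, A, cfg)
  expect_identical(rab$d, rba$d)
  expect_gte(rab$d, 0)
  expect_lte(rab$d, 2 + 1e-9)
  expect_equal(rab$d, rab$term_truth + rab$term_clustering - rab$term_cross,
               tolerance = 1e-9)
  expect_error(mmd_squared(A[1], B, cfg), "at least 2")

  # far-separated batches saturate the bound: within-kernels ~1, cross ~0
  tight <- lapply(1:3, function(i) matrix(0, 10, 2))
  far <- lapply(1:3, function(i) matrix(50, 10, 2))
  r2 <- mmd_squared(tight, far, cfg)
  expect_equal(r2$d, 2, tolerance = 1e-6)
})

test_that("the MMD matches an independent double-sum computation", {
  # same directions, but kernel values derived via brute-force 1-D optimal
  # matching and explicit loops rather than the gram fast path
  set.seed(37)
  batches0 <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
  batches1 <- lapply(1:3, function(i) matrix(rnorm(8, 1), 4, 2))
  cfg <- discrepancy_config(n_batches = 3, batch_size = 4,
                            n_projections = 7, seed = 5)
  D <- spaceval:::unit_directions(7, 2, derive_seed(5L, "projections"))
  all_b <- c(batches0, batches1)
  k <- function(i, j) {
    w <- mean(vapply(1:7, function(l) {
      brute_w2sq_1d(as.numeric(all_b[[i]] %*% D[l, ]),
                    as.numeric(all_b[[j]] %*% D[l, ]))
    }, numeric(1)))
    exp(-cfg$gamma * w)
  }
  G <- outer(1:6, 1:6, Vectorize(k))
  ref <- mean(G[1:3, 1:3]) + mean(G[4:6, 4:6]) - 2 * mean(G[1:3, 4:6])
  got <- mmd_squared(batches0, batches1, cfg)
  expect_equal(got$d, ref, tolerance = 1e-10)
})

test_that("kernel Gram matrices are positive semidefinite", {
  set.seed(39)
  for (r in 1:10) {
    K <- sample(2:4, 1)
    n <- sample(3:6, 1)
    A <- lapply(seq_len(n), function(i) matrix(rnorm(10 * K, sd = 2), 10, K))
    B <- lapply(seq_len(n), function(i) matrix(rnorm(10 * K, mean = 1), 10,
                                               K))
    cfg <- discrepancy_config(n_batches = n, batch_size = 10,
                              n_projections = 15, seed = r,
                              gamma = sample(c(0.5, 5, 10), 1))
    expect_gte(mmd_squared(A, B, cfg)$gram_eigen_min, -1e-8)
  }
})

test_that("the end-to-end score is deterministic and near zero on identity", {
  d <- random_labeling_suite(8, 2, seeds = 1, kinds = "identity")[[1]]
  cfg <- fast_config(11)
  r1 <- score_clustering(d, cfg)
  r2 <- score_clustering(d, cfg)
  expect_identical(r1$d, r2$d)
  expect_lte(r1$d, 0.05)
  r3 <- score_clustering(d, fast_config(12))
  expect_false(identical(r1$d, r3$d))
})

test_that("stage failures name the failing step", {
  d <- toy_dataset()
  expect_error(score_clustering(d, fast_config(), weights = "expression"),
               "configuration error")
  expect_error(score_clustering(d, fast_config(), weights = "cost"),
               "cost")
})
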