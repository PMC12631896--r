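test_that("CORAL matches hand-derived values and invariances", {
  expect_equal(coral_loss(matrix(c(0, 2, 0, 0), 2, 2),
                          matrix(c(0, 0, 0, 2), 2, 2)), 0.5)
  set.seed(1)
  F1 <- matrix(rnorm(12 * 4), 12, 4)
  expect_equal(coral_loss(F1, F1), 0)
  expect_lt(coral_loss(F1, sweep(F1, 2, c(5, -2, 0.3, 9), "+")), 1e-20)
  expect_gte(coral_loss(F1, matrix(rnorm(12 * 4), 12, 4)), 0)
  expect_equal(coral_loss(F1, F1 * 2), coral_loss(F1 * 2, F1))  # symmetry
  expect_error(coral_loss(F1[1, , drop = FALSE], F1), "2 rows")
  # cross-check the covariance route against stats::cov
  F2 <- matrix(rnorm(12 * 4), 12, 4)
  d <- 4
  expect_equal(coral_loss(F1, F2),
               sum((stats::cov(F1) - stats::cov(F2))^2) / (4 * d^2),
               tolerance = 1e-12)
})

test_that("DCCA attains -k on identical batches and ~0 on independent ones", {
  set.seed(2)
  X <- matrix(rnorm(50 * 3), 50, 3)
  expect_equal(dcca_loss(X, X, dcca_config(k = 3, r = 1e-9)), -3,
               tolerance = 1e-4)
  set.seed(3)
  n <- 400
  A <- matrix(rnorm(n * 2), n, 2)
  B <- matrix(rnorm(n * 2), n, 2)
  expect_lt(abs(dcca_loss(A, B, dcca_config(k = 1, r = 1e-4))), 3 / sqrt(n))
  # bounds: -k <= loss <= 0 over random batches
  for (rep in 1:5) {
    P <- matrix(rnorm(20 * 4), 20, 4); Q <- matrix(rnorm(20 * 4), 20, 4)
    l <- dcca_loss(P, Q, dcca_config(k = 2, r = 1e-3))
    expect_gte(l, -2); expect_lte(l, 1e-10)
  }
  expect_error(dcca_loss(X, X[1:10, ]), "pairs batches")
  expect_error(dcca_loss(X, X, dcca_config(k = 5)), "infeasible")
})

test_that("DCCA is invariant to affine maps and symmetric in its arguments", {
  set.seed(4)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- X %*% matrix(c(1, 0.3, 0, 0.2, 1, 0, 0, 0.1, 1), 3, 3) +
    matrix(rnorm(200 * 3, sd = 0.5), 200, 3)
  cfg <- dcca_config(k = 2, r = 1e-6)
  base <- dcca_loss(X, Y, cfg)
  A <- matrix(c(2, 0.5, 0, 0, 1, 0.3, 0.2, 0, 1.5), 3, 3)  # invertible
  expect_equal(dcca_loss(X %*% A + 3, Y, cfg), base, tolerance = 1e-3)
  expect_equal(dcca_loss(Y, X, cfg), base, tolerance = 1e-9)
})

test_that("DCCA moves toward -k as shared signal strength grows", {
  set.seed(5)
  n <- 120
  s <- matrix(rnorm(n * 2), n, 2)
  cfg <- dcca_config(k = 2, r = 1e-3)
  losses <- vapply(c(0.5, 1, 2, 4, 8), function(amp) {
    dcca_loss(amp * s + matrix(rnorm(n * 2), n, 2),
              amp * s + matrix(rnorm(n * 2), n, 2), cfg)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))  # monotone toward -k
})

test_that("MMD separates Gaussian clouds in proportion to their distance", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3)
  bw <- c(1, 2, 4)
  expect_equal(mmd_loss(X, X, bw, biased = TRUE), 0, tolerance = 1e-12)
  expect_lte(mmd_loss(X, X, bw), 1e-12)  # unbiased, identical batches
  seps <- c(1, 2, 4)
  vals <- vapply(seps, function(s)
    mmd_loss(X, matrix(rnorm(40 * 3, mean = s), 40, 3), bw), numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
  # direct double-sum oracle at one bandwidth
  Y <- matrix(rnorm(10 * 2, mean = 1), 10, 2)
  Z <- matrix(rnorm(12 * 2), 12, 2)
  k <- function(a, b, s) exp(-sum((a - b)^2) / (2 * s))
  oracle <- function(X, Y, s) {
    m <- nrow(X); n <- nrow(Y)
    xx <- sum(vapply(1:m, function(i) sum(vapply(setdiff(1:m, i), function(j)
      k(X[i, ], X[j, ], s), numeric(1))), numeric(1))) / (m * (m - 1))
    yy <- sum(vapply(1:n, function(i) sum(vapply(setdiff(1:n, i), function(j)
      k(Y[i, ], Y[j, ], s), numeric(1))), numeric(1))) / (n * (n - 1))
    xy <- mean(vapply(1:m, function(i) mean(vapply(1:n, function(j)
      k(X[i, ], Y[j, ], s), numeric(1))), numeric(1)))
    xx + yy - 2 * xy
  }
  expect_equal(mmd_loss(Y, Z, 1.7), oracle(Y, Z, 1.7), tolerance = 1e-12)
  # permutation invariance within a batch
  expect_equal(mmd_loss(Y[sample(10), ], Z, bw), mmd_loss(Y, Z, bw),
               tolerance = 1e-12)
})

test_that("the combined transfer loss composes its parts", {
  set.seed(7)
  X <- matrix(rnorm(30 * 4), 30, 4)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  cfg <- dcca_config(k = 2, r = 1e-3)
  tl <- transfer_loss(X, Y, cfg, arm = "ours")
  expect_equal(tl$dcca, dcca_loss(X, Y, cfg))
  expect_equal(tl$coral, coral_loss(X, Y))
  expect_equal(tl$trans, tl$dcca + tl$coral)
  # identical batches: (-k, 0, -k) in the small-ridge limit
  cfg0 <- dcca_config(k = 2, r = 1e-9)
  tl0 <- transfer_loss(X, X, cfg0, arm = "ours")
  expect_equal(tl0$dcca, -2, tolerance = 1e-4)
  expect_equal(tl0$coral, 0)
  expect_equal(tl0$trans, tl0$dcca)
  # ablation arms isolate their component
  expect_equal(transfer_loss(X, Y, cfg, arm = "coral")$trans, coral_loss(X, Y))
  expect_equal(transfer_loss(X, Y, cfg, arm = "mmd")$trans, mmd_loss(X, Y))
})

test_that("loss gradients flow to both argument batches", {
  set.seed(8)
  Fs <- matrix(rnorm(8 * 4), 8, 4)
  Ft <- matrix(rnorm(8 * 4), 8, 4)
  cfg <- dcca_config(k = 2, r = 0.05)
  g <- transfer_loss(Fs, Ft, cfg, arm = "ours", grad = TRUE)
  idx <- c(1, 9, 17, 30)
  fd_s <- fd_grad(function(A) transfer_loss(A, Ft, cfg, arm = "ours")$trans,
                  Fs, idx = idx)
  fd_t <- fd_grad(function(A) transfer_loss(Fs, A, cfg, arm = "ours")$trans,
                  Ft, idx = idx)
  expect_lt(max(rel_err(fd_s, g$dFs[idx])), 1e-4)
  expect_lt(max(rel_err(fd_t, g$dFt[idx])), 1e-4)
  expect_true(any(g$dFs != 0) && any(g$dFt != 0))
})
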