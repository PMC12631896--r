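test_that("stratified folds partition trials evenly and reproducibly", {
  labels <- rep(c(0L, 1L), each = 30)
  plan <- make_folds(labels, k = 5, seed = 3)
  sizes <- lengths(plan$folds)
  expect_equal(sizes, rep(12L, 5))
  for (f in plan$folds)
    expect_equal(sum(labels[f] == 0), 6L)
  expect_identical(sort(unlist(plan$folds)), seq_along(labels))
  expect_identical(plan$folds, make_folds(labels, k = 5, seed = 3)$folds)
  expect_false(identical(plan$folds, make_folds(labels, k = 5, seed = 4)$folds))
  expect_error(make_folds(rep(0:1, c(3, 30)), k = 5), "fewer than k")
})

test_that("confusion metrics match hand arithmetic", {
  expect_equal(metrics_from_confusion(matrix(c(30, 0, 0, 30), 2, 2,
                                             byrow = TRUE)),
               c(1, 1, 1, 1), ignore_attr = TRUE)
  expect_equal(metrics_from_confusion(matrix(c(15, 15, 15, 15), 2, 2))[["accuracy"]],
               0.5)
  m <- metrics_from_confusion(matrix(c(20, 10, 5, 25), 2, 2, byrow = TRUE))
  expect_equal(m, c(0.75, 0.8, 2 / 3, 0.727), tolerance = 1e-3,
               ignore_attr = TRUE)
  # degenerate: no predictions of the positive class
  md <- metrics_from_confusion(matrix(c(0, 10, 0, 10), 2, 2, byrow = TRUE))
  expect_true(attr(md, "degenerate"))
  expect_equal(md[["precision"]], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "total > 0")
  # accuracy identity with raw counts
  set.seed(2)
  truth <- sample(0:1, 40, TRUE); pred <- sample(0:1, 40, TRUE)
  cm <- confusion_counts(truth, pred)
  expect_equal(metrics_from_confusion(cm)[["accuracy"]], mean(truth == pred))
})

test_that("Friedman test matches closed form, base R, and permutation null", {
  # identical methods -> degenerate (0, 1)
  acc <- matrix(0.7, 6, 3)
  r <- friedman_test(acc)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # strict dominance across 10 subjects, 3 methods: chi2 = 12n/(k(k+1)) *
  # sum((Rbar_j - (k+1)/2)^2) = 20 for n = 10, k = 3
  set.seed(4)
  base <- matrix(runif(30, 0.5, 0.6), 10, 3)
  dom <- base + matrix(rep(c(0.3, 0.15, 0), each = 10), 10, 3)
  rd <- friedman_test(dom)
  expect_equal(rd$statistic, 20, tolerance = 1e-12)
  expect_lt(rd$p_value, 0.05)
  expect_equal(unname(rd$mean_ranks), c(3, 2, 1))

  # column permutation permutes mean ranks, statistic unchanged
  rp <- friedman_test(dom[, c(2, 3, 1)])
  expect_equal(rp$statistic, rd$statistic)
  expect_equal(unname(rp$mean_ranks), c(2, 1, 3))

  # agreement with stats::friedman.test on tie-free data
  set.seed(5)
  m <- matrix(rnorm(18), 6, 3)
  ours <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # permutation-null oracle: our statistic must equal an independently coded
  # rank statistic on every permutation (tie-free data), and the chi-square
  # p must approximate the resulting permutation p
  oracle_stat <- function(a) {
    n <- nrow(a); k <- ncol(a)
    Rj <- colSums(t(apply(a, 1, rank)))
    12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  }
  set.seed(7)
  small <- matrix(rnorm(18, sd = 0.5), 6, 3)
  obs <- friedman_test(small)$statistic
  expect_equal(obs, oracle_stat(small), tolerance = 1e-12)
  null_ours <- null_oracle <- numeric(2000)
  for (i in 1:2000) {
    perm <- t(apply(small, 1, sample))
    null_ours[i] <- friedman_test(perm)$statistic
    null_oracle[i] <- oracle_stat(perm)
  }
  expect_equal(null_ours, null_oracle, tolerance = 1e-12)
  p_perm <- mean(null_ours >= obs - 1e-12)
  expect_lt(abs(p_perm - friedman_test(small)$p_value), 0.12)
  expect_error(friedman_test(matrix(1, 1, 3)), ">= 2 subjects")
})

test_that("evaluate_method validates arms and conserves trial counts", {
  expect_error(evaluate_method(list(), "nope", eval_config(NULL, NULL)),
               "valid arms")
  pop <- list(A = tiny_subject(seed = 61, erd_depth = 0.85, snr = 0.3))
  pop$A$subject_id <- "A"
  cfg <- eval_config(tiny_eeg_spec(), scaled_network_spec(8, 100),
                     epochs = 12, patience = 12, folds = 5, seed = 2)
  res <- evaluate_method(pop, "fnirs_base", cfg)
  expect_equal(sum(res$confusion), 60)  # every trial evaluated exactly once
  expect_equal(nrow(res$summary), 1)
  expect_gte(res$mean_accuracy, 0.7)    # strongly separable subject
})
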