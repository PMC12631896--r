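test_that("wasserstein_1d matches hand values and metric axioms", {
  expect_equal(wasserstein_1d(c(3, 1, 2), c(2, 1, 3)), 0)
  expect_equal(wasserstein_1d(0, 3), 3)
  expect_equal(wasserstein_1d(c(0, 1), c(2, 3)), 2)
  expect_error(wasserstein_1d(numeric(0), 1), "empty")
  set.seed(42)
  for (rep in 1:20) {
    p <- rnorm(sample(2:8, 1)); q <- rnorm(sample(2:8, 1)); r <- rnorm(5)
    expect_gte(wasserstein_1d(p, q), 0)
    expect_equal(wasserstein_1d(p, q), wasserstein_1d(q, p), tolerance = 1e-12)
    expect_lte(wasserstein_1d(p, q),
               wasserstein_1d(p, r) + wasserstein_1d(r, q) + 1e-12)
    expect_lt(wasserstein_1d(p, p), 1e-12)
  }
})

test_that("wasserstein_1d agrees with the exhaustive matching oracle", {
  set.seed(7)
  for (n in 2:5) {
    for (rep in 1:8) {
      p <- round(rnorm(n), 2)
      q <- round(rnorm(n), 2)
      expect_equal(wasserstein_1d(p, q), w1_matching_oracle(p, q),
                   tolerance = 1e-12)
    }
  }
})

make_ts <- function(data, id = "a") {
  trial_set(id, "EEG", data, rep(c(0L, 1L), length.out = dim(data)[1]), 100)
}

test_that("subject distance has the translation property and symmetry", {
  set.seed(9)
  A <- array(rnorm(6 * 3 * 50), c(6, 3, 50))
  a <- make_ts(A, "a")
  b <- make_ts(A + 2.5, "b")
  expect_equal(subject_distance(a, a), 0)
  expect_equal(subject_distance(a, b), 2.5, tolerance = 1e-12)
  expect_equal(subject_distance(a, b), subject_distance(b, a))
  bad <- make_ts(array(rnorm(6 * 2 * 50), c(6, 2, 50)))
  expect_error(subject_distance(a, bad), "channel count")
})

test_that("distance matrix is symmetric with exact mean distances", {
  set.seed(10)
  A <- array(rnorm(4 * 2 * 40), c(4, 2, 40))
  cc <- 1.5
  subs <- list(make_ts(A, "s1"), make_ts(A + cc, "s2"), make_ts(A + 2 * cc, "s3"))
  dm <- distance_matrix(subs)
  expect_equal(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  expect_equal(unname(dm$mean_distance),
               c((cc + 2 * cc) / 2, cc, (2 * cc + cc) / 2), tolerance = 1e-12)
  # identical subjects give the zero matrix
  dm0 <- distance_matrix(list(make_ts(A, "x"), make_ts(A, "y"), make_ts(A, "z")))
  expect_true(all(dm0$values == 0))
  expect_error(distance_matrix(subs[1]), "at least 2")
  # input order only permutes the stored labels
  dm_r <- distance_matrix(rev(subs))
  expect_equal(dm_r$values[rev(1:3), rev(1:3)], unname(dm$values),
               ignore_attr = TRUE)
})

test_that("trusted scores implement accuracy x (1 - minmax) with tie-breaks", {
  set.seed(11)
  A <- array(rnorm(4 * 2 * 30), c(4, 2, 30))
  dm <- distance_matrix(list(make_ts(A, "s1"), make_ts(A + 2, "s2")))
  # mean distances are (2, 2) -> degenerate; force the worked example instead
  dm$mean_distance <- c(s1 = 2, s2 = 1)
  tab <- trusted_scores(c(s1 = 0.8, s2 = 0.6), dm)
  expect_equal(tab$normalized_distance, c(1, 0))
  expect_equal(tab$trusted, c(0, 0.6))
  expect_identical(select_source(tab), "s2")

  # degenerate normalization: all distances equal -> T_k = Acc_k
  dm$mean_distance <- c(s1 = 3, s2 = 3)
  tab2 <- trusted_scores(c(s1 = 0.8, s2 = 0.6), dm)
  expect_equal(tab2$trusted, c(0.8, 0.6))

  # monotonicity in accuracy at fixed distances (for any subject whose
  # normalized distance is below the min-max ceiling)
  dm3 <- distance_matrix(list(make_ts(A, "s1"), make_ts(A + 2, "s2"),
                              make_ts(A + 4, "s3")))
  dm3$mean_distance <- c(s1 = 2, s2 = 1, s3 = 0)
  t_lo <- trusted_scores(c(s1 = 0.6, s2 = 0.55, s3 = 0.6), dm3)$trusted[2]
  t_hi <- trusted_scores(c(s1 = 0.6, s2 = 0.75, s3 = 0.6), dm3)$trusted[2]
  expect_gt(t_hi, t_lo)
  expect_error(trusted_scores(c(s1 = 1.2, s2 = 0.5), dm), "\\[0, 1\\]")
})

test_that("trusted ranking is invariant to a global distance rescale", {
  set.seed(12)
  subs <- lapply(1:4, function(i)
    make_ts(array(rnorm(4 * 2 * 30), c(4, 2, 30)) + i * 0.3, paste0("s", i)))
  dm <- distance_matrix(subs)
  acc <- c(s1 = 0.7, s2 = 0.65, s3 = 0.8, s4 = 0.6)
  t1 <- trusted_scores(acc, dm)
  dm2 <- dm
  dm2$values <- dm$values * 7.3
  dm2$mean_distance <- dm$mean_distance * 7.3
  t2 <- trusted_scores(acc, dm2)
  expect_identical(order(-t1$trusted), order(-t2$trusted))
  expect_identical(select_source(t1), select_source(t2))
})

test_that("joint selection sums modality trust and handles edge cases", {
  tab <- function(ids, trusted, acc = rep(0.7, length(ids)))
    structure(data.frame(subject_id = ids, acc = acc,
                         mean_distance = seq_along(ids),
                         normalized_distance = 0, trusted = trusted,
                         stringsAsFactors = FALSE),
              class = c("trusted_score_table", "data.frame"))
  e <- tab(c("s1", "s2"), c(0.5, 0.1))
  f <- tab(c("s1", "s2"), c(0.1, 0.6))
  expect_identical(joint_trusted_selection(e, f), "s2")  # 0.7 > 0.6
  z <- tab(c("s1", "s2"), c(0, 0))
  expect_identical(joint_trusted_selection(e, z), select_source(e))
  expect_identical(joint_trusted_selection(e, e), select_source(e))
  expect_error(joint_trusted_selection(e, tab(c("s1", "s3"), c(1, 1))),
               "roster")
  # single candidate trivially selected
  expect_identical(select_source(tab("only", 0.4)), "only")
})
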