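test_that("layer_output_length reproduces the canonical architecture chain", {
  # EEG branch
  expect_equal(layer_output_length(2000, 63, 31, 1, "conv"), 2000L)
  expect_equal(layer_output_length(2000, 30, 0, 1, "conv"), 1971L)
  expect_equal(layer_output_length(1971, 4, op_kind = "pool"), 492L)
  expect_equal(layer_output_length(492, 15, 7, 1, "conv"), 492L)
  expect_equal(layer_output_length(492, 2, op_kind = "pool"), 246L)
  # fNIRS branch (self-consistent rows)
  expect_equal(layer_output_length(100, 101, 50, 1, "conv"), 100L)
  expect_equal(layer_output_length(100, 4, op_kind = "pool"), 25L)
  expect_error(layer_output_length(5, 2, op_kind = "pool") &&
                 layer_output_length(1, 2, op_kind = "pool"),
               "non-positive")
})

test_that("canonical specs produce the printed flatten lengths", {
  se <- eeg_network_spec()
  expect_equal(se$F1, 16L)
  expect_equal(se$F2, 64L)  # F2 = F1 * D, D = 4
  expect_equal(flatten_length(se), 64L * 246L)
  sn <- fnirs_network_spec()
  expect_equal(spec_lengths(sn)$conv1, 100L)   # 101 cropped to the printed 100
  expect_equal(spec_lengths(sn)$conv2, 100L)
  expect_equal(spec_lengths(sn)$pool1, 25L)
  expect_equal(flatten_length(sn), 64L * 17L)  # printed adaptive-pool length
  sn_strict <- fnirs_network_spec(strict_formula = TRUE)
  expect_equal(flatten_length(sn_strict), 64L * 12L)
})

test_that("depthwise separable block uses fewer parameters than a full conv", {
  F2 <- 64L; k <- 15L
  sep <- nn_sepconv1d(F2, F2, k, 7)
  n_sep <- sum(vapply(sep$params, length, numeric(1)))
  n_full <- F2 * F2 * k + F2
  expect_equal(n_sep, F2 * k + F2 * F2 + F2)  # 5056 + bias
  expect_lt(n_sep, n_full)                    # << 61440 + bias
})

test_that("full-size networks build and emit correctly shaped outputs", {
  m <- build_base_model(eeg_network_spec(), "EEG", seed = 1)
  X <- array(rnorm(2 * 30 * 2000, sd = 0.1), c(2, 30, 2000))
  ts <- trial_set("s", "EEG", X, c(0L, 1L), 200)
  fb <- extract_features(m, ts)
  expect_equal(dim(fb$values), c(2L, 64L * 246L))
  logits <- net_forward(m$layers, X)$out
  expect_equal(dim(logits), c(2L, 2L))

  mn <- build_base_model(fnirs_network_spec(), "FNIRS", seed = 1)
  Xn <- array(rnorm(2 * 36 * 100, sd = 0.1), c(2, 36, 100))
  tn <- trial_set("s", "FNIRS", Xn, c(0L, 1L), 10)
  expect_equal(ncol(extract_features(mn, tn)$values), 64L * 17L)
})

test_that("feature extraction is deterministic and permutation-equivariant", {
  sd1 <- tiny_subject(seed = 2)
  m <- build_base_model(tiny_eeg_spec(), "EEG", seed = 3)
  fb <- extract_features(m, sd1$eeg)
  expect_equal(nrow(fb$values), dim(sd1$eeg$data)[1])
  # identical inputs -> identical rows
  ts0 <- sd1$eeg
  ts0$data[] <- 0
  fb0 <- extract_features(m, ts0)
  expect_true(all(apply(fb0$values, 2, function(col) max(col) - min(col)) == 0))
  # permuting trials permutes rows
  perm <- rev(seq_len(dim(sd1$eeg$data)[1]))
  ts_p <- sd1$eeg
  ts_p$data <- ts_p$data[perm, , , drop = FALSE]
  ts_p$labels <- ts_p$labels[perm]
  expect_equal(extract_features(m, ts_p)$values, fb$values[perm, ],
               tolerance = 1e-12)
  # shape mismatch errors
  expect_error(extract_features(m, sd1$fnirs), "does not match")
})

test_that("training separates a strongly separable subject and is seeded", {
  sd1 <- tiny_subject(seed = 8, erd_depth = 0.9, snr = 0.15)
  parts <- split_train_val(sd1$eeg, seed = 1)
  m <- build_base_model(tiny_eeg_spec(), "EEG", seed = 1)
  r1 <- train_base(m, parts$train, parts$val, epochs = 30, patience = 30,
                   seed = 5)
  expect_gte(r1$val_accuracy, 0.95)
  # determinism: same seed, same result (parameters included)
  r2 <- train_base(m, parts$train, parts$val, epochs = 30, patience = 30,
                   seed = 5)
  expect_identical(r1$val_accuracy, r2$val_accuracy)
  expect_identical(r1$model$layers[[13]]$params$W, r2$model$layers[[13]]$params$W)
  # single-class training set is refused
  one_class <- parts$train
  one_class$labels[] <- 0L
  expect_error(train_base(m, one_class, parts$val), "single class")
})

test_that("shuffled labels yield chance-level validation accuracy", {
  sd1 <- tiny_subject(seed = 13, erd_depth = 0.8, snr = 0.3)
  ts <- sd1$eeg
  ts$labels <- with_seed(77, sample(ts$labels))
  parts <- split_train_val(ts, seed = 2)
  m <- build_base_model(tiny_eeg_spec(), "EEG", seed = 2)
  r <- train_base(m, parts$train, parts$val, epochs = 12, patience = 12,
                  seed = 2)
  n_val <- dim(parts$val$data)[1]
  band <- qbinom(c(0.025, 0.975), n_val, 0.5) / n_val
  expect_gte(r$val_accuracy, band[1])
  expect_lte(r$val_accuracy, band[2])
})
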