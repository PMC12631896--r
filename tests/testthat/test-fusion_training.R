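test_that("fusion weights realize the normalized-accuracy mixing ratio", {
  w <- fusion_weights(0.7, 0.7)
  expect_equal(c(w$a, w$b), c(0.5, 0.5))
  w2 <- fusion_weights(0.75, 0.25)
  expect_equal(c(w2$a, w2$b), c(0.75, 0.25))
  for (pair in list(c(0.9, 0.3), c(0.5, 1), c(0.01, 0.99))) {
    w3 <- fusion_weights(pair[1], pair[2])
    expect_equal(w3$a + w3$b, 1)
    expect_true(w3$a >= 0 && w3$a <= 1)
  }
  expect_error(fusion_weights(0, 0), "undefined")
  expect_error(fusion_weights(1.2, 0.5), "\\[0, 1\\]")
})

test_that("feature fusion is a weighted concatenation with shape contract", {
  set.seed(1)
  Fe <- matrix(rnorm(6 * 4), 6, 4)
  Fn <- matrix(rnorm(6 * 3), 6, 3)
  fused <- fuse_features(Fe, Fn, fusion_weights(0.5, 0.5))
  expect_equal(dim(fused$values), c(6L, 7L))
  # boundary weights zero out the other modality's block
  f10 <- fuse_features(Fe, Fn, fusion_weights(1, 1e-12))
  expect_lt(max(abs(f10$values[, 5:7])), 1e-10)
  expect_equal(f10$values[, 1:4], Fe, ignore_attr = TRUE, tolerance = 1e-9)
  # equal inputs, equal weights -> equal halves
  feq <- fuse_features(Fe, Fe, fusion_weights(0.5, 0.5))
  expect_equal(feq$values[, 1:4], feq$values[, 5:8])
  expect_error(fuse_features(Fe, Fn[1:3, ], fusion_weights(0.5, 0.5)),
               "paired")
})

test_that("total loss follows the weighted decomposition", {
  w <- fusion_weights(0.5, 0.5)
  expect_equal(total_loss(loss_bundle(0.42), w), 0.42)
  w10 <- fusion_weights(1, 1e-12)
  expect_equal(total_loss(loss_bundle(0.3, trans_eeg = -0.1, trans_fnirs = 99),
                          w10), 0.2, tolerance = 1e-9)
  expect_equal(total_loss(loss_bundle(0.6931, trans_eeg = -0.2,
                                      trans_fnirs = 0.1), w),
               0.6431, tolerance = 1e-12)
})

test_that("fusion model construction obeys the simplified-head contract", {
  spe <- tiny_eeg_spec()
  spn <- scaled_network_spec(8, 100)
  me <- build_base_model(spe, "EEG", seed = 1)
  mn <- build_base_model(spn, "FNIRS", seed = 2)
  w <- fusion_weights(0.6, 0.4)
  fm <- build_fusion_model(me, mn, w, seed = 3)
  d <- flatten_length(spe) + flatten_length(spn)
  expect_equal(sum(vapply(fm$head$params, length, numeric(1))), d * 2 + 2)
  # forward pass on one paired trial yields 2 logits
  pr <- predict_fusion(fm,
                       array(rnorm(2 * 8 * 320, sd = 0.1), c(2, 8, 320)),
                       array(rnorm(2 * 8 * 100, sd = 0.1), c(2, 8, 100)))
  expect_equal(dim(pr$logits), c(2L, 2L))
  expect_true(all(pr$labels %in% c(0L, 1L)))
  # same checkpoints and seed -> identical initial outputs
  fm2 <- build_fusion_model(me, mn, w, seed = 3)
  X <- array(rnorm(2 * 8 * 320), c(2, 8, 320))
  Y <- array(rnorm(2 * 8 * 100), c(2, 8, 100))
  expect_identical(predict_fusion(fm, X, Y)$logits,
                   predict_fusion(fm2, X, Y)$logits)
  expect_error(build_fusion_model(list(), mn, w), "pretrain")
})

test_that("transfer training runs, logs coherent losses, and honors config", {
  pop <- list(S01 = tiny_subject(seed = 31, erd_depth = 0.85, snr = 0.3),
              S02 = tiny_subject(seed = 32, erd_depth = 0.6, snr = 0.5))
  pop$S01$subject_id <- "S01"; pop$S02$subject_id <- "S02"
  spe <- tiny_eeg_spec(); spn <- scaled_network_spec(8, 100)
  ck <- pretrain_population(pop, spe, spn, epochs = 6, patience = 6, seed = 3)
  cfg <- transfer_run_config("S01", "S01", "S02", epochs = 3, seed = 4,
                             folds = 5)
  res <- train_transfer(pop, cfg, ck)
  expect_s3_class(res$report, "eval_report")
  expect_equal(sum(res$report$confusion_matrix), 60L)  # all trials evaluated
  # Eq. 14 / 16 identities hold in every logged epoch
  log <- res$fold_logs[[1]]
  expect_equal(log$a + log$b, rep(1, nrow(log)))
  recon <- log$clf +
    log$a * (log$dcca_eeg + log$coral_eeg + log$mmd_eeg) +
    log$b * (log$dcca_fnirs + log$coral_fnirs + log$mmd_fnirs)
  expect_equal(recon, log$total, tolerance = 1e-6)

  # config errors
  expect_error(train_transfer(pop, transfer_run_config("S01", "S01", "S01"),
                              ck), "differ")
  expect_error(train_transfer(pop, cfg, list()), "pretrain")
  bad <- transfer_run_config("S99", "S01", "S02")
  expect_error(train_transfer(pop, bad, ck), "not in population")
})

test_that("source initialization and transfer losses change the trajectory", {
  pop <- list(S01 = tiny_subject(seed = 41, erd_depth = 0.85, snr = 0.3),
              S02 = tiny_subject(seed = 42, erd_depth = 0.6, snr = 0.5))
  pop$S01$subject_id <- "S01"; pop$S02$subject_id <- "S02"
  spe <- tiny_eeg_spec(); spn <- scaled_network_spec(8, 100)
  ck <- pretrain_population(pop, spe, spn, epochs = 5, patience = 5, seed = 5)
  tgt <- pop$S02
  labeled <- 1:20
  w <- fusion_weights(ck$S02$acc_eeg, ck$S02$acc_fnirs)
  run <- function(source_init, scale) {
    cfg <- transfer_run_config("S01", "S01", "S02", epochs = 2, seed = 6,
                               transfer_scale = scale)
    fm <- if (source_init)
      build_fusion_model(ck$S01$eeg, ck$S01$fnirs, w, seed = 6)
    else
      build_fusion_model(build_base_model(spe, "EEG", 7),
                         build_base_model(spn, "FNIRS", 8), w, seed = 6)
    transfer_fit(fm, pop$S01$eeg, pop$S01$fnirs, tgt$eeg, tgt$fnirs,
                 labeled, cfg)
  }
  ours <- run(TRUE, 1)
  finetune <- run(TRUE, 0)
  fresh <- run(FALSE, 0)
  # with transfer off the loss log carries no transfer components
  expect_true(all(finetune$loss_log$dcca_eeg == 0))
  expect_true(any(ours$loss_log$dcca_eeg != 0))
  # transfer losses alter the learned parameters relative to fine-tuning
  expect_false(isTRUE(all.equal(ours$head$params$W, finetune$head$params$W)))
  # source initialization alters the trajectory relative to random init
  expect_false(isTRUE(all.equal(finetune$loss_log$clf, fresh$loss_log$clf)))
})
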