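#' Accuracy-derived multimodal mixing weights
#'
#' `a = A_eeg / (A_eeg + A_nirs)`, `b = A_nirs / (A_eeg + A_nirs)`: the
#' fusion weights are the normalized single-modality validation accuracies of
#' the target subject, so the more decodable modality dominates both the
#' fused feature and the transfer-loss weighting.
#'
#' @param A_eeg,A_nirs Single-modality target validation accuracies in
#'   `[0, 1]`, not both zero.
#' @return An object of class `fusion_weights` with fields `a`, `b`,
#'   `A_eeg`, `A_nirs` (`a + b == 1`).
#' @export
fusion_weights <- function(A_eeg, A_nirs) {
  if (A_eeg < 0 || A_eeg > 1 || A_nirs < 0 || A_nirs > 1)
    stopf("accuracies must lie in [0, 1]")
  if (A_eeg + A_nirs == 0)
    stopf("both accuracies are zero; mixing ratio undefined")
  structure(list(a = A_eeg / (A_eeg + A_nirs),
                 b = A_nirs / (A_eeg + A_nirs),
                 A_eeg = A_eeg, A_nirs = A_nirs), class = "fusion_weights")
}

#' Weighted concatenation of paired modality features
#'
#' Fuses paired EEG and fNIRS feature rows into
#' `[a * F_eeg_row, b * F_nirs_row]` (dimension `d_eeg + d_fnirs`), realizing
#' the accuracy-weighted mixing ratio while keeping the direct-connection
#' concatenation architecture.
#'
#' @param F_eeg,F_nirs Paired [feature_batch()]es (equal row counts).
#' @param w A [fusion_weights()].
#' @return A fused [feature_batch()].
#' @export
fuse_features <- function(F_eeg, F_nirs, w) {
  Xe <- as_feature_matrix(F_eeg); Xn <- as_feature_matrix(F_nirs)
  if (nrow(Xe) != nrow(Xn))
    stopf("paired trials required: %d vs %d rows", nrow(Xe), nrow(Xn))
  fb <- feature_batch(cbind(w$a * Xe, w$b * Xn),
                      subject_id = if (inherits(F_eeg, "feature_batch"))
                        F_eeg$subject_id else "unknown",
                      domain_tag = if (inherits(F_eeg, "feature_batch"))
                        F_eeg$domain_tag else "target")
  fb
}

#' Loss decomposition tracked during transfer training
#'
#' @param clf Classification cross-entropy on labeled target trials.
#' @param trans_eeg,trans_fnirs Per-modality transfer losses (DCCA + CORAL,
#'   or the configured ablation component).
#' @param components Optional named list of sub-components for logging.
#' @return An object of class `loss_bundle`.
#' @export
loss_bundle <- function(clf, trans_eeg = 0, trans_fnirs = 0,
                        components = list()) {
  structure(list(clf = clf, trans_eeg = trans_eeg, trans_fnirs = trans_fnirs,
                 components = components), class = "loss_bundle")
}

#' Total training loss
#'
#' `L = L_clf + a * L_trans_eeg + b * L_trans_fnirs`: classification loss
#' plus the accuracy-weighted per-modality transfer losses.
#'
#' @param bundle A [loss_bundle()].
#' @param w A [fusion_weights()].
#' @return Scalar total loss.
#' @export
total_loss <- function(bundle, w) {
  stopifnot(is.finite(bundle$clf), is.finite(bundle$trans_eeg),
            is.finite(bundle$trans_fnirs))
  bundle$clf + w$a * bundle$trans_eeg + w$b * bundle$trans_fnirs
}

#' Build the multimodal fusion model
#'
#' Takes the feature extractors of the two (per-modality optimal) source
#' models, concatenates their flattened outputs through a direct connection,
#' and attaches a single fresh linear head to 2 logits - deliberately no
#' additional hidden layers, to limit overfitting on small target sets.
#'
#' @param eeg_ckpt,fnirs_ckpt Source [build_base_model()]s (trained or fresh).
#' @param w A [fusion_weights()].
#' @param seed Head-initialization seed.
#' @return An object of class `fusion_model` with the two extractors, the
#'   linear head, and the weights.
#' @export
build_fusion_model <- function(eeg_ckpt, fnirs_ckpt, w, seed = 1L) {
  if (!inherits(eeg_ckpt, "base_model") || !inherits(fnirs_ckpt, "base_model"))
    stopf("checkpoints must be base_model objects (run the pretrain step first)")
  d_eeg <- flatten_length(eeg_ckpt$spec)
  d_nirs <- flatten_length(fnirs_ckpt$spec)
  head <- with_seed(seed, nn_linear(d_eeg + d_nirs, 2L))
  structure(list(
    eeg_extractor = eeg_ckpt$layers[seq_len(eeg_ckpt$flatten_index)],
    fnirs_extractor = fnirs_ckpt$layers[seq_len(fnirs_ckpt$flatten_index)],
    eeg_spec = eeg_ckpt$spec, fnirs_spec = fnirs_ckpt$spec,
    head = head, weights = w, d_eeg = d_eeg, d_nirs = d_nirs,
    meta = list(seed = as.integer(seed))
  ), class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> a = %.3f (EEG, d=%d) + b = %.3f (fNIRS, d=%d) -> 2 logits\n",
              x$weights$a, x$d_eeg, x$weights$b, x$d_nirs))
  invisible(x)
}

fusion_check_shapes <- function(fm, eeg_data, fnirs_data) {
  if (dim(eeg_data)[2] != fm$eeg_spec$input_channels ||
      dim(eeg_data)[3] != fm$eeg_spec$input_samples)
    stopf("EEG trials (%d x %d) do not match fusion model input (%d x %d)",
          dim(eeg_data)[2], dim(eeg_data)[3],
          fm$eeg_spec$input_channels, fm$eeg_spec$input_samples)
  if (dim(fnirs_data)[2] != fm$fnirs_spec$input_channels ||
      dim(fnirs_data)[3] != fm$fnirs_spec$input_samples)
    stopf("fNIRS trials do not match fusion model input")
}

#' Predict with a fusion model
#'
#' @param fm A [build_fusion_model()].
#' @param eeg_data,fnirs_data Paired trial arrays `n x ch x samples`.
#' @return List with `labels` (0/1), `probs`, `logits`.
#' @export
predict_fusion <- function(fm, eeg_data, fnirs_data) {
  fusion_check_shapes(fm, eeg_data, fnirs_data)
  Fe <- net_forward(fm$eeg_extractor, eeg_data, train = FALSE)$out
  Fn <- net_forward(fm$fnirs_extractor, fnirs_data, train = FALSE)$out
  fused <- cbind(fm$weights$a * Fe, fm$weights$b * Fn)
  logits <- layer_forward(fm$head, fused)$out
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  list(labels = as.integer(max.col(p) - 1L), probs = p, logits = logits)
}

#' Transfer-run configuration
#'
#' All knobs of one transfer-training run: the per-modality source subjects,
#' the target subject, the optimizer settings, the transfer-loss arm
#' (`"ours"` = DCCA + CORAL, `"coral"`, `"mmd"`), and the source mode
#' (`"separate"`: per-modality optimal subjects; `"same"`: one subject picked
#' by joint trusted score).
#'
#' @param source_eeg,source_fnirs,target Subject ids.
#' @param epochs,batch_size,lr,seed Optimization settings (Adam, lr 0.001).
#' @param loss_arm One of `"ours"`, `"coral"`, `"mmd"`.
#' @param source_mode `"separate"` or `"same"`.
#' @param transfer_scale Multiplier on the transfer-loss terms; 0 reduces the
#'   run to supervised fine-tuning of the fusion model.
#' @param freeze_extractors Train only the fusion head.
#' @param dcca A [dcca_config()].
#' @param folds Cross-validation folds for evaluation.
#' @return An object of class `transfer_run_config`.
#' @export
transfer_run_config <- function(source_eeg, source_fnirs, target,
                                epochs = 30, batch_size = 16, lr = 0.001,
                                seed = 1L,
                                loss_arm = c("ours", "coral", "mmd"),
                                source_mode = c("separate", "same"),
                                transfer_scale = 1,
                                freeze_extractors = FALSE,
                                dcca = dcca_config(), folds = 5L) {
  loss_arm <- match.arg(loss_arm)
  source_mode <- match.arg(source_mode)
  if (lr <= 0) stopf("lr must be > 0")
  structure(list(source_eeg = source_eeg, source_fnirs = source_fnirs,
                 target = target, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed), loss_arm = loss_arm,
                 source_mode = source_mode, transfer_scale = transfer_scale,
                 freeze_extractors = freeze_extractors, dcca = dcca,
                 folds = as.integer(folds)), class = "transfer_run_config")
}

# Core transfer-training loop for one target subject and one labeled subset.
#
# Per step three batches flow through each modality's extractor: the labeled
# target batch (classification loss through the fused head), and an
# unlabeled-target + source batch pair (transfer loss between their feature
# distributions). The total loss L = L_clf + a L_trans_eeg + b L_trans_fnirs
# is backpropagated into the head and, unless frozen, both extractors.
transfer_fit <- function(fm, eeg_src, fnirs_src, eeg_tgt, fnirs_tgt,
                         labeled_idx, cfg) {
  n_lab <- length(labeled_idx)
  if (n_lab < 2) stopf("need at least 2 labeled target trials")
  w <- fm$weights
  head <- list(fm$head)
  st_e <- adam_init(fm$eeg_extractor)
  st_n <- adam_init(fm$fnirs_extractor)
  st_h <- adam_init(head)
  n_src <- dim(eeg_src$data)[1]
  n_tgt <- dim(eeg_tgt$data)[1]
  log <- NULL
  t_step <- 0L
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample(labeled_idx)
      ep_losses <- c(clf = 0, dcca_eeg = 0, coral_eeg = 0, mmd_eeg = 0,
                     dcca_fnirs = 0, coral_fnirs = 0, mmd_fnirs = 0,
                     total = 0)
      n_b <- 0L
      for (b in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
        if (length(b) < 2) next
        bs <- length(b)
        src_b <- sample.int(n_src, bs, replace = bs > n_src)
        unl_b <- sample.int(n_tgt, bs, replace = bs > n_tgt)

        # --- forward: labeled target through both extractors + head
        fe_lab <- net_forward(fm$eeg_extractor, eeg_tgt$data[b, , , drop = FALSE],
                              train = TRUE)
        fm$eeg_extractor <- fe_lab$layers
        fn_lab <- net_forward(fm$fnirs_extractor,
                              fnirs_tgt$data[b, , , drop = FALSE], train = TRUE)
        fm$fnirs_extractor <- fn_lab$layers
        fused <- cbind(w$a * fe_lab$out, w$b * fn_lab$out)
        hd <- layer_forward(head[[1]], fused)
        ce <- softmax_xent(hd$out, eeg_tgt$labels[b])

        # --- forward: source and unlabeled-target batches (transfer loss)
        fe_src <- net_forward(fm$eeg_extractor,
                              eeg_src$data[src_b, , , drop = FALSE], train = TRUE)
        fm$eeg_extractor <- fe_src$layers
        fe_unl <- net_forward(fm$eeg_extractor,
                              eeg_tgt$data[unl_b, , , drop = FALSE], train = TRUE)
        fm$eeg_extractor <- fe_unl$layers
        fn_src <- net_forward(fm$fnirs_extractor,
                              fnirs_src$data[src_b, , , drop = FALSE], train = TRUE)
        fm$fnirs_extractor <- fn_src$layers
        fn_unl <- net_forward(fm$fnirs_extractor,
                              fnirs_tgt$data[unl_b, , , drop = FALSE], train = TRUE)
        fm$fnirs_extractor <- fn_unl$layers

        use_transfer <- cfg$transfer_scale != 0
        if (use_transfer) {
          tl_e <- transfer_loss(fe_src$out, fe_unl$out, cfg$dcca,
                                arm = cfg$loss_arm, grad = TRUE)
          tl_n <- transfer_loss(fn_src$out, fn_unl$out, cfg$dcca,
                                arm = cfg$loss_arm, grad = TRUE)
        } else {
          tl_e <- tl_n <- list(dcca = 0, coral = 0, mmd = 0, trans = 0)
        }
        bundle <- loss_bundle(ce$loss,
                              cfg$transfer_scale * tl_e$trans,
                              cfg$transfer_scale * tl_n$trans)
        L <- total_loss(bundle, w)

        # --- backward: head and classification path
        hb <- layer_backward(head[[1]], hd$cache, ce$dlogits)
        g_head <- list(hb$grads)
        d_fe_lab <- w$a * hb$dX[, seq_len(fm$d_eeg), drop = FALSE]
        d_fn_lab <- w$b * hb$dX[, fm$d_eeg + seq_len(fm$d_nirs), drop = FALSE]

        if (!cfg$freeze_extractors) {
          g_e <- net_backward(fm$eeg_extractor, fe_lab$caches, d_fe_lab)$grads
          g_n <- net_backward(fm$fnirs_extractor, fn_lab$caches, d_fn_lab)$grads
          if (use_transfer) {
            sa <- cfg$transfer_scale * w$a
            sb <- cfg$transfer_scale * w$b
            g_e <- grads_add(g_e, net_backward(fm$eeg_extractor, fe_src$caches,
                                               sa * tl_e$dFs)$grads)
            g_e <- grads_add(g_e, net_backward(fm$eeg_extractor, fe_unl$caches,
                                               sa * tl_e$dFt)$grads)
            g_n <- grads_add(g_n, net_backward(fm$fnirs_extractor, fn_src$caches,
                                               sb * tl_n$dFs)$grads)
            g_n <- grads_add(g_n, net_backward(fm$fnirs_extractor, fn_unl$caches,
                                               sb * tl_n$dFt)$grads)
          }
        }

        t_step <- t_step + 1L
        if (!cfg$freeze_extractors) {
          up <- adam_step(fm$eeg_extractor, g_e, st_e, lr = cfg$lr, t = t_step)
          fm$eeg_extractor <- up$layers; st_e <- up$state
          up <- adam_step(fm$fnirs_extractor, g_n, st_n, lr = cfg$lr, t = t_step)
          fm$fnirs_extractor <- up$layers; st_n <- up$state
        }
        up <- adam_step(head, g_head, st_h, lr = cfg$lr, t = t_step)
        head <- up$layers; st_h <- up$state

        ep_losses <- ep_losses + c(ce$loss, tl_e$dcca, tl_e$coral, tl_e$mmd,
                                   tl_n$dcca, tl_n$coral, tl_n$mmd, L)
        n_b <- n_b + 1L
      }
      log <- rbind(log, data.frame(epoch = ep,
                                   t(ep_losses / max(1L, n_b)),
                                   a = w$a, b = w$b))
    }
  })
  fm$head <- head[[1]]
  fm$loss_log <- log
  fm
}

#' Run transfer training for one target subject with cross-validation
#'
#' Implements the full transfer step of the framework: the per-modality
#' optimal source subjects provide the initial extractor parameters and the
#' source-domain feature batches; the target's labeled training folds supply
#' the classification loss and all target trials the (unlabeled) transfer
#' batches. The total loss is backpropagated with Adam (lr 0.001). Fold
#' metrics follow the evaluation module's stratified 5-fold protocol.
#'
#' @param population Named list of [subject_dataset()]s.
#' @param cfg A [transfer_run_config()].
#' @param checkpoints Named per-subject list with elements `eeg` / `fnirs`
#'   (trained [build_base_model()]s) and `acc_eeg` / `acc_fnirs`, as produced
#'   by [pretrain_population()].
#' @return List: `model` (fusion model from the last fold), `report`
#'   ([eval_report()] across folds), `fold_models` loss logs.
#' @export
train_transfer <- function(population, cfg, checkpoints) {
  for (id in c(cfg$source_eeg, cfg$source_fnirs, cfg$target))
    if (is.null(population[[id]]))
      stopf("subject '%s' not in population", id)
  if (cfg$target %in% c(cfg$source_eeg, cfg$source_fnirs))
    stopf("target subject must differ from the source subjects")
  for (id in unique(c(cfg$source_eeg, cfg$source_fnirs, cfg$target)))
    if (is.null(checkpoints[[id]]) || is.null(checkpoints[[id]]$eeg))
      stopf("missing checkpoint for subject '%s'; run pretrain_population() first",
            id)
  tgt <- population[[cfg$target]]
  eeg_src <- population[[cfg$source_eeg]]$eeg
  fnirs_src <- population[[cfg$source_fnirs]]$fnirs
  w <- fusion_weights(checkpoints[[cfg$target]]$acc_eeg,
                      checkpoints[[cfg$target]]$acc_fnirs)
  plan <- make_folds(tgt$eeg$labels, k = cfg$folds, seed = cfg$seed)
  fold_rows <- NULL
  cm_total <- matrix(0L, 2, 2)
  model <- NULL
  logs <- list()
  for (f in seq_along(plan$folds)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(tgt$eeg$labels), test_idx)
    fm <- build_fusion_model(checkpoints[[cfg$source_eeg]]$eeg,
                             checkpoints[[cfg$source_fnirs]]$fnirs, w,
                             seed = derive_seed(cfg$seed, f))
    fm <- transfer_fit(fm, eeg_src, fnirs_src, tgt$eeg, tgt$fnirs,
                       train_idx, cfg)
    pred <- predict_fusion(fm, tgt$eeg$data[test_idx, , , drop = FALSE],
                           tgt$fnirs$data[test_idx, , , drop = FALSE])
    cm <- confusion_counts(tgt$eeg$labels[test_idx], pred$labels)
    m <- metrics_from_confusion(cm)
    fold_rows <- rbind(fold_rows,
                       data.frame(fold = f, accuracy = m["accuracy"],
                                  precision = m["precision"],
                                  recall = m["recall"], f1 = m["f1"]))
    cm_total <- cm_total + cm
    logs[[f]] <- fm$loss_log
    model <- fm
  }
  label <- sprintf("%s source - %s", cfg$source_mode, toupper(cfg$loss_arm))
  list(model = model,
       report = eval_report(label, fold_rows, cm_total),
       fold_logs = logs)
}

#' Pretrain base networks for every subject
#'
#' Table-style steps 1-2 of the framework: trains an EEG and an fNIRS base
#' network per subject on a stratified 80/20 split and records the held-out
#' validation accuracies used by trusted scores and fusion weights.
#'
#' @param population Named list of [subject_dataset()]s.
#' @param spec_eeg,spec_fnirs [network_spec()]s matching the trial shapes.
#' @param epochs,batch_size,patience Training settings per [train_base()].
#' @param seed Master seed; per-subject seeds are derived deterministically.
#' @return Named list per subject: `eeg`, `fnirs` (trained models),
#'   `acc_eeg`, `acc_fnirs`.
#' @export
pretrain_population <- function(population, spec_eeg, spec_fnirs,
                                epochs = 30, batch_size = 16, patience = 10,
                                seed = 1L) {
  out <- list()
  for (i in seq_along(population)) {
    sd <- population[[i]]
    s <- derive_seed(seed, i)
    sp_e <- split_train_val(sd$eeg, seed = s)
    me <- build_base_model(spec_eeg, "EEG", seed = s)
    re <- train_base(me, sp_e$train, sp_e$val, epochs = epochs,
                     batch_size = batch_size, patience = patience, seed = s)
    sp_n <- split_train_val(sd$fnirs, seed = s + 1L)
    mn <- build_base_model(spec_fnirs, "FNIRS", seed = s + 1L)
    rn <- train_base(mn, sp_n$train, sp_n$val, epochs = epochs,
                     batch_size = batch_size, patience = patience,
                     seed = s + 1L)
    out[[sd$subject_id]] <- list(eeg = re$model, fnirs = rn$model,
                                 acc_eeg = re$val_accuracy,
                                 acc_fnirs = rn$val_accuracy)
  }
  out
}

#' Trusted-score source selection over a population
#'
#' Steps 3-4 of the framework: builds the per-modality Wasserstein distance
#' matrices and trusted-score tables from pretrained accuracies, and selects
#' the optimal source subject per modality (or jointly for the same-source
#' ablation arm).
#'
#' @param population Named list of [subject_dataset()]s.
#' @param checkpoints Output of [pretrain_population()].
#' @param exclude Subject ids to exclude from the candidate roster (e.g. the
#'   transfer target).
#' @return List: `eeg_table`, `fnirs_table` ([trusted_scores()] tables),
#'   `eeg_dm`, `fnirs_dm`, `source_eeg`, `source_fnirs`, `source_joint`.
#' @export
select_sources <- function(population, checkpoints, exclude = character(0)) {
  ids <- setdiff(names(population), exclude)
  if (length(ids) < 2) stopf("need at least 2 candidate source subjects")
  eeg_dm <- distance_matrix(lapply(population[ids], function(s) s$eeg))
  fnirs_dm <- distance_matrix(lapply(population[ids], function(s) s$fnirs))
  acc_e <- vapply(checkpoints[ids], function(c) c$acc_eeg, numeric(1))
  acc_n <- vapply(checkpoints[ids], function(c) c$acc_fnirs, numeric(1))
  names(acc_e) <- names(acc_n) <- ids
  te <- trusted_scores(acc_e, eeg_dm)
  tn <- trusted_scores(acc_n, fnirs_dm)
  list(eeg_table = te, fnirs_table = tn, eeg_dm = eeg_dm, fnirs_dm = fnirs_dm,
       source_eeg = select_source(te), source_fnirs = select_source(tn),
       source_joint = joint_trusted_selection(te, tn))
}
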