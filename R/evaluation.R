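#' Stratified k-fold plan
#'
#' Deterministic stratified partition of trial indices: within each class,
#' trials are shuffled with the seed and dealt across folds, so every fold
#' contains both classes and fold sizes differ by at most one per class.
#'
#' @param labels Integer 0/1 label vector.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return An object of class `fold_plan`: list of per-fold index vectors
#'   plus `k`, `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  for (cl in unique(labels))
    if (sum(labels == cl) < k)
      stopf("class %d has %d trials, fewer than k = %d folds",
            cl, sum(labels == cl), k)
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      grp <- rep(seq_len(k), length.out = length(idx))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
    }
  })
  structure(list(folds = lapply(folds, sort), k = k, seed = as.integer(seed),
                 stratified = TRUE), class = "fold_plan")
}

#' Confusion-matrix counts for binary predictions
#'
#' Rows are the true class (0 then 1), columns the predicted class. Class 0
#' (first class, "left" by convention) is the positive class.
#'
#' @param truth,pred Integer 0/1 vectors.
#' @return 2x2 integer matrix.
#' @export
confusion_counts <- function(truth, pred) {
  cm <- matrix(0L, 2, 2, dimnames = list(truth = c("0", "1"),
                                         pred = c("0", "1")))
  for (i in seq_along(truth))
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Standard binary accuracy, precision, recall and F1 with the positive
#' class fixed as class 0 (the first class). Degenerate denominators yield 0
#' with a `degenerate` attribute set.
#'
#' @param cm 2x2 non-negative integer count matrix (rows = truth).
#' @return Named numeric vector `(accuracy, precision, recall, f1)`.
#' @export
metrics_from_confusion <- function(cm) {
  if (any(cm < 0) || any(cm != round(cm)) || sum(cm) == 0)
    stopf("confusion matrix must hold non-negative counts with total > 0")
  tp <- cm[1, 1]; fn <- cm[1, 2]; fp <- cm[2, 1]; tn <- cm[2, 2]
  acc <- (tp + tn) / sum(cm)
  degenerate <- FALSE
  prec <- if (tp + fp == 0) { degenerate <- TRUE; 0 } else tp / (tp + fp)
  rec <- if (tp + fn == 0) { degenerate <- TRUE; 0 } else tp / (tp + fn)
  f1 <- if (prec + rec == 0) { degenerate <- TRUE; 0 } else
    2 * prec * rec / (prec + rec)
  out <- c(accuracy = acc, precision = prec, recall = rec, f1 = f1)
  attr(out, "degenerate") <- degenerate
  out
}

#' Friedman rank test across methods
#'
#' Non-parametric omnibus test for differences between related samples:
#' subjects are blocks, methods are treatments. Uses within-subject average
#' ranks and the tie-corrected chi-square statistic; the degenerate case of
#' all-constant rows returns statistic 0, p = 1.
#'
#' @param acc Numeric matrix `subjects x methods` (no missing cells).
#' @return List `(statistic, p_value, df, mean_ranks)`.
#' @export
friedman_test <- function(acc) {
  acc <- as.matrix(acc)
  n <- nrow(acc); k <- ncol(acc)
  if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 methods")
  if (any(!is.finite(acc))) stopf("missing or non-finite cells")
  R <- t(apply(acc, 1, rank))
  Rj <- colSums(R)
  num <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2)
  den <- sum(R^2) - n * k * (k + 1)^2 / 4
  if (den <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- num / den
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, df = k - 1,
       mean_ranks = stats::setNames(Rj / n, colnames(acc)))
}

#' Configuration for population-level evaluation
#'
#' @param spec_eeg,spec_fnirs Network specs matching the population's trial
#'   shapes.
#' @param epochs,batch_size,patience Training budget per model.
#' @param folds Cross-validation folds.
#' @param seed Master seed (fold plans are derived per subject from it and
#'   reused across method arms, so the Friedman test compares methods on
#'   identical partitions).
#' @return An `eval_config` list.
#' @export
eval_config <- function(spec_eeg, spec_fnirs, epochs = 20, batch_size = 16,
                        patience = 8, folds = 5L, seed = 1L) {
  list(spec_eeg = spec_eeg, spec_fnirs = spec_fnirs, epochs = epochs,
       batch_size = batch_size, patience = patience, folds = as.integer(folds),
       seed = as.integer(seed))
}

eval_method_arms <- function() {
  c("eeg_base", "fnirs_base", "linear_fusion_no_transfer",
    "ours", "coral_arm", "mmd_arm")
}

# Cross-validate one single-modality base network on one subject's own data.
cv_base_single <- function(ts, spec, modality, cfg, subj_seed) {
  plan <- make_folds(ts$labels, k = cfg$folds, seed = subj_seed)
  rows <- NULL
  cm_total <- matrix(0L, 2, 2)
  for (f in seq_along(plan$folds)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(ts$labels), test_idx)
    sub <- function(i) trial_set(ts$subject_id, ts$modality,
                                 ts$data[i, , , drop = FALSE], ts$labels[i],
                                 ts$fs, ts$channel_names, ts$classes)
    sp <- split_train_val(sub(train_idx), seed = derive_seed(subj_seed, f))
    model <- build_base_model(spec, modality, seed = derive_seed(subj_seed, f))
    model <- train_base(model, sp$train, sp$val, epochs = cfg$epochs,
                        batch_size = cfg$batch_size, patience = cfg$patience,
                        seed = derive_seed(subj_seed, f + 100L))$model
    pred <- predict_base(model, sub(test_idx))
    cm <- confusion_counts(ts$labels[test_idx], pred$labels)
    m <- metrics_from_confusion(cm)
    rows <- rbind(rows, data.frame(fold = f, accuracy = m["accuracy"],
                                   precision = m["precision"],
                                   recall = m["recall"], f1 = m["f1"]))
    cm_total <- cm_total + cm
  }
  eval_report(modality, rows, cm_total)
}

# Cross-validate the fusion model without transfer (fresh extractors, no
# transfer loss): the "linear fusion" baseline.
cv_fusion_baseline <- function(sd, cfg, subj_seed) {
  cfg_run <- transfer_run_config("_self", "_self", sd$subject_id,
                                 epochs = cfg$epochs,
                                 batch_size = cfg$batch_size,
                                 seed = subj_seed, transfer_scale = 0,
                                 folds = cfg$folds)
  plan <- make_folds(sd$eeg$labels, k = cfg$folds, seed = subj_seed)
  rows <- NULL
  cm_total <- matrix(0L, 2, 2)
  w <- fusion_weights(0.5, 0.5)
  for (f in seq_along(plan$folds)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(sd$eeg$labels), test_idx)
    s <- derive_seed(subj_seed, f)
    fm <- build_fusion_model(build_base_model(cfg$spec_eeg, "EEG", s),
                             build_base_model(cfg$spec_fnirs, "FNIRS", s + 1L),
                             w, seed = s + 2L)
    fm <- transfer_fit(fm, sd$eeg, sd$fnirs, sd$eeg, sd$fnirs,
                       train_idx, cfg_run)
    pred <- predict_fusion(fm, sd$eeg$data[test_idx, , , drop = FALSE],
                           sd$fnirs$data[test_idx, , , drop = FALSE])
    cm <- confusion_counts(sd$eeg$labels[test_idx], pred$labels)
    m <- metrics_from_confusion(cm)
    rows <- rbind(rows, data.frame(fold = f, accuracy = m["accuracy"],
                                   precision = m["precision"],
                                   recall = m["recall"], f1 = m["f1"]))
    cm_total <- cm_total + cm
  }
  eval_report("linear_fusion_no_transfer", rows, cm_total)
}

#' Evaluate a method arm over a whole population
#'
#' Runs one of the six comparison arms - the two single-modality base
#' networks, the no-transfer fusion baseline, and the three transfer arms
#' (full DCCA+CORAL, CORAL-only, MMD) - with stratified 5-fold
#' cross-validation per subject, reporting per-subject metrics and the
#' population mean +/- SD. Transfer arms pretrain the population once,
#' select sources by trusted score (excluding each target from its own
#' candidate roster), and transfer onto every remaining subject.
#'
#' @param population Named list of [subject_dataset()]s.
#' @param method One of `eeg_base`, `fnirs_base`, `linear_fusion_no_transfer`,
#'   `ours`, `coral_arm`, `mmd_arm`.
#' @param cfg An [eval_config()].
#' @param checkpoints Optional precomputed [pretrain_population()] output
#'   (reused across arms).
#' @return List: `per_subject` (named [eval_report()]s), `summary` data
#'   frame, `mean_accuracy`, `confusion` (pooled), `method`.
#' @export
evaluate_method <- function(population, method, cfg,
                            checkpoints = NULL) {
  if (!(method %in% eval_method_arms()))
    stopf("unknown method '%s'; valid arms: %s", method,
          paste(eval_method_arms(), collapse = ", "))
  ids <- names(population)
  reports <- list()
  if (method %in% c("ours", "coral_arm", "mmd_arm")) {
    arm <- switch(method, ours = "ours", coral_arm = "coral", mmd_arm = "mmd")
    if (is.null(checkpoints))
      checkpoints <- pretrain_population(population, cfg$spec_eeg,
                                         cfg$spec_fnirs, epochs = cfg$epochs,
                                         batch_size = cfg$batch_size,
                                         patience = cfg$patience,
                                         seed = cfg$seed)
    for (i in seq_along(ids)) {
      id <- ids[i]
      sel <- select_sources(population, checkpoints, exclude = id)
      run <- transfer_run_config(sel$source_eeg, sel$source_fnirs, id,
                                 epochs = cfg$epochs,
                                 batch_size = cfg$batch_size,
                                 seed = derive_seed(cfg$seed, i),
                                 loss_arm = arm, folds = cfg$folds)
      reports[[id]] <- train_transfer(population, run, checkpoints)$report
    }
  } else {
    for (i in seq_along(ids)) {
      id <- ids[i]
      s <- derive_seed(cfg$seed, i)
      reports[[id]] <- switch(method,
        eeg_base = cv_base_single(population[[id]]$eeg, cfg$spec_eeg, "EEG",
                                  cfg, s),
        fnirs_base = cv_base_single(population[[id]]$fnirs, cfg$spec_fnirs,
                                    "FNIRS", cfg, s),
        linear_fusion_no_transfer = cv_fusion_baseline(population[[id]], cfg, s))
    }
  }
  summary <- do.call(rbind, lapply(ids, function(id) {
    r <- reports[[id]]
    data.frame(subject_id = id, accuracy = r$mean["accuracy"],
               precision = r$mean["precision"], recall = r$mean["recall"],
               f1 = r$mean["f1"], stringsAsFactors = FALSE)
  }))
  cm <- Reduce(`+`, lapply(reports, function(r) r$confusion_matrix))
  list(per_subject = reports, summary = summary,
       mean_accuracy = mean(summary$accuracy), confusion = cm,
       method = method)
}

#' Write an evaluation summary to CSV
#' @param result Output of [evaluate_method()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_eval_csv <- function(result, path) {
  utils::write.csv(result$summary, path, row.names = FALSE)
  invisible(path)
}
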