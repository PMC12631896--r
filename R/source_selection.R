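#' Order-1 Wasserstein distance between two empirical distributions
#'
#' Earth-Mover's distance between equal-weight sample sets, computed through
#' the quantile-function (sorted) coupling, which is exact in one dimension:
#' `W1 = integral |F_p^{-1}(u) - F_q^{-1}(u)| du`. Sample counts may differ.
#'
#' @param p_samples,q_samples Non-empty finite numeric vectors.
#' @return Non-negative scalar distance.
#' @export
wasserstein_1d <- function(p_samples, q_samples) {
  if (!length(p_samples) || !length(q_samples))
    stopf("wasserstein_1d: empty sample set")
  if (!all(is.finite(p_samples)) || !all(is.finite(q_samples)))
    stopf("wasserstein_1d: non-finite samples")
  np <- length(p_samples); nq <- length(q_samples)
  if (np == nq) return(mean(abs(sort(p_samples) - sort(q_samples))))
  # merge the two quantile grids: piecewise-constant quantile functions
  u <- sort(unique(c(seq_len(np) / np, seq_len(nq) / nq)))
  widths <- diff(c(0, u))
  ps <- sort(p_samples); qs <- sort(q_samples)
  qp <- ps[pmin(np, ceiling(u * np - 1e-12))]
  qq <- qs[pmin(nq, ceiling(u * nq - 1e-12))]
  sum(widths * abs(qp - qq))
}

#' Wasserstein distance between two subjects' recordings
#'
#' The paper-level inter-subject divergence: per channel, all preprocessed
#' trial samples of a subject are pooled into one empirical 1-D distribution;
#' the distance is the mean over channels of the channelwise order-1
#' Wasserstein distance. Symmetric by construction.
#'
#' @param a,b [trial_set()] objects of the same modality and channel count.
#' @return Non-negative scalar.
#' @export
subject_distance <- function(a, b) {
  if (a$modality != b$modality)
    stopf("modality mismatch: %s vs %s", a$modality, b$modality)
  if (dim(a$data)[2] != dim(b$data)[2])
    stopf("channel count mismatch: %d vs %d", dim(a$data)[2], dim(b$data)[2])
  ch_d <- vapply(seq_len(dim(a$data)[2]), function(ch)
    wasserstein_1d(as.vector(a$data[, ch, ]), as.vector(b$data[, ch, ])),
    numeric(1))
  mean(ch_d)
}

#' Pairwise inter-subject Wasserstein distance matrix
#'
#' The similarity matrix underlying source selection: a full symmetric,
#' zero-diagonal matrix of [subject_distance()] values, plus each subject's
#' mean distance to all others (self-term excluded).
#'
#' @param subjects Named list of [trial_set()] objects (>= 2), one modality.
#' @return An object of class `distance_matrix` with fields `values`,
#'   `subject_ids`, `modality`, and `mean_distance`.
#' @export
distance_matrix <- function(subjects) {
  n <- length(subjects)
  if (n < 2) stopf("need at least 2 subjects, got %d", n)
  ids <- vapply(subjects, function(s) s$subject_id, character(1))
  if (is.null(names(subjects))) names(subjects) <- ids
  V <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) {
      V[i, j] <- subject_distance(subjects[[i]], subjects[[j]])
      V[j, i] <- V[i, j]
    }
  structure(list(values = V, subject_ids = ids,
                 modality = subjects[[1]]$modality,
                 mean_distance = rowSums(V) / (n - 1)),
            class = "distance_matrix")
}

#' Trusted scores for source-domain selection
#'
#' Balances classification skill against distributional typicality:
#' `T_k = Acc_k * (1 - Norm(mean_k W(k, i)))`, where `Norm` is min-max
#' normalization of the per-subject mean Wasserstein distances across the
#' roster. When all mean distances are equal the normalization is degenerate
#' and `Norm` is defined as 0, so `T_k = Acc_k`.
#'
#' @param acc Named numeric vector of per-subject validation accuracies in
#'   `[0, 1]`, aligned with (or named by) the distance-matrix subject order.
#' @param dm A [distance_matrix()].
#' @return An object of class `trusted_score_table`: data frame with
#'   `subject_id`, `acc`, `mean_distance`, `normalized_distance`, `trusted`.
#' @export
trusted_scores <- function(acc, dm) {
  ids <- dm$subject_ids
  if (!is.null(names(acc))) {
    if (!setequal(names(acc), ids))
      stopf("accuracy names do not match distance-matrix subjects")
    acc <- acc[ids]
  } else if (length(acc) != length(ids)) {
    stopf("accuracy vector length %d does not match %d subjects",
          length(acc), length(ids))
  }
  if (any(acc < 0 | acc > 1)) stopf("accuracies must lie in [0, 1]")
  md <- dm$mean_distance
  rng <- range(md)
  norm <- if (diff(rng) <= 0) rep(0, length(md)) else (md - rng[1]) / diff(rng)
  tab <- data.frame(subject_id = ids, acc = as.numeric(acc),
                    mean_distance = as.numeric(md),
                    normalized_distance = norm,
                    trusted = as.numeric(acc) * (1 - norm),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("trusted_score_table", "data.frame"))
}

#' Select the optimal source subject from a trusted-score table
#'
#' Argmax of the trusted score; ties broken by higher accuracy, then lower
#' mean distance, then lexicographic subject id (fully deterministic).
#'
#' @param table A [trusted_scores()] table.
#' @return The selected `subject_id` (character).
#' @export
select_source <- function(table) {
  if (!nrow(table)) stopf("empty trusted-score table")
  o <- order(-table$trusted, -table$acc, table$mean_distance,
             table$subject_id)
  table$subject_id[o[1]]
}

#' Joint (same-source) selection across both modalities
#'
#' The "same source" ablation arm: picks the subject maximizing the sum of
#' its EEG and fNIRS trusted scores.
#'
#' @param eeg_table,fnirs_table [trusted_scores()] tables over the same
#'   subject roster.
#' @return The selected `subject_id`.
#' @export
joint_trusted_selection <- function(eeg_table, fnirs_table) {
  if (!setequal(eeg_table$subject_id, fnirs_table$subject_id))
    stopf("EEG and fNIRS tables cover different subject rosters")
  f <- fnirs_table[match(eeg_table$subject_id, fnirs_table$subject_id), ]
  joint <- eeg_table$trusted + f$trusted
  o <- order(-joint, -(eeg_table$acc + f$acc),
             eeg_table$mean_distance + f$mean_distance,
             eeg_table$subject_id)
  eeg_table$subject_id[o[1]]
}
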