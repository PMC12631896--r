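as_feature_matrix <- function(F) {
  if (inherits(F, "feature_batch")) F$values else as.matrix(F)
}

#' DCCA configuration
#'
#' @param k Number of canonical components whose correlations are summed
#'   (default: `min(d, n - 1)` capped at 10, resolved at evaluation time when
#'   `NULL`).
#' @param r Ridge added to both covariance matrices (default 1e-3).
#' @param epsilon Eigenvalue floor used when forming inverse square roots.
#' @return An object of class `dcca_config`.
#' @export
dcca_config <- function(k = NULL, r = 1e-3, epsilon = 1e-8) {
  if (r <= 0) stopf("ridge r must be > 0")
  structure(list(k = k, r = r, epsilon = epsilon), class = "dcca_config")
}

# symmetric inverse square root with eigenvalue floor
inv_sqrt_sym <- function(S, floor_ev = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, floor_ev)
  e$vectors %*% (t(e$vectors) / sqrt(ev))
}

#' Deep CORAL loss
#'
#' Correlation-alignment domain-adaptation loss: the squared Frobenius
#' distance between the unbiased feature covariance matrices of the source
#' and target batches, scaled by `1 / (4 d^2)`. Zero iff the covariances
#' agree; invariant to feature translation.
#'
#' @param F_s,F_t Feature batches (`n x d` matrices or [feature_batch()]),
#'   equal `d`, each with at least 2 rows.
#' @param grad If `TRUE`, also return analytic gradients with respect to both
#'   batches.
#' @return Scalar loss, or (with `grad`) list `(loss, dFs, dFt)`.
#' @export
coral_loss <- function(F_s, F_t, grad = FALSE) {
  Xs <- as_feature_matrix(F_s); Xt <- as_feature_matrix(F_t)
  if (ncol(Xs) != ncol(Xt))
    stopf("feature dimension mismatch: %d vs %d", ncol(Xs), ncol(Xt))
  if (nrow(Xs) < 2 || nrow(Xt) < 2)
    stopf("covariance needs at least 2 rows per batch")
  d <- ncol(Xs)
  Xs_c <- scale(Xs, center = TRUE, scale = FALSE)
  Xt_c <- scale(Xt, center = TRUE, scale = FALSE)
  Cs <- crossprod(Xs_c) / (nrow(Xs) - 1)
  Ct <- crossprod(Xt_c) / (nrow(Xt) - 1)
  Delta <- Cs - Ct
  loss <- sum(Delta^2) / (4 * d^2)
  if (!grad) return(loss)
  list(loss = loss,
       dFs = Xs_c %*% Delta / (d^2 * (nrow(Xs) - 1)),
       dFt = -Xt_c %*% Delta / (d^2 * (nrow(Xt) - 1)))
}

#' Deep CCA correlation loss
#'
#' The negative total canonical correlation between two paired feature
#' batches: with ridge-regularized covariances `H_ss`, `H_tt` and
#' cross-covariance `H_st`, the loss is minus the sum of the top-k singular
#' values of `T = H_ss^{-1/2} H_st H_tt^{-1/2}`. Lies in `[-k, 0]`; reaches
#' `-k` when the batches are perfectly correlated in k components (ridge -> 0).
#' Differentiable in both inputs.
#'
#' @param F_s,F_t Paired feature batches with the same row count `n >= 2`.
#' @param cfg A [dcca_config()].
#' @param grad If `TRUE`, also return analytic gradients.
#' @return Scalar loss, or list `(loss, dFs, dFt)`.
#' @export
dcca_loss <- function(F_s, F_t, cfg = dcca_config(), grad = FALSE) {
  Xs <- as_feature_matrix(F_s); Xt <- as_feature_matrix(F_t)
  n <- nrow(Xs)
  if (nrow(Xt) != n)
    stopf("DCCA pairs batches by position: %d vs %d rows", n, nrow(Xt))
  if (n < 2) stopf("DCCA needs at least 2 paired rows")
  ds <- ncol(Xs); dt_ <- ncol(Xt)
  k <- cfg$k %||% min(ds, dt_, n - 1, 10L)
  if (k < 1 || k > min(ds, dt_))
    stopf("k = %d infeasible for feature dimensions (%d, %d)", k, ds, dt_)
  H1 <- t(scale(Xs, center = TRUE, scale = FALSE))  # d_s x n
  H2 <- t(scale(Xt, center = TRUE, scale = FALSE))
  S11 <- tcrossprod(H1) / (n - 1) + cfg$r * diag(ds)
  S22 <- tcrossprod(H2) / (n - 1) + cfg$r * diag(dt_)
  S12 <- tcrossprod(H1, H2) / (n - 1)
  K11 <- inv_sqrt_sym(S11, cfg$epsilon)
  K22 <- inv_sqrt_sym(S22, cfg$epsilon)
  Tm <- K11 %*% S12 %*% K22
  sv <- svd(Tm, nu = k, nv = k)
  corr <- sum(sv$d[seq_len(k)])
  if (!grad) return(-corr)
  U <- sv$u; V <- sv$v; D <- diag(sv$d[seq_len(k)], k, k)
  Delta12 <- K11 %*% U %*% t(V) %*% K22
  Delta11 <- -0.5 * K11 %*% U %*% D %*% t(U) %*% K11
  Delta22 <- -0.5 * K22 %*% V %*% D %*% t(V) %*% K22
  dH1 <- (2 * Delta11 %*% H1 + Delta12 %*% H2) / (n - 1)
  dH2 <- (2 * Delta22 %*% H2 + t(Delta12) %*% H1) / (n - 1)
  center_rows <- function(A) A - rowMeans(A)  # backprop through centering
  list(loss = -corr,
       dFs = -t(center_rows(dH1)),
       dFt = -t(center_rows(dH2)))
}

#' Maximum mean discrepancy (ablation baseline)
#'
#' Unbiased squared-MMD estimator with a multi-bandwidth Gaussian kernel,
#' the established transfer-loss baseline the framework is compared against.
#'
#' @param F_s,F_t Feature batches with equal dimension, >= 2 rows each.
#' @param bandwidths Gaussian kernel bandwidths (squared-distance scale);
#'   default: `(0.5, 1, 2) x` median pairwise squared distance.
#' @param grad If `TRUE`, also return analytic gradients.
#' @param biased Use the biased V-statistic (exactly 0 for identical batches).
#' @return Scalar loss, or list `(loss, dFs, dFt)`.
#' @export
mmd_loss <- function(F_s, F_t, bandwidths = NULL, grad = FALSE,
                     biased = FALSE) {
  X <- as_feature_matrix(F_s); Y <- as_feature_matrix(F_t)
  if (ncol(X) != ncol(Y))
    stopf("feature dimension mismatch: %d vs %d", ncol(X), ncol(Y))
  m <- nrow(X); n <- nrow(Y)
  if (m < 2 || n < 2) stopf("MMD estimator needs >= 2 rows per batch")
  sq <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  Dxx <- sq(X, X); Dyy <- sq(Y, Y); Dxy <- sq(X, Y)
  if (is.null(bandwidths)) {
    med <- stats::median(c(Dxy, Dxx[upper.tri(Dxx)], Dyy[upper.tri(Dyy)]))
    if (med <= 0) med <- 1
    bandwidths <- med * c(0.5, 1, 2)
  }
  loss <- 0
  dX <- if (grad) matrix(0, m, ncol(X)) else NULL
  dY <- if (grad) matrix(0, n, ncol(Y)) else NULL
  for (bw in bandwidths) {
    g <- 1 / (2 * bw)
    Kxx <- exp(-g * Dxx); Kyy <- exp(-g * Dyy); Kxy <- exp(-g * Dxy)
    if (biased) {
      loss <- loss + mean(Kxx) + mean(Kyy) - 2 * mean(Kxy)
      wxx <- 1 / m^2; wyy <- 1 / n^2
    } else {
      diag(Kxx) <- 0; diag(Kyy) <- 0
      loss <- loss + sum(Kxx) / (m * (m - 1)) + sum(Kyy) / (n * (n - 1)) -
        2 * mean(Kxy)
      wxx <- 1 / (m * (m - 1)); wyy <- 1 / (n * (n - 1))
    }
    if (grad) {
      # d/dx exp(-g ||x-y||^2) = -2 g (x - y) K
      dX <- dX - 4 * g * wxx * (rowSums(Kxx) * X - Kxx %*% X) +
        4 * g / (m * n) * (rowSums(Kxy) * X - Kxy %*% Y)
      dY <- dY - 4 * g * wyy * (rowSums(Kyy) * Y - Kyy %*% Y) +
        4 * g / (m * n) * (colSums(Kxy) * Y - t(Kxy) %*% X)
    }
  }
  if (!grad) return(loss)
  list(loss = loss, dFs = dX, dFt = dY)
}

#' Combined transfer loss
#'
#' The per-modality transfer objective: `L_trans = L_dcca + L_coral` (the
#' `"ours"` arm), or a single component for the `"coral"` / `"mmd"` ablation
#' arms.
#'
#' @param F_s,F_t Feature batches.
#' @param cfg A [dcca_config()].
#' @param arm `"ours"` (DCCA + CORAL), `"coral"`, or `"mmd"`.
#' @param grad If `TRUE` include gradients.
#' @return List with `dcca`, `coral`, `mmd` (as applicable), `trans`, and
#'   with `grad` the combined `dFs`, `dFt`.
#' @export
transfer_loss <- function(F_s, F_t, cfg = dcca_config(),
                          arm = c("ours", "coral", "mmd"), grad = FALSE) {
  arm <- match.arg(arm)
  out <- list(dcca = 0, coral = 0, mmd = 0)
  zero <- function(F) matrix(0, nrow(as_feature_matrix(F)),
                             ncol(as_feature_matrix(F)))
  dFs <- if (grad) zero(F_s) else NULL
  dFt <- if (grad) zero(F_t) else NULL
  add <- function(res, name) {
    if (grad) {
      out[[name]] <<- res$loss
      dFs <<- dFs + res$dFs
      dFt <<- dFt + res$dFt
    } else out[[name]] <<- res
  }
  if (arm == "ours") {
    add(dcca_loss(F_s, F_t, cfg, grad = grad), "dcca")
    add(coral_loss(F_s, F_t, grad = grad), "coral")
  } else if (arm == "coral") {
    add(coral_loss(F_s, F_t, grad = grad), "coral")
  } else {
    add(mmd_loss(F_s, F_t, grad = grad), "mmd")
  }
  out$trans <- out$dcca + out$coral + out$mmd
  if (grad) {
    out$dFs <- dFs
    out$dFt <- dFt
  }
  out
}
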