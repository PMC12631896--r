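#' Base-network architecture specification
#'
#' Describes the three-block convolutional feature extractor plus linear
#' classifier shared by the EEG and fNIRS base networks: two plain 1-D
#' convolutions (each followed by batch normalization and a sigmoid), average
#' pooling, a depthwise separable convolution block, a second pooling stage,
#' flatten, and a 2-logit linear classifier. Filter counts follow the
#' F1 / F2 = F1 * D convention (defaults F1 = 16, D = 4).
#'
#' @param input_channels,input_samples Input trial shape.
#' @param F1 First-stage filter count (default 16).
#' @param D Depth multiplier; F2 = F1 * D (default 4).
#' @param kernel1,pad1,crop1 Conv1 temporal kernel, zero padding, and number
#'   of trailing output samples to crop (crop reconciles printed architecture
#'   lengths that the convolution formula misses by one).
#' @param kernel2,pad2 Conv2 kernel and padding.
#' @param pool1 First average-pooling factor.
#' @param kernel3,pad3 Depthwise separable Conv3 kernel and padding.
#' @param pool2 Second pooling factor (used when `pool2_out` is `NULL`).
#' @param pool2_out If non-`NULL`, the second pooling stage is adaptive
#'   average pooling to exactly this output length.
#' @param n_classes Number of classes (fixed at 2).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_channels, input_samples, F1 = 16, D = 4,
                         kernel1, pad1 = (kernel1 - 1) %/% 2, crop1 = 0,
                         kernel2, pad2 = 0, pool1 = 4,
                         kernel3 = 15, pad3 = (kernel3 - 1) %/% 2,
                         pool2 = 2, pool2_out = NULL, n_classes = 2) {
  if (n_classes != 2) stopf("the classifier head is binary (n_classes = 2)")
  sp <- structure(list(
    input_channels = as.integer(input_channels),
    input_samples = as.integer(input_samples),
    F1 = as.integer(F1), D = as.integer(D), F2 = as.integer(F1 * D),
    kernel1 = as.integer(kernel1), pad1 = as.integer(pad1),
    crop1 = as.integer(crop1),
    kernel2 = as.integer(kernel2), pad2 = as.integer(pad2),
    pool1 = as.integer(pool1),
    kernel3 = as.integer(kernel3), pad3 = as.integer(pad3),
    pool2 = as.integer(pool2), pool2_out = pool2_out,
    n_classes = 2L
  ), class = "network_spec")
  invisible(spec_lengths(sp))  # validates all intermediate lengths
  sp
}

#' Output length of a convolution or pooling layer
#'
#' `conv`: `L_in + 2*padding - kernel + 1`; `pool`: `floor(L_in / kernel)`.
#'
#' @param L_in Input temporal length in samples.
#' @param kernel Kernel size (conv) or pooling factor (pool).
#' @param padding Zero padding per side (conv only).
#' @param stride Stride (only 1 supported for conv).
#' @param op_kind `"conv"` or `"pool"`.
#' @return Integer output length.
#' @export
layer_output_length <- function(L_in, kernel, padding = 0, stride = 1,
                                op_kind = c("conv", "pool")) {
  op_kind <- match.arg(op_kind)
  out <- if (op_kind == "conv") {
    if (L_in < kernel - 2 * padding) stopf(
      "conv layer: input length %d shorter than kernel %d minus padding", L_in, kernel)
    (L_in + 2 * padding - kernel + 1) %/% stride
  } else {
    L_in %/% kernel
  }
  if (out < 1)
    stopf("%s layer with input %d, kernel %d yields non-positive length %d",
          op_kind, L_in, kernel, out)
  as.integer(out)
}

# The temporal-length chain through the extractor, by layer.
spec_lengths <- function(sp) {
  L1 <- layer_output_length(sp$input_samples, sp$kernel1, sp$pad1, 1, "conv") -
    sp$crop1
  if (L1 < 1) stopf("crop1 leaves non-positive Conv1 length")
  L2 <- layer_output_length(L1, sp$kernel2, sp$pad2, 1, "conv")
  Lp1 <- layer_output_length(L2, sp$pool1, op_kind = "pool")
  L3 <- layer_output_length(Lp1, sp$kernel3, sp$pad3, 1, "conv")
  Lp2 <- if (is.null(sp$pool2_out)) {
    layer_output_length(L3, sp$pool2, op_kind = "pool")
  } else as.integer(sp$pool2_out)
  list(conv1 = L1, conv2 = L2, pool1 = Lp1, conv3 = L3, pool2 = Lp2,
       flatten = sp$F2 * Lp2)
}

#' @rdname network_spec
#' @return `flatten_length`: the flattened feature dimension the classifier
#'   consumes (`F2 * final pooled length`).
#' @param spec A `network_spec`.
#' @export
flatten_length <- function(spec) spec_lengths(spec)$flatten

#' @rdname network_spec
#' @export
eeg_network_spec <- function() {
  network_spec(30, 2000, F1 = 16, D = 4,
               kernel1 = 63, pad1 = 31,
               kernel2 = 30, pad2 = 0, pool1 = 4,
               kernel3 = 15, pad3 = 7, pool2 = 2)
}

#' @rdname network_spec
#' @param strict_formula Use the plain convolution/pooling formulas instead of
#'   the crop / adaptive-pooling reconciliation of the printed lengths.
#' @export
fnirs_network_spec <- function(strict_formula = FALSE) {
  if (strict_formula) {
    network_spec(36, 100, F1 = 16, D = 4,
                 kernel1 = 36, pad1 = 18, crop1 = 0,
                 kernel2 = 101, pad2 = 50, pool1 = 4,
                 kernel3 = 15, pad3 = 7, pool2 = 2)
  } else {
    # Conv1 prints 100 where the formula gives 101 (crop one sample); the
    # final pooled length prints 17 where floor(25/2) gives 12 (adaptive
    # average pooling 25 -> 17, matching the prose).
    network_spec(36, 100, F1 = 16, D = 4,
                 kernel1 = 36, pad1 = 18, crop1 = 1,
                 kernel2 = 101, pad2 = 50, pool1 = 4,
                 kernel3 = 15, pad3 = 7, pool2_out = 17L)
  }
}

#' @rdname network_spec
#' @param input_channels,input_samples Trial shape the scaled spec must accept.
#' @details `scaled_network_spec()` keeps the architecture family but scales
#'   kernel sizes to an arbitrary (typically much smaller) trial shape, for
#'   fast simulation studies.
#' @export
scaled_network_spec <- function(input_channels, input_samples, F1 = 4, D = 2) {
  odd <- function(x) { x <- max(3L, as.integer(x)); if (x %% 2 == 0) x + 1L else x }
  k1 <- odd(round(input_samples / 32))
  k2 <- max(2L, as.integer(round(input_samples / 64)))
  L2 <- layer_output_length(input_samples, k2, 0, 1, "conv")
  p1 <- if (L2 >= 8) 4L else 2L
  Lp1 <- L2 %/% p1
  k3 <- odd(min(15L, max(3L, Lp1 %/% 3)))
  network_spec(input_channels, input_samples, F1 = F1, D = D,
               kernel1 = k1, kernel2 = k2, pool1 = p1,
               kernel3 = k3, pool2 = 2)
}

#' Build a base model (feature extractor + classifier)
#'
#' Instantiates the network a [network_spec()] describes: three convolution
#' blocks (1-D convolution, batch normalization, sigmoid), average pooling
#' after the second and third blocks, flatten, and a single linear map to two
#' logits. The third block is depthwise separable: a per-channel temporal
#' convolution followed by a pointwise (1x1) cross-channel convolution.
#' Initialization is a fixed-seed uniform fan-in scheme.
#'
#' @param spec A [network_spec()].
#' @param modality `"EEG"` or `"FNIRS"` (metadata only).
#' @param seed Initialization seed.
#' @return An object of class `base_model`.
#' @export
build_base_model <- function(spec, modality = "EEG", seed = 1L) {
  len <- spec_lengths(spec)
  pool2 <- if (is.null(spec$pool2_out)) nn_avgpool(spec$pool2) else
    nn_adaptive_avgpool(spec$pool2_out)
  layers <- with_seed(seed, list(
    nn_conv1d(spec$input_channels, spec$F1, spec$kernel1, spec$pad1, spec$crop1),
    nn_batchnorm(spec$F1),
    nn_sigmoid(),
    nn_conv1d(spec$F1, spec$F2, spec$kernel2, spec$pad2),
    nn_batchnorm(spec$F2),
    nn_sigmoid(),
    nn_avgpool(spec$pool1),
    nn_sepconv1d(spec$F2, spec$F2, spec$kernel3, spec$pad3),
    nn_batchnorm(spec$F2),
    nn_sigmoid(),
    pool2,
    nn_flatten(),
    nn_linear(len$flatten, 2L)
  ))
  structure(list(layers = layers, flatten_index = 12L, spec = spec,
                 modality = toupper(modality),
                 meta = list(seed = as.integer(seed))),
            class = "base_model")
}

#' @export
print.base_model <- function(x, ...) {
  len <- spec_lengths(x$spec)
  cat(sprintf("<base_model> %s: %d ch x %d samples -> %d features -> 2 logits\n",
              x$modality, x$spec$input_channels, x$spec$input_samples,
              len$flatten))
  if (!is.null(x$meta$val_accuracy))
    cat(sprintf("  trained: val accuracy %.3f\n", x$meta$val_accuracy))
  invisible(x)
}

check_trial_shape <- function(model, ts) {
  d <- dim(ts$data)
  if (d[2] != model$spec$input_channels || d[3] != model$spec$input_samples)
    stopf("trial shape %d ch x %d samples does not match model input %d x %d",
          d[2], d[3], model$spec$input_channels, model$spec$input_samples)
}

#' Feature batch: flattened extractor outputs
#'
#' @param values `n x d` numeric matrix, one row per trial.
#' @param subject_id Producing subject.
#' @param domain_tag `"source"` or `"target"`.
#' @return An object of class `feature_batch`.
#' @export
feature_batch <- function(values, subject_id = "unknown",
                          domain_tag = c("source", "target")) {
  domain_tag <- match.arg(domain_tag)
  if (!all(is.finite(values))) stopf("feature batch contains non-finite values")
  structure(list(values = as.matrix(values), subject_id = subject_id,
                 domain_tag = domain_tag), class = "feature_batch")
}

#' Extract flattened features from a trial set
#'
#' Runs the extractor (through the flatten layer, batch-norm in evaluation
#' mode) on every trial. Deterministic for fixed model parameters.
#'
#' @param model A trained or fresh [build_base_model()].
#' @param ts A [trial_set()] matching the model's input shape.
#' @param domain_tag Tag recorded on the output batch.
#' @return A [feature_batch()] with one row per trial.
#' @export
extract_features <- function(model, ts, domain_tag = "source") {
  check_trial_shape(model, ts)
  out <- net_forward(model$layers, ts$data, train = FALSE,
                     upto = model$flatten_index)$out
  feature_batch(out, ts$subject_id, domain_tag)
}

#' Predict class labels for a trial set
#'
#' @param model A [build_base_model()].
#' @param ts A [trial_set()].
#' @return List with integer `labels` (0/1) and `probs` (`n x 2`).
#' @export
predict_base <- function(model, ts) {
  check_trial_shape(model, ts)
  logits <- net_forward(model$layers, ts$data, train = FALSE)$out
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  list(labels = as.integer(max.col(p) - 1L), probs = p)
}

#' Train a base network
#'
#' Minimizes softmax cross-entropy with Adam (learning rate 0.001) on
#' mini-batches, evaluating held-out accuracy each epoch and keeping the
#' best-scoring parameters (early stopping). The recorded validation accuracy
#' `Acc_k` feeds the trusted-score source selection and the fusion mixing
#' ratio downstream. Reproducible for a fixed seed.
#'
#' @param model A [build_base_model()].
#' @param train,val [trial_set()] splits; the training split must contain
#'   both classes.
#' @param lr Adam learning rate.
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed RNG seed for shuffling.
#' @return List `(model, val_accuracy)`; the model's `meta` records the
#'   training configuration and accuracy.
#' @export
train_base <- function(model, train, val, lr = 0.001, epochs = 200,
                       batch_size = 16, patience = 20, seed = 1L) {
  if (length(unique(train$labels)) < 2)
    stopf("training set contains a single class; cannot fit a discriminator")
  if (!dim(val$data)[1]) stopf("validation set is empty")
  check_trial_shape(model, train)
  n <- dim(train$data)[1]
  layers <- model$layers
  state <- adam_init(layers)
  best <- list(acc = -1, layers = layers)
  t_step <- 0L
  with_seed(seed, {
    stall <- 0L
    for (ep in seq_len(epochs)) {
      idx <- sample.int(n)
      for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
        if (length(b) < 2) next  # batch norm needs > 1 sample
        fw <- net_forward(layers, train$data[b, , , drop = FALSE], train = TRUE)
        layers <- fw$layers
        ce <- softmax_xent(fw$out, train$labels[b])
        bw <- net_backward(layers, fw$caches, ce$dlogits)
        t_step <- t_step + 1L
        upd <- adam_step(layers, bw$grads, state, lr = lr, t = t_step)
        layers <- upd$layers
        state <- upd$state
      }
      model$layers <- layers
      acc <- mean(predict_base(model, val)$labels == val$labels)
      if (acc > best$acc + 1e-12) {
        best <- list(acc = acc, layers = layers)
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= patience) break
    }
  })
  model$layers <- best$layers
  model$meta <- c(model$meta[setdiff(names(model$meta),
                                     c("val_accuracy", "lr", "epochs"))],
                  list(val_accuracy = best$acc, lr = lr, epochs = epochs,
                       batch_size = batch_size, train_seed = as.integer(seed),
                       val_split = "held-out"))
  list(model = model, val_accuracy = best$acc)
}

#' Split a trial set into stratified train / validation parts
#'
#' @param ts A [trial_set()].
#' @param val_fraction Fraction of trials per class held out (default 0.2).
#' @param seed RNG seed.
#' @return List with `train` and `val` trial sets.
#' @export
split_train_val <- function(ts, val_fraction = 0.2, seed = 1L) {
  n <- dim(ts$data)[1]
  val_idx <- with_seed(seed, {
    unlist(lapply(unique(ts$labels), function(cl) {
      cand <- which(ts$labels == cl)
      sample(cand, max(1L, round(length(cand) * val_fraction)))
    }))
  })
  subset_ts <- function(i) trial_set(ts$subject_id, ts$modality,
                                     ts$data[i, , , drop = FALSE],
                                     ts$labels[i], ts$fs, ts$channel_names,
                                     ts$classes)
  list(train = subset_ts(setdiff(seq_len(n), val_idx)),
       val = subset_ts(sort(val_idx)))
}

#' Count trainable parameters of a model or layer stack
#' @param model A `base_model`, `fusion_model`, or list of layers.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  layers <- if (!is.null(model$layers)) model$layers else model
  sum(vapply(layers, function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))
}
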