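# Minimal 1-D CNN engine with manual backpropagation.
#
# No deep-learning framework is available in this environment, so the layers
# the base networks need -- 1-D convolution, depthwise separable convolution,
# batch normalization, sigmoid, (adaptive) average pooling, flatten, linear --
# are implemented directly on R arrays, together with Adam. Batches are
# arrays [n_trials, channels, samples]; convolutions are evaluated as im2col
# matrix products. Gradient correctness is pinned by finite-difference tests.

uniform_init <- function(dims, fan_in, rng) {
  s <- sqrt(1 / fan_in)
  array(stats::runif(prod(dims), -s, s), dim = dims)
}

nn_conv1d <- function(in_ch, out_ch, kernel, padding = 0, crop = 0) {
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       padding = padding, crop = crop,
       params = list(W = uniform_init(c(out_ch, in_ch * kernel), in_ch * kernel),
                     b = numeric(out_ch)))
}

nn_sepconv1d <- function(ch, out_ch, kernel, padding = 0, crop = 0) {
  list(type = "sepconv1d", in_ch = ch, out_ch = out_ch, kernel = kernel,
       padding = padding, crop = crop,
       params = list(Wd = uniform_init(c(ch, kernel), kernel),
                     Wp = uniform_init(c(out_ch, ch), ch),
                     b = numeric(out_ch)))
}

nn_batchnorm <- function(ch, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", ch = ch, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, ch), beta = numeric(ch)),
       running_mean = numeric(ch), running_var = rep(1, ch))
}

nn_sigmoid <- function() list(type = "sigmoid", params = list())

nn_avgpool <- function(factor) {
  list(type = "avgpool", factor = as.integer(factor), params = list())
}

# PyTorch-style adaptive average pooling to a fixed output length.
nn_adaptive_avgpool <- function(out_len) {
  list(type = "adaptive_avgpool", out_len = as.integer(out_len), params = list())
}

nn_flatten <- function() list(type = "flatten", params = list())

nn_linear <- function(d_in, d_out) {
  list(type = "linear", d_in = d_in, d_out = d_out,
       params = list(W = uniform_init(c(d_out, d_in), d_in),
                     b = numeric(d_out)))
}

pad_batch <- function(X, p) {
  if (p == 0) return(X)
  d <- dim(X)
  Xp <- array(0, dim = c(d[1], d[2], d[3] + 2 * p))
  Xp[, , p + seq_len(d[3])] <- X
  Xp
}

im2col <- function(Xp, kernel, L_out) {
  d <- dim(Xp)
  P <- array(0, dim = c(d[2] * kernel, L_out, d[1]))
  for (j in seq_len(kernel))
    P[(j - 1) * d[2] + seq_len(d[2]), , ] <-
      aperm(Xp[, , j:(j + L_out - 1), drop = FALSE], c(2, 3, 1))
  P
}

col2im <- function(dP, n, ch, kernel, Lp, L_out) {
  # dP: matrix [ch * kernel, L_out * n]
  dXp <- array(0, dim = c(n, ch, Lp))
  for (j in seq_len(kernel)) {
    blk <- aperm(array(dP[(j - 1) * ch + seq_len(ch), , drop = FALSE],
                       dim = c(ch, L_out, n)), c(3, 1, 2))
    dXp[, , j:(j + L_out - 1)] <- dXp[, , j:(j + L_out - 1)] + blk
  }
  dXp
}

# channel-broadcast multiply / add for [n, C, L] arrays
ch_mul <- function(X, v) X * rep(v, each = dim(X)[1])
ch_add <- function(X, v) X + rep(v, each = dim(X)[1])

layer_forward <- function(layer, X, train = FALSE) {
  switch(layer$type,
    conv1d = {
      d <- dim(X)
      L_full <- d[3] + 2 * layer$padding - layer$kernel + 1
      if (L_full < 1) stopf("conv1d: non-positive output length %d", L_full)
      Xp <- pad_batch(X, layer$padding)
      P <- im2col(Xp, layer$kernel, L_full)
      Pm <- matrix(P, nrow = dim(P)[1])
      Ym <- layer$params$W %*% Pm + layer$params$b
      Y <- aperm(array(Ym, dim = c(layer$out_ch, L_full, d[1])), c(3, 1, 2))
      if (layer$crop > 0) Y <- Y[, , seq_len(L_full - layer$crop), drop = FALSE]
      list(out = Y, cache = list(Pm = Pm, d = d, L_full = L_full), layer = layer)
    },
    sepconv1d = {
      d <- dim(X)
      L_full <- d[3] + 2 * layer$padding - layer$kernel + 1
      if (L_full < 1) stopf("sepconv1d: non-positive output length %d", L_full)
      Xp <- pad_batch(X, layer$padding)
      Yd <- array(0, dim = c(d[1], layer$in_ch, L_full))
      for (j in seq_len(layer$kernel))
        Yd <- Yd + ch_mul(Xp[, , j:(j + L_full - 1), drop = FALSE],
                          layer$params$Wd[, j])
      Ydm <- matrix(aperm(Yd, c(2, 3, 1)), nrow = layer$in_ch)
      Ym <- layer$params$Wp %*% Ydm + layer$params$b
      Y <- aperm(array(Ym, dim = c(layer$out_ch, L_full, d[1])), c(3, 1, 2))
      if (layer$crop > 0) Y <- Y[, , seq_len(L_full - layer$crop), drop = FALSE]
      list(out = Y, cache = list(Xp = Xp, Ydm = Ydm, d = d, L_full = L_full),
           layer = layer)
    },
    batchnorm = {
      d <- dim(X)
      if (train) {
        Xm <- matrix(aperm(X, c(2, 1, 3)), nrow = d[2])
        m <- rowMeans(Xm)
        v <- rowMeans(Xm^2) - m^2
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * m
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * v
      } else {
        m <- layer$running_mean
        v <- layer$running_var
      }
      inv <- 1 / sqrt(v + layer$eps)
      xhat <- ch_mul(ch_add(X, -m), inv)
      Y <- ch_add(ch_mul(xhat, layer$params$gamma), layer$params$beta)
      list(out = Y, cache = list(xhat = xhat, inv = inv, train = train, d = d),
           layer = layer)
    },
    sigmoid = {
      Y <- 1 / (1 + exp(-X))
      list(out = Y, cache = list(Y = Y), layer = layer)
    },
    avgpool = {
      d <- dim(X)
      p <- layer$factor
      L_out <- d[3] %/% p
      if (L_out < 1) stopf("avgpool: non-positive output length")
      arr <- array(X[, , seq_len(L_out * p), drop = FALSE],
                   dim = c(d[1] * d[2], p, L_out))
      Y <- array(colSums(aperm(arr, c(2, 1, 3))) / p,
                 dim = c(d[1], d[2], L_out))
      list(out = Y, cache = list(d = d, L_out = L_out), layer = layer)
    },
    adaptive_avgpool = {
      d <- dim(X)
      Lo <- layer$out_len
      Y <- array(0, dim = c(d[1], d[2], Lo))
      bins <- lapply(seq_len(Lo), function(t) {
        a <- floor((t - 1) * d[3] / Lo) + 1
        b <- ceiling(t * d[3] / Lo)
        c(a, b)
      })
      for (t in seq_len(Lo)) {
        ab <- bins[[t]]
        Y[, , t] <- rowSums(X[, , ab[1]:ab[2], drop = FALSE], dims = 2) /
          (ab[2] - ab[1] + 1)
      }
      list(out = Y, cache = list(d = d, bins = bins), layer = layer)
    },
    flatten = {
      d <- dim(X)
      list(out = matrix(X, nrow = d[1]), cache = list(d = d), layer = layer)
    },
    linear = {
      Y <- X %*% t(layer$params$W) +
        matrix(layer$params$b, nrow(X), layer$d_out, byrow = TRUE)
      list(out = Y, cache = list(X = X), layer = layer)
    },
    stopf("unknown layer type '%s'", layer$type)
  )
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    conv1d = {
      d <- cache$d
      if (layer$crop > 0) {
        full <- array(0, dim = c(d[1], layer$out_ch, cache$L_full))
        full[, , seq_len(cache$L_full - layer$crop)] <- dY
        dY <- full
      }
      dYm <- matrix(aperm(dY, c(2, 3, 1)), nrow = layer$out_ch)
      dW <- dYm %*% t(cache$Pm)
      db <- rowSums(dYm)
      dP <- t(layer$params$W) %*% dYm
      dXp <- col2im(dP, d[1], d[2], layer$kernel,
                    d[3] + 2 * layer$padding, cache$L_full)
      dX <- if (layer$padding > 0)
        dXp[, , layer$padding + seq_len(d[3]), drop = FALSE] else dXp
      list(dX = dX, grads = list(W = dW, b = db))
    },
    sepconv1d = {
      d <- cache$d
      if (layer$crop > 0) {
        full <- array(0, dim = c(d[1], layer$out_ch, cache$L_full))
        full[, , seq_len(cache$L_full - layer$crop)] <- dY
        dY <- full
      }
      dYm <- matrix(aperm(dY, c(2, 3, 1)), nrow = layer$out_ch)
      dWp <- dYm %*% t(cache$Ydm)
      db <- rowSums(dYm)
      dYdm <- t(layer$params$Wp) %*% dYm
      dYd <- aperm(array(dYdm, dim = c(layer$in_ch, cache$L_full, d[1])),
                   c(3, 1, 2))
      Lp <- d[3] + 2 * layer$padding
      dWd <- matrix(0, layer$in_ch, layer$kernel)
      dXp <- array(0, dim = c(d[1], layer$in_ch, Lp))
      for (j in seq_len(layer$kernel)) {
        sl <- j:(j + cache$L_full - 1)
        E <- dYd * cache$Xp[, , sl, drop = FALSE]
        dWd[, j] <- rowSums(colSums(E))       # sum over trials, then samples
        dXp[, , sl] <- dXp[, , sl] + ch_mul(dYd, layer$params$Wd[, j])
      }
      dX <- if (layer$padding > 0)
        dXp[, , layer$padding + seq_len(d[3]), drop = FALSE] else dXp
      list(dX = dX, grads = list(Wd = dWd, Wp = dWp, b = db))
    },
    batchnorm = {
      d <- cache$d
      M <- d[1] * d[3]
      sum_ch <- function(A) rowSums(colSums(A))  # per-channel sum over (n, L)
      dgamma <- sum_ch(dY * cache$xhat)
      dbeta <- sum_ch(dY)
      dxhat <- ch_mul(dY, layer$params$gamma)
      if (cache$train) {
        m1 <- sum_ch(dxhat) / M
        m2 <- sum_ch(dxhat * cache$xhat) / M
        dX <- ch_mul(dxhat - rep(m1, each = d[1]) -
                       cache$xhat * rep(m2, each = d[1]), cache$inv)
      } else {
        dX <- ch_mul(dxhat, cache$inv)
      }
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    sigmoid = {
      list(dX = dY * cache$Y * (1 - cache$Y), grads = list())
    },
    avgpool = {
      d <- cache$d
      p <- layer$factor
      darr <- aperm(array(rep(as.vector(dY) / p, each = p),
                          dim = c(p, d[1] * d[2], cache$L_out)), c(2, 1, 3))
      dX <- array(0, dim = d)
      dX[, , seq_len(cache$L_out * p)] <- array(darr, dim = c(d[1], d[2],
                                                              cache$L_out * p))
      list(dX = dX, grads = list())
    },
    adaptive_avgpool = {
      d <- cache$d
      dX <- array(0, dim = d)
      for (t in seq_along(cache$bins)) {
        ab <- cache$bins[[t]]
        w <- 1 / (ab[2] - ab[1] + 1)
        for (s in ab[1]:ab[2]) dX[, , s] <- dX[, , s] + dY[, , t] * w
      }
      list(dX = dX, grads = list())
    },
    flatten = {
      list(dX = array(dY, dim = cache$d), grads = list())
    },
    linear = {
      list(dX = dY %*% layer$params$W,
           grads = list(W = t(dY) %*% cache$X, b = colSums(dY)))
    }
  )
}

# Forward through a layer stack; returns output, per-layer caches, and the
# (possibly updated, for batch-norm running stats) layers.
net_forward <- function(layers, X, train = FALSE, upto = length(layers)) {
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    r <- layer_forward(layers[[i]], X, train = train)
    X <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = X, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dY, from = length(caches)) {
  grads <- vector("list", length(layers))
  for (i in seq(from, 1)) {
    r <- layer_backward(layers[[i]], caches[[i]], dY)
    dY <- r$dX
    grads[[i]] <- r$grads
  }
  list(dX = dY, grads = grads)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (i in seq_along(b))
    for (nm in names(b[[i]]))
      a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  a
}

grads_scale <- function(g, s) {
  lapply(g, function(l) lapply(l, function(x) x * s))
}

softmax_xent <- function(logits, labels) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
}

adam_step <- function(layers, grads, state, lr = 1e-3, t = 1,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mh / (sqrt(vh) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
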