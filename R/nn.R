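# Minimal feed-forward / convolutional network engine on base-R matrix ops.
#
# Everything runs on BLAS matrix products: convolutions are lowered to
# im2col gathers with precomputed index tables, so a forward/backward pass is
# a handful of dgemm calls. All randomness goes through R's RNG, which makes
# training bit-reproducible for a fixed seed on a fixed machine.
#
# Data layout: a batch is a matrix D x n (one flattened example per column).
# Images are flattened from (H, W, C) arrays in R's column-major order, i.e.
# row index fastest, channel slowest.

# ---- layer constructors -----------------------------------------------------

layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       W = matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
       b = rep(0, n_out))
}

layer_relu <- function() list(type = "relu")

layer_batchnorm <- function(n) {
  list(type = "batchnorm", gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n), momentum = 0.9, eps = 1e-5)
}

# valid convolution, square kernel `k`, stride `s`
layer_conv <- function(in_dim, n_filters, k, s) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]
  Ho <- (H - k) %/% s + 1L
  Wo <- (W - k) %/% s + 1L
  if (Ho < 1 || Wo < 1) stop("conv kernel larger than its input")
  ckk <- C * k * k
  # patch-internal offsets (row fastest, then col, then channel) ...
  off <- as.vector(outer(seq_len(k), (seq_len(k) - 1L) * H, "+"))
  off <- as.vector(outer(off, (seq_len(C) - 1L) * H * W, "+"))
  # ... and the flat index of each output patch's top-left corner
  starts <- as.vector(outer(1L + (seq_len(Ho) - 1L) * s,
                            (seq_len(Wo) - 1L) * s * H, "+"))
  idx <- as.integer(outer(off, starts - 1L, "+"))
  list(type = "conv",
       W = matrix(rnorm(n_filters * ckk, 0, sqrt(2 / ckk)), n_filters, ckk),
       b = rep(0, n_filters),
       idx = idx, ckk = ckk, n_patch = Ho * Wo, n_filters = n_filters,
       in_dim = in_dim, out_dim = c(Ho, Wo, n_filters))
}

# global average pooling over the spatial grid
layer_gap <- function(in_dim) {
  list(type = "gap", n_patch = in_dim[1] * in_dim[2], n_filters = in_dim[3])
}

# ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, X, train = FALSE) {
  switch(layer$type,
    dense = list(out = layer$W %*% X + layer$b, cache = X),
    relu = {
      out <- X * (X > 0)
      list(out = out, cache = X)
    },
    batchnorm = {
      if (train) {
        mu <- rowMeans(X)
        xc <- X - mu
        v <- rowMeans(xc^2)
        xh <- xc / sqrt(v + layer$eps)
        list(out = layer$gamma * xh + layer$beta,
             cache = list(xh = xh, v = v, xc = xc),
             state = list(
               run_mean = layer$momentum * layer$run_mean + (1 - layer$momentum) * mu,
               run_var = layer$momentum * layer$run_var + (1 - layer$momentum) * v))
      } else {
        xh <- (X - layer$run_mean) / sqrt(layer$run_var + layer$eps)
        list(out = layer$gamma * xh + layer$beta, cache = NULL)
      }
    },
    conv = {
      n <- ncol(X)
      P <- X[layer$idx, , drop = FALSE]
      dim(P) <- c(layer$ckk, layer$n_patch * n)
      Y <- layer$W %*% P + layer$b
      dim(Y) <- c(layer$n_filters, layer$n_patch, n)
      Y <- aperm(Y, c(2, 1, 3))
      dim(Y) <- c(layer$n_patch * layer$n_filters, n)
      list(out = Y, cache = P)
    },
    gap = {
      n <- ncol(X)
      dim(X) <- c(layer$n_patch, layer$n_filters * n)
      Y <- colMeans(X)
      dim(Y) <- c(layer$n_filters, n)
      list(out = Y, cache = NULL)
    },
    stop("unknown layer type"))
}

layer_backward <- function(layer, dY, cache, n_batch) {
  switch(layer$type,
    dense = list(dX = crossprod(layer$W, dY),
                 grads = list(W = dY %*% t(cache), b = rowSums(dY))),
    relu = list(dX = dY * (cache > 0), grads = NULL),
    batchnorm = {
      xh <- cache$xh; v <- cache$v
      n <- ncol(xh)
      dgamma <- rowSums(dY * xh)
      dbeta <- rowSums(dY)
      dxh <- dY * layer$gamma
      istd <- 1 / sqrt(v + layer$eps)
      # standard batch-norm backward, folded form
      dX <- istd * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
      list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
    },
    conv = {
      n <- n_batch
      dim(dY) <- c(layer$n_patch, layer$n_filters, n)
      dY <- aperm(dY, c(2, 1, 3))
      dim(dY) <- c(layer$n_filters, layer$n_patch * n)
      dW <- dY %*% t(cache)
      db <- rowSums(dY)
      dP <- crossprod(layer$W, dY)
      dim(dP) <- c(layer$ckk * layer$n_patch, n)
      agg <- rowsum(dP, group = layer$idx)
      D <- prod(layer$in_dim)
      dX <- matrix(0, D, n)
      dX[as.integer(rownames(agg)), ] <- agg
      list(dX = dX, grads = list(W = dW, b = db))
    },
    gap = {
      dX <- dY[rep(seq_len(layer$n_filters), each = layer$n_patch), ,
               drop = FALSE] / layer$n_patch
      list(dX = dX, grads = NULL)
    },
    stop("unknown layer type"))
}

# forward through all layers; `upto` stops after that layer index
nn_forward <- function(layers, X, train = FALSE, upto = length(layers)) {
  caches <- vector("list", length(layers))
  for (i in seq_len(upto)) {
    f <- layer_forward(layers[[i]], X, train)
    X <- f$out
    caches[[i]] <- f$cache
    if (!is.null(f$state)) layers[[i]][names(f$state)] <- f$state
  }
  list(out = X, caches = caches, layers = layers)
}

softmax_probs <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# mean cross-entropy and logits gradient; y is an integer class vector (1..K)
softmax_xent <- function(Z, y) {
  P <- softmax_probs(Z)
  n <- ncol(Z)
  picked <- P[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(y, seq_len(n))] <- dZ[cbind(y, seq_len(n))] - 1
  list(loss = loss, dZ = dZ / n)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- intersect(names(l), c("W", "b", "gamma", "beta"))
    st <- lapply(pn, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0))
    names(st) <- pn
    st
  })
}

adam_step <- function(layers, grads, state, t, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# one SGD pass setup: full backward over a batch
nn_train_step <- function(layers, X, y) {
  fwd <- nn_forward(layers, X, train = TRUE)
  layers <- fwd$layers # running batch-norm stats updated
  ls <- softmax_xent(fwd$out, y)
  if (!is.finite(ls$loss))
    stop("non-finite training loss; check inputs/learning rate")
  grads <- vector("list", length(layers))
  dY <- ls$dZ
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], dY, fwd$caches[[i]], ncol(X))
    grads[i] <- list(bk$grads) # keep NULL slots for parameter-free layers
    dY <- bk$dX
  }
  list(layers = layers, grads = grads, loss = ls$loss)
}
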