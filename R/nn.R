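# Minimal neural-network machinery for the compact convolutional encoder.
# Activations are stored as 4-D arrays with layout (H, W, N, C): flattening
# the first three dims gives the (H*W*N) x C matrix consumed by the im2col
# convolution, so every layer reduces to dense BLAS matrix products.
#
# Layers: 3x3 same-padding convolution, ReLU, 2x2 average pooling, flatten,
# dense. Everything here is internal; the user-facing surface is encoder.R.

nn_conv_init <- function(c_in, c_out) {
  # He initialization for ReLU nets
  w <- array(stats::rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
             dim = c(3, 3, c_in, c_out))
  list(type = "conv", W = w, b = numeric(c_out))
}

nn_dense_init <- function(f_in, f_out) {
  list(type = "dense",
       W = matrix(stats::rnorm(f_in * f_out, sd = sqrt(2 / f_in)),
                  f_in, f_out),
       b = numeric(f_out))
}

# x: (H, W, N, C_in) -> (H, W, N, C_out), 3x3 kernel, pad 1, stride 1
nn_conv_forward <- function(layer, x) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; c_in <- d[4]
  c_out <- dim(layer$W)[4]
  xp <- array(0, c(h + 2, w + 2, n, c_in))
  xp[2:(h + 1), 2:(w + 1), , ] <- x
  m <- h * w * n
  cols <- matrix(0, m, 9 * c_in)
  # column index o + 9*(c-1) matches matrix(W, 9*c_in, c_out) row order
  for (dj in 1:3) {
    for (di in 1:3) {
      o <- di + 3L * (dj - 1L)
      block <- xp[di:(di + h - 1), dj:(dj + w - 1), , , drop = FALSE]
      cols[, o + 9L * (seq_len(c_in) - 1L)] <- matrix(block, m, c_in)
    }
  }
  wm <- matrix(layer$W, 9 * c_in, c_out)
  y <- cols %*% wm
  y <- y + rep(layer$b, each = m)
  list(out = array(y, c(h, w, n, c_out)),
       cache = list(cols = cols, dims = d, wm = wm))
}

nn_conv_backward <- function(layer, cache, dy) {
  d <- cache$dims; h <- d[1]; w <- d[2]; n <- d[3]; c_in <- d[4]
  m <- h * w * n
  c_out <- dim(layer$W)[4]
  dym <- matrix(dy, m, c_out)
  dW <- array(crossprod(cache$cols, dym), dim = dim(layer$W))
  db <- colSums(dym)
  dcols <- dym %*% t(cache$wm)
  dxp <- array(0, c(h + 2, w + 2, n, c_in))
  for (dj in 1:3) {
    for (di in 1:3) {
      o <- di + 3L * (dj - 1L)
      block <- array(dcols[, o + 9L * (seq_len(c_in) - 1L)], c(h, w, n, c_in))
      dxp[di:(di + h - 1), dj:(dj + w - 1), , ] <-
        dxp[di:(di + h - 1), dj:(dj + w - 1), , , drop = FALSE] + block
    }
  }
  list(dx = dxp[2:(h + 1), 2:(w + 1), , , drop = FALSE],
       grads = list(W = dW, b = db))
}

nn_relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

nn_relu_backward <- function(cache, dy) dy * cache

# 2x2 average pooling, stride 2; H and W must be even
nn_pool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  i1 <- seq(1, h, by = 2); i2 <- seq(2, h, by = 2)
  j1 <- seq(1, w, by = 2); j2 <- seq(2, w, by = 2)
  y <- (x[i1, j1, , , drop = FALSE] + x[i2, j1, , , drop = FALSE] +
        x[i1, j2, , , drop = FALSE] + x[i2, j2, , , drop = FALSE]) / 4
  list(out = y, cache = d)
}

nn_pool_backward <- function(cache, dy) {
  d <- cache
  dx <- array(0, d)
  h <- d[1]; w <- d[2]
  i1 <- seq(1, h, by = 2); i2 <- seq(2, h, by = 2)
  j1 <- seq(1, w, by = 2); j2 <- seq(2, w, by = 2)
  g <- dy / 4
  dx[i1, j1, , ] <- g; dx[i2, j1, , ] <- g
  dx[i1, j2, , ] <- g; dx[i2, j2, , ] <- g
  dx
}

# (H, W, N, C) -> (N, H*W*C)
nn_flatten_forward <- function(x) {
  d <- dim(x)
  y <- t(matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3]))
  list(out = y, cache = d)
}

nn_flatten_backward <- function(cache, dy) {
  d <- cache
  aperm(array(t(dy), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

nn_dense_forward <- function(layer, x) {
  list(out = sweep(x %*% layer$W, 2, layer$b, "+"), cache = x)
}

nn_dense_backward <- function(layer, cache, dy) {
  list(dx = dy %*% t(layer$W),
       grads = list(W = crossprod(cache, dy), b = colSums(dy)))
}

# --- network assembly -------------------------------------------------------

# tiny_cnn: 3 conv(3x3)+ReLU+avgpool blocks, widths 8/16/32, then a dense
# head to the embedding dimension. Input spatial size must be divisible by 8.
nn_tiny_cnn <- function(input_size, channels, d_out, widths = c(8L, 16L, 32L)) {
  if (input_size %% 8L != 0L) {
    stop_taxembed("tiny_cnn input size must be a multiple of 8, got ",
                  input_size, class = "taxembed_validation_error")
  }
  c_in <- c(channels, widths[1], widths[2])
  layers <- list()
  for (i in 1:3) {
    layers[[length(layers) + 1L]] <- nn_conv_init(c_in[i], widths[i])
    layers[[length(layers) + 1L]] <- list(type = "relu")
    layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  layers[[length(layers) + 1L]] <- list(type = "flatten")
  f_in <- (input_size / 8)^2 * widths[3]
  layers[[length(layers) + 1L]] <- nn_dense_init(f_in, d_out)
  layers
}

nn_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv = nn_conv_forward(l, x),
      relu = nn_relu_forward(x),
      pool = nn_pool_forward(x),
      flatten = nn_flatten_forward(x),
      dense = nn_dense_forward(l, x)
    )
    x <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type == "conv") {
      r <- nn_conv_backward(l, caches[[i]], dy)
      dy <- r$dx; grads[[i]] <- r$grads
    } else if (l$type == "relu") {
      dy <- nn_relu_backward(caches[[i]], dy)
    } else if (l$type == "pool") {
      dy <- nn_pool_backward(caches[[i]], dy)
    } else if (l$type == "flatten") {
      dy <- nn_flatten_backward(caches[[i]], dy)
    } else if (l$type == "dense") {
      r <- nn_dense_backward(l, caches[[i]], dy)
      dy <- r$dx; grads[[i]] <- r$grads
    }
  }
  grads
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) {
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0, t = 0L)
    } else NULL
  })
}

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$t <- s$t + 1L
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    c1 <- 1 - beta1^s$t; c2 <- 1 - beta2^s$t
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}
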