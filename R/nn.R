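# Minimal convolutional-network engine backing the super-resolution and
# segmentation models. Single-sample tensors are (H, W, C) arrays; gradients
# are accumulated across a batch and applied with Adam. Convolution kernels
# live in src/kernels.cpp; everything here is deliberately deterministic
# given R's RNG state (no threads, no backend randomness).

# ---- layers ----------------------------------------------------------------

# Convolution layer environment. act: "linear", "relu" or "lrelu" (slope 0.2).
new_conv <- function(cin, cout, k = 3L, act = "linear", init_sd = NULL) {
  l <- new.env(parent = emptyenv())
  l$kind <- "conv"
  l$k <- as.integer(k)
  l$pad <- (as.integer(k) - 1L) %/% 2L
  fan_in <- k * k * cin
  if (is.null(init_sd)) init_sd <- sqrt(2 / fan_in)  # He init
  l$w <- matrix(stats::rnorm(fan_in * cout, sd = init_sd), fan_in, cout)
  l$b <- numeric(cout)
  l$act <- act
  l$gw <- NULL
  l$gb <- NULL
  l
}

# Dense layer (vector in, scalar out) for the discriminator head.
new_dense <- function(cin) {
  l <- new.env(parent = emptyenv())
  l$kind <- "dense"
  l$w <- matrix(stats::rnorm(cin, sd = sqrt(1 / cin)), cin, 1)
  l$b <- 0
  l$gw <- NULL
  l$gb <- NULL
  l
}

# keep = TRUE caches the im2col matrix for the backward pass (training);
# prediction-only forwards skip the cache to bound memory on large scenes.
layer_fwd <- function(l, x, keep = TRUE) {
  if (l$kind == "dense") {
    l$x <- x
    return(drop(crossprod(l$w, x)) + l$b)
  }
  r <- .conv2d_fwd(x, l$w, l$b, l$k, l$pad, keep)
  l$cin <- dim(x)[3]
  l$cols <- if (keep) r$cols else NULL
  y <- r$y
  if (l$act == "relu") {
    l$mask <- y > 0
    y <- y * l$mask
  } else if (l$act == "lrelu") {
    l$mask <- y > 0
    y <- y * (l$mask + 0.2 * !l$mask)
  }
  if (!keep) l$mask <- NULL
  if (keep) l$x <- x
  y
}

layer_bwd <- function(l, dy) {
  if (l$kind == "dense") {
    l$gw <- l$gw + l$x * dy
    l$gb <- l$gb + dy
    return(drop(l$w) * dy)
  }
  if (l$act == "relu") {
    dy <- dy * l$mask
  } else if (l$act == "lrelu") {
    dy <- dy * (l$mask + 0.2 * !l$mask)
  }
  cols <- if (is.null(l$cols)) .im2col(l$x, l$k, l$pad) else l$cols
  r <- .conv2d_bwd(cols, l$w, dy, l$cin, l$k, l$pad)
  l$gw <- l$gw + r$gw
  l$gb <- l$gb + as.numeric(r$gb)
  r$dx
}

zero_grads <- function(layers) {
  for (l in layers) {
    l$gw <- l$w * 0
    l$gb <- l$b * 0
  }
  invisible(NULL)
}

# Adam update over a list of layer environments; t is the step counter.
adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in layers) {
    if (is.null(l$mw)) {
      l$mw <- l$w * 0; l$vw <- l$w * 0
      l$mb <- l$b * 0; l$vb <- l$b * 0
    }
    l$mw <- beta1 * l$mw + (1 - beta1) * l$gw
    l$vw <- beta2 * l$vw + (1 - beta2) * l$gw^2
    l$mb <- beta1 * l$mb + (1 - beta1) * l$gb
    l$vb <- beta2 * l$vb + (1 - beta2) * l$gb^2
    corr1 <- 1 - beta1^t
    corr2 <- 1 - beta2^t
    l$w <- l$w - lr * (l$mw / corr1) / (sqrt(l$vw / corr2) + eps)
    l$b <- l$b - lr * (l$mb / corr1) / (sqrt(l$vb / corr2) + eps)
  }
  invisible(NULL)
}

get_weights <- function(layers) lapply(layers, function(l) list(w = l$w, b = l$b))

set_weights <- function(layers, snapshot) {
  for (i in seq_along(layers)) {
    layers[[i]]$w <- snapshot[[i]]$w
    layers[[i]]$b <- snapshot[[i]]$b
  }
  invisible(NULL)
}

# ---- spatial ops -----------------------------------------------------------

# 2x2 max pooling; returns y plus the argmax index (1..4, ties to first)
# needed for routing gradients back.
maxpool2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  a <- array(x, c(2L, H %/% 2L, 2L, W %/% 2L, C))
  slice <- function(i, j) {
    s <- a[i, , j, , , drop = FALSE]
    dim(s) <- c(H %/% 2L, W %/% 2L, C)
    s
  }
  s <- list(slice(1, 1), slice(2, 1), slice(1, 2), slice(2, 2))
  y <- s[[1]]
  which <- array(1L, dim(y))
  for (i in 2:4) {
    upd <- s[[i]] > y
    which[upd] <- i
    y[upd] <- s[[i]][upd]
  }
  list(y = y, which = which)
}

maxpool2_bwd <- function(dy, which) {
  d <- dim(dy); H2 <- d[1]; W2 <- d[2]; C <- d[3]
  b <- array(0, c(2L, H2, 2L, W2, C))
  pos <- list(c(1L, 1L), c(2L, 1L), c(1L, 2L), c(2L, 2L))
  for (i in 1:4) {
    b[pos[[i]][1], , pos[[i]][2], , ] <- dy * (which == i)
  }
  dim(b) <- c(2L * H2, 2L * W2, C)
  b
}

upsample2 <- function(x) upsample_nearest(x, 2L)

upsample2_bwd <- function(dy) {
  d <- dim(dy); H <- d[1] %/% 2L; W <- d[2] %/% 2L; C <- d[3]
  a <- array(dy, c(2L, H, 2L, W, C))
  s <- 0
  for (i in 1:2) for (j in 1:2) {
    sl <- a[i, , j, , , drop = FALSE]
    dim(sl) <- c(H, W, C)
    s <- s + sl
  }
  s
}

# Sub-pixel (pixel-shuffle) x2: (H, W, 4C) -> (2H, 2W, C).
pixel_shuffle2 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3] %/% 4L
  a <- array(x, c(H, W, 2L, 2L, C))
  a <- aperm(a, c(3L, 1L, 4L, 2L, 5L))
  array(a, c(2L * H, 2L * W, C))
}

pixel_shuffle2_bwd <- function(dy) {
  d <- dim(dy); H <- d[1] %/% 2L; W <- d[2] %/% 2L; C <- d[3]
  a <- array(dy, c(2L, H, 2L, W, C))
  a <- aperm(a, c(2L, 4L, 1L, 3L, 5L))
  array(a, c(H, W, 4L * C))
}

concat_channels <- function(a, b) {
  array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# ---- losses ----------------------------------------------------------------

# Per-pixel softmax over the channel dimension of (H, W, K).
softmax_channels <- function(x) {
  d <- dim(x)
  xm <- matrix(x, ncol = d[3])
  mx <- xm[cbind(seq_len(nrow(xm)), max.col(xm, ties.method = "first"))]
  e <- exp(xm - mx)
  p <- e / rowSums(e)
  array(p, d)
}

# Categorical cross-entropy of softmax probabilities p against one-hot y,
# averaged over pixels; returns loss and the gradient w.r.t. the logits.
softmax_ce <- function(p, onehot) {
  d <- dim(p)
  n <- d[1] * d[2]
  pm <- matrix(p, ncol = d[3])
  ym <- matrix(onehot, ncol = d[3])
  loss <- -sum(ym * log(pmax(pm, 1e-12))) / n
  dlogits <- array((pm - ym) / n, d)
  list(loss = loss, dlogits = dlogits)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softplus <- function(z) ifelse(z > 30, z, log1p(exp(z)))
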