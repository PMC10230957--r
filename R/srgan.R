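#' SRGAN configuration
#'
#' Settings for the super-resolution GAN: a fully convolutional generator
#' (initial conv, residual blocks of two conv layers each with a residual
#' edge, and sub-pixel upsampling stages giving the `upscale_factor`) and a
#' convolutional discriminator, trained alternately (discriminator step
#' first, then generator). The generator loss combines a content term
#' (pixel-space MSE, or MSE between features of a fixed random convolutional
#' extractor when `perceptual_source = "feature_net"`) with
#' `adversarial_weight` times the adversarial term.
#'
#' @param upscale_factor Power-of-two upscale factor (default 4).
#' @param n_residual_blocks Number of residual blocks in the generator.
#' @param base_channels Feature channels of the generator trunk.
#' @param learning_rate Adam learning rate for both networks.
#' @param epochs Training epochs (one pass over the pairs each).
#' @param adversarial_weight Weight of the adversarial loss term (>= 0).
#'   The default 1e-4 balances the adversarial term against reflectance-scale
#'   pixel MSE (order 1e-4 to 1e-3); the 1e-3 convention of the original
#'   SRGAN assumes a larger content-loss scale.
#' @param perceptual_source `"pixel_mse"` or `"feature_net"`.
#' @param seed Integer seed controlling init and data order.
#' @return An object of class `srgan_config`.
#' @export
srgan_config <- function(upscale_factor = 4L,
                         n_residual_blocks = 4L,
                         base_channels = 16L,
                         learning_rate = 1e-3,
                         epochs = 100L,
                         adversarial_weight = 1e-4,
                         perceptual_source = c("pixel_mse", "feature_net"),
                         seed = 1L) {
  perceptual_source <- match.arg(perceptual_source)
  upscale_factor <- as.integer(upscale_factor)
  if (upscale_factor < 2L || bitwAnd(upscale_factor, upscale_factor - 1L) != 0L) {
    stop_domain("upscale_factor must be a power of 2 (>= 2)")
  }
  if (adversarial_weight < 0) stop_domain("adversarial_weight must be >= 0")
  structure(list(upscale_factor = upscale_factor,
                 n_residual_blocks = as.integer(n_residual_blocks),
                 base_channels = as.integer(base_channels),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 adversarial_weight = adversarial_weight,
                 perceptual_source = perceptual_source,
                 seed = as.integer(seed)),
            class = "srgan_config")
}

build_generator <- function(config, channels) {
  F <- config$base_channels
  net <- new.env(parent = emptyenv())
  net$g_in <- new_conv(channels, F, act = "relu")
  net$res <- lapply(seq_len(config$n_residual_blocks), function(i) {
    list(a = new_conv(F, F, act = "relu"), b = new_conv(F, F, act = "linear"))
  })
  net$g_mid <- new_conv(F, F, act = "linear")
  n_stages <- as.integer(log2(config$upscale_factor))
  net$ups <- lapply(seq_len(n_stages), function(i) new_conv(F, 4L * F, act = "linear"))
  # near-zero init: the untrained generator starts at the nearest-neighbour
  # baseline and training can only build on it
  net$g_out <- new_conv(F, channels, act = "linear", init_sd = 1e-3)
  net$channels <- channels
  net$factor <- config$upscale_factor
  net
}

g_layers <- function(net) {
  c(list(net$g_in, net$g_mid, net$g_out), net$ups,
    unlist(lapply(net$res, function(b) list(b$a, b$b)), recursive = FALSE))
}

g_forward <- function(net, x, keep = FALSE) {
  h0 <- layer_fwd(net$g_in, x, keep)
  h <- h0
  for (blk in net$res) {
    h <- h + layer_fwd(blk$b, layer_fwd(blk$a, h, keep), keep)
  }
  h <- layer_fwd(net$g_mid, h, keep) + h0
  net$up_masks <- vector("list", length(net$ups))
  for (i in seq_along(net$ups)) {
    u <- pixel_shuffle2(layer_fwd(net$ups[[i]], h, keep))
    if (keep) net$up_masks[[i]] <- u > 0
    h <- u * (u > 0)
  }
  # global residual: the network learns a correction over nearest-neighbour
  # upsampling, so the untrained generator already reproduces its input
  layer_fwd(net$g_out, h, keep) + upsample_nearest(x, net$factor)
}

g_backward <- function(net, dy) {
  dh <- layer_bwd(net$g_out, dy)
  for (i in rev(seq_along(net$ups))) {
    dh <- dh * net$up_masks[[i]]
    dh <- layer_bwd(net$ups[[i]], pixel_shuffle2_bwd(dh))
  }
  dh0 <- dh
  dh <- layer_bwd(net$g_mid, dh)
  for (blk in rev(net$res)) {
    dh <- dh + layer_bwd(blk$a, layer_bwd(blk$b, dh))
  }
  layer_bwd(net$g_in, dh0 + dh)
}

avgpool2 <- function(x) upsample2_bwd(x) / 4
avgpool2_bwd <- function(dy) upsample2(dy) / 4

build_discriminator <- function(config, channels) {
  F <- config$base_channels
  dn <- new.env(parent = emptyenv())
  dn$d1 <- new_conv(channels, F, act = "lrelu")
  dn$d2 <- new_conv(F, 2L * F, act = "lrelu")
  dn$d3 <- new_conv(2L * F, 2L * F, act = "lrelu")
  dn$dense <- new_dense(2L * F)
  dn
}

d_layers <- function(dn) list(dn$d1, dn$d2, dn$d3, dn$dense)

d_forward <- function(dn, x) {
  h <- avgpool2(layer_fwd(dn$d1, x))
  h <- avgpool2(layer_fwd(dn$d2, h))
  h <- layer_fwd(dn$d3, h)
  dn$gm_dim <- dim(h)
  layer_fwd(dn$dense, apply(h, 3, mean))
}

d_backward <- function(dn, dz) {
  dv <- layer_bwd(dn$dense, dz)
  n <- dn$gm_dim[1] * dn$gm_dim[2]
  dh <- array(rep(dv / n, each = n), dn$gm_dim)
  dh <- avgpool2_bwd(layer_bwd(dn$d3, dh))
  dh <- avgpool2_bwd(layer_bwd(dn$d2, dh))
  layer_bwd(dn$d1, dh)
}

#' Train a super-resolution GAN on paired images
#'
#' Alternating per-pair training: the discriminator is stepped first on one
#' real high-resolution image and the current generator output, then the
#' generator is stepped on content + adversarial loss. Deterministic given
#' the config seed.
#'
#' @param pairs List of `list(lr = , hr = )` arrays; `hr` dimensions must be
#'   `lr` times the upscale factor, same channel count throughout.
#' @param config An [srgan_config()].
#' @return An `sr_model` with the trained generator and a per-epoch history
#'   data.frame (`epoch`, `g_loss`, `d_loss`).
#' @export
train_srgan <- function(pairs, config) {
  stopifnot(inherits(config, "srgan_config"))
  if (length(pairs) == 0L) stop_domain("configuration error: no training pairs")
  f <- config$upscale_factor
  ch <- dim(pairs[[1]]$lr)[3]
  for (p in pairs) {
    dl <- dim(p$lr); dh <- dim(p$hr)
    if (length(dl) != 3L || length(dh) != 3L || dl[3] != ch || dh[3] != ch ||
        any(dh[1:2] != dl[1:2] * f)) {
      stop_domain("train_srgan: pair shapes must be (h, w, C) and (h*", f, ", w*", f, ", C)")
    }
  }
  withr::with_seed(config$seed, {
    gen <- build_generator(config, ch)
    dis <- build_discriminator(config, ch)
    feat <- if (config$perceptual_source == "feature_net") new_conv(ch, 8L, act = "relu") else NULL
    gl <- g_layers(gen)
    dl <- d_layers(dis)
    hist <- data.frame(epoch = seq_len(config$epochs), g_loss = NA_real_, d_loss = NA_real_)
    tg <- 0L
    td <- 0L
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(pairs))
      gsum <- 0; dsum <- 0
      for (i in ord) {
        lr <- pairs[[i]]$lr; hr <- pairs[[i]]$hr
        sr <- g_forward(gen, lr, keep = TRUE)
        # --- discriminator step (real vs current fake, fake detached) ---
        zero_grads(dl)
        zr <- d_forward(dis, hr)
        d_backward(dis, sigmoid(zr) - 1)
        zf <- d_forward(dis, sr)
        d_backward(dis, sigmoid(zf))
        td <- td + 1L
        adam_step(dl, config$learning_rate, td)
        dsum <- dsum + softplus(-zr) + softplus(zf)
        # --- generator step ---
        zero_grads(gl)
        if (is.null(feat)) {
          diff <- sr - hr
          content <- mean(diff^2)
          dsr <- 2 * diff / length(diff)
        } else {
          fs <- layer_fwd(feat, sr)
          fh <- layer_fwd(feat, hr)   # overwrites cache; recompute sr features below
          fdiff <- fs - fh
          content <- mean(fdiff^2)
          layer_fwd(feat, sr)         # restore cache for backward through sr path
          feat$gw <- feat$w * 0; feat$gb <- feat$b * 0
          dsr <- layer_bwd(feat, 2 * fdiff / length(fdiff))
        }
        adv <- 0
        if (config$adversarial_weight > 0) {
          zero_grads(dl)              # discard D grads from the G pass
          zf2 <- d_forward(dis, sr)
          adv <- softplus(-zf2)
          dsr <- dsr + config$adversarial_weight * d_backward(dis, sigmoid(zf2) - 1)
        }
        g_backward(gen, dsr)
        tg <- tg + 1L
        adam_step(gl, config$learning_rate, tg)
        gsum <- gsum + content + config$adversarial_weight * adv
      }
      hist$g_loss[epoch] <- gsum / length(pairs)
      hist$d_loss[epoch] <- dsum / length(pairs)
    }
    structure(list(generator = gen, config = config, history = hist, channels = ch),
              class = "sr_model")
  })
}

#' Enhance an image with a trained super-resolution generator
#'
#' @param image `(H, W, C)` array; `C` must match the training channels.
#' @param model An `sr_model` from [train_srgan()].
#' @return Array of dimensions `(H, W) * upscale_factor`, clipped to `[0, 1]`.
#' @export
enhance_image <- function(image, model) {
  stopifnot(inherits(model, "sr_model"))
  if (length(dim(image)) != 3L || dim(image)[3] != model$channels) {
    stop_domain("enhance_image: image must have ", model$channels,
                " channels (got ", paste(dim(image), collapse = "x"), ")")
  }
  clip01(g_forward(model$generator, image))
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model> x%d generator, %d residual blocks, %d epochs (final g_loss %.4g)\n",
              x$config$upscale_factor, x$config$n_residual_blocks,
              x$config$epochs, utils::tail(x$history$g_loss, 1)))
  invisible(x)
}
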