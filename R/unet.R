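#' UNet configuration
#'
#' Encoder-decoder semantic segmentation settings. The printed layer budget
#' of 10 convolution layers is realised as a symmetric UNet with double-conv
#' blocks: `levels = (conv_layer_count - 2) / 4` encoder/decoder levels plus
#' a two-conv bridge (the 1x1 classification head is not counted). The
#' network trains from scratch (no pretrained weights) with categorical
#' cross-entropy on one-hot targets, Adam at `learning_rate`, and per-epoch
#' accuracy/loss on the training and validation partitions.
#'
#' @param in_channels 3 (RGB) or 5 (R, G, B, RE, NIR).
#' @param class_count Number of semantic classes (>= 2).
#' @param conv_layer_count Convolution layers in the trunk; must satisfy
#'   `(conv_layer_count - 2) %% 4 == 0` (default 10 = two levels).
#' @param base_filters Feature channels at the first level.
#' @param batch_size Samples per gradient step.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param dropout Dropout rate applied to the bridge features (0 disables).
#' @param seed Integer seed controlling init, shuffling and dropout.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(in_channels = 3L,
                        class_count = 2L,
                        conv_layer_count = 10L,
                        base_filters = 16L,
                        batch_size = 2L,
                        learning_rate = 1e-5,
                        epochs = 120L,
                        dropout = 0,
                        seed = 1L) {
  if (!in_channels %in% c(3L, 5L)) stop_domain("in_channels must be 3 or 5")
  if (class_count < 2L) stop_domain("class_count must be >= 2")
  conv_layer_count <- as.integer(conv_layer_count)
  if (conv_layer_count %% 2L != 0L || conv_layer_count < 6L ||
      (conv_layer_count - 2L) %% 4L != 0L) {
    stop_domain("conv_layer_count must be even and equal 4*levels + 2 (e.g. 6, 10, 14)")
  }
  structure(list(in_channels = as.integer(in_channels),
                 class_count = as.integer(class_count),
                 conv_layer_count = conv_layer_count,
                 levels = (conv_layer_count - 2L) %/% 4L,
                 base_filters = as.integer(base_filters),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 dropout = dropout,
                 seed = as.integer(seed)),
            class = "unet_config")
}

build_unet <- function(config) {
  L <- config$levels
  Fb <- config$base_filters
  net <- new.env(parent = emptyenv())
  net$L <- L
  net$dropout <- config$dropout
  cin <- config$in_channels
  net$enc <- vector("list", L)
  for (lvl in seq_len(L)) {
    f <- Fb * 2^(lvl - 1L)
    net$enc[[lvl]] <- list(a = new_conv(cin, f, act = "relu"),
                           b = new_conv(f, f, act = "relu"))
    cin <- f
  }
  fL <- Fb * 2^(L - 1L)
  net$bridge <- list(a = new_conv(fL, 2L * fL, act = "relu"),
                     b = new_conv(2L * fL, 2L * fL, act = "relu"))
  net$dec <- vector("list", L)
  cup <- 2L * fL
  for (lvl in rev(seq_len(L))) {
    f <- Fb * 2^(lvl - 1L)
    net$dec[[lvl]] <- list(a = new_conv(cup + f, f, act = "relu"),
                           b = new_conv(f, f, act = "relu"))
    cup <- f
  }
  net$head <- new_conv(Fb, config$class_count, k = 1L, act = "linear")
  net
}

unet_layers <- function(net) {
  blocks <- c(net$enc, list(net$bridge), net$dec)
  c(unlist(lapply(blocks, function(b) list(b$a, b$b)), recursive = FALSE),
    list(net$head))
}

unet_forward <- function(net, x, train = FALSE) {
  L <- net$L
  net$skips <- vector("list", L)
  net$pw <- vector("list", L)
  h <- x
  for (lvl in seq_len(L)) {
    h <- layer_fwd(net$enc[[lvl]]$b, layer_fwd(net$enc[[lvl]]$a, h, train), train)
    net$skips[[lvl]] <- h
    mp <- maxpool2(h)
    net$pw[[lvl]] <- mp$which
    h <- mp$y
  }
  h <- layer_fwd(net$bridge$b, layer_fwd(net$bridge$a, h, train), train)
  if (train && net$dropout > 0) {
    keep <- array(stats::runif(length(h)) >= net$dropout, dim(h))
    net$dropmask <- keep
    h <- h * keep / (1 - net$dropout)
  } else {
    net$dropmask <- NULL
  }
  net$ucs <- integer(L)
  for (lvl in rev(seq_len(L))) {
    u <- upsample2(h)
    net$ucs[lvl] <- dim(u)[3]
    h <- layer_fwd(net$dec[[lvl]]$b,
                   layer_fwd(net$dec[[lvl]]$a, concat_channels(u, net$skips[[lvl]]), train),
                   train)
  }
  layer_fwd(net$head, h, train)
}

unet_backward <- function(net, dlogits) {
  L <- net$L
  dskips <- vector("list", L)
  dh <- layer_bwd(net$head, dlogits)
  for (lvl in seq_len(L)) {
    dcat <- layer_bwd(net$dec[[lvl]]$a, layer_bwd(net$dec[[lvl]]$b, dh))
    cu <- net$ucs[lvl]
    du <- dcat[, , seq_len(cu), drop = FALSE]
    dskips[[lvl]] <- dcat[, , (cu + 1L):dim(dcat)[3], drop = FALSE]
    dh <- upsample2_bwd(du)
  }
  if (!is.null(net$dropmask)) dh <- dh * net$dropmask / (1 - net$dropout)
  dh <- layer_bwd(net$bridge$a, layer_bwd(net$bridge$b, dh))
  for (lvl in rev(seq_len(L))) {
    de <- maxpool2_bwd(dh, net$pw[[lvl]]) + dskips[[lvl]]
    dh <- layer_bwd(net$enc[[lvl]]$a, layer_bwd(net$enc[[lvl]]$b, de))
  }
  invisible(dh)
}

select_bands <- function(image, in_channels) {
  nb <- dim(image)[3]
  if (in_channels == 5L && nb != 5L) {
    stop_domain("5-channel model requires exactly the 5-band (R, G, B, RE, NIR) ",
                "input order; got ", nb, " bands")
  }
  if (nb < in_channels) {
    stop_domain("image has ", nb, " bands but the model needs ", in_channels)
  }
  image[, , seq_len(in_channels), drop = FALSE]
}

#' Train the UNet segmenter on a tile set
#'
#' Trains on the `train` partition (which carries the augmented views) and
#' evaluates accuracy/loss on both partitions each epoch; the weights with
#' the best validation loss are kept (validation-based model selection).
#' Deterministic given the config seed.
#'
#' @param tileset A `tile_set` from [split_dataset()].
#' @param config A [unet_config()].
#' @return A `seg_model` with the trained network, the per-epoch `history`
#'   data.frame (`epoch`, `train_loss`, `train_acc`, `val_loss`, `val_acc`)
#'   and `best_epoch`.
#' @export
train_unet <- function(tileset, config) {
  stopifnot(inherits(tileset, "tile_set"), inherits(config, "unet_config"))
  tr_idx <- which(tileset$split == "train")
  va_idx <- which(tileset$split == "validation")
  if (length(tr_idx) == 0L) stop_domain("configuration error: empty training partition")
  prep <- function(idx) {
    lapply(idx, function(i) {
      tile <- tileset$tiles[[i]]
      list(x = select_bands(tile$image, config$in_channels),
           y = one_hot_encode(tile$mask, config$class_count),
           m = tile$mask)
    })
  }
  train_set <- prep(tr_idx)
  val_set <- prep(va_idx)
  ts <- dim(train_set[[1]]$x)[1:2]
  if (any(ts %% 2L^config$levels != 0L)) {
    stop_domain("tile size must be divisible by ", 2L^config$levels,
                " (network pooling depth)")
  }
  withr::with_seed(config$seed, {
    net <- build_unet(config)
    layers <- unet_layers(net)
    hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       train_acc = NA_real_, val_loss = NA_real_, val_acc = NA_real_)
    best <- list(loss = Inf, weights = NULL, epoch = NA_integer_)
    t_step <- 0L
    eval_tile <- function(s) {
      p <- softmax_channels(unet_forward(net, s$x, train = FALSE))
      pred <- predict_from_probs(p)
      c(softmax_ce(p, s$y)$loss, pixel_accuracy(pred, s$m))
    }
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train_set))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      loss_sum <- 0; acc_sum <- 0
      for (batch in batches) {
        zero_grads(layers)
        for (i in batch) {
          s <- train_set[[i]]
          logits <- unet_forward(net, s$x, train = TRUE)
          p <- softmax_channels(logits)
          ce <- softmax_ce(p, s$y)
          unet_backward(net, ce$dlogits / length(batch))
          loss_sum <- loss_sum + ce$loss
          acc_sum <- acc_sum + pixel_accuracy(predict_from_probs(p), s$m)
        }
        t_step <- t_step + 1L
        adam_step(layers, config$learning_rate, t_step)
      }
      hist$train_loss[epoch] <- loss_sum / length(train_set)
      hist$train_acc[epoch] <- acc_sum / length(train_set)
      if (length(val_set)) {
        vm <- vapply(val_set, eval_tile, c(0, 0))
        hist$val_loss[epoch] <- mean(vm[1, ])
        hist$val_acc[epoch] <- mean(vm[2, ])
      } else {
        hist$val_loss[epoch] <- hist$train_loss[epoch]
        hist$val_acc[epoch] <- hist$train_acc[epoch]
      }
      if (hist$val_loss[epoch] < best$loss) {
        best <- list(loss = hist$val_loss[epoch], weights = get_weights(layers),
                     epoch = epoch)
      }
    }
    if (!is.null(best$weights)) set_weights(layers, best$weights)
    structure(list(net = net, config = config, history = hist,
                   best_epoch = best$epoch),
              class = "seg_model")
  })
}

predict_from_probs <- function(p) {
  d <- dim(p)
  pm <- matrix(p, ncol = d[3])
  matrix(max.col(pm, ties.method = "first") - 1L, d[1], d[2])
}

#' Predict a class mask for an image
#'
#' Per-pixel argmax of the softmax scores; ties break toward the lower class
#' index. Images with more bands than the model's input channels are reduced
#' to the leading bands (R, G, B order).
#'
#' @param model A `seg_model` from [train_unet()].
#' @param tile_image `(H, W, C)` array; `H` and `W` must be divisible by the
#'   network's pooling depth.
#' @return Integer matrix of class labels (0-based), same spatial size.
#' @export
predict_mask <- function(model, tile_image) {
  stopifnot(inherits(model, "seg_model"))
  d <- dim(tile_image)
  div <- 2L^model$config$levels
  if (any(d[1:2] %% div != 0L)) {
    pad <- div * ceiling(d[1:2] / div) - d[1:2]
    stop_domain("image dimensions (", d[1], " x ", d[2], ") must be divisible by ",
                div, "; pad by (", pad[1], ", ", pad[2], ") pixels")
  }
  x <- select_bands(tile_image, model$config$in_channels)
  predict_from_probs(softmax_channels(unet_forward(model$net, x, train = FALSE)))
}

#' @export
print.seg_model <- function(x, ...) {
  h <- x$history
  cat(sprintf("<seg_model> %d-channel UNet (%d conv layers), %d epochs; best val loss %.4f (epoch %d), val acc %.4f\n",
              x$config$in_channels, x$config$conv_layer_count, x$config$epochs,
              min(h$val_loss), x$best_epoch, h$val_acc[x$best_epoch]))
  invisible(x)
}
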