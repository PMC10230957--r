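#' Crop a scene into fixed-size tiles
#'
#' Cuts the scene into non-overlapping `tile_size` squares taken top to
#' bottom and left to right; ragged edge remainders are dropped. The image
#' and the mask are cropped identically; the tile mask is the semantic
#' plant/background reduction of the instance mask (instance identity is
#' recovered downstream by connected components).
#'
#' @param scene A `scene_bundle`.
#' @param tile_size Tile edge length in pixels.
#' @return List of `tile` objects, each with `image` (`(t, t, 5)`), `mask`
#'   (integer `t x t`), `origin` (`(row, col)`, 0-based, multiples of
#'   `tile_size`), `augmentation_tag` (`"identity"`) and `tile_id`. A scene
#'   smaller than one tile returns an empty list with a warning.
#' @export
crop_tiles <- function(scene, tile_size) {
  stopifnot(inherits(scene, "scene_bundle"))
  tile_size <- as.integer(tile_size)
  if (tile_size <= 0L) stop_domain("crop_tiles: tile_size must be positive")
  H <- dim(scene$image)[1]; W <- dim(scene$image)[2]
  nr <- H %/% tile_size; nc <- W %/% tile_size
  if (nr == 0L || nc == 0L) {
    warning("scene (", H, " x ", W, ") smaller than one ", tile_size, "-px tile; no tiles produced")
    return(list())
  }
  sem <- scene_semantic_mask(scene)
  tiles <- vector("list", nr * nc)
  k <- 1L
  for (i in seq_len(nr)) {        # top to bottom ...
    for (j in seq_len(nc)) {      # ... left to right
      r0 <- (i - 1L) * tile_size
      c0 <- (j - 1L) * tile_size
      rows <- (r0 + 1L):(r0 + tile_size)
      cols <- (c0 + 1L):(c0 + tile_size)
      tiles[[k]] <- structure(list(
        image = scene$image[rows, cols, , drop = FALSE],
        mask = sem[rows, cols],
        origin = c(r0, c0),
        augmentation_tag = "identity",
        tile_id = sprintf("t%03d", k)
      ), class = "tile")
      k <- k + 1L
    }
  }
  tiles
}

flip_h <- function(m) if (is.matrix(m)) m[, rev(seq_len(ncol(m))), drop = FALSE] else m[, rev(seq_len(dim(m)[2])), , drop = FALSE]
flip_v <- function(m) if (is.matrix(m)) m[rev(seq_len(nrow(m))), , drop = FALSE] else m[rev(seq_len(dim(m)[1])), , , drop = FALSE]
transpose_raster <- function(m) if (is.matrix(m)) t(m) else aperm(m, c(2L, 1L, 3L))

apply_augmentation <- function(tile, tag) {
  op <- switch(tag,
    identity = function(x) x,
    hflip = flip_h,
    vflip = flip_v,
    transpose = transpose_raster,
    stop_domain("unknown augmentation tag '", tag, "'"))
  out <- tile
  out$image <- op(tile$image)
  out$mask <- op(tile$mask)
  out$augmentation_tag <- tag
  out$tile_id <- paste0(tile$tile_id, if (tag == "identity") "" else paste0(".", tag))
  out$parent_id <- tile$tile_id
  out
}

#' Augment tiles with flips and transposition
#'
#' Expands each tile into the closed operator set {identity, horizontal
#' flip, vertical flip, transpose} (4x count), applying the same operator to
#' image and mask. Transposition requires square tiles.
#'
#' @param tiles List of `tile` objects.
#' @param enabled If `FALSE`, tiles are returned unchanged.
#' @return List of tiles, 4x the input length when enabled.
#' @export
augment_tiles <- function(tiles, enabled = TRUE) {
  if (!enabled) return(tiles)
  out <- vector("list", 4L * length(tiles))
  k <- 1L
  for (tile in tiles) {
    if (nrow(tile$mask) != ncol(tile$mask)) {
      stop_domain("augment_tiles: transpose requires square tiles (got ",
                  nrow(tile$mask), " x ", ncol(tile$mask), ")")
    }
    for (tag in c("identity", "hflip", "vflip", "transpose")) {
      out[[k]] <- apply_augmentation(tile, tag)
      k <- k + 1L
    }
  }
  out
}

#' Split tiles into train/test/validation sets
#'
#' Shuffles tiles with the given seed, assigns contiguous blocks at the
#' configured ratio (largest-remainder rounding, remainders to train first),
#' and augments the training partition only, so no augmented view of a test
#' or validation tile can leak across partitions.
#'
#' @param tiles List of base tiles (from [crop_tiles()]).
#' @param ratios Positive ratio `(train, test, validation)`; default 8:1:1.
#' @param seed Integer seed for the permutation.
#' @param augment Augment the training partition (default `TRUE`).
#' @return A `tile_set`: list with `tiles`, parallel character vector
#'   `split`, `class_count`, and bookkeeping (`ratios`, `seed`).
#' @export
split_dataset <- function(tiles, ratios = c(8, 1, 1), seed = 1L, augment = TRUE) {
  if (length(tiles) < 3L) {
    stop_domain("configuration error: need at least 3 tiles to form 3 partitions")
  }
  if (any(ratios <= 0) || length(ratios) != 3L) {
    stop_domain("configuration error: ratios must be 3 positive numbers")
  }
  n <- length(tiles)
  perm <- withr::with_seed(seed, sample.int(n))
  frac <- n * ratios / sum(ratios)
  counts <- floor(frac)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(-(frac - counts), seq_along(frac)) # ties: train, test, validation
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  split_names <- rep(c("train", "test", "validation"), counts)
  tiles <- tiles[perm]
  out_tiles <- list()
  out_split <- character(0)
  for (part in c("train", "test", "validation")) {
    sub <- tiles[split_names == part]
    if (part == "train" && augment) sub <- augment_tiles(sub, TRUE)
    out_tiles <- c(out_tiles, sub)
    out_split <- c(out_split, rep(part, length(sub)))
  }
  structure(list(tiles = out_tiles, split = out_split, class_count = 2L,
                 n_base = n, ratios = ratios, seed = seed, augmented = augment),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles (%d base): %s\n", length(x$tiles), x$n_base,
              paste(sprintf("%s=%d", names(table(x$split)), table(x$split)), collapse = ", ")))
  invisible(x)
}

#' One-hot encode a class mask
#'
#' Turns each class of an integer label raster into its own 0/1 layer; the
#' layers sum to 1 at every pixel.
#'
#' @param mask Integer matrix with values in `[0, class_count)`.
#' @param class_count Number of classes.
#' @return `(H, W, class_count)` binary array.
#' @export
one_hot_encode <- function(mask, class_count) {
  bad <- which(mask < 0L | mask >= class_count)
  if (length(bad)) {
    r <- (bad[1] - 1L) %% nrow(mask) + 1L
    c <- (bad[1] - 1L) %/% nrow(mask) + 1L
    stop_domain("one_hot_encode: class value ", mask[bad[1]], " at (row ", r,
                ", col ", c, ") outside [0, ", class_count, ")")
  }
  out <- array(0, c(dim(mask), class_count))
  for (k in seq_len(class_count)) out[, , k] <- (mask == (k - 1L)) * 1
  out
}

# Persist a tile set as paired image/mask files plus an index CSV.
write_tileset <- function(tileset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx <- data.frame(tile_id = character(0), origin_row = integer(0),
                    origin_col = integer(0), split = character(0),
                    augmentation_tag = character(0))
  for (i in seq_along(tileset$tiles)) {
    tile <- tileset$tiles[[i]]
    base <- gsub("[^A-Za-z0-9_.-]", "_", tile$tile_id)
    pages <- lapply(seq_len(dim(tile$image)[3]), function(b) tile$image[, , b])
    tiff::writeTIFF(pages, file.path(path, paste0(base, "_img.tif")), bits.per.sample = 32L)
    tiff::writeTIFF(tile$mask / 65535, file.path(path, paste0(base, "_mask.tif")),
                    bits.per.sample = 16L)
    idx <- rbind(idx, data.frame(tile_id = tile$tile_id, origin_row = tile$origin[1],
                                 origin_col = tile$origin[2], split = tileset$split[i],
                                 augmentation_tag = tile$augmentation_tag))
  }
  utils::write.csv(idx, file.path(path, "index.csv"), row.names = FALSE)
  invisible(path)
}
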