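#' Synthetic field-scene configuration
#'
#' Describes one synthetic "stitched field": textured soil background,
#' elliptical plant canopies arranged in rows with wide inter-row spacing and
#' occasional within-row overlap, five reflectance bands (R, G, B, red edge,
#' NIR), and a latent SPAD value linearly coupled to each plant's visible
#' channel means. Defaults describe a row-planted rosette crop (heading
#' brassica) seen at nadir from roughly 10 m with a ~5.2 mm/px ground
#' sampling distance: canopies 19--31 cm across, rows ~50 cm apart.
#'
#' @param field_size Integer `(rows_px, cols_px)` of the scene raster.
#' @param n_rows Number of crop rows.
#' @param plants_per_row Plants in each row.
#' @param row_spacing Row pitch in pixels; must exceed twice the largest
#'   canopy semi-axis so rows stay separable.
#' @param within_row_spacing Nominal plant pitch along a row, pixels.
#' @param jitter_sd Gaussian jitter (px) on within-row plant positions.
#' @param semi_axis_range `(min, max)` canopy ellipse semi-axes, pixels.
#' @param overlap_probability Probability that a within-row neighbour pair is
#'   pulled together until their canopies overlap.
#' @param spad_range Documented range of SPAD values the defaults induce;
#'   must lie in `[0, 99]`.
#' @param spad_coeffs Named numeric `(b0, bR, bG, bB)`: SPAD =
#'   `b0 + bR*R + bG*G + bB*B + noise` on per-plant channel means.
#' @param spad_noise_sd SPAD noise standard deviation (SPAD units).
#' @param soil_mean Mean soil reflectance per band `(R, G, B, RE, NIR)`.
#' @param soil_texture_sd Soil texture amplitude (reflectance units).
#' @param plant_channel_ranges List with elements `R`, `G`, `B`, `RE`, `NIR`,
#'   each `(min, max)` of the uniform range plant channel means are drawn
#'   from. Vegetation defaults keep NIR and red edge well above soil.
#' @param canopy_texture_sd Multiplicative canopy texture amplitude; texture
#'   is renormalised per plant so region means stay exact.
#' @param camera A [camera_model()] fixing the GSD used to convert truth
#'   extents from pixels to metres.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(field_size = c(672L, 672L),
                         n_rows = 6L,
                         plants_per_row = 8L,
                         row_spacing = 96,
                         within_row_spacing = 80,
                         jitter_sd = 4,
                         semi_axis_range = c(18, 30),
                         overlap_probability = 0.1,
                         spad_range = c(38, 60),
                         spad_coeffs = c(b0 = 75, bR = -60, bG = -120, bB = -40),
                         spad_noise_sd = 1.5,
                         soil_mean = c(R = 0.22, G = 0.18, B = 0.12, RE = 0.28, NIR = 0.30),
                         soil_texture_sd = 0.02,
                         plant_channel_ranges = list(
                           R = c(0.04, 0.10), G = c(0.10, 0.22), B = c(0.03, 0.08),
                           RE = c(0.45, 0.55), NIR = c(0.55, 0.70)),
                         canopy_texture_sd = 0.05,
                         camera = camera_model(),
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "scene_config")
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  if (2 * max(cfg$semi_axis_range) >= cfg$row_spacing) {
    stop_domain("configuration error: row_spacing must exceed twice the ",
                "largest canopy semi-axis (rows must stay separable)")
  }
  if (cfg$spad_range[1] < 0 || cfg$spad_range[2] > 99) {
    stop_domain("configuration error: spad_range must lie within [0, 99]")
  }
  if (cfg$overlap_probability < 0 || cfg$overlap_probability > 1) {
    stop_domain("configuration error: overlap_probability must be in [0, 1]")
  }
  pad <- max(cfg$semi_axis_range)
  if (cfg$n_rows * cfg$row_spacing > cfg$field_size[1] ||
      (cfg$plants_per_row - 1) * cfg$within_row_spacing + 2 * pad > cfg$field_size[2]) {
    stop_domain("configuration error: plant layout does not fit in field_size")
  }
  invisible(cfg)
}

# Sample per-plant channel means and the SPAD values they induce.
# Returns a data.frame with columns R, G, B, RE, NIR, spad.
sample_plant_spectra <- function(n, config, seed = NULL) {
  draw <- function() {
    rng <- config$plant_channel_ranges
    ch <- lapply(rng, function(r) stats::runif(n, r[1], r[2]))
    b <- config$spad_coeffs
    spad <- b[["b0"]] + b[["bR"]] * ch$R + b[["bG"]] * ch$G + b[["bB"]] * ch$B +
      stats::rnorm(n, 0, config$spad_noise_sd)
    data.frame(R = ch$R, G = ch$G, B = ch$B, RE = ch$RE, NIR = ch$NIR, spad = spad)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Logical mask of a (possibly rotated) filled ellipse on an H x W grid.
# center is (row, col) 0-based; semi_axes is (row semi-axis, col semi-axis).
rasterize_ellipse <- function(H, W, center, semi_axes, orientation = 0) {
  b <- semi_axes[1]; a <- semi_axes[2]
  r0 <- center[1]; c0 <- center[2]
  pad <- ceiling(max(a, b)) + 1L
  rr <- max(0L, floor(r0 - pad)):min(H - 1L, ceiling(r0 + pad))
  cc <- max(0L, floor(c0 - pad)):min(W - 1L, ceiling(c0 + pad))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- dc * cos(orientation) + dr * sin(orientation)
  v <- -dc * sin(orientation) + dr * cos(orientation)
  d2 <- (u / a)^2 + (v / b)^2
  m <- matrix(FALSE, H, W)
  m[rr + 1L, cc + 1L] <- d2 <= 1
  list(mask = m, d2 = d2, rows = rr, cols = cc)
}

#' Generate a synthetic stitched-field scene
#'
#' Draws the configured row layout, rasterises each canopy as a textured
#' ellipse (contested pixels in overlapping pairs go to the plant whose
#' normalised elliptical radius is smaller), composes the five-band
#' reflectance image, and records exact per-plant ground truth. The truth
#' table's physical extents are the rasterised pixel extents of each plant's
#' label times the camera GSD, with `true_length >= true_width` by the
#' orientation-free max/min convention used in trait extraction.
#'
#' @param config A [scene_config()].
#' @return A `scene_bundle`: list with `image` (`(H, W, 5)` array, bands R,
#'   G, B, RE, NIR in `[0, 1]`), `instance_mask` (integer matrix, 0 =
#'   background), `truth` (data.frame, one row per plant), `gsd` (m/px) and
#'   `band_names`.
#' @examples
#' sc <- generate_scene(scene_config(seed = 7))
#' nrow(sc$truth)  # n_rows * plants_per_row
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  H <- as.integer(config$field_size[1]); W <- as.integer(config$field_size[2])
  n_plants <- config$n_rows * config$plants_per_row
  gsd <- compute_gsd(config$camera)

  layout <- withr::with_seed(derive_seed(config$seed, "layout"), {
    semi_a <- stats::runif(n_plants, config$semi_axis_range[1], config$semi_axis_range[2])
    semi_b <- stats::runif(n_plants, config$semi_axis_range[1], config$semi_axis_range[2])
    orient <- stats::runif(n_plants, -0.25, 0.25)
    margin_r <- (H - 1 - (config$n_rows - 1) * config$row_spacing) / 2
    centers <- matrix(0, n_plants, 2)
    idx <- 1L
    for (i in seq_len(config$n_rows)) {
      row_r <- margin_r + (i - 1) * config$row_spacing
      gaps <- rep(config$within_row_spacing, config$plants_per_row - 1)
      ids <- idx:(idx + config$plants_per_row - 1L)
      pulled <- stats::runif(config$plants_per_row - 1) < config$overlap_probability
      for (j in which(pulled)) {
        gaps[j] <- 0.9 * (semi_a[ids[j]] + semi_a[ids[j + 1L]])
      }
      cols <- cumsum(c(0, gaps))
      cols <- cols - mean(cols) + (W - 1) / 2 +
        stats::rnorm(config$plants_per_row, 0, config$jitter_sd)
      pad <- max(config$semi_axis_range) + 1
      cols <- pmin(pmax(cols, pad), W - 1 - pad)
      centers[ids, 1] <- row_r
      centers[ids, 2] <- cols
      idx <- idx + config$plants_per_row
    }
    list(centers = centers, semi_a = semi_a, semi_b = semi_b, orient = orient)
  })

  spectra <- sample_plant_spectra(n_plants, config, derive_seed(config$seed, "spectra"))

  # Rasterise with nearest-normalised-center competition for contested pixels.
  mask <- matrix(0L, H, W)
  bestd <- matrix(Inf, H, W)
  for (p in seq_len(n_plants)) {
    e <- rasterize_ellipse(H, W, layout$centers[p, ],
                           c(layout$semi_b[p], layout$semi_a[p]), layout$orient[p])
    sub_mask <- e$d2 <= 1
    sub_best <- bestd[e$rows + 1L, e$cols + 1L]
    take <- sub_mask & (e$d2 < sub_best)
    mrows <- e$rows + 1L; mcols <- e$cols + 1L
    msub <- mask[mrows, mcols]
    msub[take] <- p
    mask[mrows, mcols] <- msub
    sub_best[take] <- e$d2[take]
    bestd[mrows, mcols] <- sub_best
  }

  image <- array(0, c(H, W, 5L))
  withr::with_seed(derive_seed(config$seed, "texture"), {
    for (b in 1:5) {
      nz <- gauss_blur_mat(matrix(stats::rnorm(H * W), H, W), 3)
      nz <- nz / stats::sd(nz) * config$soil_texture_sd
      image[, , b] <- clip01(config$soil_mean[b] + nz)
    }
    tex <- gauss_blur_mat(matrix(stats::rnorm(H * W), H, W), 2)
    tex <- 1 + tex / stats::sd(tex) * config$canopy_texture_sd
    tex <- pmax(tex, 0.2)
    for (p in seq_len(n_plants)) {
      pix <- which(mask == p)
      if (length(pix) == 0L) next
      t_norm <- tex[pix] / mean(tex[pix])
      for (b in 1:5) {
        plane <- image[, , b]
        plane[pix] <- spectra[[b]][p] * t_norm
        image[, , b] <- plane
      }
    }
  })
  image <- clip01(image)

  # Truth extents from the final rasterised mask.
  present <- sort(unique(mask[mask > 0L]))
  ext <- t(vapply(present, function(p) {
    pix <- which(mask == p)
    r <- (pix - 1L) %% H
    c <- (pix - 1L) %/% H
    c(diff(range(r)) + 1L, diff(range(c)) + 1L)
  }, c(0, 0)))
  length_px <- pmax(ext[, 1], ext[, 2])
  width_px <- pmin(ext[, 1], ext[, 2])

  truth <- data.frame(
    plant_id = present,
    center_row_px = layout$centers[present, 1],
    center_col_px = layout$centers[present, 2],
    semi_a_px = layout$semi_a[present],
    semi_b_px = layout$semi_b[present],
    orientation_rad = layout$orient[present],
    length_px = as.integer(length_px),
    width_px = as.integer(width_px),
    true_length_m = length_px * gsd,
    true_width_m = width_px * gsd,
    true_spad = spectra$spad[present],
    mean_R = spectra$R[present], mean_G = spectra$G[present],
    mean_B = spectra$B[present], mean_RE = spectra$RE[present],
    mean_NIR = spectra$NIR[present]
  )
  if (length(present) < n_plants) {
    warning(n_plants - length(present), " plant(s) fully occluded and dropped from the scene")
  }

  structure(list(image = image, instance_mask = mask, truth = truth,
                 gsd = gsd, band_names = c("R", "G", "B", "RE", "NIR"),
                 config = config),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %d x %d px, 5 bands, %d plants, GSD %.3f mm/px\n",
              nrow(x$instance_mask), ncol(x$instance_mask), nrow(x$truth),
              x$gsd * 1000))
  invisible(x)
}

#' Semantic plant/background mask of a scene
#'
#' @param scene A `scene_bundle`.
#' @return Integer matrix: 1 where any plant, 0 for soil.
#' @export
scene_semantic_mask <- function(scene) {
  m <- scene$instance_mask
  m[m > 0L] <- 1L
  m
}

#' Degrade an image to a low-resolution counterpart
#'
#' Manufactures low-resolution/high-resolution training pairs for
#' super-resolution: Gaussian blur, `factor`-fold block-mean downsampling,
#' then additive Gaussian noise clipped to `[0, 1]`.
#'
#' @param image Matrix or `(H, W, C)` array with dimensions divisible by
#'   `factor`.
#' @param factor Integer downsampling factor.
#' @param blur_sd Pre-decimation Gaussian blur sd, pixels.
#' @param noise_sd Additive noise sd, reflectance units.
#' @param seed Integer seed for the noise draw.
#' @return Degraded image with spatial dimensions divided by `factor`.
#' @export
degrade_image <- function(image, factor, blur_sd = 1, noise_sd = 0.01, seed = 1L) {
  factor <- as.integer(factor)
  d <- if (is.matrix(image)) c(dim(image), 1L) else dim(image)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L) {
    stop_domain("degrade_image: image dimensions must be divisible by 'factor'")
  }
  was_matrix <- is.matrix(image)
  if (was_matrix) image <- array(image, d)
  out <- array(0, c(d[1] %/% factor, d[2] %/% factor, d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- block_mean_mat(gauss_blur_mat(image[, , c], blur_sd), factor)
  }
  if (noise_sd > 0) {
    out <- withr::with_seed(seed, out + array(stats::rnorm(length(out), 0, noise_sd), dim(out)))
  }
  out <- clip01(out)
  if (was_matrix) out <- out[, , 1]
  out
}
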