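test_that("scene layout produces one mask label and truth row per plant", {
  cfg <- scene_config(field_size = c(288L, 320L), n_rows = 3L, plants_per_row = 4L,
                      row_spacing = 96, within_row_spacing = 80, seed = 7L)
  sc <- generate_scene(cfg)
  labels <- sort(unique(sc$instance_mask[sc$instance_mask > 0]))
  expect_length(labels, 12L)
  expect_equal(nrow(sc$truth), 12L)
  expect_setequal(labels, sc$truth$plant_id)
  expect_identical(dim(sc$image)[1:2], dim(sc$instance_mask))
  expect_true(all(sc$image >= 0 & sc$image <= 1))
  expect_true(all(sc$truth$true_length_m >= sc$truth$true_width_m))
})

test_that("scene generation is bit-reproducible given the seed", {
  cfg <- tiny_scene_config(seed = 3L)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$instance_mask, b$instance_mask)
  expect_identical(a$truth, b$truth)
  c2 <- generate_scene(tiny_scene_config(seed = 4L))
  expect_false(identical(a$instance_mask, c2$instance_mask))
})

test_that("ellipse rasterisation matches a brute-force oracle", {
  m <- uavpheno:::rasterize_ellipse(201L, 201L, c(100, 100), c(20, 30), 0)$mask
  # independent oracle: test the ellipse inequality at every pixel
  oracle <- matrix(FALSE, 201L, 201L)
  for (r in 0:200) for (c in 0:200) {
    oracle[r + 1L, c + 1L] <- ((c - 100) / 30)^2 + ((r - 100) / 20)^2 <= 1
  }
  expect_identical(m, oracle)
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  expect_equal(diff(rows) + 1L, 41L)  # 2 * 20 + 1 inclusive
  expect_equal(diff(cols) + 1L, 61L)  # 2 * 30 + 1 inclusive
})

test_that("noiseless spectra regression recovers the generating coefficients", {
  cfg <- tiny_scene_config(seed = 9L, spad_noise_sd = 0)
  sc <- generate_scene(cfg)
  fit <- stats::lm(true_spad ~ mean_R + mean_G + mean_B, data = sc$truth)
  b <- cfg$spad_coeffs
  expect_lt(max(abs(stats::coef(fit) - c(b[["b0"]], b[["bR"]], b[["bG"]], b[["bB"]]))), 1e-8)
})

test_that("vegetation bands separate plants from soil", {
  sc <- default_scene()
  nir_r <- sc$image[, , 5] - sc$image[, , 1]
  plant <- sc$instance_mask > 0
  # >= 99% of plant pixels exceed >= 99% of soil pixels in NIR - R
  expect_gt(stats::quantile(nir_r[plant], 0.01), stats::quantile(nir_r[!plant], 0.99))
})

test_that("truth extents equal rasterised mask extents times the GSD", {
  sc <- default_scene()
  H <- nrow(sc$instance_mask)
  for (i in seq_len(nrow(sc$truth))) {
    pix <- which(sc$instance_mask == sc$truth$plant_id[i])
    r <- (pix - 1L) %% H
    c <- (pix - 1L) %/% H
    ext <- c(diff(range(r)) + 1L, diff(range(c)) + 1L)
    expect_equal(sc$truth$true_length_m[i], max(ext) * sc$gsd)
    expect_equal(sc$truth$true_width_m[i], min(ext) * sc$gsd)
  }
})

test_that("infeasible layouts are rejected as configuration errors", {
  expect_error(scene_config(row_spacing = 50), "row_spacing")
  expect_error(scene_config(field_size = c(100L, 100L)), "configuration error")
  expect_error(scene_config(spad_range = c(-5, 60)), "spad_range")
  expect_error(scene_config(overlap_probability = 1.5), "overlap_probability")
})

test_that("image degradation has the contracted shape and limits", {
  img <- array(stats::runif(64 * 64 * 3), c(64L, 64L, 3L))
  lo <- degrade_image(img, 4L, blur_sd = 1, noise_sd = 0.01, seed = 2L)
  expect_identical(dim(lo), c(16L, 16L, 3L))
  expect_true(all(lo >= 0 & lo <= 1))
  expect_identical(lo, degrade_image(img, 4L, 1, 0.01, seed = 2L))  # deterministic

  flat <- array(0.4, c(32L, 32L, 2L))
  lo_flat <- degrade_image(flat, 4L, blur_sd = 2, noise_sd = 0, seed = 1L)
  expect_equal(lo_flat, array(0.4, c(8L, 8L, 2L)))  # constants preserved

  expect_error(degrade_image(img, 5L), "divisible")
})

test_that("block-mean downsampling equals hand-computed block means", {
  # checkerboard of 4x4 blocks with values 0.2 / 0.8
  blk <- matrix(rep(c(0.2, 0.8), length.out = 16), 4, 4)
  board <- matrix(0, 16, 16)
  for (i in 0:3) for (j in 0:3) board[i * 4 + 1:4, j * 4 + 1:4] <- blk[i + 1, j + 1]
  lo <- degrade_image(array(board, c(16L, 16L, 1L)), 4L, blur_sd = 0, noise_sd = 0)
  expect_equal(lo[, , 1], blk)  # each output pixel is its block mean
})

test_that("scene bundles round-trip through disk", {
  sc <- generate_scene(tiny_scene_config(seed = 5L))
  dir <- withr::local_tempdir()
  write_bundle(sc, dir)
  back <- read_bundle(dir)
  expect_identical(back$instance_mask, sc$instance_mask)      # lossless
  expect_identical(back$truth$plant_id, sc$truth$plant_id)
  expect_equal(back$truth, sc$truth)                          # CSV at full precision
  expect_equal(back$image, sc$image, tolerance = 1e-6)        # float32 storage
  expect_identical(back$gsd, sc$gsd)
  expect_identical(back$band_names, sc$band_names)
})

test_that("corrupt truth tables are rejected", {
  sc <- generate_scene(tiny_scene_config(seed = 5L))
  dir <- withr::local_tempdir()
  write_bundle(sc, dir)
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  truth$plant_id[2] <- truth$plant_id[1]
  uavpheno:::write_csv_exact(truth, file.path(dir, "truth.csv"))
  expect_error(read_bundle(dir), "duplicated plant_id")
  file.remove(file.path(dir, "mask.tif"))
  expect_error(read_bundle(dir), "mask.tif")
})
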