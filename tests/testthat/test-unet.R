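# One small trained segmenter shared across blocks in this file: 9 base
# tiles (96 px) from a 3x3-plant scene, augmented training partition.
seg_scene <- generate_scene(tiny_scene_config(seed = 21L))
seg_tiles <- split_dataset(crop_tiles(seg_scene, 96L), ratios = c(7, 1, 1), seed = 3L)
seg_cfg <- unet_config(in_channels = 3L, base_filters = 8L, epochs = 4L,
                       learning_rate = 1e-3, batch_size = 2L, seed = 5L)
seg_model <- train_unet(seg_tiles, seg_cfg)

test_that("training records complete history with a decreasing loss trend", {
  h <- seg_model$history
  expect_equal(nrow(h), seg_cfg$epochs)
  expect_true(all(is.finite(unlist(h[-1]))))
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
  expect_gt(utils::tail(h$val_acc, 1), 0.9)
  expect_true(seg_model$best_epoch %in% seq_len(seg_cfg$epochs))
})

test_that("predicted masks are valid class rasters and deterministic", {
  img <- seg_tiles$tiles[[which(seg_tiles$split == "test")[1]]]$image
  pred <- predict_mask(seg_model, img)
  expect_identical(dim(pred), dim(img)[1:2])
  expect_true(all(pred %in% c(0L, 1L)))
  expect_identical(pred, predict_mask(seg_model, img))
})

test_that("training is reproducible given the seed", {
  cfg <- unet_config(in_channels = 3L, base_filters = 4L, epochs = 2L,
                     learning_rate = 1e-3, seed = 8L)
  m1 <- train_unet(seg_tiles, cfg)
  m2 <- train_unet(seg_tiles, cfg)
  expect_identical(m1$history, m2$history)
})

test_that("a model trained with flip augmentation scores equally on flipped tiles", {
  i <- which(seg_tiles$split == "test")[1]
  tile <- seg_tiles$tiles[[i]]
  acc <- pixel_accuracy(predict_mask(seg_model, tile$image), tile$mask)
  flipped <- uavpheno:::apply_augmentation(tile, "hflip")
  acc_f <- pixel_accuracy(predict_mask(seg_model, flipped$image), flipped$mask)
  expect_lt(abs(acc - acc_f), 0.02)
})

test_that("an all-soil tile is predicted as background", {
  soil_cfg <- tiny_scene_config(seed = 22L)
  soil_cfg$n_rows <- 1L
  soil_cfg$plants_per_row <- 1L
  soil <- generate_scene(soil_cfg)
  tile <- soil$image[1 + 192:287, 1:96, 1:3]  # corner far from the single plant
  expect_true(all(soil$instance_mask[1 + 192:287, 1:96] == 0L))
  pred <- predict_mask(seg_model, tile)
  expect_gt(mean(pred == 0L), 0.99)
})

test_that("channel contracts fail fast", {
  expect_error(unet_config(in_channels = 4L), "3 or 5")
  expect_error(unet_config(conv_layer_count = 8L), "conv_layer_count")
  img3 <- seg_tiles$tiles[[1]]$image[, , 1:3]
  cfg5 <- unet_config(in_channels = 5L, base_filters = 4L, epochs = 1L, seed = 1L)
  expect_error(uavpheno:::select_bands(img3, 5L), "5-band")
  odd <- array(0.5, c(90, 96, 3))
  expect_error(predict_mask(seg_model, odd), "pad")
})

test_that("the 5-channel variant consumes the full band stack", {
  cfg5 <- unet_config(in_channels = 5L, base_filters = 8L, epochs = 3L,
                      learning_rate = 1e-3, seed = 4L)
  m5 <- train_unet(seg_tiles, cfg5)
  pred <- predict_mask(m5, seg_tiles$tiles[[1]]$image)
  expect_true(all(pred %in% c(0L, 1L)))
  expect_gt(utils::tail(m5$history$val_acc, 1), 0.9)
})

test_that("softmax class scores are a simplex over the class dimension", {
  x <- array(stats::rnorm(8 * 8 * 3), c(8, 8, 3))
  p <- uavpheno:::softmax_channels(x)
  expect_equal(apply(p, c(1, 2), sum), matrix(1, 8, 8))
  expect_true(all(p >= 0 & p <= 1))
})
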