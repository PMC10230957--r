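test_that("tiles cover the scene on a reading-order grid, dropping ragged edges", {
  sc <- generate_scene(scene_config(field_size = c(288L, 320L), n_rows = 3L,
                                    plants_per_row = 4L, row_spacing = 96,
                                    within_row_spacing = 80, seed = 2L))
  tiles <- crop_tiles(sc, 96L)
  expect_length(tiles, 3L * 3L)  # floor(320/96) = 3 columns
  origins <- t(vapply(tiles, function(t) t$origin, c(0, 0)))
  expect_equal(origins[1:3, ], rbind(c(0, 0), c(0, 96), c(0, 192)))
  expect_equal(origins[4, ], c(96, 0))
  expect_true(all(origins %% 96 == 0))
  for (tile in tiles) {
    expect_identical(dim(tile$image)[1:2], c(96L, 96L))
    expect_identical(dim(tile$mask), c(96L, 96L))
    expect_true(all(tile$mask %in% c(0L, 1L)))  # semantic reduction
  }
  expect_warning(small <- crop_tiles(sc, 608L), "smaller")
  expect_length(small, 0L)
})

test_that("reassembling tiles at their origins reproduces the cropped region", {
  sc <- generate_scene(tiny_scene_config(seed = 4L))
  tiles <- crop_tiles(sc, 96L)
  rebuilt <- array(NA_real_, c(288L, 288L, 5L))
  for (tile in tiles) {
    rebuilt[tile$origin[1] + 1:96, tile$origin[2] + 1:96, ] <- tile$image
  }
  expect_identical(rebuilt, sc$image)
})

test_that("augmentation produces the closed 4-operator set", {
  sc <- generate_scene(tiny_scene_config(seed = 4L))
  tiles <- crop_tiles(sc, 96L)
  aug <- augment_tiles(tiles)
  expect_length(aug, 4L * length(tiles))
  expect_identical(augment_tiles(tiles, enabled = FALSE), tiles)

  tile <- tiles[[5]]
  hf <- uavpheno:::apply_augmentation(tile, "hflip")
  expect_identical(uavpheno:::apply_augmentation(hf, "hflip")$mask, tile$mask)   # involution
  expect_identical(uavpheno:::apply_augmentation(hf, "hflip")$image, tile$image)
  tr <- uavpheno:::apply_augmentation(tile, "transpose")
  expect_identical(tr$mask[3, 17], tile$mask[17, 3])  # (r, c) -> (c, r)
  expect_identical(tr$image[3, 17, ], tile$image[17, 3, ])

  # connected-component count is invariant under every operator
  for (tag in c("hflip", "vflip", "transpose")) {
    for (tile in tiles[c(1, 5, 9)]) {
      a <- uavpheno:::apply_augmentation(tile, tag)
      expect_length(label_regions(a$mask), length(label_regions(tile$mask)))
    }
  }

  bad <- tile
  bad$mask <- tile$mask[1:48, ]
  bad$image <- tile$image[1:48, , , drop = FALSE]
  expect_error(augment_tiles(list(bad)), "square")
})

test_that("the 8:1:1 split partitions tiles and confines augmentation to train", {
  sc <- generate_scene(scene_config(field_size = c(480L, 384L), n_rows = 5L,
                                    plants_per_row = 4L, row_spacing = 96,
                                    within_row_spacing = 80, seed = 6L))
  tiles <- crop_tiles(sc, 96L)
  expect_length(tiles, 20L)
  ts <- split_dataset(tiles, ratios = c(8, 1, 1), seed = 13L)
  counts <- table(ts$split)
  expect_equal(unname(counts["train"]), 16L * 4L)  # augmented
  expect_equal(unname(counts["test"]), 2L)
  expect_equal(unname(counts["validation"]), 2L)

  # no augmented view leaks outside train, and partitions are disjoint on base ids
  tags <- vapply(ts$tiles, function(t) t$augmentation_tag, "")
  expect_true(all(tags[ts$split != "train"] == "identity"))
  base_of <- vapply(ts$tiles, function(t) t$parent_id %||% t$tile_id, "")
  expect_length(intersect(base_of[ts$split == "train"], base_of[ts$split != "train"]), 0L)
  expect_setequal(unique(base_of), vapply(tiles, function(t) t$tile_id, ""))

  ts2 <- split_dataset(tiles, ratios = c(8, 1, 1), seed = 13L)
  expect_identical(ts$split, ts2$split)
  expect_identical(vapply(ts$tiles, function(t) t$tile_id, ""),
                   vapply(ts2$tiles, function(t) t$tile_id, ""))

  expect_error(split_dataset(tiles[1:2]), "at least 3")
  expect_error(split_dataset(tiles, ratios = c(1, 0, 1)), "positive")
})

test_that("one-hot encoding layers are exact indicators summing to one", {
  m <- matrix(c(0L, 2L, 1L, 1L), 2, 2, byrow = TRUE)  # [[0,2],[1,1]]
  oh <- one_hot_encode(m, 3L)
  expect_identical(dim(oh), c(2L, 2L, 3L))
  expect_equal(oh[, , 2], matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  expect_true(all(apply(oh, c(1, 2), sum) == 1))

  bg <- matrix(0L, 4, 4)
  oh_bg <- one_hot_encode(bg, 2L)
  expect_true(all(oh_bg[, , 1] == 1) && all(oh_bg[, , 2] == 0))

  bad <- matrix(c(0L, 3L, 1L, 0L), 2, 2)
  expect_error(one_hot_encode(bad, 2L), "row 2, col 1")
})
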