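# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale so the whole suite trains on one CPU.

# Small field: 3 rows x 3 plants on a 288 px square (9 tiles of 96 px).
tiny_scene_config <- function(seed = 1L, ...) {
  scene_config(field_size = c(288L, 288L), n_rows = 3L, plants_per_row = 3L,
               row_spacing = 96, within_row_spacing = 80, jitter_sd = 2,
               seed = seed, ...)
}

# Default-sized scene (48 plants, 49 tiles of 96 px) used by the
# acceptance-level checks.
default_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_scene(scene_config(seed = 7L))
    cache
  }
})

# Low/high-resolution training pairs cut from a scene's RGB tiles.
make_sr_pairs <- function(n, tile_size = 96L, factor = 4L, seed = 11L) {
  sc <- default_scene()
  tiles <- crop_tiles(sc, tile_size)
  stopifnot(length(tiles) >= n)
  lapply(seq_len(n), function(i) {
    hr <- tiles[[i]]$image[, , 1:3, drop = FALSE]
    list(lr = degrade_image(hr, factor, blur_sd = 1, noise_sd = 0.01, seed = seed + i),
         hr = hr)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel_equal <- function(object, expected, tol = 1e-12) {
  expect_lt(abs(object - expected), tol * max(abs(expected), 1e-300))
}
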