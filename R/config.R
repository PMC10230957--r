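#' Experiment configuration
#'
#' Assembles and validates the nested configuration of a full experiment:
#' camera constants, synthetic scene, tiling/split, super-resolution,
#' segmentation, trait extraction, the model variants to compare, the output
#' directory and the global seed every stochastic stage derives its own seed
#' from. Each block accepts the same keys as the corresponding constructor
#' ([camera_model()], [scene_config()], [srgan_config()], [unet_config()]);
#' unspecified keys take that constructor's defaults.
#'
#' @param camera Named list for the camera block.
#' @param scene Named list for the scene block.
#' @param dataset Named list: `tile_size` (px), `ratios`
#'   (train/test/validation), `augment`.
#' @param srgan Named list for the SRGAN block, plus degradation keys
#'   `degrade_blur_sd` and `degrade_noise_sd` used to manufacture the
#'   low-resolution inputs.
#' @param unet Named list for the UNet block (`in_channels` is set per
#'   variant by the runner).
#' @param traits Named list: `min_area_px`, `max_match_dist_px`,
#'   `spad_mode` (`"RGB"` or `"G_only"`).
#' @param variants Subset of `c("multispectral", "rgb", "rgb_sr")`.
#' @param output_dir Writable directory for artifacts and reports.
#' @param seed Global integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(camera = list(),
                              scene = list(),
                              dataset = list(),
                              srgan = list(),
                              unet = list(),
                              traits = list(),
                              variants = c("multispectral", "rgb", "rgb_sr"),
                              output_dir = tempfile("uavpheno_run_"),
                              seed = 1L) {
  merge_block <- function(defaults, block, name) {
    if (is.null(block)) stop_domain("config schema error: block '", name, "' is missing")
    unknown <- setdiff(names(block), names(defaults))
    if (length(unknown)) {
      stop_domain("config schema error: unknown key(s) in '", name, "': ",
                  paste(unknown, collapse = ", "))
    }
    utils::modifyList(defaults, block)
  }
  dataset_def <- list(tile_size = 96L, ratios = c(8, 1, 1), augment = TRUE)
  srgan_def <- list(upscale_factor = 4L, n_residual_blocks = 4L, base_channels = 16L,
                    learning_rate = 1e-3, epochs = 40L, adversarial_weight = 1e-4,
                    perceptual_source = "pixel_mse",
                    degrade_blur_sd = 1, degrade_noise_sd = 0.01)
  unet_def <- list(class_count = 2L, conv_layer_count = 10L, base_filters = 8L,
                   batch_size = 2L, learning_rate = 1e-3, epochs = 10L, dropout = 0)
  traits_def <- list(min_area_px = 30L, max_match_dist_px = 25, spad_mode = "RGB")
  scene_def <- lapply(formals(scene_config)[setdiff(names(formals(scene_config)),
                                                    c("camera", "seed"))], eval)
  camera_def <- lapply(formals(camera_model), eval)

  if (length(variants) == 0L) stop_domain("config schema error: need at least one variant")
  variants <- match.arg(variants, c("multispectral", "rgb", "rgb_sr"), several.ok = TRUE)

  cfg <- structure(list(
    camera = merge_block(camera_def, camera, "camera"),
    scene = merge_block(scene_def, scene, "scene"),
    dataset = merge_block(dataset_def, dataset, "dataset"),
    srgan = merge_block(srgan_def, srgan, "srgan"),
    unet = merge_block(unet_def, unet, "unet"),
    traits = merge_block(traits_def, traits, "traits"),
    variants = variants,
    output_dir = output_dir,
    seed = as.integer(seed)
  ), class = "experiment_config")
  # fail fast on invalid nested blocks before any computation
  do.call(camera_model, cfg$camera)
  do.call(scene_config, c(cfg$scene, list(camera = do.call(camera_model, cfg$camera))))
  do.call(srgan_config, cfg$srgan[setdiff(names(cfg$srgan),
                                          c("degrade_blur_sd", "degrade_noise_sd"))])
  do.call(unet_config, c(cfg$unet, list(in_channels = 3L)))
  if (!cfg$traits$spad_mode %in% c("RGB", "G_only")) {
    stop_domain("config schema error: traits$spad_mode must be 'RGB' or 'G_only'")
  }
  cfg
}

#' Read an experiment configuration from YAML
#'
#' The file must contain the blocks `camera`, `scene`, `dataset`, `unet` and
#' the key `variants` (plus `srgan` when the `rgb_sr` variant is requested);
#' a missing block is a schema error naming the block. Keys within each
#' block are the constructor argument names (e.g. `flight_height_m`).
#'
#' @param path Path to a YAML file.
#' @param output_dir,seed Optional overrides of the file's values.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path, output_dir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  for (block in c("camera", "scene", "dataset", "unet")) {
    if (is.null(raw[[block]])) {
      stop_domain("config schema error: block '", block, "' is missing from ", path)
    }
  }
  if (is.null(raw$variants)) stop_domain("config schema error: key 'variants' is missing from ", path)
  if ("rgb_sr" %in% raw$variants && is.null(raw$srgan)) {
    stop_domain("config schema error: block 'srgan' is required for the rgb_sr variant")
  }
  # YAML reads vectors of length 1 as scalars; normalise known vector keys
  norm_vec <- function(x) if (is.list(x)) unlist(x) else x
  if (!is.null(raw$scene$field_size)) raw$scene$field_size <- as.integer(norm_vec(raw$scene$field_size))
  for (k in c("semi_axis_range", "spad_range", "spad_coeffs", "soil_mean")) {
    if (!is.null(raw$scene[[k]])) raw$scene[[k]] <- norm_vec(raw$scene[[k]])
  }
  if (!is.null(raw$dataset$ratios)) raw$dataset$ratios <- norm_vec(raw$dataset$ratios)
  experiment_config(
    camera = raw$camera,
    scene = raw$scene %||% list(),
    dataset = raw$dataset %||% list(),
    srgan = raw$srgan %||% list(),
    unet = raw$unet %||% list(),
    traits = raw$traits %||% list(),
    variants = unlist(raw$variants),
    output_dir = output_dir %||% raw$output_dir %||% tempfile("uavpheno_run_"),
    seed = seed %||% raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
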