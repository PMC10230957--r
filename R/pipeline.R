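#' Run the full phenotyping experiment
#'
#' Orchestrates the study design end to end: generates a training and a
#' held-out evaluation scene, tiles and splits the training scene, then for
#' each requested variant trains its segmenter (after super-resolution
#' enhancement for `rgb_sr`), predicts masks for both scenes, extracts
#' per-plant traits, calibrates the SPAD regression on the training scene's
#' matched plants, and evaluates length/width/SPAD predictions against the
#' evaluation scene's ground truth.
#'
#' All variants share the same scenes, tiling and split, so comparisons are
#' paired; only the input bands and the enhancement step differ. Every stage
#' writes its artifact under `output_dir/stages` and is reused on re-run
#' when `resume = TRUE`, making a completed run resumable per stage. All
#' randomness derives from the global seed.
#'
#' The `rgb_sr` variant treats the 4x-degraded imagery as its native input:
#' low-resolution tiles are manufactured with [degrade_image()], the SRGAN
#' is trained on (low, native) pairs, and segmentation runs on the enhanced
#' output, whose ground scale is `ground_scale(gsd * factor, sr_factor =
#' factor)` — physically identical to the native grid, reached through the
#' super-resolution bookkeeping.
#'
#' @param config An [experiment_config()].
#' @param resume Reuse stage artifacts found in `output_dir` (default TRUE).
#' @param quiet Suppress progress messages.
#' @param stop_after Optionally halt after an early stage (`"scenes"`,
#'   `"tiles"`, `"sr"`, `"seg"`), returning the stage artifacts instead of a
#'   report; later invocations resume from the cached artifacts.
#' @return A `comparison_report`: per-variant segmentation accuracy,
#'   per-(variant, trait) evaluation table, run metadata, and paths of the
#'   per-plant trait CSVs written under `output_dir`.
#' @export
run_experiment <- function(config, resume = TRUE, quiet = FALSE, stop_after = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$output_dir
  stage_dir <- file.path(out_dir, "stages")
  dir.create(stage_dir, recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out_dir, "run.log")
  log_msg <- function(stage, msg) {
    line <- sprintf("[%s] seed=%d %s", stage, config$seed, msg)
    if (!quiet) message(line)
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
        file = log_file, append = TRUE, sep = "")
  }
  stage <- function(name, compute) {
    f <- file.path(stage_dir, paste0(name, ".rds"))
    if (resume && file.exists(f)) {
      log_msg(name, "reusing cached artifact")
      return(readRDS(f))
    }
    log_msg(name, "running")
    value <- tryCatch(compute(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (partial artifacts kept in ", stage_dir, ")", call. = FALSE)
    })
    saveRDS(value, f)
    value
  }

  camera <- do.call(camera_model, config$camera)
  gsd <- compute_gsd(camera)
  scene_cfg <- function(s) do.call(scene_config,
                                   c(config$scene, list(camera = camera, seed = s)))
  scene_train <- stage("scene_train", function()
    generate_scene(scene_cfg(derive_seed(config$seed, "scene_train"))))
  scene_eval <- stage("scene_eval", function()
    generate_scene(scene_cfg(derive_seed(config$seed, "scene_eval"))))

  if (identical(stop_after, "scenes")) {
    return(invisible(list(scene_train = scene_train, scene_eval = scene_eval)))
  }

  tileset <- stage("tiles", function() {
    tiles <- crop_tiles(scene_train, config$dataset$tile_size)
    split_dataset(tiles, config$dataset$ratios,
                  seed = derive_seed(config$seed, "split"),
                  augment = config$dataset$augment)
  })
  if (identical(stop_after, "tiles")) return(invisible(list(tileset = tileset)))

  sr_cfg <- do.call(srgan_config, c(
    config$srgan[setdiff(names(config$srgan), c("degrade_blur_sd", "degrade_noise_sd"))],
    list(seed = derive_seed(config$seed, "srgan"))))
  degrade_tile <- function(img, tag) {
    degrade_image(img, sr_cfg$upscale_factor, config$srgan$degrade_blur_sd,
                  config$srgan$degrade_noise_sd, derive_seed(config$seed, tag))
  }

  variant_setup <- function(variant) {
    if (variant == "multispectral") {
      list(tileset = tileset, in_channels = 5L,
           scale = ground_scale(gsd, 1),
           train_img = scene_train$image, eval_img = scene_eval$image,
           train_rgb = scene_train$image[, , 1:3], eval_rgb = scene_eval$image[, , 1:3])
    } else if (variant == "rgb") {
      list(tileset = tileset, in_channels = 3L,
           scale = ground_scale(gsd, 1),
           train_img = scene_train$image[, , 1:3], eval_img = scene_eval$image[, , 1:3],
           train_rgb = scene_train$image[, , 1:3], eval_rgb = scene_eval$image[, , 1:3])
    } else { # rgb_sr
      sr_model <- stage("sr_model", function() {
        base_train <- which(tileset$split == "train" &
          vapply(tileset$tiles, function(t) t$augmentation_tag == "identity", TRUE))
        pairs <- lapply(base_train, function(i) {
          hr <- tileset$tiles[[i]]$image[, , 1:3, drop = FALSE]
          list(lr = degrade_tile(hr, paste0("deg_", tileset$tiles[[i]]$tile_id)), hr = hr)
        })
        train_srgan(pairs, sr_cfg)
      })
      sr_tileset <- stage("sr_tiles", function() {
        ts <- tileset
        ts$tiles <- lapply(seq_along(ts$tiles), function(i) {
          tile <- ts$tiles[[i]]
          lr <- degrade_tile(tile$image[, , 1:3, drop = FALSE],
                             paste0("deg_", tile$tile_id, "_", tile$augmentation_tag))
          tile$image <- enhance_image(lr, sr_model)
          tile
        })
        ts
      })
      enhance_scene <- function(scene, tag) {
        lr <- degrade_tile(scene$image[, , 1:3, drop = FALSE], tag)
        enhance_image(lr, sr_model)
      }
      train_sr <- stage("sr_scene_train", function() enhance_scene(scene_train, "deg_scene_train"))
      eval_sr <- stage("sr_scene_eval", function() enhance_scene(scene_eval, "deg_scene_eval"))
      list(tileset = sr_tileset, in_channels = 3L,
           scale = ground_scale(gsd * sr_cfg$upscale_factor, sr_cfg$upscale_factor),
           train_img = train_sr, eval_img = eval_sr,
           train_rgb = train_sr, eval_rgb = eval_sr,
           sr_model = sr_model)
    }
  }

  evaluations <- NULL
  seg_accuracy <- c()
  trait_csvs <- character(0)
  if (identical(stop_after, "sr")) {
    if (!"rgb_sr" %in% config$variants) {
      stop_domain("stop_after = 'sr' needs the rgb_sr variant")
    }
    return(invisible(variant_setup("rgb_sr")["sr_model"]))
  }
  seg_models <- list()
  for (variant in config$variants) {
    vs <- variant_setup(variant)
    seg <- stage(paste0("seg_", variant), function() {
      ucfg <- do.call(unet_config, c(config$unet, list(
        in_channels = vs$in_channels,
        seed = derive_seed(config$seed, paste0("unet_", variant)))))
      train_unet(vs$tileset, ucfg)
    })
    seg_models[[variant]] <- seg
    if (identical(stop_after, "seg")) next
    res <- stage(paste0("traits_", variant), function() {
      pred_eval <- predict_mask(seg, vs$eval_img)
      pred_train <- predict_mask(seg, vs$train_img)
      acc <- pixel_accuracy(pred_eval, scene_semantic_mask(scene_eval))
      rec_train <- extract_traits(pred_train, vs$train_rgb, vs$scale,
                                  config$traits$min_area_px)
      mt_train <- match_to_truth(rec_train, scene_train$truth,
                                 config$traits$max_match_dist_px)
      cal <- mt_train[!is.na(mt_train$matched_truth_id), ]
      mlr <- fit_spad_mlr(cal[c("R", "G", "B")], cal$true_spad,
                          config$traits$spad_mode)
      rec_eval <- extract_traits(pred_eval, vs$eval_rgb, vs$scale,
                                 config$traits$min_area_px)
      mt_eval <- match_to_truth(rec_eval, scene_eval$truth,
                                config$traits$max_match_dist_px)
      matched <- mt_eval[!is.na(mt_eval$matched_truth_id), ]
      matched$pred_spad <- as.numeric(predict_spad(mlr, matched))
      ev <- function(trait, actual, pred) {
        r <- tryCatch(evaluate_predictions(actual, pred), error = function(e) NULL)
        data.frame(variant = variant, trait = trait,
                   r2 = r$r2 %||% NA_real_, r2_residual = r$r2_residual %||% NA_real_,
                   rmspe = r$rmspe %||% NA_real_, rmse = r$rmse %||% NA_real_,
                   n = r$n %||% nrow(matched))
      }
      evals <- rbind(
        ev("length", matched$true_length_m * 100, matched$pred_length_m * 100),
        ev("width", matched$true_width_m * 100, matched$pred_width_m * 100),
        ev("spad", matched$true_spad, matched$pred_spad))
      list(acc = acc, evals = evals, records = mt_eval, matched = matched, mlr = mlr)
    })
    seg_accuracy[variant] <- res$acc
    evaluations <- rbind(evaluations, res$evals)
    csv <- file.path(out_dir, paste0("traits_", variant, ".csv"))
    tab <- res$records
    out_tab <- data.frame(
      region_id = tab$region_id,
      length_cm = tab$pred_length_m * 100,
      width_cm = tab$pred_width_m * 100,
      spad_pred = as.numeric(predict_spad(res$mlr, tab)),
      matched_truth_id = tab$matched_truth_id,
      true_length_cm = if (is.null(tab$true_length_m)) NA_real_ else tab$true_length_m * 100,
      true_width_cm = if (is.null(tab$true_width_m)) NA_real_ else tab$true_width_m * 100,
      true_spad = if (is.null(tab$true_spad)) NA_real_ else tab$true_spad)
    utils::write.csv(out_tab, csv, row.names = FALSE)
    trait_csvs[variant] <- csv
    log_msg(variant, sprintf("seg accuracy %.4f; %d/%d plants matched",
                             res$acc, sum(!is.na(tab$matched_truth_id)),
                             nrow(scene_eval$truth)))
  }
  if (identical(stop_after, "seg")) return(invisible(seg_models))

  eval_csv <- file.path(out_dir, "evaluation.csv")
  utils::write.csv(evaluations, eval_csv, row.names = FALSE)
  report <- structure(list(
    seg_accuracy = seg_accuracy,
    evaluations = evaluations,
    trait_csvs = trait_csvs,
    evaluation_csv = eval_csv,
    metadata = list(seed = config$seed, variants = config$variants,
                    package_version = as.character(utils::packageVersion("uavpheno")),
                    timestamp = format(Sys.time())),
    output_dir = out_dir
  ), class = "comparison_report")
  saveRDS(report, file.path(out_dir, "report.rds"))
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n segmentation accuracy:\n")
  for (v in names(x$seg_accuracy)) cat(sprintf("   %-13s %.4f\n", v, x$seg_accuracy[v]))
  cat(" trait evaluation (eval scene):\n")
  print(x$evaluations, row.names = FALSE)
  invisible(x)
}

#' Rank model variants per trait
#'
#' Ranks variants within each trait by R-squared (higher better), breaking
#' ties by lower RMSE, and summarises an overall ranking by mean rank.
#'
#' @param report A `comparison_report` from [run_experiment()].
#' @param path Optional CSV path for the flat ranked table.
#' @return List with `table` (ranked per-trait rows) and `overall`
#'   (variant, mean_rank; best first).
#' @export
compare_variants <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  ev <- report$evaluations
  if (is.null(ev) || nrow(ev) == 0L) stop_domain("compare_variants: empty report")
  ranked <- do.call(rbind, lapply(split(ev, ev$trait), function(g) {
    g <- g[order(-g$r2, g$rmse), ]
    g$rank <- seq_len(nrow(g))
    g
  }))
  rownames(ranked) <- NULL
  overall <- stats::aggregate(rank ~ variant, ranked, mean)
  names(overall)[2] <- "mean_rank"
  overall <- overall[order(overall$mean_rank, overall$variant), ]
  rownames(overall) <- NULL
  if (!is.null(path)) utils::write.csv(ranked, path, row.names = FALSE)
  out <- list(table = ranked, overall = overall)
  class(out) <- "variant_comparison"
  out
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("Per-trait ranking (R2 primary, RMSE tie-break):\n")
  print(x$table[c("trait", "variant", "r2", "rmse", "rank")], row.names = FALSE)
  cat("\nOverall (mean rank, best first):\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}
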