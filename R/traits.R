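#' Label plant regions in a segmentation mask
#'
#' Finds plant instances as 8-connected components of the foreground (or
#' reads them directly from an instance-labelled mask), drops speckles below
#' `min_area_px`, and numbers regions in reading order of their top-left
#' bounding-box corner. Coordinates are 0-based with half-open bounding
#' boxes; `length_px`/`width_px` are the max/min bounding-box extents
#' (orientation-free convention).
#'
#' @param mask Integer matrix; 0 is background. With `mode = "connected"`
#'   any positive value is foreground; with `mode = "instance"` each
#'   distinct positive value is its own region.
#' @param min_area_px Minimum pixel area for a region to be kept.
#' @param mode `"connected"` (default) or `"instance"`.
#' @return List of `plant_region` objects with fields `region_id`, `bbox`
#'   (`min_row, min_col, max_row, max_col`, half-open), `length_px`,
#'   `width_px`, `area_px`, `centroid` (row, col), `pixels` (linear indices)
#'   and `channel_means` (filled by [extract_region_features()]).
#' @export
label_regions <- function(mask, min_area_px = 0L, mode = c("connected", "instance")) {
  mode <- match.arg(mode)
  H <- nrow(mask)
  lab <- if (mode == "connected") .label8(mask > 0L) else mask
  ids <- sort(unique(lab[lab > 0L]))
  regions <- list()
  for (id in ids) {
    pix <- which(lab == id)
    if (length(pix) < min_area_px) next
    r <- (pix - 1L) %% H
    c <- (pix - 1L) %/% H
    bbox <- c(min(r), min(c), max(r) + 1L, max(c) + 1L)
    ext <- c(bbox[3] - bbox[1], bbox[4] - bbox[2])
    regions[[length(regions) + 1L]] <- structure(list(
      region_id = NA_integer_,
      bbox = bbox,
      length_px = max(ext),
      width_px = min(ext),
      area_px = length(pix),
      centroid = c(mean(r), mean(c)),
      pixels = pix,
      source_label = id,
      channel_means = NULL
    ), class = "plant_region")
  }
  if (length(regions) == 0L) return(regions)
  ord <- order(vapply(regions, function(x) x$bbox[1], 0),
               vapply(regions, function(x) x$bbox[2], 0))
  regions <- regions[ord]
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  regions
}

#' Complete a region with per-channel means
#'
#' Averages the first three bands (R, G, B) over the region's own pixels
#' only — background and bounding-box fill are excluded.
#'
#' @param region A `plant_region`.
#' @param rgb_image `(H, W, >= 3)` array the mask was predicted on.
#' @return The region with `channel_means` set (named R, G, B).
#' @export
extract_region_features <- function(region, rgb_image) {
  stopifnot(inherits(region, "plant_region"))
  if (length(region$pixels) == 0L) stop_domain("extract_region_features: empty region")
  npix <- dim(rgb_image)[1] * dim(rgb_image)[2]
  if (max(region$pixels) > npix) {
    stop_domain("extract_region_features: region pixels outside image bounds")
  }
  means <- vapply(1:3, function(b) mean(rgb_image[, , b][region$pixels]), 0)
  region$channel_means <- c(R = means[1], G = means[2], B = means[3])
  region
}

#' Convert region pixel extents to physical lengths
#'
#' @param region A `plant_region`.
#' @param scale A [ground_scale()]; `sr_factor` is honoured for masks
#'   predicted on super-resolved imagery.
#' @return Named numeric `(length, width)` in metres.
#' @export
region_to_physical <- function(region, scale) {
  c(length = px_to_length(region$length_px, scale),
    width = px_to_length(region$width_px, scale))
}

#' Fit the SPAD multiple linear regression
#'
#' Ordinary least squares with intercept of observed SPAD on per-plant
#' channel means: either the G channel alone or all three RGB channels.
#'
#' @param features Data frame with columns `R`, `G`, `B` (or at least `G`
#'   for `mode = "G_only"`), per-plant channel means in `[0, 1]`.
#' @param spad Observed SPAD values, same length.
#' @param mode `"RGB"` (3 slopes) or `"G_only"` (1 slope).
#' @return An `mlr_model` with `intercept`, named `coefficients`, their
#'   standard errors `se`, and `fit_n`.
#' @export
fit_spad_mlr <- function(features, spad, mode = c("RGB", "G_only")) {
  mode <- match.arg(mode)
  vars <- if (mode == "RGB") c("R", "G", "B") else "G"
  missing_cols <- setdiff(vars, names(features))
  if (length(missing_cols)) {
    stop_domain("fit_spad_mlr: missing feature column(s) ", paste(missing_cols, collapse = ", "))
  }
  n <- length(spad)
  if (nrow(features) != n) stop_domain("fit_spad_mlr: features and spad lengths differ")
  if (n < length(vars) + 2L) {
    stop_domain("fit_spad_mlr: need at least ", length(vars) + 2L, " observations")
  }
  df <- cbind(data.frame(spad = spad), features[vars])
  fit <- stats::lm(stats::reformulate(vars, "spad"), data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_domain("fit_spad_mlr: collinear feature column(s): ",
                paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  # suppressed: noiseless calibration data triggers stats' perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(mode = mode,
                 intercept = unname(cf[1]),
                 coefficients = cf[-1],
                 se = se,
                 sigma = sm$sigma,
                 fit_n = n),
            class = "mlr_model")
}

#' Predict SPAD from channel means
#'
#' Linear evaluation of a fitted [fit_spad_mlr()] model. Predictions are not
#' clipped; values outside the instrument's 0--99 range are flagged in the
#' `out_of_range` attribute.
#'
#' @param model An `mlr_model`.
#' @param features Data frame containing the model's feature columns.
#' @return Numeric predictions with attribute `out_of_range`.
#' @export
predict_spad <- function(model, features) {
  stopifnot(inherits(model, "mlr_model"))
  vars <- names(model$coefficients)
  missing_cols <- setdiff(vars, names(features))
  if (length(missing_cols)) {
    stop_domain("predict_spad: missing feature column(s) ", paste(missing_cols, collapse = ", "))
  }
  pred <- model$intercept + as.matrix(features[vars]) %*% model$coefficients
  pred <- drop(pred)
  attr(pred, "out_of_range") <- pred < 0 | pred > 99
  pred
}

#' Evaluate predictions with R-squared, RMSPE and RMSE
#'
#' The coefficient of determination follows the explained-variance form
#' `sum((pred - mean(actual))^2) / sum((actual - mean(actual))^2)`, which can
#' exceed 1; the conventional residual form `1 - SSE/SST` is also returned
#' as `r2_residual`. RMSPE is the root mean square of relative errors
#' `(actual - pred)/actual` and RMSE the root mean square error.
#'
#' @param actual,predicted Numeric vectors of equal length `n >= 2`.
#' @return An `eval_report` list: `r2`, `r2_residual`, `rmspe`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(actual, predicted) {
  n <- length(actual)
  if (length(predicted) != n) stop_domain("evaluate_predictions: length mismatch")
  if (n < 2L) stop_domain("evaluate_predictions: need n >= 2")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop_domain("evaluate_predictions: zero variance in 'actual'; R-squared undefined")
  if (any(actual == 0)) stop_domain("evaluate_predictions: zero value in 'actual'; RMSPE undefined")
  ssr <- sum((predicted - mean(actual))^2)
  sse <- sum((actual - predicted)^2)
  structure(list(r2 = ssr / sst,
                 r2_residual = 1 - sse / sst,
                 rmspe = sqrt(mean(((actual - predicted) / actual)^2)),
                 rmse = sqrt(sse / n),
                 n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d: R2 = %.4f (residual form %.4f), RMSPE = %.4f, RMSE = %.4f\n",
              x$n, x$r2, x$r2_residual, x$rmspe, x$rmse))
  invisible(x)
}

#' Extract per-plant trait records from a mask
#'
#' Convenience composition of [label_regions()], [extract_region_features()]
#' and [region_to_physical()] into one record table.
#'
#' @param mask Integer segmentation (or instance) mask.
#' @param image `(H, W, >= 3)` array the mask belongs to.
#' @param scale A [ground_scale()].
#' @param min_area_px Speckle-removal threshold, pixels.
#' @param mode Passed to [label_regions()].
#' @return Data frame with one row per region: `region_id`, centroid,
#'   pixel and physical extents, and RGB channel means.
#' @export
extract_traits <- function(mask, image, scale, min_area_px = 0L,
                           mode = c("connected", "instance")) {
  regions <- label_regions(mask, min_area_px, match.arg(mode))
  if (length(regions) == 0L) {
    return(data.frame(region_id = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), length_px = integer(0),
                      width_px = integer(0), area_px = integer(0),
                      pred_length_m = numeric(0), pred_width_m = numeric(0),
                      R = numeric(0), G = numeric(0), B = numeric(0),
                      source_label = integer(0)))
  }
  rows <- lapply(regions, function(rg) {
    rg <- extract_region_features(rg, image)
    phys <- region_to_physical(rg, scale)
    data.frame(region_id = rg$region_id,
               centroid_row = rg$centroid[1], centroid_col = rg$centroid[2],
               length_px = rg$length_px, width_px = rg$width_px,
               area_px = rg$area_px,
               pred_length_m = unname(phys["length"]),
               pred_width_m = unname(phys["width"]),
               R = unname(rg$channel_means["R"]),
               G = unname(rg$channel_means["G"]),
               B = unname(rg$channel_means["B"]),
               source_label = rg$source_label)
  })
  do.call(rbind, rows)
}

#' Match predicted regions to ground-truth plants
#'
#' Greedy mutual-nearest centroid matching: repeatedly pairs the globally
#' closest unmatched (region, truth) pair within `max_dist_px`; distance
#' ties break toward the region (then truth) earlier in reading order.
#'
#' @param records Data frame from [extract_traits()] (needs `region_id`,
#'   `centroid_row`, `centroid_col`).
#' @param truth Scene truth table (needs `plant_id`, `center_row_px`,
#'   `center_col_px`, and any `true_*` columns to carry over).
#' @param max_dist_px Maximum matching radius in pixels.
#' @return The records with `matched_truth_id` and truth columns joined for
#'   matched rows; attributes `unmatched_regions` (false positives) and
#'   `unmatched_truth` (misses) list the leftovers.
#' @export
match_to_truth <- function(records, truth, max_dist_px = 20) {
  nr <- nrow(records); nt <- nrow(truth)
  match_r <- rep(NA_integer_, nr)
  if (nr > 0 && nt > 0) {
    d <- outer(records$centroid_row, truth$center_row_px, "-")^2 +
      outer(records$centroid_col, truth$center_col_px, "-")^2
    d <- sqrt(d)
    free_r <- rep(TRUE, nr); free_t <- rep(TRUE, nt)
    repeat {
      dd <- d
      dd[!free_r, ] <- Inf
      dd[, !free_t] <- Inf
      m <- min(dd)
      if (!is.finite(m) || m > max_dist_px) break
      hits <- which(dd == m, arr.ind = TRUE)
      hit <- hits[order(hits[, 1], hits[, 2])[1], ]
      match_r[hit[1]] <- hit[2]
      free_r[hit[1]] <- FALSE
      free_t[hit[2]] <- FALSE
    }
  }
  out <- records
  out$matched_truth_id <- ifelse(is.na(match_r), NA_integer_, truth$plant_id[match_r])
  carry <- intersect(c("true_length_m", "true_width_m", "true_spad"), names(truth))
  for (cn in carry) out[[cn]] <- ifelse(is.na(match_r), NA_real_, truth[[cn]][match_r])
  attr(out, "unmatched_regions") <- records$region_id[is.na(match_r)]
  attr(out, "unmatched_truth") <- truth$plant_id[!seq_len(nt) %in% match_r]
  out
}
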