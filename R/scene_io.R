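#' Write a scene bundle to disk
#'
#' Persists one synthetic scene as plain, documented formats inside a
#' directory: `image.tif` (multi-page 32-bit float TIFF, one page per band in
#' the order R, G, B, RE, NIR), `mask.tif` (16-bit single-band TIFF instance labels),
#' `truth.csv` (per-plant truth with unit-suffixed column names, written at
#' full precision so doubles round-trip exactly) and `meta.yml` (GSD and band
#' order). Mask and truth round-trip losslessly; image values round-trip to
#' 32-bit float precision.
#'
#' @param bundle A `scene_bundle` from [generate_scene()].
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "scene_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(bundle$image)[3]), function(b) bundle$image[, , b])
  tiff::writeTIFF(pages, file.path(path, "image.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(bundle$instance_mask / 65535, file.path(path, "mask.tif"),
                  bits.per.sample = 16L)
  write_csv_exact(bundle$truth, file.path(path, "truth.csv"))
  # gsd as a 17-significant-digit string so the double round-trips exactly
  yaml::write_yaml(list(gsd_m_per_px = sprintf("%.17g", bundle$gsd),
                        band_names = as.list(bundle$band_names)),
                   file.path(path, "meta.yml"))
  invisible(path)
}

# masks travel as [0,1]-scaled 16-bit rasters; decode back to integer labels
decode_mask <- function(img) {
  m <- as.integer(round(img * 65535))
  dim(m) <- dim(img)
  m
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  for (f in c("image.tif", "mask.tif", "truth.csv", "meta.yml")) {
    if (!file.exists(file.path(path, f))) {
      stop_domain("read_bundle: missing file '", f, "' in ", path)
    }
  }
  pages <- tiff::readTIFF(file.path(path, "image.tif"), all = TRUE)
  image <- array(0, c(dim(pages[[1]]), length(pages)))
  for (b in seq_along(pages)) image[, , b] <- pages[[b]]
  mask <- decode_mask(tiff::readTIFF(file.path(path, "mask.tif")))
  truth <- utils::read.csv(file.path(path, "truth.csv"))
  meta <- yaml::read_yaml(file.path(path, "meta.yml"))
  if (anyDuplicated(truth$plant_id)) {
    stop_domain("read_bundle: duplicated plant_id ",
                truth$plant_id[duplicated(truth$plant_id)][1], " in truth.csv")
  }
  labels <- sort(unique(mask[mask > 0L]))
  if (!setequal(labels, truth$plant_id)) {
    stop_domain("read_bundle: mask labels and truth plant_ids disagree")
  }
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop_domain("read_bundle: image and mask dimensions disagree")
  }
  structure(list(image = image, instance_mask = mask, truth = truth,
                 gsd = as.numeric(meta$gsd_m_per_px),
                 band_names = unlist(meta$band_names),
                 config = NULL),
            class = "scene_bundle")
}
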