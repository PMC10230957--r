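#' Camera and flight model
#'
#' Bundles the flight/optics constants from which the ground sampling
#' distance (GSD) derives: flight height above ground, physical pixel pitch
#' on the sensor, focal length, and the sensor's pixel counts. All values are
#' converted to metres internally; the constructor accepts the mixed units
#' conventionally quoted for UAV platforms (m, micrometres, mm).
#'
#' Defaults correspond to a consumer multispectral drone platform flown at
#' 10 m: pixel pitch 3 um, focal length 5.74 mm, 1600 x 1300 px frames.
#'
#' @param flight_height_m Flight height above ground, metres.
#' @param pixel_pitch_um Physical size of one sensor pixel, micrometres.
#' @param focal_length_mm Lens focal length, millimetres.
#' @param image_width_px Sensor width in pixels (the long, 1600-px axis).
#' @param image_height_px Sensor height in pixels (the short, 1300-px axis).
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' compute_gsd(cam) * 1000   # ~5.23 mm per pixel
#' @export
camera_model <- function(flight_height_m = 10,
                         pixel_pitch_um = 3,
                         focal_length_mm = 5.74,
                         image_width_px = 1600,
                         image_height_px = 1300) {
  check_positive(flight_height_m, "flight_height_m")
  check_positive(pixel_pitch_um, "pixel_pitch_um")
  check_positive(focal_length_mm, "focal_length_mm")
  check_positive(image_width_px, "image_width_px")
  check_positive(image_height_px, "image_height_px")
  structure(list(
    flight_height = flight_height_m,          # m
    pixel_pitch = pixel_pitch_um * 1e-6,      # m
    focal_length = focal_length_mm * 1e-3,    # m
    image_width = as.integer(image_width_px),
    image_height = as.integer(image_height_px)
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf(
    "<camera_model> H = %g m, pixel pitch = %g um, f = %g mm, frame %d x %d px\n",
    x$flight_height, x$pixel_pitch * 1e6, x$focal_length * 1e3,
    x$image_width, x$image_height))
  cat(sprintf("  GSD = %.4f mm/px\n", compute_gsd(x) * 1000))
  invisible(x)
}

#' Ground sampling distance
#'
#' Physical ground distance covered by one image pixel for a nadir camera:
#' `GSD = H * a / f`, with flight height `H`, pixel pitch `a`, and focal
#' length `f` all in metres.
#'
#' @param camera A [camera_model()].
#' @return GSD in metres per pixel.
#' @export
compute_gsd <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  camera$flight_height * camera$pixel_pitch / camera$focal_length
}

#' Ground footprint of one captured frame
#'
#' Physical extent of a full frame on the ground: length is the 1600-px
#' (width) axis times GSD, width the 1300-px (height) axis times GSD, and
#' area their product.
#'
#' @param camera A [camera_model()].
#' @return A `footprint` list with `length`, `width` (m) and `area` (m^2).
#' @export
image_footprint <- function(camera) {
  gsd <- compute_gsd(camera)
  len <- camera$image_width * gsd
  wid <- camera$image_height * gsd
  structure(list(length = len, width = wid, area = len * wid),
            class = "footprint")
}

#' Ground scale for pixel-to-length conversion
#'
#' Couples a GSD with the resolution-enhancement factor of the imagery a mask
#' was measured on. Super-resolved imagery has `sr_factor` times more pixels
#' per ground distance, so physical sizes divide pixel counts by `sr_factor`.
#'
#' @param gsd Ground sampling distance of the *native* grid, m/px.
#' @param sr_factor Resolution-enhancement multiplier, >= 1 (1 = native).
#' @return An object of class `ground_scale`.
#' @export
ground_scale <- function(gsd, sr_factor = 1) {
  check_positive(gsd, "gsd")
  if (!is.numeric(sr_factor) || length(sr_factor) != 1L || sr_factor < 1) {
    stop_domain("field 'sr_factor' must be a single number >= 1")
  }
  structure(list(gsd = gsd, sr_factor = sr_factor), class = "ground_scale")
}

#' Convert a pixel count to a physical ground length
#'
#' @param n_px Non-negative pixel count (extent along one axis).
#' @param scale A [ground_scale()].
#' @return Length in metres: `n_px * gsd / sr_factor`.
#' @export
px_to_length <- function(n_px, scale) {
  stopifnot(inherits(scale, "ground_scale"))
  if (any(n_px < 0)) stop_domain("field 'n_px' must be non-negative")
  n_px * scale$gsd / scale$sr_factor
}

# Build a camera_model from a `camera:` config block (YAML/JSON keys).
camera_from_config <- function(block) {
  if (is.null(block)) stop_domain("config block 'camera' is missing")
  defaults <- formals(camera_model)
  keys <- names(defaults)
  args <- lapply(keys, function(k) if (!is.null(block[[k]])) block[[k]] else eval(defaults[[k]]))
  names(args) <- keys
  do.call(camera_model, args)
}
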