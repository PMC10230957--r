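#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)` between two equally shaped images. Identical
#' images (MSE = 0) return `Inf` as the documented sentinel.
#'
#' @param a,b Matrices or arrays of identical dimensions.
#' @param max_val Maximum possible pixel value of the stored domain
#'   (1 for reflectance-domain images, 255 for 8-bit exports).
#' @return PSNR in decibels.
#' @export
psnr <- function(a, b, max_val = 1) {
  if (!identical(dim(a), dim(b))) stop_domain("psnr: images have different dimensions")
  check_positive(max_val, "max_val")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

#' Structural similarity index
#'
#' Windowed SSIM with a Gaussian window (sd 1.5 px, radius 5) and the
#' standard stabilising constants `C1 = (0.01 max_val)^2`,
#' `C2 = (0.03 max_val)^2`. Multi-channel inputs report the channel mean.
#' Larger is better; identical images score 1.
#'
#' @inheritParams psnr
#' @return SSIM in `[0, 1]` for non-negative image domains.
#' @export
ssim <- function(a, b, max_val = 1) {
  if (!identical(dim(a), dim(b))) stop_domain("ssim: images have different dimensions")
  check_positive(max_val, "max_val")
  if (!is.matrix(a)) {
    vals <- vapply(seq_len(dim(a)[3]), function(c) ssim(a[, , c], b[, , c], max_val), 0)
    return(mean(vals))
  }
  C1 <- (0.01 * max_val)^2
  C2 <- (0.03 * max_val)^2
  win_sd <- 1.5
  mu_a <- gauss_blur_mat(a, win_sd)
  mu_b <- gauss_blur_mat(b, win_sd)
  var_a <- gauss_blur_mat(a * a, win_sd) - mu_a^2
  var_b <- gauss_blur_mat(b * b, win_sd) - mu_b^2
  cov_ab <- gauss_blur_mat(a * b, win_sd) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * cov_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (var_a + var_b + C2)
  mean(num / den)
}

#' Pixel accuracy of a predicted label raster
#'
#' Fraction of pixels whose predicted label equals the reference label.
#'
#' @param pred,truth Integer label matrices of identical dimensions.
#' @return Accuracy in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop_domain("pixel_accuracy: rasters have different dimensions")
  }
  mean(pred == truth)
}
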