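#' @useDynLib uavpheno, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif lm coef predict sd
#' @importFrom utils read.csv write.csv
NULL

# Derive a reproducible sub-seed for a named stage from a master seed.
# Keeps results < 2^31 so they remain valid R integers.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483629 + 1)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) || value <= 0) {
    stop_domain("field '", field, "' must be a single strictly positive number")
  }
  invisible(value)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Separable Gaussian blur with replicated edges; m is a matrix.
gauss_blur_mat <- function(m, sd) {
  if (sd <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sd)))
  kern <- stats::dnorm(seq(-r, r), sd = sd)
  kern <- kern / sum(kern)
  blur1 <- function(mm) { # along rows
    H <- nrow(mm)
    out <- 0
    for (j in seq_along(kern)) {
      idx <- pmin(pmax(seq_len(H) + j - 1L - r, 1L), H)
      out <- out + kern[j] * mm[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(m))))
}

# Gaussian blur applied per channel of an (H, W, C) array (or a matrix).
gauss_blur <- function(x, sd) {
  if (is.matrix(x)) return(gauss_blur_mat(x, sd))
  for (c in seq_len(dim(x)[3])) x[, , c] <- gauss_blur_mat(x[, , c], sd)
  x
}

# factor x factor block-mean downsampling of a matrix.
block_mean_mat <- function(m, factor) {
  H <- nrow(m); W <- ncol(m)
  a <- array(m, c(factor, H %/% factor, factor, W %/% factor))
  s <- 0
  for (i in seq_len(factor)) for (j in seq_len(factor)) {
    sl <- a[i, , j, , drop = FALSE]
    dim(sl) <- c(H %/% factor, W %/% factor)
    s <- s + sl
  }
  s / (factor * factor)
}

#' Nearest-neighbour upsampling
#'
#' Repeats each pixel `factor` times along both spatial axes. Used as the
#' non-learned baseline that super-resolution output is compared against.
#'
#' @param image Matrix or `(H, W, C)` array.
#' @param factor Positive integer upscale factor.
#' @return Array of dimensions `(H*factor, W*factor, C)` (or matrix).
#' @export
upsample_nearest <- function(image, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop_domain("'factor' must be a positive integer")
  if (is.matrix(image)) {
    return(image[rep(seq_len(nrow(image)), each = factor),
                 rep(seq_len(ncol(image)), each = factor), drop = FALSE])
  }
  image[rep(seq_len(dim(image)[1]), each = factor),
        rep(seq_len(dim(image)[2]), each = factor), , drop = FALSE]
}

# Write a data.frame to CSV with numerics at 17 significant digits so that
# reading the file back reproduces the doubles exactly.
write_csv_exact <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}
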