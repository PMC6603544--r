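#' Round half away from zero
#'
#' Fixed-point rounding with ties going up, the convention used when
#' reporting NNI to two decimals. Base `round()` rounds half to even, which
#' would turn 1.005 into 1.00 rather than 1.01.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Label connected components of a binary mask
#'
#' Two-pass union-find labelling with selectable pixel connectivity.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape; background 0, components
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  .cc_label(mask & !is.na(mask), as.integer(connectivity))
}

#' Read an 8-bit RGB image
#'
#' @param path PNG (or JPEG read through png is not supported; use PNG).
#' @return numeric array `height x width x 3` with values in 0..255.
#' @export
read_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  round(a * 255)
}

#' Write an 8-bit RGB image or mask as PNG
#'
#' Logical matrices are written as 0/255 grayscale.
#'
#' @param x RGB array (0..255) or logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x) * 255, nrow(x), ncol(x))
  png::writePNG(clamp(x / 255, 0, 1), path)
  invisible(path)
}

validate_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("image must be a height x width x 3 array")
  if (min(image) < 0 || max(image) > 255)
    stop("channel values must lie in [0, 255]")
  invisible(image)
}

# derive a stage seed from a master seed; keeps results < 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000L * as.integer(offset)) %% .Machine$integer.max
}
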