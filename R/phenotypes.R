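# The 65-feature phenotype extractor: 45 colour statistics over nine
# channels in three colour spaces, six grey-level co-occurrence (Haralick)
# texture features, and 14 contour-geometry features (see geometry.R).

# --- colour-space conversions (8-bit imaging-toolchain conventions) -------

# HSV with H on the half-degree scale [0, 180) and S, V scaled to 0-255
rgb_to_hsv8 <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  list(H = hsv[1, ] * 180, S = hsv[2, ] * 255, V = hsv[3, ] * 255)
}

# CIE Lab (D65) with L scaled to 0-255 and a, b offset by +128
rgb_to_lab8 <- function(r, g, b) {
  lab <- grDevices::convertColor(cbind(r, g, b) / 255,
                                 from = "sRGB", to = "Lab")
  list(L = lab[, 1] * 255 / 100, a = lab[, 2] + 128, b = lab[, 3] + 128)
}

# five order statistics per channel; population standard deviation
.channel_stats <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  c(mean = m, std = s, median = median(x), range = max(x) - min(x),
    cv = if (m == 0) 0 else s / m)
}

#' Colour features (45 values)
#'
#' Mean, population standard deviation, median, range and coefficient of
#' variation of each of the nine channels R, G, B (raw 8-bit), L, a, b
#' (CIE Lab, 8-bit offsets) and H, S, V (H on the half-degree 0-180 scale),
#' computed over plant-mask pixels only. A channel with zero mean reports a
#' coefficient of variation of 0.
#'
#' @param image RGB array (0-255).
#' @param mask logical plant mask of the same extent.
#' @return named numeric vector of length 45.
#' @export
color_features <- function(image, mask) {
  validate_rgb(image)
  stopifnot(identical(dim(mask), dim(image)[1:2]))
  if (!any(mask)) stop("mask is empty")
  r <- image[, , 1][mask]; g <- image[, , 2][mask]; b <- image[, , 3][mask]
  hsv <- rgb_to_hsv8(r, g, b)
  lab <- rgb_to_lab8(r, g, b)
  chans <- list(R = r, G = g, B = b, L = lab$L, a = lab$a, b = lab$b,
                H = hsv$H, S = hsv$S, V = hsv$V)
  out <- unlist(lapply(chans, .channel_stats))
  names(out) <- feature_names()[1:45]
  out
}

#' Grey-level co-occurrence parameters
#'
#' Canonical Haralick configuration: unit distance, the four principal
#' directions averaged, full 8-bit grey resolution, symmetric and
#' normalised counts.
#'
#' @param distance pixel offset distance.
#' @param angles offset directions in degrees (subset of 0, 45, 90, 135).
#' @param levels number of grey levels (2-256).
#' @param symmetric count each pair in both directions.
#' @param normalized normalise counts to probabilities.
#' @return object of class `glcm_params`.
#' @export
glcm_params <- function(distance = 1, angles = c(0, 45, 90, 135),
                        levels = 256, symmetric = TRUE, normalized = TRUE) {
  if (distance < 1) stop("distance must be >= 1")
  if (levels < 2 || levels > 256) stop("levels must be in [2, 256]")
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop("angles must be a subset of {0, 45, 90, 135}")
  structure(list(distance = as.integer(distance), angles = angles,
                 levels = as.integer(levels), symmetric = symmetric,
                 normalized = normalized),
            class = "glcm_params")
}

# row/column offset of a co-occurrence direction, image convention
# (0 deg = east, angles measured counter-clockwise)
.angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("unsupported angle: ", angle))
}

# accumulate the (optionally symmetric) co-occurrence count matrix for one
# offset, pairing only pixels that are both inside the mask
.glcm_counts <- function(q, mask, offset, levels, symmetric) {
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) return(matrix(0, levels, levels))
  a <- q[r1, c1, drop = FALSE]
  bm <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  i <- a[bm]; j <- b[bm]
  if (!length(i)) return(matrix(0, levels, levels))
  cnt <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  m <- matrix(cnt, levels, levels, byrow = TRUE)  # rows = i, cols = j
  if (symmetric) m <- m + t(m)
  m
}

#' Grey-level co-occurrence texture features (6 values)
#'
#' The image is converted to BT.601 grey levels over the mask bounding box,
#' quantised to `levels` grey levels, and co-occurrence pairs are tallied
#' at the configured offsets with background pixels excluded. Matrices are
#' normalised per direction and averaged; features follow the classical
#' definitions (contrast, dissimilarity, homogeneity, energy, correlation,
#' angular second moment), with `energy = sqrt(ASM)`. A single-grey-level
#' region has zero co-occurrence dispersion; its correlation is reported as
#' 1 by convention (attribute `degenerate_correlation`).
#'
#' @param image RGB array (0-255).
#' @param mask logical plant mask.
#' @param glcm a [glcm_params()].
#' @return named numeric vector of length 6.
#' @export
texture_features <- function(image, mask, glcm = glcm_params()) {
  validate_rgb(image)
  if (!any(mask)) stop("mask is empty")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  if (diff(rows) < 1 || diff(cols) < 1)
    stop("mask bounding box must be at least 2x2")
  sub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  img <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  g <- round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  L <- glcm$levels
  q <- pmin(floor(g * L / 256), L - 1L)
  mats <- lapply(glcm$angles, function(a) {
    m <- .glcm_counts(q, sub, .angle_offset(a, glcm$distance), L,
                      glcm$symmetric)
    if (glcm$normalized && sum(m) > 0) m <- m / sum(m)
    m
  })
  nonzero <- vapply(mats, function(m) sum(m) > 0, logical(1))
  if (!any(nonzero)) stop("no valid co-occurrence pairs inside the mask")
  P <- Reduce(`+`, mats[nonzero]) / sum(nonzero)
  if (!glcm$normalized) P <- P / sum(P)

  iv <- rep(0:(L - 1), times = L)   # row index of each cell
  jv <- rep(0:(L - 1), each = L)
  p <- as.vector(P)                 # column-major: i varies fastest
  dif <- iv - jv
  contrast <- sum(p * dif^2)
  dissimilarity <- sum(p * abs(dif))
  homogeneity <- sum(p / (1 + dif^2))
  asm <- sum(p^2)
  mu_i <- sum(iv * p); mu_j <- sum(jv * p)
  s_i <- sqrt(sum((iv - mu_i)^2 * p)); s_j <- sqrt(sum((jv - mu_j)^2 * p))
  degenerate <- s_i == 0 || s_j == 0
  correlation <- if (degenerate) 1 else
    sum((iv - mu_i) * (jv - mu_j) * p) / (s_i * s_j)
  out <- c(contrast = contrast, dissimilarity = dissimilarity,
           homogeneity = homogeneity, energy = sqrt(asm),
           correlation = correlation, ASM = asm)
  names(out) <- feature_names()[46:51]
  attr(out, "degenerate_correlation") <- degenerate
  out
}

#' Extract the full 65-feature phenotype vector
#'
#' Concatenates [color_features()], [texture_features()] and
#' [geometry_features()] in the canonical order. Deterministic.
#'
#' @param image RGB array (0-255).
#' @param mask logical plant mask.
#' @param glcm a [glcm_params()].
#' @param mm_per_px calibration scale (1 = pixel units).
#' @return named numeric vector of length 65.
#' @export
extract_features <- function(image, mask, glcm = glcm_params(),
                             mm_per_px = 1) {
  out <- c(color_features(image, mask),
           texture_features(image, mask, glcm),
           geometry_features(mask, mm_per_px = mm_per_px))
  attributes(out) <- list(names = names(out))
  stopifnot(length(out) == 65, identical(names(out), feature_names()))
  out
}

#' Extract features for a directory of images and masks
#'
#' @param truth data.frame with columns `sample_id` and `image_path`.
#' @param params segmentation parameters used to produce the masks.
#' @param glcm a [glcm_params()].
#' @param mm_per_px calibration scale.
#' @return data.frame: sample_id plus 65 feature columns.
#' @export
extract_features_batch <- function(truth, params = segmentation_params(),
                                   glcm = glcm_params(), mm_per_px = 1) {
  rows <- lapply(seq_len(nrow(truth)), function(k) {
    img <- read_rgb(truth$image_path[k])
    mask <- segment_plant(img, params)
    extract_features(img, mask, glcm, mm_per_px)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(sample_id = truth$sample_id, out, stringsAsFactors = FALSE)
}
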