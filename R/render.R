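# Synthetic top-view renderer: a rosette of filled rotated ellipses on a
# near-white/grey background. Leaves all overlap the canvas centre so the
# plant is one connected region; a shared grey-level noise field (added
# equally to R, G and B) provides co-occurrence texture without moving the
# excess green index of any pixel.

# leaf colour ramp: pale yellow-green (hue 80 deg) to deep green (hue 120
# deg), saturation rising with greenness, fixed value. Chosen so plant
# pixels keep 40 <= ExG <= 200 at segmentation defaults.
.leaf_rgb <- function(greenness) {
  h <- (80 + 40 * greenness) / 360
  s <- 0.30 + 0.25 * greenness
  v <- 0.60
  as.numeric(grDevices::col2rgb(grDevices::hsv(h, s, v)))
}

#' Render one synthetic plant image
#'
#' Draws `state$n_leaves` overlapping elliptical leaves arranged radially
#' (with angular jitter) around the canvas centre. Leaf colour follows the
#' state's `greenness`; `texture_amp` controls both a per-leaf brightness
#' jitter and a per-pixel grey-level noise field. The noise is added
#' identically to all three channels, so it perturbs grey-level texture but
#' leaves each pixel's excess green index (2G - R - B) untouched.
#'
#' @param state a [latent_state()].
#' @param canvas_px integer `c(height, width)`.
#' @param background background grey level, 0-255 (near-white/grey so it
#'   fails the ExG band of the segmentation stage).
#' @param seed integer seed for jitter and noise.
#' @return object of class `rendered_sample`: list with `image` (H x W x 3,
#'   0-255), `truth_mask` (logical H x W) and `state`.
#' @export
render_plant <- function(state, canvas_px = c(224, 224), background = 235,
                         seed = 1) {
  stopifnot(inherits(state, "latent_state"))
  H <- as.integer(canvas_px[1]); W <- as.integer(canvas_px[2])
  n_leaves <- state$n_leaves
  if (n_leaves < 1) stop("n_leaves must be >= 1")
  cy <- (H + 1) / 2; cx <- (W + 1) / 2

  withr::with_seed(seed, {
    rot0 <- runif(1, 0, 2 * pi)
    ang <- 2 * pi * seq_len(n_leaves) / n_leaves + rot0 +
      rnorm(n_leaves, 0, 0.06)
    len <- state$scale_px * (0.9 + 0.2 * runif(n_leaves))
    semi_a <- len / 2
    semi_b <- semi_a * (0.38 + 0.08 * runif(n_leaves))
    bright <- 1 + 0.004 * state$texture_amp * rnorm(n_leaves)
    noise <- matrix(rnorm(H * W, 0, state$texture_amp), H, W)
  })
  # leaf centres sit so every ellipse covers the canvas centre
  d <- 0.92 * semi_a
  tip <- max(d + semi_a)
  if (tip + 2 > min(H, W) / 2)
    stop("rosette exceeds canvas: tip radius ", round(tip, 1),
         " px on a ", H, "x", W, " canvas")

  base_col <- .leaf_rgb(state$greenness)
  img <- array(background, dim = c(H, W, 3))
  mask <- matrix(FALSE, H, W)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  for (k in seq_len(n_leaves)) {
    lcx <- d[k] * cos(ang[k]); lcy <- d[k] * sin(ang[k])
    u <- (xx - lcx) * cos(ang[k]) + (yy - lcy) * sin(ang[k])
    v <- -(xx - lcx) * sin(ang[k]) + (yy - lcy) * cos(ang[k])
    inside <- (u / semi_a[k])^2 + (v / semi_b[k])^2 <= 1
    new <- inside & !mask  # first leaf to claim a pixel keeps it
    if (!any(new)) next
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[new] <- clamp(base_col[ch] * bright[k], 0, 255)
      img[, , ch] <- plane
    }
    mask <- mask | inside
  }
  if (!any(mask)) stop("truth mask is empty")
  if (state$texture_amp > 0) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- plane[mask] + noise[mask]
      img[, , ch] <- plane
    }
  }
  img <- round(clamp(img, 0, 255))
  structure(list(image = img, truth_mask = mask, state = state),
            class = "rendered_sample")
}

#' @export
print.rendered_sample <- function(x, ...) {
  cat("Rendered sample:", paste(dim(x$image)[1:2], collapse = "x"),
      "px;", sum(x$truth_mask), "plant pixels; true NNI",
      round(x$state$nni_true, 3), "\n")
  invisible(x)
}
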