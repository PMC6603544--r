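# Vegetation segmentation: excess-green band AND a brightness rejection,
# then morphological opening, fractional-area object removal and hole
# filling, in that order.

#' Segmentation parameters
#'
#' Defaults follow the published pipeline: ExG band 40-200 (inclusive at
#' both ends), grey-level rejection at 240 (pixels with grey >= 240
#' removed), a 3x3 square opening, removal of objects smaller than one
#' tenth of the mask area and filling of holes smaller than one twentieth
#' of it. The boundary conventions (inclusive ExG band, strict grey
#' threshold) and the kernel size are pinned here because they are
#' otherwise under-determined choices.
#'
#' @param exg_min,exg_max inclusive band for the excess green index.
#' @param gray_max grey levels `>= gray_max` are rejected as background.
#' @param open_kernel_px odd side of the square structuring element.
#' @param min_object_frac objects smaller than this fraction of the mask
#'   area are removed.
#' @param max_hole_frac holes smaller than this fraction of the mask area
#'   are filled.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(exg_min = 40, exg_max = 200, gray_max = 240,
                                open_kernel_px = 3,
                                min_object_frac = 1 / 10,
                                max_hole_frac = 1 / 20) {
  if (exg_min > exg_max) stop("exg_min must be <= exg_max")
  if (exg_min < 0) stop("exg_min must be >= 0")
  if (gray_max <= 0 || gray_max > 255) stop("gray_max must be in (0, 255]")
  if (open_kernel_px < 1 || open_kernel_px %% 2 != 1)
    stop("open_kernel_px must be a positive odd integer")
  if (min_object_frac <= 0 || min_object_frac >= 1 ||
      max_hole_frac <= 0 || max_hole_frac >= 1)
    stop("area fractions must lie in (0, 1)")
  structure(list(exg_min = exg_min, exg_max = exg_max, gray_max = gray_max,
                 open_kernel_px = as.integer(open_kernel_px),
                 min_object_frac = min_object_frac,
                 max_hole_frac = max_hole_frac),
            class = "segmentation_params")
}

#' Excess green index map
#'
#' Per-pixel 2G - R - B in signed arithmetic on the raw 8-bit channels
#' (no normalisation, no clipping); values lie in `[-510, 510]`.
#'
#' @param image RGB array (H x W x 3, 0-255).
#' @return numeric H x W matrix.
#' @export
compute_exg <- function(image) {
  validate_rgb(image)
  2 * image[, , 2] - image[, , 1] - image[, , 3]
}

#' Threshold an ExG map into a mask
#'
#' @param exg ExG matrix from [compute_exg()].
#' @param exg_min,exg_max inclusive band.
#' @return logical matrix.
#' @export
exg_mask <- function(exg, exg_min = 40, exg_max = 200) {
  if (exg_min > exg_max) stop("exg_min must be <= exg_max")
  exg >= exg_min & exg <= exg_max
}

#' Brightness mask
#'
#' Grey level is the ITU-R BT.601 luma `round(0.299 R + 0.587 G +
#' 0.114 B)`; a pixel is kept iff its grey level is strictly below
#' `gray_max`, rejecting the bright background.
#'
#' @param image RGB array (0-255).
#' @param gray_max rejection threshold.
#' @return logical matrix.
#' @export
gray_mask <- function(image, gray_max = 240) {
  validate_rgb(image)
  g <- round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
               0.114 * image[, , 3])
  g < gray_max
}

#' Morphological clean-up of a plant mask
#'
#' Three steps in fixed order: (1) opening with a square structuring
#' element; (2) removal of 8-connected components with area below
#' `min_object_frac` of the current total mask area; (3) filling of
#' 4-connected background holes (complement components not touching the
#' image border) with area below `max_hole_frac` of the current total mask
#' area. The reference area for each fractional filter is recomputed at
#' the moment that filter runs.
#'
#' @param mask logical matrix (nonempty).
#' @param params a [segmentation_params()].
#' @return cleaned logical matrix.
#' @export
clean_mask <- function(mask, params = segmentation_params()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("no plant detected: input mask is empty")
  if (params$open_kernel_px > 1) {
    brush <- EBImage::makeBrush(params$open_kernel_px, shape = "box")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  if (!any(mask)) stop("no plant detected: mask empty after opening")
  # small-object removal (8-connected)
  lab <- label_components(mask, connectivity = 8)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= params$min_object_frac * sum(mask))
  mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  if (!any(mask)) stop("no plant detected: mask empty after object removal")
  # hole filling (4-connected complement components away from the border)
  hole_lab <- label_components(!mask, connectivity = 4)
  border <- unique(c(hole_lab[1, ], hole_lab[nrow(mask), ],
                     hole_lab[, 1], hole_lab[, ncol(mask)]))
  hole_areas <- tabulate(hole_lab[hole_lab > 0])
  fill <- setdiff(which(hole_areas < params$max_hole_frac * sum(mask)),
                  border)
  if (length(fill)) mask[hole_lab %in% fill] <- TRUE
  mask
}

#' Segment the plant from a top-view image
#'
#' Intersection of the ExG band mask and the brightness mask, followed by
#' [clean_mask()]. Fully deterministic.
#'
#' @param image RGB array (0-255).
#' @param params a [segmentation_params()].
#' @return logical plant mask.
#' @export
segment_plant <- function(image, params = segmentation_params()) {
  m <- exg_mask(compute_exg(image), params$exg_min, params$exg_max) &
    gray_mask(image, params$gray_max)
  if (!any(m)) stop("no plant detected: empty mask after thresholding")
  clean_mask(m, params)
}
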