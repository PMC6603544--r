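# Contour-geometry features of a binary plant mask. The region of interest
# is the largest 8-connected component; its area is the pixel count, its
# outline is a Moore-traced 8-connected boundary chain, and hull-based
# measures are computed over the boundary pixels expanded to their four
# pixel corners (so a rasterised s x s square has hull area exactly s^2).

# Moore-neighbour boundary tracing with an explicit backtrack pixel;
# returns boundary pixel coordinates (row, col) in traversal order
.trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # neighbour ring, clockwise in image coordinates (row axis points down)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  start <- which(mask)[1]  # column-major: topmost pixel of leftmost column
  sr <- (start - 1L) %% nr + 1L
  sc <- (start - 1L) %/% nr + 1L
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  cap <- 4L * sum(mask) + 8L
  path_r <- integer(cap); path_c <- integer(cap)
  n <- 0L
  r <- sr; c <- sc
  br <- sr; bc <- sc - 1L  # west of start is guaranteed background
  repeat {
    n <- n + 1L
    path_r[n] <- r; path_c[n] <- c
    pos <- which(dr == (br - r) & dc == (bc - c))
    found <- FALSE
    last_r <- br; last_c <- bc
    for (s in 1:8) {
      k <- (pos + s - 1L) %% 8L + 1L
      r2 <- r + dr[k]; c2 <- c + dc[k]
      if (fg(r2, c2)) {
        br <- last_r; bc <- last_c
        r <- r2; c <- c2
        found <- TRUE
        break
      }
      last_r <- r2; last_c <- c2
    }
    if (!found) break  # isolated pixel
    if (r == sr && c == sc && br == sr && bc == sc - 1L) break
    if (n >= cap) break  # safety
  }
  cbind(row = path_r[seq_len(n)], col = path_c[seq_len(n)])
}

# chain length of the closed boundary (steps weighted 1 or sqrt(2))
.chain_perimeter <- function(bd) {
  n <- nrow(bd)
  if (n < 2) return(0)
  nxt <- rbind(bd[-1, , drop = FALSE], bd[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - bd)^2)))
}

# polygon area by the shoelace formula
.polygon_area <- function(x, y) {
  n <- length(x)
  i2 <- c(2:n, 1)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

# minimum-area enclosing rectangle by rotating calipers over hull vertices;
# returns c(w, h) with w the extent along the supporting edge
.min_area_rect <- function(hx, hy) {
  n <- length(hx)
  if (n == 1) return(c(0, 0))
  best <- c(Inf, 0, 0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    u <- c(ex, ey) / len
    proj_w <- hx * u[1] + hy * u[2]
    proj_h <- -hx * u[2] + hy * u[1]
    w <- diff(range(proj_w)); h <- diff(range(proj_h))
    if (w * h < best[1]) best <- c(w * h, w, h)
  }
  best[2:3]
}

# smallest enclosing circle (Welzl, incremental); points as columns x, y
.min_enclosing_circle <- function(x, y) {
  circ2 <- function(i, j) {
    c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2,
      sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) / 2)
  }
  circ3 <- function(i, j, k) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      # collinear: diametric circle of the farthest pair
      cands <- rbind(circ2(i, j), circ2(i, k), circ2(j, k))
      return(cands[which.max(cands[, 3]), ])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
  }
  inside <- function(cc, i) {
    sqrt((x[i] - cc[1])^2 + (y[i] - cc[2])^2) <= cc[3] + 1e-9
  }
  n <- length(x)
  if (n == 1) return(c(x[1], y[1], 0))
  cc <- circ2(1, 2)
  for (i in seq_len(n)[-(1:2)]) {
    if (inside(cc, i)) next
    cc <- circ2(1, i)
    for (j in seq_len(i - 1)[-1]) {
      if (inside(cc, j)) next
      cc <- circ2(i, j)
      for (k in seq_len(j - 1)) {
        if (!inside(cc, k)) cc <- circ3(i, j, k)
      }
    }
  }
  cc
}

#' Contour-geometry features (14 values)
#'
#' Measures of the largest 8-connected component of the mask: contour area
#' (pixel count), boundary-chain perimeter, axis-aligned bounding-box width
#' and height, convex-hull area, minimum-area rotated-rectangle sides,
#' moment-ellipse major and minor axes, minimum enclosing circle radius,
#' equivalent diameter `sqrt(4 A / pi)`, aspect ratio `w/h`, extent
#' `A/(w h)` and solidity `A/hull_area`. Additional components are ignored
#' with a warning. A component of fewer than 5 pixels has no stable moment
#' ellipse; its axes fall back to the rotated-rectangle sides (flagged by
#' attribute `ellipse_fallback`). Lengths scale with `mm_per_px`, areas
#' with its square.
#'
#' @param mask logical matrix.
#' @param mm_per_px calibration scale (mm per pixel; 1 = pixel units).
#' @return named numeric vector of length 14.
#' @export
geometry_features <- function(mask, mm_per_px = 1) {
  stopifnot(is.matrix(mask), is.logical(mask), mm_per_px > 0)
  if (!any(mask)) stop("mask is empty")
  lab <- label_components(mask, connectivity = 8)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) > 1) {
    warning(length(areas) - 1, " secondary component(s) ignored")
    mask <- lab == which.max(areas)
  }
  px <- which(mask, arr.ind = TRUE)
  A <- nrow(px)
  w <- diff(range(px[, 2])) + 1
  h <- diff(range(px[, 1])) + 1

  bd <- .trace_boundary(mask)
  perimeter <- .chain_perimeter(bd)

  # hull over boundary-pixel corners (x = col, y = row)
  cx <- rep(bd[, "col"], each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  cy <- rep(bd[, "row"], each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  hidx <- grDevices::chull(cx, cy)
  hx <- cx[hidx]; hy <- cy[hidx]
  hull_area <- .polygon_area(hx, hy)
  rect <- .min_area_rect(hx, hy)
  mec <- .min_enclosing_circle(hx, hy)

  ellipse_fallback <- A < 5
  if (ellipse_fallback) {
    ax <- sort(rect, decreasing = TRUE)
  } else {
    cv <- cov(px[, c(2, 1)]) * (A - 1) / A  # population moments
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ax <- 4 * sqrt(pmax(ev, 0))
  }

  s <- mm_per_px
  out <- c(
    contour_area = A * s^2,
    perimeter = perimeter * s,
    w = w * s,
    h = h * s,
    hull_area = hull_area * s^2,
    rect_w = rect[1] * s,
    rect_h = rect[2] * s,
    MA = ax[1] * s,
    ma = ax[2] * s,
    r = mec[3] * s,
    equivalent_diameter = sqrt(4 * A / pi) * s,
    aspect_ratio = w / h,
    extent = A / (w * h),
    solidity = A / hull_area
  )
  names(out) <- feature_names()[52:65]
  attr(out, "ellipse_fallback") <- ellipse_fallback
  out
}
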