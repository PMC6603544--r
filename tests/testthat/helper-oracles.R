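# Independent oracles and small fixtures used across the suite. These are
# deliberately naive implementations (flood fill, exhaustive pair
# enumeration) kept separate from the package's own algorithms.

# stack-based flood-fill component labelling, independent of the package's
# union-find labeller
flood_fill_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1); dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (idx in which(mask)) {
    if (lab[idx] != 0L) next
    cur <- cur + 1L
    stack <- idx
    lab[idx] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- c + dc[k]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          q <- (c2 - 1L) * nr + r2
          lab[q] <- cur
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

# exhaustive-pair GLCM oracle: loops over every pixel and offset, tallies
# grey-level pairs by hand, then evaluates the six texture features from
# first principles
glcm_oracle <- function(gray, mask, distance, angles, levels) {
  q <- pmin(floor(gray * levels / 256), levels - 1)
  offs <- list("0" = c(0, distance), "45" = c(-distance, distance),
               "90" = c(-distance, 0), "135" = c(-distance, -distance))
  mats <- list()
  for (a in as.character(angles)) {
    off <- offs[[a]]
    m <- matrix(0, levels, levels)
    for (r in seq_len(nrow(gray))) {
      for (cc in seq_len(ncol(gray))) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > nrow(gray) || c2 < 1 || c2 > ncol(gray)) next
        if (!mask[r, cc] || !mask[r2, c2]) next
        i <- q[r, cc] + 1; j <- q[r2, c2] + 1
        m[i, j] <- m[i, j] + 1
        m[j, i] <- m[j, i] + 1  # symmetric
      }
    }
    if (sum(m) > 0) mats[[a]] <- m / sum(m)
  }
  if (!length(mats)) stop("oracle: no pairs")
  P <- Reduce(`+`, mats) / length(mats)
  iv <- row(P) - 1; jv <- col(P) - 1
  asm <- sum(P^2)
  mu_i <- sum(iv * P); mu_j <- sum(jv * P)
  s_i <- sqrt(sum((iv - mu_i)^2 * P)); s_j <- sqrt(sum((jv - mu_j)^2 * P))
  corr <- if (s_i == 0 || s_j == 0) 1 else
    sum((iv - mu_i) * (jv - mu_j) * P) / (s_i * s_j)
  c(contrast = sum(P * (iv - jv)^2),
    dissimilarity = sum(P * abs(iv - jv)),
    homogeneity = sum(P / (1 + (iv - jv)^2)),
    energy = sqrt(asm),
    correlation = corr,
    ASM = asm)
}

# uniform-colour RGB image fixture
flat_image <- function(nr, nc, rgb = c(235, 235, 235)) {
  array(rep(rgb, each = nr * nc), dim = c(nr, nc, 3))
}

# paint a logical mask onto an image with one colour
paint <- function(image, mask, rgb) {
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- rgb[ch]
    image[, , ch] <- plane
  }
  image
}

disc_mask <- function(n, radius, center = (n + 1) / 2) {
  rr <- matrix(seq_len(n), n, n) - center
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - center
  rr^2 + cc^2 <= radius^2
}

square_mask <- function(n, side, top = ceiling((n - side) / 2)) {
  m <- matrix(FALSE, n, n)
  m[top:(top + side - 1), top:(top + side - 1)] <- TRUE
  m
}

# rendered sample at a given true NNI (biomass chosen mid-range)
render_at_nni <- function(nni, biomass = 0.5, seed = 11,
                          canvas = c(224, 224)) {
  curve <- generator_curve()
  st <- latent_state(biomass, nni * curve$a * biomass^curve$b,
                     nni_true = nni)
  render_plant(st, canvas_px = canvas, seed = seed)
}

mean_exg_over <- function(sample) {
  mean(compute_exg(sample$image)[sample$truth_mask])
}
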