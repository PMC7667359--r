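# Independent oracles and fixture builders, kept deliberately naive so they
# share no code path with the implementation they check.

# Brute-force pairwise AUC: P(pos > neg) + 0.5 P(tie) over all pairs.
brute_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# All four corners (physical mm) of every lesion pixel, no boundary pruning.
all_corners <- function(mask, spacing) {
  idx <- which(mask != 0, arr.ind = TRUE)
  cx <- (idx[, 1] - 1) * spacing[1]
  cy <- (idx[, 2] - 1) * spacing[2]
  hx <- spacing[1] / 2; hy <- spacing[2] / 2
  unique(cbind(c(cx - hx, cx - hx, cx + hx, cx + hx),
               c(cy - hy, cy + hy, cy - hy, cy + hy)))
}

# Exhaustive max corner-pair distance in mm (O(n^2) double loop).
naive_feret_mm <- function(mask, spacing) {
  pts <- all_corners(mask, spacing)
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- (pts[(i + 1):nrow(pts), 1] - pts[i, 1])^2 +
          (pts[(i + 1):nrow(pts), 2] - pts[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Projection width (mm) of all corners onto the axis perpendicular to `dir`.
naive_perp_width_mm <- function(mask, spacing, dir) {
  dir <- dir / sqrt(sum(dir^2))
  pts <- all_corners(mask, spacing)
  proj <- pts %*% c(-dir[2], dir[1])
  max(proj) - min(proj)
}

# Digital ellipse slice: pixel centers inside an ellipse with semi-axes in
# mm, rotated by `theta` radians, centered on the grid.
digital_ellipse_slice <- function(semi_a, semi_b, theta = 0, spacing = c(1, 1),
                                  slice_index = 1L) {
  half <- ceiling(max(semi_a, semi_b) / min(spacing)) + 2
  i <- seq(-half, half)
  x <- outer(i * spacing[1], rep(0, length(i)), `+`)
  y <- outer(rep(0, length(i)), i * spacing[2], `+`)
  xr <- cos(theta) * x + sin(theta) * y
  yr <- -sin(theta) * x + cos(theta) * y
  mask <- (xr / semi_a)^2 + (yr / semi_b)^2 <= 1
  slice_mask(mask, spacing, slice_index)
}

# Digital solid sphere as a lesion_image.
digital_sphere <- function(radius_mm, spacing = c(1, 1, 1)) {
  n <- 2 * ceiling(radius_mm / spacing) + 5
  ctr <- (n - 1) / 2 * spacing
  dx <- (seq_len(n[1]) - 1) * spacing[1] - ctr[1]
  dy <- (seq_len(n[2]) - 1) * spacing[2] - ctr[2]
  dz <- (seq_len(n[3]) - 1) * spacing[3] - ctr[3]
  r2 <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
  lesion_image(r2 <= radius_mm^2, spacing, "sphere")
}

# Random sparse 2D mask with at least one pixel.
random_mask <- function(nr, nc, n_pix) {
  m <- matrix(FALSE, nr, nc)
  m[sample(nr * nc, min(nr * nc, max(1, n_pix)))] <- TRUE
  m
}
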