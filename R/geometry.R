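#' @title In-slice caliper geometry
#' @description
#' The measurement procedure a reader performs at the workstation: on the
#' slice showing the largest lesion extent, draw the maximum lesion diameter
#' *a* and the maximal diameter *b* perpendicular to it. Both are caliper
#' (Feret) measurements on the lesion pixel set, taken edge-to-edge: every
#' lesion pixel contributes its four corners in physical mm coordinates, so
#' a single pixel already has a positive diameter (its diagonal), as it
#' would under an electronic caliper.
#' @name caliper-geometry
NULL

# Physical-mm corner points of the lesion pixels in a slice. Only pixels on
# the 4-connected boundary are expanded to corners: interior pixels cannot
# support the convex hull or any directional extremum.
pixel_corners <- function(slice, boundary_only = TRUE) {
  m <- slice$mask
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("slice contains no lesion pixels")
  if (boundary_only && nrow(idx) > 4L) {
    nr <- nrow(m); nc <- ncol(m)
    pad <- matrix(FALSE, nr + 2L, nc + 2L)
    pad[2:(nr + 1L), 2:(nc + 1L)] <- m
    core <- pad[2:(nr + 1L), 2:(nc + 1L)] &
      pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
      pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
    idx <- which(m & !core, arr.ind = TRUE)
  }
  sp <- slice$spacing
  cx <- (idx[, 1] - 1) * sp[1]
  cy <- (idx[, 2] - 1) * sp[2]
  hx <- sp[1] / 2; hy <- sp[2] / 2
  pts <- cbind(
    x = c(cx - hx, cx - hx, cx + hx, cx + hx),
    y = c(cy - hy, cy + hy, cy - hy, cy + hy)
  )
  unique(pts)
}

#' Maximum Feret (caliper) diameter of a slice
#'
#' The largest distance between two parallel supporting lines of the lesion
#' pixel set, i.e. the reader's maximum diameter *a*. Computed exactly in
#' physical mm over the pixel-corner point set: convex hull first, then the
#' maximum over all hull-vertex pairs. Anisotropic in-plane spacing is
#' applied before the hull.
#'
#' @param slice a [slice_mask] with at least one lesion pixel.
#' @return A list with `length_cm`, the unit `direction` (physical mm frame)
#'   between the attaining endpoints, and the 2x2 matrix `endpoints` (mm).
#' @export
max_feret_diameter <- function(slice) {
  stopifnot(inherits(slice, "slice_mask"))
  if (slice$empty) stop("cannot measure a diameter on an empty slice")
  pts <- pixel_corners(slice)
  hull <- pts[chull(pts), , drop = FALSE]
  d <- as.matrix(dist(hull))
  at <- which(d == max(d), arr.ind = TRUE)[1, ]
  p1 <- hull[at[1], ]; p2 <- hull[at[2], ]
  len <- sqrt(sum((p2 - p1)^2))
  list(
    length_cm = len / 10,
    direction = (p2 - p1) / len,
    endpoints = rbind(p1, p2, deparse.level = 0)
  )
}

#' Brute-force Feret diameter (reference path)
#'
#' Exhaustive maximum distance over all pixel-corner pairs, with no convex
#' hull. Serves as the independent reference for [max_feret_diameter()] and
#' as the ground-truth measurement recorded at phantom-generation time.
#'
#' @inheritParams max_feret_diameter
#' @return Same structure as [max_feret_diameter()].
#' @export
feret_diameter_brute <- function(slice) {
  stopifnot(inherits(slice, "slice_mask"))
  if (slice$empty) stop("cannot measure a diameter on an empty slice")
  pts <- pixel_corners(slice, boundary_only = FALSE)
  best <- -1; bi <- c(1L, 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    dx <- pts[(i + 1L):nrow(pts), 1] - pts[i, 1]
    dy <- pts[(i + 1L):nrow(pts), 2] - pts[i, 2]
    d2 <- dx * dx + dy * dy
    j <- which.max(d2)
    if (d2[j] > best) { best <- d2[j]; bi <- c(i, i + j) }
  }
  p1 <- pts[bi[1], ]; p2 <- pts[bi[2], ]
  len <- sqrt(best)
  list(
    length_cm = len / 10,
    direction = (p2 - p1) / len,
    endpoints = rbind(p1, p2, deparse.level = 0)
  )
}

#' Maximal orthogonal diameter of a slice
#'
#' The reader's second measurement *b*: the lesion's maximal extent along
#' the axis perpendicular to a given direction, computed as the width of the
#' projection of the pixel-corner point set onto that perpendicular axis.
#'
#' @param slice a [slice_mask] with at least one lesion pixel.
#' @param direction unit 2-vector in the physical mm frame (typically the
#'   direction of the maximum diameter *a*).
#' @return A list with `length_cm`, the perpendicular unit `direction`, and
#'   the two support points `endpoints` (mm) attaining the projection
#'   extremes.
#' @export
orthogonal_diameter <- function(slice, direction) {
  stopifnot(inherits(slice, "slice_mask"))
  if (slice$empty) stop("cannot measure a diameter on an empty slice")
  direction <- as.numeric(direction)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("`direction` must be a nonzero vector")
  direction <- direction / nrm
  perp <- c(-direction[2], direction[1])
  pts <- pixel_corners(slice)
  proj <- pts %*% perp
  i_lo <- which.min(proj); i_hi <- which.max(proj)
  list(
    length_cm = (proj[i_hi] - proj[i_lo]) / 10,
    direction = perp,
    endpoints = rbind(pts[i_lo, ], pts[i_hi, ], deparse.level = 0)
  )
}

#' Select the measurement slice and take both diameters
#'
#' Implements the full per-patient measurement: the slice demonstrating the
#' largest lesion diameter is selected (ties break to the lowest slice
#' index); the maximum diameter *a* and the maximal orthogonal diameter *b*
#' are then measured on that same slice.
#'
#' @param image a [lesion_image] with at least one lesion voxel.
#' @param feret_fun function used per slice; the hull-based
#'   [max_feret_diameter()] by default.
#' @return An object of class `diameter_measurement`: `a_cm`, `b_cm`
#'   (`a_cm >= b_cm`), `slice_index`, `a_direction` (unit vector, mm frame),
#'   `a_endpoints`, `b_endpoints`.
#' @export
select_measurement_slice <- function(image, feret_fun = max_feret_diameter) {
  stopifnot(inherits(image, "lesion_image"))
  if (!any(image$mask)) stop("cannot measure an empty lesion image")
  slices <- slice_masks(image)
  nonempty <- which(!vapply(slices, `[[`, logical(1), "empty"))
  ferets <- lapply(slices[nonempty], feret_fun)
  lens <- vapply(ferets, `[[`, numeric(1), "length_cm")
  w <- which.max(lens)  # which.max returns the first (lowest-index) maximum
  a <- ferets[[w]]
  sl <- slices[[nonempty[w]]]
  b <- orthogonal_diameter(sl, a$direction)
  # Feret maximality over the same point set makes b > a impossible.
  if (b$length_cm > a$length_cm + 1e-9)
    stop("internal consistency error: orthogonal extent exceeds maximum Feret")
  structure(
    list(
      a_cm = a$length_cm, b_cm = b$length_cm,
      slice_index = sl$slice_index,
      a_direction = a$direction,
      a_endpoints = a$endpoints, b_endpoints = b$endpoints
    ),
    class = "diameter_measurement"
  )
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("<diameter_measurement> a = %.2f cm, b = %.2f cm on slice %d\n",
              x$a_cm, x$b_cm, x$slice_index))
  invisible(x)
}
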