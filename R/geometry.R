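#' @name geometry
#' @title Pixel-grid and polygon geometry helpers
#'
#' @description
#' World coordinates are millimetres with the origin at the image corner:
#' the centre of the pixel in (1-based) row `r`, column `c` lies at
#' `x = (c - 0.5) * spacing_col`, `y = (r - 0.5) * spacing_row`.
#' A pixel belongs to a region iff its centre is inside the region's polygon
#' under the even-odd rule.
NULL

# Pixel-centre coordinates (mm) for an nrow x ncol grid.
pixel_centers <- function(nrow, ncol, spacing_mm) {
  list(x = (seq_len(ncol) - 0.5) * spacing_mm[2],
       y = (seq_len(nrow) - 0.5) * spacing_mm[1])
}

# Even-odd (crossing number) point-in-polygon test, vectorised over points.
# poly: n x 2 matrix of (x, y) vertices, implicitly closed.
points_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  inside <- logical(length(px))
  xj <- poly[nv, 1]; yj <- poly[nv, 2]
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

#' Rasterise a polygon onto a pixel grid
#'
#' Marks every pixel whose centre lies inside the polygon (even-odd rule,
#' pixel-centre convention). Evaluation is restricted to the polygon's
#' bounding box for speed.
#'
#' @param poly n x 2 matrix of polygon vertices in mm `(x, y)`.
#' @param dim Grid dimensions `c(nrow, ncol)`.
#' @param spacing_mm Pixel spacing `c(row, col)` in mm.
#' @return Logical `nrow x ncol` matrix.
#' @export
rasterize_polygon <- function(poly, dim, spacing_mm) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  out <- matrix(FALSE, dim[1], dim[2])
  cmin <- max(1L, floor(min(poly[, 1]) / spacing_mm[2] + 0.5))
  cmax <- min(dim[2], ceiling(max(poly[, 1]) / spacing_mm[2] + 0.5))
  rmin <- max(1L, floor(min(poly[, 2]) / spacing_mm[1] + 0.5))
  rmax <- min(dim[1], ceiling(max(poly[, 2]) / spacing_mm[1] + 0.5))
  if (cmin > cmax || rmin > rmax) return(out)
  rows <- rmin:rmax; cols <- cmin:cmax
  cx <- (cols - 0.5) * spacing_mm[2]
  cy <- (rows - 0.5) * spacing_mm[1]
  px <- rep(cx, each = length(rows))
  py <- rep(cy, times = length(cols))
  out[rows, cols] <- points_in_polygon(px, py, poly)
  out
}

#' Regular polygon approximating a circle
#'
#' @param center_mm Centre `c(x, y)` in mm.
#' @param radius_mm Radius in mm (> 0).
#' @param n Number of vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(center_mm, radius_mm, n = 180L) {
  stopifnot(radius_mm > 0, n >= 3)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center_mm[1] + radius_mm * cos(th),
        center_mm[2] + radius_mm * sin(th))
}

# Annular-sector polygon: outer arc from theta1 to theta2, back along the
# inner arc. Used for remote-ROI contours.
annular_sector_polygon <- function(center_mm, r_inner, r_outer,
                                   theta1, theta2, n_arc = 64L) {
  stopifnot(r_outer > r_inner, r_inner > 0)
  th <- seq(theta1, theta2, length.out = n_arc)
  outer <- cbind(center_mm[1] + r_outer * cos(th),
                 center_mm[2] + r_outer * sin(th))
  inner <- cbind(center_mm[1] + r_inner * cos(rev(th)),
                 center_mm[2] + r_inner * sin(rev(th)))
  rbind(outer, inner)
}

# Smallest absolute angular distance between angles (radians).
angle_distance <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

# Proper segment-intersection test for polygon simplicity. O(n^2); contours
# have at most a few hundred vertices.
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), , drop = FALSE])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent segments (shared endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      a <- seg[i, 1:2]; b <- seg[i, 3:4]; c <- seg[j, 1:2]; d <- seg[j, 3:4]
      o1 <- orient(a[1], a[2], b[1], b[2], c[1], c[2])
      o2 <- orient(a[1], a[2], b[1], b[2], d[1], d[2])
      o3 <- orient(c[1], c[2], d[1], d[2], a[1], a[2])
      o4 <- orient(c[1], c[2], d[1], d[2], b[1], b[2])
      # strict crossings only: collinear touching along staircase contours
      # is not self-intersection
      if (o1 * o2 < 0 && o3 * o4 < 0) return(FALSE)
    }
  }
  TRUE
}

# All vertices of `inner` strictly inside `outer`?
polygon_inside <- function(inner, outer) {
  all(points_in_polygon(inner[, 1], inner[, 2], outer))
}

# Trace the 0.5-level boundary of a logical mask as a polygon in mm
# coordinates (longest contour if the mask has several pieces).
mask_to_polygon <- function(mask, spacing_mm) {
  if (!any(mask)) return(NULL)
  nr <- nrow(mask); nc <- ncol(mask)
  # pad so contourLines closes boundaries at the mask edge
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  y <- (seq_len(nr + 2L) - 1.5) * spacing_mm[1]
  x <- (seq_len(nc + 2L) - 1.5) * spacing_mm[2]
  # contourLines treats the first index as x; transpose so x follows columns
  cl <- grDevices::contourLines(x = y, y = x, z = z, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  best <- cl[[which.max(vapply(cl, function(l) length(l$x), numeric(1)))]]
  poly <- cbind(best$y, best$x)  # back to (x, y)
  # drop a duplicated closing vertex; the polygon is implicitly closed
  if (nrow(poly) > 1L && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  poly
}
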