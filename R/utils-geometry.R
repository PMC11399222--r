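## Low-level planar geometry helpers shared across modules.
## Convention: points are n x 2 matrices in mm, x rightward, y downward
## (image convention); "proximal" is larger y on AP/PA canvases.

#' Signed polygon area (shoelace)
#'
#' Signed area of a closed polygon in the package's image coordinate frame
#' (x right, y down). Contours are stored counter-clockwise as seen on the
#' displayed image, which corresponds to a negative raw shoelace sum; the
#' sign is therefore flipped so that package-convention contours have
#' positive signed area.
#'
#' @param pts n x 2 matrix of vertices (closure implicit, first vertex not
#'   repeated).
#' @return Signed area in squared input units.
#' @keywords internal
shoelaceArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  -sum(x * y2 - x2 * y) / 2
}

#' Polygon area (absolute)
#' @param pts n x 2 vertex matrix.
#' @return Non-negative area.
#' @keywords internal
polygonArea <- function(pts) abs(shoelaceArea(pts))

## Ensure package orientation (positive signed area as defined above).
orientCCW <- function(pts) {
  if (shoelaceArea(pts) < 0) pts[rev(seq_len(nrow(pts))), , drop = FALSE] else pts
}

## Euclidean norm of rows.
rowNorms <- function(m) sqrt(rowSums(m * m))

## Cumulative arc length of an (open) polyline, starting at 0.
cumArcLength <- function(pts) {
  d <- diff(pts)
  c(0, cumsum(sqrt(rowSums(d * d))))
}

#' Directed and symmetric Hausdorff distance between point sets
#' @param a,b point matrices (n x 2, m x 2).
#' @return Symmetric Hausdorff distance.
#' @keywords internal
hausdorffDistance <- function(a, b) {
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

## Rotation matrix for an angle in degrees (acts on row vectors via %*% t(R)).
rotationMatrix <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

## Apply similarity transform: scale s, rotation deg about `center`, then
## translation `shift`.
similarityTransform <- function(pts, scale = 1, deg = 0, center = c(0, 0),
                                shift = c(0, 0)) {
  p <- sweep(pts, 2, center)
  p <- p * scale
  if (deg != 0) p <- p %*% t(rotationMatrix(deg))
  sweep(p, 2, center + shift, "+")
}

## Point-in-polygon for pixel centers (even-odd rule via mgcv::in.out).
pointsInPolygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(bnd, pts)
}

## Does any vertex of polygon a fall strictly inside polygon b (or vice
## versa)?  Cheap overlap test for the convex-ish synthetic bone shapes.
polygonsOverlap <- function(a, b) {
  any(pointsInPolygon(b, a)) || any(pointsInPolygon(a, b))
}

## Circular (cyclic) index shift of contour rows by k (k = 0 is identity).
cyclicShift <- function(pts, k) {
  n <- nrow(pts)
  k <- ((k - 1) %% n) + 1
  idx <- c(seq(k, n), seq_len(k - 1))
  pts[idx, , drop = FALSE]
}

## Degrees <-> unit vector helpers.
unitVector <- function(v) {
  nv <- sqrt(sum(v * v))
  if (nv < 1e-12) stop("cannot normalize a zero-length vector")
  v / nv
}
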