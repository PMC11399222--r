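## Bone template geometry for the synthetic wrist generator.
##
## AP/PA view: the proximal surfaces of scaphoid/lunate/triquetrum lie on a
## common circle (Gilula's arc I), their distal surfaces on a second circle
## (arc II), and the proximal surfaces of capitate/hamate on a third (arc
## III), so the generated carpal arcs are smooth across bones with known
## curvature (1/60 mm^-1 at unit scale). The scapholunate-facing walls of
## scaphoid and lunate are vertical segments sharing the same y-range, so
## their arc-length midpoints face each other exactly and the SL distance
## equals the applied gap by construction.
##
## Lateral view: lunate and capitate carry horizontal proximal/distal facets
## whose midpoints are vertically aligned in the template (axis straight
## down the bone); the scaphoid is a mirror-symmetric egg whose principal
## axis is its long axis. Rotating the scaphoid about its centroid and the
## capitate about its capitolunate facet midpoint therefore realizes exact
## SL and CL angles.
##
## Templates are constructed deterministically here and shipped as a JSON
## fixture (inst/extdata/wrist_templates.json, regenerated by
## tools/make_templates.R) so facet index ranges are stable package data.

.pkgEnv <- new.env(parent = emptyenv())

## y on one of the three AP arc circles (centers above the canvas, R = 60).
.apArcY <- function(x, arc = c("I", "II", "III")) {
  arc <- match.arg(arc)
  yc <- c(I = -10, II = -24, III = -28)[[arc]]
  yc + sqrt(60^2 - (x - 29)^2)
}

## Straight segment sampled with n points, endpoints included.
.seg <- function(p0, p1, n) {
  t <- seq(0, 1, length.out = n)
  cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
}

## Quadratic Bezier through p0, m (at t = 0.5) and p1.
.qcurve <- function(p0, m, p1, n) {
  cpt <- 2 * m - (p0 + p1) / 2
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * t * (1 - t) * cpt[1] + t^2 * p1[1],
        (1 - t)^2 * p0[2] + 2 * t * (1 - t) * cpt[2] + t^2 * p1[2])
}

## Superellipse |x/a|^p + |y/b|^p = 1, sampled and oriented to the package
## convention.
.superellipse <- function(center, a, b, p, n) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  pts <- cbind(center[1] + a * sign(cos(t)) * abs(cos(t))^(2 / p),
               center[2] + b * sign(sin(t)) * abs(sin(t))^(2 / p))
  orientCCW(pts)
}

## Proximal-row bone (scaphoid, lunate, triquetrum): curved proximal and
## distal surfaces on the shared arc circles, vertical side walls with a
## common y-range [36, 49.5] so facing SL facet midpoints are level.
.proxRowBone <- function(xl, xr) {
  ## arcs span the full bone width so the vertical walls continue them
  ## collinearly (no sliver corners that could fragment at rasterization)
  xsB <- seq(xl, xr, length.out = 28)
  bottom <- cbind(xsB, .apArcY(xsB, "I"))
  right <- .seg(c(xr, 49.5), c(xr, 36.0), 10)
  xsT <- seq(xr, xl, length.out = 28)
  top <- cbind(xsT, .apArcY(xsT, "II"))
  left <- .seg(c(xl, 36.0), c(xl, 49.5), 10)
  list(pts = rbind(bottom, right, top, left),
       sections = list(bottom = c(1L, 28L), right = c(29L, 38L),
                       top = c(39L, 66L), left = c(67L, 76L)))
}

.capitateAP <- function() {
  ## sides meet the proximal arc at its endpoints (duplicates dropped)
  xs <- seq(22, 34, length.out = 32)
  bottom <- cbind(xs, .apArcY(xs, "III"))
  right <- .qcurve(c(34, .apArcY(34, "III")), c(33.4, 24.0),
                   c(31.5, 17.0), 13)[-1, ]
  topF <- .seg(c(31.0, 16.5), c(27.0, 16.5), 8)
  left <- .qcurve(c(26.5, 17.0), c(23.2, 24.0),
                  c(22, .apArcY(22, "III")), 13)[-13, ]
  list(pts = rbind(bottom, right, topF, left),
       facets = list(proximal_surface = c(1L, 32L),
                     capitate_lunate = c(1L, 32L),
                     capitate_mc3 = c(45L, 52L)))
}

.hamateAP <- function() {
  xs <- seq(35.5, 46, length.out = 32)
  bottom <- cbind(xs, .apArcY(xs, "III"))
  right <- .qcurve(c(46, .apArcY(46, "III")), c(45.6, 24.0),
                   c(44.0, 20.0), 11)[-1, ]
  topF <- .seg(c(43.0, 19.0), c(38.0, 19.0), 8)
  left <- .qcurve(c(36.5, 20.0), c(35.6, 25.5),
                  c(35.5, .apArcY(35.5, "III")), 11)[-11, ]
  list(pts = rbind(bottom, right, topF, left),
       facets = list(proximal_surface = c(1L, 32L)))
}

.lunateLat <- function() {
  bottom <- .seg(c(27.5, 46), c(34.5, 46), 14)
  right <- .qcurve(c(35.0, 45.5), c(36.3, 41.0), c(35.0, 36.5), 16)
  top <- .seg(c(34.5, 36), c(27.5, 36), 14)
  left <- .qcurve(c(27.0, 36.5), c(25.0, 41.0), c(27.0, 45.5), 16)
  list(pts = rbind(bottom, right, top, left),
       facets = list(lunate_radius = c(1L, 14L),
                     proximal_surface = c(1L, 14L),
                     lunate_capitate = c(31L, 44L),
                     distal_surface = c(31L, 44L)))
}

.capitateLat <- function() {
  bottom <- .seg(c(28.5, 33), c(33.5, 33), 16)
  right <- .qcurve(c(34.2, 32.2), c(36.0, 25.0), c(32.8, 14.5), 18)
  top <- .seg(c(32.5, 14), c(29.5, 14), 10)
  left <- .qcurve(c(29.2, 14.5), c(27.0, 24.0), c(27.8, 32.2), 18)
  list(pts = rbind(bottom, right, top, left),
       facets = list(capitate_lunate = c(1L, 16L),
                     proximal_surface = c(1L, 16L),
                     capitate_mc3 = c(35L, 44L),
                     distal_surface = c(35L, 44L)))
}

## Mirror-symmetric egg (narrower distal pole): principal axis is exactly
## the template long axis; the asymmetry along the axis makes the cyclic
## correspondence search unambiguous. Starts at the proximal pole and runs
## counter-clockwise; the distal pole sits at index 33 of 64.
.scaphoidLat <- function() {
  a <- 9; b0 <- 4.2; cx <- 14; cy <- 42
  u <- pi - 2 * pi * (seq_len(64) - 1) / 64
  f <- 1 - 0.22 * cos(u)
  pts <- cbind(cx + b0 * sin(u) * f, cy - a * cos(u))
  list(pts = pts,
       facets = list(distal_surface = c(29L, 37L)))
}

#' Construct the synthetic-wrist bone templates
#'
#' Deterministic constructor behind the shipped JSON fixture; see the file
#' header of `templates.R` for the geometric design. Coordinates are mm on a
#' 58 x 76 mm canvas, x rightward, y downward (proximal = larger y).
#'
#' @return List with `ap` and `lat` bone lists (each bone: `pts`, `facets`),
#'   canvas size, default SL gap, scale centers and rotation anchors.
#' @keywords internal
buildWristTemplates <- function() {
  sca <- .proxRowBone(12, 24)
  lun <- .proxRowBone(26, 36)
  tri <- .proxRowBone(37.5, 46.5)
  ap <- list(
    scaphoid = list(pts = sca$pts,
      facets = list(proximal_surface = sca$sections$bottom,
                    scaphoid_lunate = sca$sections$right,
                    distal_surface = sca$sections$top)),
    lunate = list(pts = lun$pts,
      facets = list(proximal_surface = lun$sections$bottom,
                    lunate_radius = lun$sections$bottom,
                    distal_surface = lun$sections$top,
                    lunate_capitate = lun$sections$top,
                    lunate_scaphoid = lun$sections$left)),
    triquetrum = list(pts = tri$pts,
      facets = list(proximal_surface = tri$sections$bottom,
                    distal_surface = tri$sections$top)),
    capitate = .capitateAP(),
    hamate = .hamateAP(),
    metacarpal3 = list(pts = .superellipse(c(28.75, 10.5), 4.25, 4, 4, 60),
                       facets = list()),
    radius = list(pts = .superellipse(c(28.5, 61.5), 18.5, 7.5, 6, 72),
                  facets = list()))
  lat <- list(
    scaphoid = .scaphoidLat(),
    lunate = .lunateLat(),
    capitate = .capitateLat(),
    metacarpal3 = list(pts = .superellipse(c(31, 9), 3.5, 3, 4, 60),
                      facets = list()),
    radius = list(pts = .superellipse(c(31, 58), 11, 7.5, 6, 72),
                  facets = list()))
  list(ap = ap, lat = lat,
       canvasMm = c(58, 76),          # width (x), height (y)
       gapDefaultMm = 2,
       scaleCenterAP = c(29, 36), scaleCenterLat = c(31, 40),
       capitateLatPivot = c(31, 33),  # capitolunate facet midpoint
       arcCurvature = 1 / 60)
}

## Load the shipped template fixture (cached); falls back to the
## constructor when running from a source tree without installed extdata.
wristTemplates <- function() {
  if (!is.null(.pkgEnv$templates)) return(.pkgEnv$templates)
  path <- system.file("extdata", "wrist_templates.json", package = "carpalign")
  tpl <- if (nzchar(path)) .templatesFromJSON(path) else buildWristTemplates()
  .pkgEnv$templates <- tpl
  tpl
}

.templatesFromJSON <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixView <- function(v) {
    lapply(v, function(b) {
      facets <- b$facets
      facets <- if (length(facets)) lapply(facets, as.integer) else list()
      list(pts = matrix(unlist(b$pts), ncol = 2), facets = facets)
    })
  }
  list(ap = fixView(raw$ap), lat = fixView(raw$lat),
       canvasMm = as.numeric(raw$canvasMm),
       gapDefaultMm = raw$gapDefaultMm,
       scaleCenterAP = as.numeric(raw$scaleCenterAP),
       scaleCenterLat = as.numeric(raw$scaleCenterLat),
       capitateLatPivot = as.numeric(raw$capitateLatPivot),
       arcCurvature = raw$arcCurvature)
}

.templatesToJSON <- function(tpl, path) {
  enc <- function(v) lapply(v, function(b)
    list(pts = unname(lapply(seq_len(nrow(b$pts)),
                             function(i) unname(b$pts[i, ]))),
         facets = b$facets))
  out <- list(format_version = "1.0",
              ap = enc(tpl$ap), lat = enc(tpl$lat),
              canvasMm = tpl$canvasMm, gapDefaultMm = tpl$gapDefaultMm,
              scaleCenterAP = tpl$scaleCenterAP,
              scaleCenterLat = tpl$scaleCenterLat,
              capitateLatPivot = tpl$capitateLatPivot,
              arcCurvature = tpl$arcCurvature)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
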