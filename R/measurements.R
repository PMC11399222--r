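## Radiographic measurements: bone axes, SL distance, SL/CL angles, and
## classification against view- and age-specific reference thresholds.
##
## Axis constructions: the capitate long axis joins the midpoints of its
## capitolunate and capitate-metacarpal-III facets; the lunate mid-plane
## axis joins the midpoints of its lunate-radius and lunate-capitate
## facets; the scaphoid long axis is the principal axis of its lateral
## contour, oriented toward the distal pole.

#' Principal (long) axis of a landmarked bone
#'
#' Major eigenvector of the landmark second-central-moment matrix,
#' canonically oriented distally: toward the midpoint of `orientFacet`
#' when present, otherwise toward smaller y (the distal direction in the
#' upright image frame).
#'
#' @param shape a [LandmarkedShape-class] (>= 3 non-collinear landmarks).
#' @param orientFacet facet name used to orient the direction (default
#'   "distal_surface" when the shape has it).
#' @param minEigenRatio elongation guard: an eigenvalue ratio below this
#'   means the orientation is ambiguous (near-isotropic shape) and an
#'   error is raised.
#' @return An [Axis-class] anchored at the landmark centroid.
#' @examples
#' rect <- cbind(c(0, 4, 4, 0), c(0, 0, 1, 1))
#' principalAxis(LandmarkedShape("capitate", rect))
#' @export
principalAxis <- function(shape, orientFacet = "distal_surface",
                          minEigenRatio = 1.05) {
  lm <- shape@landmarks
  ctr <- colMeans(lm)
  C <- stats::cov(lm)
  eig <- eigen(C, symmetric = TRUE)
  if (eig$values[2] > 0 && eig$values[1] / eig$values[2] < minEigenRatio)
    stop(sprintf(
      "ambiguous principal axis for %s: eigenvalue ratio %.3f < %.2f (near-isotropic shape)",
      shape@bone, eig$values[1] / eig$values[2], minEigenRatio))
  dir <- eig$vectors[, 1]
  if (!is.null(shape@facets[[orientFacet]])) {
    toFacet <- facetMidpoint(shape, orientFacet) - ctr
    if (sum(dir * toFacet) < 0) dir <- -dir
  } else if (dir[2] > 0 || (dir[2] == 0 && dir[1] < 0)) {
    dir <- -dir
  }
  Axis(ctr, dir)
}

#' Facet-midpoint bone axis
#'
#' Line through the arc-length midpoints of two facets, anchored at their
#' average and directed from the proximal facet toward the distal one.
#'
#' @param shape a [LandmarkedShape-class].
#' @param facetProximal,facetDistal facet names; the direction points from
#'   the proximal facet midpoint to the distal one.
#' @return An [Axis-class].
#' @examples
#' sh <- LandmarkedShape("capitate", cbind(c(0, 1, 1, 0), c(4, 4, 0, 0)),
#'                       list(capitate_lunate = c(1, 2),
#'                            capitate_mc3 = c(3, 4)))
#' facetAxis(sh, "capitate_lunate", "capitate_mc3")
#' @export
facetAxis <- function(shape, facetProximal, facetDistal) {
  mp <- facetMidpoint(shape, facetProximal)
  md <- facetMidpoint(shape, facetDistal)
  if (sqrt(sum((md - mp)^2)) < 1e-9)
    stop(sprintf("coincident facet midpoints (%s, %s) on %s",
                 facetProximal, facetDistal, shape@bone))
  Axis((mp + md) / 2, md - mp)
}

#' Angle between two oriented axes
#'
#' Angle in degrees, in [0, 180), between the canonically oriented
#' directions. Exactly opposite directions indicate an orientation-flag
#' error upstream and raise a warning.
#'
#' @param axis1,axis2 [Axis-class] objects.
#' @return Angle in degrees.
#' @examples
#' angleBetween(Axis(c(0, 0), c(0, -1)), Axis(c(0, 0), c(1, -1)))
#' @export
angleBetween <- function(axis1, axis2) {
  d <- sum(axis1@direction * axis2@direction)
  ang <- acos(pmin(1, pmax(-1, d))) * 180 / pi
  if (ang > 180 - 1e-9) {
    warning("axes are exactly opposed; check orientation flags upstream")
    ang <- 180 - 1e-9
  }
  ang
}

#' Scapholunate joint distance
#'
#' Euclidean distance (mm) between the arc-length midpoints of the facing
#' scaphoid-lunate facets on an AP/PA view.
#'
#' @param scaphoidShape,lunateShape [LandmarkedShape-class] objects with
#'   `scaphoid_lunate` / `lunate_scaphoid` facets.
#' @return Distance in mm.
#' @export
slDistance <- function(scaphoidShape, lunateShape) {
  a <- facetMidpoint(scaphoidShape, "scaphoid_lunate")
  b <- facetMidpoint(lunateShape, "lunate_scaphoid")
  sqrt(sum((a - b)^2))
}

#' Bone axes used by the angle measurements
#'
#' Convenience constructors for the three measurement axes on the lateral
#' view.
#'
#' @param shape fitted [LandmarkedShape-class] of the respective bone.
#' @return An [Axis-class].
#' @export
capitateAxis <- function(shape) facetAxis(shape, "capitate_lunate",
                                          "capitate_mc3")

#' @rdname capitateAxis
#' @export
lunateAxis <- function(shape) facetAxis(shape, "lunate_radius",
                                        "lunate_capitate")

#' @rdname capitateAxis
#' @export
scaphoidAxis <- function(shape) principalAxis(shape)

#' Classify a measurement against the reference thresholds
#'
#' Abnormality uses strict exceedance of the reference values: SL distance
#' abnormal iff above the view- and age-appropriate limit (3.0 mm neutral
#' and clenched-fist, 3.7 mm ulnar-deviated for adults); SL angle abnormal
#' iff outside 30..60 degrees (boundaries normal); CL angle abnormal iff
#' above 30 degrees (30.0 exactly is normal). Ages 6-14 use the
#' user-supplied pediatric SL-distance table; a pediatric age without a
#' covering band (and ages below 6) is unclassifiable and returns NA with
#' an explanatory rule.
#'
#' @param name one of "sl_distance", "sl_angle", "cl_angle".
#' @param value measured value (mm or degrees).
#' @param view one of [wristViews()]; distances require an AP/PA view,
#'   angles the lateral view.
#' @param ageYears patient age.
#' @param config a [ThresholdConfig-class].
#' @return List with `abnormal` (logical or NA), `thresholdRule` (text) and
#'   the echoed inputs.
#' @examples
#' classifyMeasurement("sl_distance", 3.5, "neutral_ap_pa", 40,
#'                     defaultThresholds())$abnormal
#' @export
classifyMeasurement <- function(name, value, view, ageYears,
                                config = defaultThresholds()) {
  name <- match.arg(name, c("sl_distance", "sl_angle", "cl_angle"))
  apViews <- c("neutral_ap_pa", "ulnar_deviated_ap_pa", "clenched_fist_ap_pa")
  if (name == "sl_distance" && !view %in% apViews)
    stop("SL distance is defined on AP/PA views")
  if (name %in% c("sl_angle", "cl_angle") && view != "lateral")
    stop("SL and CL angles are defined on the lateral view")
  out <- list(name = name, value = value, view = view, ageYears = ageYears)
  if (name == "sl_distance") {
    if (ageYears < 15) {
      tb <- config@pediatricTable
      hit <- which(ageYears >= tb$ageMin & ageYears <= tb$ageMax)
      if (ageYears < 6 || length(hit) == 0) {
        out$abnormal <- NA
        out$thresholdRule <- sprintf(
          "unclassifiable: no pediatric SL-distance limit for age %.1f (supply pediatricTable)",
          ageYears)
        return(out)
      }
      thr <- tb$slDistanceMm[hit[1]]
      out$thresholdRule <- sprintf("pediatric: abnormal iff > %.2f mm (age band %g-%g)",
                                   thr, tb$ageMin[hit[1]], tb$ageMax[hit[1]])
    } else {
      thr <- if (view == "ulnar_deviated_ap_pa") config@slDistanceUlnarMm
             else config@slDistanceNeutralMm
      rule <- if (view == "ulnar_deviated_ap_pa") "ulnar-deviated"
              else if (view == "clenched_fist_ap_pa")
                "clenched-fist (neutral threshold assumed)"
              else "neutral"
      out$thresholdRule <- sprintf("abnormal iff > %.1f mm (%s view)", thr,
                                   rule)
    }
    out$abnormal <- value > thr
  } else if (name == "sl_angle") {
    rng <- config@slAngleRangeDeg
    out$abnormal <- value < rng[1] || value > rng[2]
    out$thresholdRule <- sprintf(
      "abnormal iff outside [%g, %g] degrees (boundaries normal)", rng[1],
      rng[2])
  } else {
    out$abnormal <- value > config@clAngleMaxDeg
    out$thresholdRule <- sprintf(
      "abnormal iff > %g degrees (boundary normal)", config@clAngleMaxDeg)
  }
  out
}
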