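## S4 classes for the carpal-instability pipeline.

#' Carpal bone vocabulary
#'
#' The fixed set of bones the measurements require, and the integer labels
#' used in label-mask images (background = 0).
#'
#' @return `carpalBones()`: character vector of bone names.
#'   `boneLabelTable()`: named integer vector mapping bone name to mask label.
#' @examples
#' boneLabelTable()
#' @export
carpalBones <- function() {
  c("scaphoid", "lunate", "triquetrum", "capitate", "hamate",
    "metacarpal3", "radius")
}

#' @rdname carpalBones
#' @export
boneLabelTable <- function() {
  stats::setNames(seq_len(7L), carpalBones())
}

#' Radiographic view vocabulary
#'
#' View types a study can declare in its sidecar. Distances and arcs are
#' defined on AP/PA views (arcs on the neutral view only); angles on the
#' lateral view.
#'
#' @return Character vector of valid view names.
#' @export
wristViews <- function() {
  c("neutral_ap_pa", "ulnar_deviated_ap_pa", "clenched_fist_ap_pa",
    "lateral", "oblique")
}

#' StudyMeta: per-study calibration and context
#'
#' Pixel spacing, radiographic view and patient age gate every measurement
#' rule downstream, so they travel with the data from ingestion on.
#'
#' @slot spacingMmPerPx positive pixel spacing in mm/px.
#' @slot view one of [wristViews()].
#' @slot ageYears patient age in years (>= 0).
#' @slot studyId free-text study identifier.
#' @export
setClass("StudyMeta",
  representation(spacingMmPerPx = "numeric", view = "character",
                 ageYears = "numeric", studyId = "character"),
  prototype(spacingMmPerPx = 0.2, view = "neutral_ap_pa",
            ageYears = 40, studyId = ""))

setValidity("StudyMeta", function(object) {
  if (length(object@spacingMmPerPx) != 1 || !is.finite(object@spacingMmPerPx) ||
      object@spacingMmPerPx <= 0)
    return("spacingMmPerPx must be a single positive number")
  if (!object@view %in% wristViews())
    return(sprintf("view must be one of: %s", paste(wristViews(), collapse = ", ")))
  if (object@ageYears < 0) return("ageYears must be >= 0")
  TRUE
})

#' Construct a StudyMeta
#' @param spacingMmPerPx pixel spacing, mm per pixel (> 0).
#' @param view one of [wristViews()].
#' @param ageYears patient age in years.
#' @param studyId study identifier.
#' @return A [StudyMeta-class] object.
#' @export
StudyMeta <- function(spacingMmPerPx, view = "neutral_ap_pa", ageYears = 40,
                      studyId = "") {
  methods::new("StudyMeta", spacingMmPerPx = spacingMmPerPx, view = view,
               ageYears = as.numeric(ageYears), studyId = studyId)
}

#' Contour: closed bone outline in mm
#'
#' Ordered closed polyline (first vertex not repeated) in millimetres,
#' stored counter-clockwise as seen on the displayed image.
#'
#' @slot bone bone name, one of [carpalBones()].
#' @slot pts n x 2 matrix of vertices (mm).
#' @export
setClass("Contour", representation(bone = "character", pts = "matrix"))

setValidity("Contour", function(object) {
  if (!object@bone %in% carpalBones()) return("unknown bone")
  p <- object@pts
  if (!is.numeric(p) || ncol(p) != 2) return("pts must be an n x 2 numeric matrix")
  if (nrow(p) < 3) return("a contour needs at least 3 points")
  if (any(!is.finite(p))) return("non-finite coordinates")
  d <- diff(rbind(p, p[1, ]))
  if (any(rowSums(d * d) < 1e-20)) return("duplicate consecutive vertices")
  if (shoelaceArea(p) <= 0) return("contour must be counter-clockwise (image frame)")
  TRUE
})

#' Construct a Contour
#' @param bone bone name.
#' @param pts n x 2 vertex matrix in mm; re-oriented to the package
#'   convention if needed.
#' @return A [Contour-class] object.
#' @export
Contour <- function(bone, pts) {
  pts <- as.matrix(pts)
  colnames(pts) <- c("x", "y")
  methods::new("Contour", bone = bone, pts = orientCCW(pts))
}

#' LandmarkedShape: ordered landmarks with named articular facets
#'
#' A bone outline reduced to n corresponding landmarks, with named facet
#' segments given as contiguous index ranges (used to build axes, the SL
#' distance, and the carpal arcs).
#'
#' @slot bone bone name.
#' @slot landmarks n x 2 matrix (mm).
#' @slot facets named list of integer c(start, end) ranges (1-based,
#'   inclusive, non-wrapping).
#' @export
setClass("LandmarkedShape",
  representation(bone = "character", landmarks = "matrix", facets = "list"))

setValidity("LandmarkedShape", function(object) {
  n <- nrow(object@landmarks)
  if (ncol(object@landmarks) != 2) return("landmarks must be n x 2")
  if (n < 3) return("need >= 3 landmarks")
  for (nm in names(object@facets)) {
    r <- object@facets[[nm]]
    if (length(r) != 2 || r[1] < 1 || r[2] > n || r[1] > r[2])
      return(sprintf("facet '%s' range outside [1, %d]", nm, n))
  }
  TRUE
})

#' Construct a LandmarkedShape
#' @param bone bone name.
#' @param landmarks n x 2 landmark matrix (mm).
#' @param facets named list of integer c(start, end) index ranges.
#' @return A [LandmarkedShape-class] object.
#' @export
LandmarkedShape <- function(bone, landmarks, facets = list()) {
  lm <- as.matrix(landmarks)
  colnames(lm) <- c("x", "y")
  methods::new("LandmarkedShape", bone = bone, landmarks = lm,
               facets = lapply(facets, function(r) as.integer(r[1:2])))
}

#' ShapeModel: point distribution model (PDM)
#'
#' PCA model of Procrustes-aligned landmark configurations. The model frame
#' is scaled to the mean training centroid size, so model-frame distances
#' (and the per-landmark residual scales used for z-scores) are in mm.
#'
#' @slot name model name (bone or arc).
#' @slot meanShape n x 2 mean landmarks (model frame, mm).
#' @slot modes 2n x k orthonormal mode matrix (landmark-interleaved x,y).
#' @slot eigenvalues k non-negative variances, descending.
#' @slot retainedVariance fraction of total variance the k modes explain.
#' @slot residualSD n per-landmark residual scales (mm, floored).
#' @slot facets facet index ranges transferred to fitted shapes.
#' @slot meanSize mean training centroid size (mm) used to scale the frame.
#' @slot closed whether landmarks form a closed outline (cyclic
#'   correspondence search applies) or an open polyline (fixed ordering).
#' @export
setClass("ShapeModel",
  representation(name = "character", meanShape = "matrix", modes = "matrix",
                 eigenvalues = "numeric", retainedVariance = "numeric",
                 residualSD = "numeric", facets = "list", meanSize = "numeric",
                 closed = "logical"))

setValidity("ShapeModel", function(object) {
  n <- nrow(object@meanShape)
  k <- length(object@eigenvalues)
  if (ncol(object@meanShape) != 2) return("meanShape must be n x 2")
  if (nrow(object@modes) != 2 * n || ncol(object@modes) != k)
    return("modes must be 2n x k")
  if (k > 1 && any(diff(object@eigenvalues) > 1e-9))
    return("eigenvalues must be sorted descending")
  if (any(object@eigenvalues < -1e-9)) return("negative eigenvalue")
  if (k > 0) {
    g <- crossprod(object@modes)
    if (max(abs(g - diag(k))) > 1e-6) return("modes must be orthonormal")
  }
  if (length(object@residualSD) != n) return("residualSD must have length n")
  if (any(object@residualSD <= 0)) return("residualSD must be positive (floored)")
  TRUE
})

#' ArcSet: Gilula's three carpal arcs
#'
#' The proximal (I), middle (II) and distal (III) carpal arcs as open
#' 100-point polylines in mm, radial to ulnar. An arc that cannot be built
#' (missing bone) is NULL in the slot list.
#'
#' @slot arcs named list (proximal, middle, distal) of 100 x 2 matrices or
#'   NULL.
#' @slot view the view the arcs were built on (must be neutral_ap_pa).
#' @export
setClass("ArcSet", representation(arcs = "list", view = "character"))

setValidity("ArcSet", function(object) {
  if (!identical(names(object@arcs), c("proximal", "middle", "distal")))
    return("arcs must be named proximal, middle, distal")
  for (a in object@arcs) {
    if (is.null(a)) next
    if (!is.matrix(a) || ncol(a) != 2 || nrow(a) != 100)
      return("each arc must be a 100 x 2 matrix")
    if (any(!is.finite(a))) return("non-finite arc coordinates")
  }
  if (object@view != "neutral_ap_pa")
    return("carpal arcs are defined on the neutral AP/PA view only")
  TRUE
})

#' ArcAssessment: observed vs reconstructed arcs with z-scores
#'
#' @slot observed,reconstructed [ArcSet-class] objects.
#' @slot displacement named list of 100 x 2 displacement vectors
#'   (observed - reconstructed, image frame, mm).
#' @slot zscores named list of length-100 non-negative z-score vectors.
#' @slot score overall disruption score in 0..1 (fraction of arc points with
#'   z >= zCrit).
#' @slot detected logical, score >= threshold.
#' @slot threshold operating threshold on the disruption score.
#' @slot zCrit z-score cut-off defining an exceeding point.
#' @slot markers per-arc list of c(start, end) runs of exceeding points.
#' @export
setClass("ArcAssessment",
  representation(observed = "ArcSet", reconstructed = "ArcSet",
                 displacement = "list", zscores = "list", score = "numeric",
                 detected = "logical", threshold = "numeric",
                 zCrit = "numeric", markers = "list"))

setValidity("ArcAssessment", function(object) {
  if (object@score < 0 || object@score > 1) return("score must be in [0, 1]")
  if (!identical(object@detected, object@score >= object@threshold))
    return("detected must equal score >= threshold")
  for (z in object@zscores) if (!is.null(z) && any(z < 0))
    return("z-scores must be >= 0")
  TRUE
})

#' WristParams: ground-truth parameters of a synthetic wrist
#'
#' @slot slGapMm scapholunate joint gap (mm, >= 0).
#' @slot slAngleDeg scapholunate angle (degrees, 0..120).
#' @slot clAngleDeg capitolunate angle (degrees, -30..90; the measurement
#'   convention is unsigned, so the ground-truth record stores the
#'   magnitude).
#' @slot subluxationMm proximal translation of the subluxating bone (mm).
#' @slot subluxBone "capitate" or "lunate".
#' @slot interrupted TRUE iff subluxationMm exceeds the generator's step
#'   threshold (1 mm).
#' @slot globalScale,rotationDeg global similarity pose of the wrist.
#' @slot noiseSdMm smoothed per-vertex contour jitter SD (mm).
#' @slot seed integer RNG seed.
#' @export
setClass("WristParams",
  representation(slGapMm = "numeric", slAngleDeg = "numeric",
                 clAngleDeg = "numeric", subluxationMm = "numeric",
                 subluxBone = "character", interrupted = "logical",
                 globalScale = "numeric", rotationDeg = "numeric",
                 noiseSdMm = "numeric", seed = "integer"))

setValidity("WristParams", function(object) {
  if (object@slGapMm < 0) return("slGapMm must be >= 0")
  if (object@slAngleDeg < 0 || object@slAngleDeg > 120)
    return("slAngleDeg must be in [0, 120]")
  if (object@clAngleDeg < -30 || object@clAngleDeg > 90)
    return("clAngleDeg must be in [-30, 90]")
  if (object@subluxationMm < 0) return("subluxationMm must be >= 0")
  if (!object@subluxBone %in% c("capitate", "lunate"))
    return("subluxBone must be 'capitate' or 'lunate'")
  if (object@globalScale <= 0) return("globalScale must be > 0")
  if (object@noiseSdMm < 0) return("noiseSdMm must be >= 0")
  if (!identical(object@interrupted,
                 object@subluxationMm > interruptionStepThreshold()))
    return("interrupted must equal subluxationMm > step threshold (1 mm)")
  TRUE
})

#' SyntheticCase: a generated wrist with ground truth
#'
#' @slot params the [WristParams-class] applied.
#' @slot contoursAP,contoursLat named lists of [Contour-class] objects.
#' @slot maskAP,maskLat integer label matrices (possibly 0 x 0 when
#'   rasterization was skipped).
#' @slot spacingMmPerPx pixel spacing the masks were rasterized at.
#' @slot truth list of ground-truth measurement values (slDistanceMm,
#'   slAngleDeg, clAngleDeg, interrupted, subluxationMm).
#' @slot truthFacets per-view, per-bone facet index ranges into the
#'   contours.
#' @export
setClass("SyntheticCase",
  representation(params = "WristParams", contoursAP = "list",
                 contoursLat = "list", maskAP = "matrix", maskLat = "matrix",
                 spacingMmPerPx = "numeric", truth = "list",
                 truthFacets = "list"))

#' ThresholdConfig: reference thresholds for classification and detection
#'
#' Defaults follow the adult reference values: SL distance abnormal above
#' 3.0 mm (neutral and clenched-fist AP/PA) or 3.7 mm (ulnar-deviated,
#' Stecher's projection); SL angle normal in 30..60 degrees inclusive; CL
#' angle abnormal above 30 degrees; arc disruption detected at a score of
#' 0.11 (11%). The pediatric table (ages 6-14) ships empty and must be
#' supplied by the user; pediatric cases without an entry are flagged
#' unclassifiable.
#'
#' @slot slDistanceNeutralMm,slDistanceUlnarMm SL distance upper limits.
#' @slot slAngleRangeDeg normal SL angle range (inclusive boundaries).
#' @slot clAngleMaxDeg CL angle upper limit (inclusive boundary).
#' @slot pediatricTable data.frame(ageMin, ageMax, slDistanceMm).
#' @slot arcDetectionThreshold operating threshold on the disruption score.
#' @slot zCrit z-score cut-off for the disruption score.
#' @export
setClass("ThresholdConfig",
  representation(slDistanceNeutralMm = "numeric", slDistanceUlnarMm = "numeric",
                 slAngleRangeDeg = "numeric", clAngleMaxDeg = "numeric",
                 pediatricTable = "data.frame",
                 arcDetectionThreshold = "numeric", zCrit = "numeric"))

setValidity("ThresholdConfig", function(object) {
  vals <- c(object@slDistanceNeutralMm, object@slDistanceUlnarMm,
            object@clAngleMaxDeg, object@arcDetectionThreshold, object@zCrit)
  if (any(vals <= 0)) return("thresholds must be positive")
  if (length(object@slAngleRangeDeg) != 2 ||
      diff(object@slAngleRangeDeg) <= 0)
    return("slAngleRangeDeg must be an increasing pair")
  if (!all(c("ageMin", "ageMax", "slDistanceMm") %in%
           names(object@pediatricTable)))
    return("pediatricTable needs columns ageMin, ageMax, slDistanceMm")
  TRUE
})

#' Default threshold configuration
#' @param pediatricTable optional data.frame(ageMin, ageMax, slDistanceMm)
#'   with age-band SL distance upper limits for ages 6-14; empty by default
#'   (values must come from the pediatric reference literature and are not
#'   shipped).
#' @param arcDetectionThreshold disruption-score operating point (default
#'   0.11).
#' @param zCrit z-score cut-off (default 2).
#' @return A [ThresholdConfig-class] object.
#' @examples
#' cfg <- defaultThresholds()
#' @export
defaultThresholds <- function(pediatricTable = NULL,
                              arcDetectionThreshold = 0.11, zCrit = 2) {
  if (is.null(pediatricTable))
    pediatricTable <- data.frame(ageMin = numeric(0), ageMax = numeric(0),
                                 slDistanceMm = numeric(0))
  methods::new("ThresholdConfig",
    slDistanceNeutralMm = 3.0, slDistanceUlnarMm = 3.7,
    slAngleRangeDeg = c(30, 60), clAngleMaxDeg = 30,
    pediatricTable = pediatricTable,
    arcDetectionThreshold = arcDetectionThreshold, zCrit = zCrit)
}

#' Axis: anatomical bone axis
#'
#' @slot anchor 2-D anchor point (mm).
#' @slot direction unit 2-D vector, canonically oriented distally (toward
#'   smaller y in the upright image frame, or toward the bone's distal
#'   facet).
#' @export
setClass("Axis", representation(anchor = "numeric", direction = "numeric"))

setValidity("Axis", function(object) {
  if (length(object@anchor) != 2 || length(object@direction) != 2)
    return("anchor and direction must be 2-D")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit vector")
  TRUE
})

#' Construct an Axis
#' @param anchor 2-D anchor point.
#' @param direction 2-D direction (normalized internally).
#' @return An [Axis-class] object.
#' @export
Axis <- function(anchor, direction) {
  methods::new("Axis", anchor = as.numeric(anchor),
               direction = unitVector(as.numeric(direction)))
}
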