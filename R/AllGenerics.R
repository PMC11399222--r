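## Generics, accessors and show methods.

#' Coordinates of a geometric object
#' @param x a [Contour-class], [LandmarkedShape-class] or [ArcSet-class].
#' @param ... further arguments for methods.
#' @return An n x 2 coordinate matrix (for `ArcSet`, a named list of them).
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "Contour", function(x, ...) x@pts)

#' @rdname coords
#' @export
setMethod("coords", "LandmarkedShape", function(x, ...) x@landmarks)

#' @rdname coords
#' @export
setMethod("coords", "ArcSet", function(x, ...) x@arcs)

#' Bone name of an object
#' @param x a [Contour-class] or [LandmarkedShape-class].
#' @return Bone name string.
#' @export
setGeneric("boneName", function(x) standardGeneric("boneName"))

#' @rdname boneName
#' @export
setMethod("boneName", "Contour", function(x) x@bone)

#' @rdname boneName
#' @export
setMethod("boneName", "LandmarkedShape", function(x) x@bone)

#' Facet index ranges
#' @param x a [LandmarkedShape-class] or [ShapeModel-class].
#' @return Named list of integer c(start, end) ranges.
#' @export
setGeneric("facetRanges", function(x) standardGeneric("facetRanges"))

#' @rdname facetRanges
#' @export
setMethod("facetRanges", "LandmarkedShape", function(x) x@facets)

#' @rdname facetRanges
#' @export
setMethod("facetRanges", "ShapeModel", function(x) x@facets)

#' PDM components
#'
#' Accessors for the slots of a [ShapeModel-class]: mean shape, modes,
#' eigenvalues, per-landmark residual scales.
#'
#' @param x a [ShapeModel-class].
#' @return `modelMean`: n x 2 matrix; `modelModes`: 2n x k matrix;
#'   `modelEigenvalues`: numeric vector; `residualScale`: length-n vector.
#' @export
setGeneric("modelMean", function(x) standardGeneric("modelMean"))

#' @rdname modelMean
#' @export
setMethod("modelMean", "ShapeModel", function(x) x@meanShape)

#' @rdname modelMean
#' @export
setGeneric("modelModes", function(x) standardGeneric("modelModes"))

#' @rdname modelMean
#' @export
setMethod("modelModes", "ShapeModel", function(x) x@modes)

#' @rdname modelMean
#' @export
setGeneric("modelEigenvalues", function(x) standardGeneric("modelEigenvalues"))

#' @rdname modelMean
#' @export
setMethod("modelEigenvalues", "ShapeModel", function(x) x@eigenvalues)

#' @rdname modelMean
#' @export
setGeneric("residualScale", function(x) standardGeneric("residualScale"))

#' @rdname modelMean
#' @export
setMethod("residualScale", "ShapeModel", function(x) x@residualSD)

#' Arc assessment accessors
#' @param x an [ArcAssessment-class].
#' @return `arcScore`: disruption score in 0..1; `isDetected`: logical;
#'   `arcZ`: named list of per-point z-score vectors; `arcMarkers`: per-arc
#'   runs of exceeding points.
#' @export
setGeneric("arcScore", function(x) standardGeneric("arcScore"))

#' @rdname arcScore
#' @export
setMethod("arcScore", "ArcAssessment", function(x) x@score)

#' @rdname arcScore
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))

#' @rdname arcScore
#' @export
setMethod("isDetected", "ArcAssessment", function(x) x@detected)

#' @rdname arcScore
#' @export
setGeneric("arcZ", function(x) standardGeneric("arcZ"))

#' @rdname arcScore
#' @export
setMethod("arcZ", "ArcAssessment", function(x) x@zscores)

#' @rdname arcScore
#' @export
setGeneric("arcMarkers", function(x) standardGeneric("arcMarkers"))

#' @rdname arcScore
#' @export
setMethod("arcMarkers", "ArcAssessment", function(x) x@markers)

#' Synthetic case accessors
#' @param x a [SyntheticCase-class].
#' @return `caseParams`: the [WristParams-class] applied; `caseTruth`: list
#'   of ground-truth measurement values.
#' @export
setGeneric("caseParams", function(x) standardGeneric("caseParams"))

#' @rdname caseParams
#' @export
setMethod("caseParams", "SyntheticCase", function(x) x@params)

#' @rdname caseParams
#' @export
setGeneric("caseTruth", function(x) standardGeneric("caseTruth"))

#' @rdname caseParams
#' @export
setMethod("caseTruth", "SyntheticCase", function(x) x@truth)

setMethod("show", "StudyMeta", function(object) {
  cat(sprintf("StudyMeta '%s': %s view, %.3g mm/px, age %.3g y\n",
              object@studyId, object@view, object@spacingMmPerPx,
              object@ageYears))
})

setMethod("show", "Contour", function(object) {
  cat(sprintf("Contour of %s: %d vertices, area %.1f mm^2\n", object@bone,
              nrow(object@pts), polygonArea(object@pts)))
})

setMethod("show", "LandmarkedShape", function(object) {
  cat(sprintf("LandmarkedShape of %s: %d landmarks, facets: %s\n",
              object@bone, nrow(object@landmarks),
              if (length(object@facets)) paste(names(object@facets),
                                               collapse = ", ") else "none"))
})

setMethod("show", "ShapeModel", function(object) {
  cat(sprintf(
    "ShapeModel '%s': %d landmarks (%s), %d modes (%.1f%% variance)\n",
    object@name, nrow(object@meanShape),
    if (object@closed) "closed" else "open",
    length(object@eigenvalues), 100 * object@retainedVariance))
})

setMethod("show", "ArcSet", function(object) {
  av <- vapply(object@arcs, Negate(is.null), logical(1))
  cat(sprintf("ArcSet (%s): %s\n", object@view,
              paste(sprintf("%s[%s]", names(av),
                            ifelse(av, "ok", "unavailable")), collapse = " ")))
})

setMethod("show", "ArcAssessment", function(object) {
  cat(sprintf(
    "ArcAssessment: disruption score %.3f (threshold %.2f) -> %s\n",
    object@score, object@threshold,
    if (object@detected) "INTERRUPTED" else "not interrupted"))
})

setMethod("show", "WristParams", function(object) {
  cat(sprintf(
    paste0("WristParams: SL gap %.2f mm, SL %.1f deg, CL %.1f deg, ",
           "subluxation %.2f mm (%s)%s, scale %.2f, rot %.1f deg, ",
           "noise %.2f mm, seed %d\n"),
    object@slGapMm, object@slAngleDeg, object@clAngleDeg,
    object@subluxationMm, object@subluxBone,
    if (object@interrupted) " [interrupted]" else "", object@globalScale,
    object@rotationDeg, object@noiseSdMm, object@seed))
})

setMethod("show", "SyntheticCase", function(object) {
  cat(sprintf("SyntheticCase: %d AP + %d lateral bones, masks %s\n",
              length(object@contoursAP), length(object@contoursLat),
              if (nrow(object@maskAP)) sprintf("%dx%d @ %.3g mm/px",
                nrow(object@maskAP), ncol(object@maskAP),
                object@spacingMmPerPx) else "not rasterized"))
  show(object@params)
})

setMethod("show", "ThresholdConfig", function(object) {
  cat(sprintf(
    paste0("ThresholdConfig: SL distance > %.1f mm (neutral) / > %.1f mm ",
           "(ulnar-deviated); SL angle outside [%g, %g] deg; CL angle > %g ",
           "deg; arc score >= %.2f (zCrit %.1f); pediatric table: %d rows\n"),
    object@slDistanceNeutralMm, object@slDistanceUlnarMm,
    object@slAngleRangeDeg[1], object@slAngleRangeDeg[2],
    object@clAngleMaxDeg, object@arcDetectionThreshold, object@zCrit,
    nrow(object@pediatricTable)))
})

setMethod("show", "Axis", function(object) {
  cat(sprintf("Axis: anchor (%.2f, %.2f), direction (%.3f, %.3f)\n",
              object@anchor[1], object@anchor[2], object@direction[1],
              object@direction[2]))
})
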