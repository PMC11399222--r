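## Pipeline orchestration: model training on a synthetic cohort, per-study
## measurement (ingest -> fit -> measure -> arcs -> report), cohort
## evaluation, and model file IO.

.latBones <- c("scaphoid", "lunate", "capitate", "metacarpal3", "radius")

## Map facet vertex ranges of an original contour onto the indices of its
## n-point arc-length resampling (resampling starts at vertex 1).
.mapFacetsToResampled <- function(pts, facets, n) {
  tcum <- cumArcLength(rbind(pts, pts[1, ]))
  L <- tcum[length(tcum)]
  pos <- (seq_len(n) - 1) * L / n
  out <- list()
  for (nm in names(facets)) {
    r <- facets[[nm]]
    idx <- which(pos >= tcum[r[1]] - 1e-9 & pos <= tcum[r[2]] + 1e-9)
    if (length(idx) < 2) {
      i0 <- which.min(abs(pos - (tcum[r[1]] + tcum[r[2]]) / 2))
      idx <- max(1, i0 - 1):min(n, i0 + 1)
    }
    out[[nm]] <- c(min(idx), max(idx))
  }
  out
}

#' Ground-truth landmarked shapes of a synthetic case
#'
#' The generator's exact contour vertices with the template facet ranges:
#' the reference the fitted shapes are compared against. Measuring these
#' shapes returns the generator parameters exactly (at zero contour
#' noise). With `n` set, the contours are first resampled to n landmarks
#' (introducing sub-sample discretization) and the facet ranges are mapped
#' by arc length - the representation the bone models are trained on.
#'
#' @param case a [SyntheticCase-class].
#' @param view "ap" or "lat".
#' @param n optional landmark count; NULL (default) keeps the exact
#'   template vertices.
#' @return Named list of [LandmarkedShape-class] objects.
#' @export
truthLandmarks <- function(case, view = c("ap", "lat"), n = NULL) {
  view <- match.arg(view)
  contours <- if (view == "ap") case@contoursAP else case@contoursLat
  facets <- case@truthFacets[[view]]
  shapes <- list()
  for (bone in names(contours)) {
    pts <- coords(contours[[bone]])
    if (is.null(n)) {
      shapes[[bone]] <- LandmarkedShape(bone, pts, facets[[bone]])
    } else {
      lm <- resampleArclength(pts, n, closed = TRUE)
      shapes[[bone]] <- LandmarkedShape(
        bone, lm, .mapFacetsToResampled(pts, facets[[bone]], n))
    }
  }
  shapes
}

#' Train bone and arc shape models from a synthetic cohort
#'
#' Builds one PDM per bone and view from the non-interrupted cases'
#' ground-truth contours. The arc PDMs are then trained on arcs produced
#' by the same measurement chain used at analysis time (mask -> contour ->
#' PDM fit -> arc construction) so that the per-landmark residual scales
#' encode the realistic per-point noise of the pipeline and the arc
#' z-scores are calibrated; cases without rasterized masks fall back to
#' fitting their exact contours. Deterministic given the cohort.
#'
#' @param cohort list of [SyntheticCase-class] (from [generateCohort()]);
#'   interrupted cases are excluded from training.
#' @param varianceTarget PCA variance target (default 0.95).
#' @param nLandmarks landmarks per bone model (default 64).
#' @param residualFloorMm residual-scale floor (mm).
#' @param arcSource "fitted" (default) trains arc models through the
#'   measurement chain as described; "truth" uses the exact ground-truth
#'   arcs (residual scales then reflect only anatomy, not measurement
#'   noise).
#' @return List with `bonesAP`, `bonesLat`, `arcs` (model lists) and
#'   `manifest` (training sizes and retained variances).
#' @export
trainModels <- function(cohort, varianceTarget = 0.95, nLandmarks = 64,
                        residualFloorMm = 0.05,
                        arcSource = c("fitted", "truth")) {
  arcSource <- match.arg(arcSource)
  normals <- Filter(function(cs) !cs@truth$interrupted, cohort)
  if (length(normals) < 3)
    stop(sprintf("insufficient normal cases for training (%d < 3)",
                 length(normals)))
  trainView <- function(view, boneNames) {
    models <- list()
    for (bone in boneNames) {
      shapesAll <- lapply(normals, function(cs) {
        contours <- if (view == "ap") cs@contoursAP else cs@contoursLat
        resampleArclength(coords(contours[[bone]]), nLandmarks,
                          closed = TRUE)
      })
      pts1 <- coords((if (view == "ap") normals[[1]]@contoursAP
                      else normals[[1]]@contoursLat)[[bone]])
      facets <- .mapFacetsToResampled(
        pts1, normals[[1]]@truthFacets[[view]][[bone]], nLandmarks)
      models[[bone]] <- buildPDM(shapesAll, varianceTarget = varianceTarget,
                                 facets = facets,
                                 residualFloorMm = residualFloorMm,
                                 closed = TRUE,
                                 name = paste(view, bone, sep = "_"))
    }
    models
  }
  bonesAP <- trainView("ap", carpalBones())
  bonesLat <- trainView("lat", .latBones)
  arcSets <- lapply(normals, function(cs) {
    if (arcSource == "truth")
      return(buildArcs(truthLandmarks(cs, "ap", nLandmarks)))
    contours <- if (nrow(cs@maskAP) > 0)
      .contoursFromMasks(.splitLabelImage(cs@maskAP), cs@spacingMmPerPx)
    else cs@contoursAP
    buildArcs(.fitView(contours, bonesAP))
  })
  arcModels <- trainArcPDM(arcSets, varianceTarget = varianceTarget,
                           residualFloorMm = residualFloorMm)
  manifest <- list(
    nTraining = length(normals), nLandmarks = nLandmarks,
    varianceTarget = varianceTarget,
    retainedVariance = c(
      lapply(bonesAP, function(mm) mm@retainedVariance),
      lapply(arcModels, function(mm) mm@retainedVariance)))
  list(bonesAP = bonesAP, bonesLat = bonesLat, arcs = arcModels,
       manifest = manifest)
}

#' Write / read a trained model set
#'
#' One JSON shape-model file per bone and arc plus a manifest, under
#' `dir`.
#'
#' @param models model set from [trainModels()].
#' @param dir directory (created if needed).
#' @return `writeModels`: invisibly `dir`; `readModels`: the model set.
#' @export
writeModels <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (grp in c("bonesAP", "bonesLat", "arcs"))
    for (nm in names(models[[grp]]))
      writeShapeModel(models[[grp]][[nm]],
                      file.path(dir, sprintf("%s_%s.json", grp, nm)))
  jsonlite::write_json(models$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeModels
#' @export
readModels <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  readGrp <- function(grp, nms) {
    out <- lapply(nms, function(nm) {
      path <- file.path(dir, sprintf("%s_%s.json", grp, nm))
      if (!file.exists(path)) stop(sprintf("model file missing: %s", path))
      readShapeModel(path)
    })
    stats::setNames(out, nms)
  }
  list(bonesAP = readGrp("bonesAP", carpalBones()),
       bonesLat = readGrp("bonesLat", .latBones),
       arcs = readGrp("arcs", c("proximal", "middle", "distal")),
       manifest = manifest)
}

## Fit all bones of one view. Returns named list of LandmarkedShape (bones
## whose mask/contour is missing are absent).
.fitView <- function(contours, boneModels) {
  shapes <- list()
  for (bone in names(boneModels)) {
    ct <- contours[[bone]]
    if (is.null(ct)) next
    shapes[[bone]] <- fitToContour(boneModels[[bone]], ct)$shape
  }
  shapes
}

## Contours from per-bone binary masks.
.contoursFromMasks <- function(masks, spacing) {
  out <- list()
  for (bone in names(masks))
    out[[bone]] <- extractContour(masks[[bone]], spacing, bone)
  out
}

#' Analyze one study
#'
#' Full measurement pass over the available views of one study: extract
#' contours from the label masks, fit the bone PDMs, compute SL distance
#' (AP/PA) and SL/CL angles (lateral), classify them, and assess the
#' carpal arcs (neutral AP/PA). Missing views or bones yield explicit
#' "unavailable" report fields, never silent omissions.
#'
#' @param apMaskPath,latMaskPath paths to the view label masks (PNG/TIFF,
#'   JSON sidecars alongside); either may be NULL.
#' @param models model set from [trainModels()] or [readModels()].
#' @param config a [ThresholdConfig-class].
#' @param case alternatively, a [SyntheticCase-class] analyzed in memory
#'   (masks if rasterized, otherwise its contours), with `ageYears`
#'   metadata.
#' @param ageYears age used when analyzing an in-memory case.
#' @return Report list (see [writeReport()] for the schema) with an
#'   `assessment` attribute carrying the [ArcAssessment-class] when arcs
#'   were computed.
#' @export
runStudy <- function(apMaskPath = NULL, latMaskPath = NULL, models,
                     config = defaultThresholds(), case = NULL,
                     ageYears = 40) {
  unavailable <- "unavailable"
  report <- list(study_id = "", sl_distance_mm = unavailable,
                 sl_angle_deg = unavailable, cl_angle_deg = unavailable,
                 arcs = unavailable, zscores = unavailable,
                 disruption_score = unavailable, detections = list(),
                 thresholds_used = .thresholdEcho(config))
  apContours <- latContours <- NULL
  apMeta <- latMeta <- NULL
  if (!is.null(case)) {
    sp <- case@spacingMmPerPx
    apContours <- if (nrow(case@maskAP) > 0)
      .contoursFromMasks(.splitLabelImage(case@maskAP), sp) else
      case@contoursAP
    latContours <- if (nrow(case@maskLat) > 0)
      .contoursFromMasks(.splitLabelImage(case@maskLat), sp) else
      case@contoursLat
    apMeta <- StudyMeta(max(case@spacingMmPerPx, 1e-6),
                        "neutral_ap_pa", ageYears, "in_memory")
    latMeta <- StudyMeta(max(case@spacingMmPerPx, 1e-6), "lateral",
                         ageYears, "in_memory")
  } else {
    if (is.null(apMaskPath) && is.null(latMaskPath))
      stop("no usable view: provide at least one mask path or a case")
    if (!is.null(apMaskPath)) {
      rd <- readLabelMask(apMaskPath)
      apMeta <- rd$meta
      apContours <- .contoursFromMasks(rd$masks, rd$meta@spacingMmPerPx)
      report$study_id <- rd$meta@studyId
    }
    if (!is.null(latMaskPath)) {
      rd <- readLabelMask(latMaskPath)
      latMeta <- rd$meta
      latContours <- .contoursFromMasks(rd$masks, rd$meta@spacingMmPerPx)
      if (report$study_id == "") report$study_id <- rd$meta@studyId
    }
  }

  assessment <- NULL
  if (!is.null(apContours)) {
    shapes <- .fitView(apContours, models$bonesAP)
    if (!is.null(shapes$scaphoid) && !is.null(shapes$lunate)) {
      v <- slDistance(shapes$scaphoid, shapes$lunate)
      cls <- classifyMeasurement("sl_distance", v, apMeta@view,
                                 apMeta@ageYears, config)
      report$sl_distance_mm <- v
      report$detections$sl_distance_abnormal <- cls$abnormal
      report$detections$sl_distance_rule <- cls$thresholdRule
    }
    if (apMeta@view == "neutral_ap_pa" &&
        all(c("scaphoid", "lunate", "triquetrum", "capitate", "hamate")
            %in% names(shapes))) {
      observed <- buildArcs(shapes, apMeta@view)
      assessment <- assessArcs(observed, models$arcs, zCrit = config@zCrit,
                               threshold = config@arcDetectionThreshold)
      report$arcs <- lapply(coords(observed), function(a)
        if (is.null(a)) "unavailable" else unname(a))
      report$zscores <- lapply(arcZ(assessment), function(z)
        if (is.null(z)) "unavailable" else unname(z))
      report$disruption_score <- arcScore(assessment)
      report$detections$arc_interruption <- isDetected(assessment)
    }
  }
  if (!is.null(latContours)) {
    shapes <- .fitView(latContours, models$bonesLat)
    haveLun <- !is.null(shapes$lunate)
    if (haveLun && !is.null(shapes$scaphoid)) {
      v <- angleBetween(scaphoidAxis(shapes$scaphoid),
                        lunateAxis(shapes$lunate))
      cls <- classifyMeasurement("sl_angle", v, "lateral",
                                 latMeta@ageYears, config)
      report$sl_angle_deg <- v
      report$detections$sl_angle_abnormal <- cls$abnormal
    }
    if (haveLun && !is.null(shapes$capitate)) {
      v <- angleBetween(capitateAxis(shapes$capitate),
                        lunateAxis(shapes$lunate))
      cls <- classifyMeasurement("cl_angle", v, "lateral",
                                 latMeta@ageYears, config)
      report$cl_angle_deg <- v
      report$detections$cl_angle_abnormal <- cls$abnormal
    }
  }
  attr(report, "assessment") <- assessment
  report
}

.splitLabelImage <- function(img, labelTable = boneLabelTable()) {
  masks <- list()
  for (bone in names(labelTable)) {
    m <- (img == labelTable[[bone]]) * 1L
    if (any(m > 0)) masks[[bone]] <- m
  }
  masks
}

.thresholdEcho <- function(config) {
  list(sl_distance_neutral_mm = config@slDistanceNeutralMm,
       sl_distance_ulnar_mm = config@slDistanceUlnarMm,
       sl_angle_range_deg = config@slAngleRangeDeg,
       cl_angle_max_deg = config@clAngleMaxDeg,
       arc_detection_threshold = config@arcDetectionThreshold,
       z_crit = config@zCrit,
       pediatric_table_rows = nrow(config@pediatricTable),
       assumptions = "clenched-fist AP/PA classified with the neutral 3.0 mm threshold")
}

#' Evaluate pipeline predictions against cohort ground truth
#'
#' Runs the full evaluation stack on a cohort of analyzed cases:
#' measurement agreement (MAE, bias, limits of agreement; stratified
#' bootstrap CIs with 1 mm / 10 degree strata), mean Frechet distance of
#' the predicted vs ground-truth arcs, and arc-interruption detection
#' (sensitivity and specificity at the configured threshold, AUC, Youden
#' operating point).
#'
#' @param reports list of reports from [runStudy()].
#' @param cases the matching list of [SyntheticCase-class] objects.
#' @param config a [ThresholdConfig-class].
#' @param iters bootstrap iterations for CIs.
#' @param seed bootstrap seed.
#' @param ci compute CIs.
#' @return Nested list: slDistance, slAngle, clAngle (agreement reports),
#'   arcs (MFD per arc), detection (sens/spec/auc).
#' @export
evaluateCohort <- function(reports, cases, config = defaultThresholds(),
                           iters = 1000, seed = 1L, ci = TRUE) {
  stopifnot(length(reports) == length(cases))
  num <- function(field) vapply(reports, function(r)
    if (is.numeric(r[[field]])) r[[field]] else NA_real_, numeric(1))
  truthOf <- function(field) vapply(cases, function(cs)
    cs@truth[[field]], numeric(1))
  out <- list()
  pair <- function(pred, truth, width) {
    ok <- !is.na(pred)
    measurementAgreement(pred[ok], truth[ok], strataWidth = width,
                         iters = iters, seed = seed, ci = ci)
  }
  out$slDistance <- pair(num("sl_distance_mm"), truthOf("slDistanceMm"), 1)
  out$slAngle <- pair(num("sl_angle_deg"), truthOf("slAngleDeg"), 10)
  out$clAngle <- pair(num("cl_angle_deg"), truthOf("clAngleDeg"), 10)

  out$arcs <- list()
  for (nm in c("proximal", "middle", "distal")) {
    predArcs <- lapply(reports, function(r)
      if (is.list(r$arcs) && is.numeric(r$arcs[[nm]])) r$arcs[[nm]] else
        if (is.list(r$arcs) && is.matrix(r$arcs[[nm]])) r$arcs[[nm]] else NULL)
    truthArcs <- lapply(cases, function(cs)
      coords(buildArcs(truthLandmarks(cs, "ap")))[[nm]])
    ok <- !vapply(predArcs, is.null, logical(1))
    if (sum(ok) >= 1)
      out$arcs[[nm]] <- meanFrechet(predArcs[ok], truthArcs[ok],
                                    iters = iters, seed = seed, ci = ci)
  }

  scores <- num("disruption_score")
  labels <- vapply(cases, function(cs) cs@truth$interrupted, logical(1))
  ok <- !is.na(scores)
  if (sum(labels[ok]) > 0 && sum(!labels[ok]) > 0) {
    roc <- rocAnalysis(scores[ok], labels[ok], iters = iters, seed = seed,
                       ci = ci)
    thr <- config@arcDetectionThreshold
    roc$sensitivityAtThreshold <- mean(scores[ok][labels[ok]] >= thr)
    roc$specificityAtThreshold <- mean(scores[ok][!labels[ok]] < thr)
    roc$threshold <- thr
    out$detection <- roc
  }
  out
}
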