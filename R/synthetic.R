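## Parametric synthetic wrist generator: AP/PA and lateral bone contours
## with exact ground-truth SL gap, SL/CL angles and arc-interruption state.

#' Generator step threshold for arc interruption
#'
#' A proximal subluxation larger than this (mm) produces a step-off in the
#' carpal arcs and is labelled interrupted; pure joint-space widening (gap
#' only, no proximal shift) is generated as a non-interrupted case.
#'
#' @return Threshold in mm (1.0).
#' @export
interruptionStepThreshold <- function() 1.0

#' Construct WristParams
#'
#' @param slGapMm scapholunate gap in mm (>= 0; the ground-truth SL
#'   distance).
#' @param slAngleDeg scapholunate angle in degrees (0..120).
#' @param clAngleDeg capitolunate angle in degrees (-30..90).
#' @param subluxationMm proximal translation of `subluxBone` in mm; values
#'   above [interruptionStepThreshold()] make the case interrupted.
#' @param subluxBone which bone subluxates, "capitate" (default) or
#'   "lunate".
#' @param globalScale global anatomy scale (> 0).
#' @param rotationDeg global in-plane rotation of the wrist.
#' @param noiseSdMm SD of smoothed per-vertex contour jitter (mm).
#' @param seed integer seed controlling the jitter.
#' @return A [WristParams-class] object.
#' @examples
#' wristParams(slGapMm = 2, slAngleDeg = 45)
#' @export
wristParams <- function(slGapMm = 2, slAngleDeg = 47, clAngleDeg = 5,
                        subluxationMm = 0, subluxBone = "capitate",
                        globalScale = 1, rotationDeg = 0, noiseSdMm = 0,
                        seed = 1L) {
  methods::new("WristParams", slGapMm = slGapMm, slAngleDeg = slAngleDeg,
               clAngleDeg = clAngleDeg, subluxationMm = subluxationMm,
               subluxBone = subluxBone,
               interrupted = subluxationMm > interruptionStepThreshold(),
               globalScale = globalScale, rotationDeg = rotationDeg,
               noiseSdMm = noiseSdMm, seed = as.integer(seed))
}

## Evaluate expr with a local, restored RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

## Smoothed circular jitter: white Gaussian noise moving-averaged over a
## 7-vertex window, rescaled so the marginal SD equals `sd`.
.smoothJitter <- function(n, sd) {
  if (sd == 0) return(matrix(0, n, 2))
  k <- 7
  e <- matrix(stats::rnorm(n * 2, sd = sd * sqrt(k)), n, 2)
  idx <- outer(seq_len(n), -3:3, function(i, j) ((i + j - 1) %% n) + 1)
  apply(e, 2, function(col) rowMeans(matrix(col[idx], n, k)))
}

.vertexCentroid <- function(pts) colMeans(pts)

#' Generate one synthetic wrist case
#'
#' Builds AP/PA and lateral bone contours from the package templates so
#' that analytic measurement of the geometry returns the parameters
#' exactly: the SL facet walls of scaphoid and lunate are parallel segments
#' separated by `slGapMm`, the lateral scaphoid and capitate are rotated so
#' the enclosed SL and CL angles equal the requested values, and an
#' interruption is a proximal translation of the capitate (or lunate) by
#' `subluxationMm`. Deterministic for a fixed seed.
#'
#' @param params a [WristParams-class] (see [wristParams()]).
#' @param spacingMmPerPx pixel spacing for the rasterized label masks.
#' @param rasterize if FALSE, skip mask rasterization (contours and truth
#'   only; much faster for analytic tests).
#' @param views which views to rasterize ("both", "ap" or "lat"); arcs and
#'   the SL distance only need the AP view, the angles only the lateral.
#' @return A [SyntheticCase-class].
#' @examples
#' case <- generateCase(wristParams(slGapMm = 2.5, seed = 7),
#'                      spacingMmPerPx = 0.3)
#' caseTruth(case)$slDistanceMm
#' @export
generateCase <- function(params, spacingMmPerPx = 0.2, rasterize = TRUE,
                         views = c("both", "ap", "lat")) {
  views <- match.arg(views)
  stopifnot(spacingMmPerPx > 0)
  methods::validObject(params)
  tpl <- wristTemplates()
  s <- params@globalScale

  ## --- AP/PA view ---------------------------------------------------
  ap <- lapply(tpl$ap, function(b)
    similarityTransform(b$pts, scale = s, center = tpl$scaleCenterAP))
  gapShift <- c(params@slGapMm - tpl$gapDefaultMm * s, 0)
  for (bone in c("lunate", "triquetrum"))
    ap[[bone]] <- sweep(ap[[bone]], 2, gapShift, "+")
  if (params@subluxationMm > 0)
    ap[[params@subluxBone]] <- sweep(ap[[params@subluxBone]], 2,
                                     c(0, params@subluxationMm), "+")
  ap <- lapply(ap, function(p)
    similarityTransform(p, deg = params@rotationDeg,
                        center = tpl$scaleCenterAP))

  ## --- lateral view -------------------------------------------------
  lat <- lapply(tpl$lat, function(b)
    similarityTransform(b$pts, scale = s, center = tpl$scaleCenterLat))
  scaCtr <- .vertexCentroid(lat$scaphoid)
  lat$scaphoid <- similarityTransform(lat$scaphoid, deg = params@slAngleDeg,
                                      center = scaCtr)
  pivot <- tpl$scaleCenterLat + s * (tpl$capitateLatPivot - tpl$scaleCenterLat)
  lat$capitate <- similarityTransform(lat$capitate, deg = params@clAngleDeg,
                                      center = pivot)
  lat <- lapply(lat, function(p)
    similarityTransform(p, deg = params@rotationDeg,
                        center = tpl$scaleCenterLat))

  ## --- contour jitter (seeded, smooth) ------------------------------
  if (params@noiseSdMm > 0) {
    withSeed(params@seed, {
      for (bone in names(ap))
        ap[[bone]] <- ap[[bone]] + .smoothJitter(nrow(ap[[bone]]),
                                                 params@noiseSdMm)
      for (bone in names(lat))
        lat[[bone]] <- lat[[bone]] + .smoothJitter(nrow(lat[[bone]]),
                                                   params@noiseSdMm)
    })
  }

  .checkNoOverlap(ap, "AP/PA")
  .checkNoOverlap(lat, "lateral")

  contoursAP <- mapply(function(p, nm) Contour(nm, p), ap, names(ap))
  contoursLat <- mapply(function(p, nm) Contour(nm, p), lat, names(lat))

  maskAP <- maskLat <- matrix(integer(0), 0, 0)
  if (rasterize) {
    size <- rev(round(tpl$canvasMm / spacingMmPerPx))  # rows, cols
    if (views != "lat")
      maskAP <- rasterizeContours(contoursAP, spacingMmPerPx, size)
    if (views != "ap")
      maskLat <- rasterizeContours(contoursLat, spacingMmPerPx, size)
  }

  truth <- list(slDistanceMm = params@slGapMm,
                slAngleDeg = params@slAngleDeg,
                clAngleDeg = abs(params@clAngleDeg),
                interrupted = params@interrupted,
                subluxationMm = params@subluxationMm,
                subluxBone = params@subluxBone)
  truthFacets <- list(
    ap = lapply(tpl$ap, function(b) b$facets),
    lat = lapply(tpl$lat, function(b) b$facets))

  methods::new("SyntheticCase", params = params, contoursAP = contoursAP,
               contoursLat = contoursLat, maskAP = maskAP, maskLat = maskLat,
               spacingMmPerPx = spacingMmPerPx, truth = truth,
               truthFacets = truthFacets)
}

.checkNoOverlap <- function(polys, view) {
  nms <- names(polys)
  for (i in seq_along(polys)) for (j in seq_len(i - 1L)) {
    if (polygonsOverlap(polys[[i]], polys[[j]]))
      stop(sprintf(
        "infeasible geometry: %s and %s overlap on the %s view",
        nms[i], nms[j], view))
  }
}

#' Generate a reproducible synthetic cohort
#'
#' Samples case parameters from the generator's study conditions: global
#' scale U(0.9, 1.1), rotation U(-10, 10) degrees, SL angle U(35, 55), CL
#' angle U(0, 25); normal cases have zero subluxation with SL gap
#' U(1.5, 2.5), a `widenedFrac` fraction of them widened to U(3.5, 4.5)
#' (lengthened-but-aligned, still normal); interrupted cases combine a
#' widened gap U(3, 5) with a proximal capitate subluxation of
#' `subluxationMm`.
#'
#' @param n number of cases (> 0).
#' @param interruptedFrac fraction of interrupted cases.
#' @param widenedFrac fraction of the normal cases that are widened-only.
#' @param subluxationMm subluxation applied to interrupted cases (mm).
#' @param noiseSdMm contour jitter SD passed to every case.
#' @param seed cohort seed; case i uses seed + i for its jitter.
#' @param spacingMmPerPx pixel spacing for rasterization.
#' @param rasterize,views passed to [generateCase()].
#' @param paramSampler optional function(i) returning a
#'   [WristParams-class], overriding the built-in sampling.
#' @return List of [SyntheticCase-class] objects with attributes
#'   `interruptedFrac` (realized fraction) and `widenedOnly` (logical
#'   vector).
#' @examples
#' cohort <- generateCohort(5, seed = 3, rasterize = FALSE)
#' attr(cohort, "interruptedFrac")
#' @export
generateCohort <- function(n, interruptedFrac = 0, widenedFrac = 0.2,
                           subluxationMm = 3, noiseSdMm = 0, seed = 1L,
                           spacingMmPerPx = 0.2, rasterize = TRUE,
                           views = "both", paramSampler = NULL) {
  stopifnot(n > 0)
  if (!is.null(paramSampler)) {
    cases <- lapply(seq_len(n), function(i)
      generateCase(paramSampler(i), spacingMmPerPx, rasterize, views))
    attr(cases, "interruptedFrac") <-
      mean(vapply(cases, function(cs) cs@truth$interrupted, logical(1)))
    return(cases)
  }
  plan <- withSeed(seed, {
    nInt <- round(n * interruptedFrac)
    interrupted <- seq_len(n) %in% sample.int(n, nInt)
    normIdx <- which(!interrupted)
    widened <- logical(n)
    if (length(normIdx) > 0) {
      nW <- round(length(normIdx) * widenedFrac)
      widened[sample(normIdx, nW)] <- TRUE
    }
    gap <- ifelse(interrupted, stats::runif(n, 3, 5),
                  ifelse(widened, stats::runif(n, 3.5, 4.5),
                         stats::runif(n, 1.5, 2.5)))
    list(interrupted = interrupted, widened = widened, gap = gap,
         sl = stats::runif(n, 35, 55), cl = stats::runif(n, 0, 25),
         scale = stats::runif(n, 0.9, 1.1), rot = stats::runif(n, -10, 10))
  })
  cases <- lapply(seq_len(n), function(i) {
    p <- wristParams(
      slGapMm = plan$gap[i], slAngleDeg = plan$sl[i], clAngleDeg = plan$cl[i],
      subluxationMm = if (plan$interrupted[i]) subluxationMm else 0,
      globalScale = plan$scale[i], rotationDeg = plan$rot[i],
      noiseSdMm = noiseSdMm, seed = seed + i)
    generateCase(p, spacingMmPerPx, rasterize, views)
  })
  attr(cases, "interruptedFrac") <- mean(plan$interrupted)
  attr(cases, "widenedOnly") <- plan$widened
  cases
}

#' Rasterize bone contours into a label image
#'
#' Pixel centers lie at (col-1, row-1) * spacing (origin at the top-left
#' pixel center, 0-based); a pixel belongs to a bone iff its center falls
#' inside the bone polygon (even-odd rule). Labels follow
#' [boneLabelTable()]; background is 0.
#'
#' @param contours named list of [Contour-class] objects (or n x 2
#'   matrices) keyed by bone name.
#' @param spacingMmPerPx pixel spacing (mm/px, > 0).
#' @param imageSizePx integer c(rows, cols).
#' @return Integer label matrix (rows x cols).
#' @examples
#' sq <- Contour("lunate", cbind(c(1, 4, 4, 1), c(1, 1, 4, 4)))
#' m <- rasterizeContours(list(lunate = sq), 0.5, c(12, 12))
#' table(m)
#' @export
rasterizeContours <- function(contours, spacingMmPerPx, imageSizePx) {
  stopifnot(spacingMmPerPx > 0, length(imageSizePx) == 2)
  rows <- as.integer(imageSizePx[1]); cols <- as.integer(imageSizePx[2])
  img <- matrix(0L, rows, cols)
  if (length(contours) == 0) return(img)
  labels <- boneLabelTable()
  xmax <- (cols - 1) * spacingMmPerPx; ymax <- (rows - 1) * spacingMmPerPx
  for (bone in names(contours)) {
    pts <- if (methods::is(contours[[bone]], "Contour"))
      coords(contours[[bone]]) else as.matrix(contours[[bone]])
    if (any(pts[, 1] < -spacingMmPerPx / 2) ||
        any(pts[, 2] < -spacingMmPerPx / 2) ||
        any(pts[, 1] > xmax + spacingMmPerPx / 2) ||
        any(pts[, 2] > ymax + spacingMmPerPx / 2))
      stop(sprintf("contour of %s falls outside the canvas", bone))
    ci <- floor(min(pts[, 1]) / spacingMmPerPx):ceiling(max(pts[, 1]) / spacingMmPerPx)
    ri <- floor(min(pts[, 2]) / spacingMmPerPx):ceiling(max(pts[, 2]) / spacingMmPerPx)
    ci <- ci[ci >= 0 & ci < cols]; ri <- ri[ri >= 0 & ri < rows]
    if (!length(ci) || !length(ri)) next
    grid <- cbind(rep(ci, each = length(ri)) * spacingMmPerPx,
                  rep(ri, times = length(ci)) * spacingMmPerPx)
    inside <- pointsInPolygon(pts, grid)
    if (any(inside)) {
      rr <- rep(ri, times = length(ci)) + 1L
      cc <- rep(ci, each = length(ri)) + 1L
      img[cbind(rr[inside], cc[inside])] <- labels[[bone]]
    }
  }
  img
}

#' Write a synthetic case to disk
#'
#' Writes PNG label masks with JSON sidecars (spacing, view, age, ground
#' truth) plus a contour JSON, the on-disk study layout [runStudy()] reads.
#'
#' @param case a [SyntheticCase-class] with rasterized masks.
#' @param dir output directory (created if needed).
#' @param id study identifier used as the file stem.
#' @param ageYears age recorded in the sidecars.
#' @return Invisibly, the paths written.
#' @export
writeSyntheticCase <- function(case, dir, id = "case", ageYears = 40) {
  stopifnot(nrow(case@maskAP) > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ap = file.path(dir, paste0(id, "_ap.png")),
             lat = file.path(dir, paste0(id, "_lat.png")),
             contours = file.path(dir, paste0(id, "_contours.json")))
  png::writePNG(case@maskAP / 255, paths[["ap"]])
  png::writePNG(case@maskLat / 255, paths[["lat"]])
  sidecar <- function(view) list(
    format_version = "1.0", spacing_mm_per_px = case@spacingMmPerPx,
    view = view, age_years = ageYears, study_id = id,
    truth = case@truth)
  jsonlite::write_json(sidecar("neutral_ap_pa"),
                       sub("\\.png$", ".json", paths[["ap"]]),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(sidecar("lateral"),
                       sub("\\.png$", ".json", paths[["lat"]]),
                       auto_unbox = TRUE, digits = NA)
  enc <- function(ct) unname(apply(coords(ct), 1,
                                   function(p) unname(as.list(p)),
                                   simplify = FALSE))
  p <- case@params
  conts <- list(
    format_version = "1.0",
    ap = lapply(case@contoursAP, enc),
    lat = lapply(case@contoursLat, enc),
    facets = case@truthFacets,
    params = list(slGapMm = p@slGapMm, slAngleDeg = p@slAngleDeg,
                  clAngleDeg = p@clAngleDeg,
                  subluxationMm = p@subluxationMm,
                  subluxBone = p@subluxBone, globalScale = p@globalScale,
                  rotationDeg = p@rotationDeg, noiseSdMm = p@noiseSdMm,
                  seed = p@seed))
  jsonlite::write_json(conts, paths[["contours"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read a synthetic case back from its study files
#'
#' Inverse of [writeSyntheticCase()]: rebuilds a [SyntheticCase-class]
#' from the label masks, sidecars and contour JSON, including the ground
#' truth and facet ranges needed for model training.
#'
#' @param dir study directory.
#' @param id file stem used at write time.
#' @return A [SyntheticCase-class].
#' @export
readSyntheticCase <- function(dir, id) {
  cpath <- file.path(dir, paste0(id, "_contours.json"))
  if (!file.exists(cpath)) stop(sprintf("contour file missing: %s", cpath))
  raw <- jsonlite::read_json(cpath, simplifyVector = TRUE)
  dec <- function(v) mapply(function(b, nm) {
    pts <- if (is.matrix(b)) b else matrix(unlist(b), ncol = 2,
                                           byrow = TRUE)
    Contour(nm, pts)
  }, v, names(v))
  pr <- raw$params
  params <- wristParams(slGapMm = pr$slGapMm, slAngleDeg = pr$slAngleDeg,
                        clAngleDeg = pr$clAngleDeg,
                        subluxationMm = pr$subluxationMm,
                        subluxBone = pr$subluxBone,
                        globalScale = pr$globalScale,
                        rotationDeg = pr$rotationDeg,
                        noiseSdMm = pr$noiseSdMm, seed = pr$seed)
  ap <- readLabelMask(file.path(dir, paste0(id, "_ap.png")))
  lab <- boneLabelTable()
  maskAP <- matrix(0L, nrow(ap$masks[[1]]), ncol(ap$masks[[1]]))
  for (bone in names(ap$masks))
    maskAP[ap$masks[[bone]] > 0] <- lab[[bone]]
  latPath <- file.path(dir, paste0(id, "_lat.png"))
  maskLat <- matrix(integer(0), 0, 0)
  if (file.exists(latPath)) {
    lt <- readLabelMask(latPath)
    maskLat <- matrix(0L, nrow(lt$masks[[1]]), ncol(lt$masks[[1]]))
    for (bone in names(lt$masks))
      maskLat[lt$masks[[bone]] > 0] <- lab[[bone]]
  }
  facets <- lapply(raw$facets, function(v)
    lapply(v, function(b) lapply(b, as.integer)))
  methods::new("SyntheticCase", params = params, contoursAP = dec(raw$ap),
               contoursLat = dec(raw$lat), maskAP = maskAP,
               maskLat = maskLat,
               spacingMmPerPx = ap$meta@spacingMmPerPx,
               truth = list(slDistanceMm = params@slGapMm,
                            slAngleDeg = params@slAngleDeg,
                            clAngleDeg = abs(params@clAngleDeg),
                            interrupted = params@interrupted,
                            subluxationMm = params@subluxationMm,
                            subluxBone = params@subluxBone),
               truthFacets = facets)
}
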