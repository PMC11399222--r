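## Gilula's carpal arcs: construction from fitted bone shapes,
## PDM reconstruction of the hypothetical non-interrupted shape, per-point
## z-scores and displacement vectors, disruption score and detection.

.arcRecipe <- list(
  proximal = list(bones = c("scaphoid", "lunate", "triquetrum"),
                  facet = "proximal_surface"),
  middle = list(bones = c("scaphoid", "lunate", "triquetrum"),
                facet = "distal_surface"),
  distal = list(bones = c("capitate", "hamate"),
                facet = "proximal_surface"))

#' Build Gilula's three carpal arcs
#'
#' Arc I (proximal) concatenates the proximal articular surfaces of
#' scaphoid, lunate and triquetrum; arc II (middle) their distal surfaces;
#' arc III (distal) the proximal surfaces of capitate and hamate. Each
#' concatenation is resampled to 100 arc-length-uniform points running
#' radial to ulnar (the radial end is the most radial point; ties take the
#' smaller x). Arcs whose bones are missing are returned unavailable
#' (NULL), not fatal.
#'
#' @param shapes named list of [LandmarkedShape-class] objects keyed by
#'   bone.
#' @param view must be "neutral_ap_pa": the arcs are defined on the
#'   neutral AP/PA view only.
#' @return An [ArcSet-class].
#' @export
buildArcs <- function(shapes, view = "neutral_ap_pa") {
  if (view != "neutral_ap_pa")
    stop("carpal arcs are defined on the neutral AP/PA view only")
  arcs <- lapply(.arcRecipe, function(rc) {
    segs <- list()
    for (bone in rc$bones) {
      sh <- shapes[[bone]]
      if (is.null(sh) || is.null(sh@facets[[rc$facet]])) return(NULL)
      r <- sh@facets[[rc$facet]]
      seg <- sh@landmarks[r[1]:r[2], , drop = FALSE]
      if (seg[1, 1] > seg[nrow(seg), 1])
        seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      segs[[bone]] <- seg
    }
    segs <- segs[order(vapply(segs, function(s) mean(s[, 1]), 0))]
    resampleArclength(do.call(rbind, segs), 100, closed = FALSE)
  })
  methods::new("ArcSet", arcs = arcs, view = view)
}

#' Train per-arc point distribution models
#'
#' One PDM per arc (100 landmarks, open polyline) from Procrustes-aligned
#' non-interrupted arcs. The training set should include widened-but-
#' aligned (lengthened) normal variants so that pure joint-space widening
#' stays inside the model subspace and scores low.
#'
#' @param arcSets list of [ArcSet-class] objects from normal cases.
#' @param varianceTarget PCA variance target (default 0.95).
#' @param residualFloorMm floor on the per-landmark residual scale (mm).
#' @return Named list (proximal, middle, distal) of [ShapeModel-class]
#'   objects.
#' @export
trainArcPDM <- function(arcSets, varianceTarget = 0.95,
                        residualFloorMm = 0.05) {
  if (length(arcSets) < 10)
    warning(sprintf(
      "arc PDM trained on %d cases; at least 10 non-interrupted cases are recommended",
      length(arcSets)))
  models <- list()
  for (nm in names(.arcRecipe)) {
    shapes <- lapply(arcSets, function(a) a@arcs[[nm]])
    shapes <- Filter(Negate(is.null), shapes)
    if (length(shapes) < 3)
      stop(sprintf("fewer than 3 usable training arcs for the %s arc", nm))
    models[[nm]] <- buildPDM(shapes, varianceTarget = varianceTarget,
                             residualFloorMm = residualFloorMm,
                             closed = FALSE, name = paste0("arc_", nm))
  }
  models
}

## Core arc reconstruction: align the observed arc to the model frame
## (fixed correspondence - arcs are ordered radial to ulnar), project onto
## the mode subspace with +/-3 sqrt(eigenvalue) clamping, and map back.
.reconstructArc <- function(obs, model, maxIter = 10) {
  z <- .toComplex(obs)
  recon <- .toComplex(model@meanShape)
  coeffs <- numeric(0)
  for (iter in seq_len(maxIter)) {
    pose <- .similarityTo(recon, z)
    w <- (z - pose$t) / pose$a
    pr <- .projectClamped(model, w)
    if (length(pr$coeffs) && length(coeffs) &&
        max(abs(pr$coeffs - coeffs)) < 1e-10) {
      recon <- pr$recon; coeffs <- pr$coeffs; break
    }
    recon <- pr$recon; coeffs <- pr$coeffs
  }
  pose <- .similarityTo(recon, z)
  w <- (z - pose$t) / pose$a
  list(reconImage = .fromComplex(pose$a * recon + pose$t),
       modelFrameObs = .fromComplex(w),
       reconModel = .fromComplex(recon),
       z = Mod(.toComplex(.fromComplex(w)) - recon) / model@residualSD,
       pose = pose, coeffs = coeffs)
}

#' Reconstruct the hypothetical non-interrupted arcs
#'
#' Each observed arc is similarity-aligned to its model frame, projected
#' onto the PDM mode subspace with coefficients clamped to +/-3 standard
#' deviations, and mapped back to the image frame: the closest "plausible
#' normal" arc. Deviations of the observation from this reconstruction
#' localize interruptions.
#'
#' @param observed an [ArcSet-class].
#' @param models per-arc models from [trainArcPDM()].
#' @return An [ArcSet-class] of reconstructed arcs (NULL where the
#'   observation is unavailable).
#' @export
reconstructNormal <- function(observed, models) {
  arcs <- lapply(names(.arcRecipe), function(nm) {
    a <- observed@arcs[[nm]]
    if (is.null(a) || is.null(models[[nm]])) return(NULL)
    .reconstructArc(a, models[[nm]])$reconImage
  })
  names(arcs) <- names(.arcRecipe)
  methods::new("ArcSet", arcs = arcs, view = observed@view)
}

#' Per-point arc z-scores
#'
#' z_i = ||observed_i - reconstructed_i|| / residual scale_i, computed in
#' the pose-normalized model frame so the score is invariant to global
#' similarity transforms of the arc set.
#'
#' @param observed,reconstructed [ArcSet-class] objects (the reconstruction
#'   is recomputed in the model frame; passing it documents the pairing).
#' @param models per-arc models from [trainArcPDM()].
#' @return Named list of length-100 non-negative z-score vectors (NULL for
#'   unavailable arcs).
#' @export
arcZscores <- function(observed, reconstructed, models) {
  zs <- lapply(names(.arcRecipe), function(nm) {
    a <- observed@arcs[[nm]]
    if (is.null(a) || is.null(models[[nm]])) return(NULL)
    .reconstructArc(a, models[[nm]])$z
  })
  names(zs) <- names(.arcRecipe)
  zs
}

#' Overall disruption score
#'
#' Fraction of all arc points whose z-score reaches `zCrit`: a percentage-
#' valued, localizable score that is monotone in every z value. With all
#' three arcs present the denominator is 300; 33 exceeding points give
#' 0.11, the operating threshold.
#'
#' @param zscores list of per-arc z-score vectors (or a numeric vector).
#' @param zCrit critical z (default 2).
#' @return Score between 0 and 1.
#' @examples
#' disruptionScore(list(rep(0, 100), rep(3, 33), rep(0, 67)))
#' @export
disruptionScore <- function(zscores, zCrit = 2) {
  z <- unlist(zscores, use.names = FALSE)
  if (!length(z)) return(0)
  mean(z >= zCrit)
}

#' Assess the carpal arcs of a study
#'
#' Runs reconstruction, z-scoring, disruption scoring and detection in one
#' pass.
#'
#' @param observed an [ArcSet-class].
#' @param models per-arc models from [trainArcPDM()].
#' @param zCrit critical z-score (default 2).
#' @param threshold operating threshold on the disruption score (default
#'   0.11).
#' @return An [ArcAssessment-class].
#' @export
assessArcs <- function(observed, models, zCrit = 2, threshold = 0.11) {
  recon <- displacement <- zs <- markers <- list()
  for (nm in names(.arcRecipe)) {
    a <- observed@arcs[[nm]]
    if (is.null(a) || is.null(models[[nm]])) {
      recon[nm] <- list(NULL); displacement[nm] <- list(NULL)
      zs[nm] <- list(NULL); markers[nm] <- list(NULL)
      next
    }
    rc <- .reconstructArc(a, models[[nm]])
    recon[[nm]] <- rc$reconImage
    displacement[[nm]] <- a - rc$reconImage
    zs[[nm]] <- rc$z
    markers[[nm]] <- .zRuns(rc$z, zCrit)
  }
  score <- disruptionScore(zs, zCrit)
  methods::new("ArcAssessment",
    observed = observed,
    reconstructed = methods::new("ArcSet", arcs = recon,
                                 view = observed@view),
    displacement = displacement, zscores = zs, score = score,
    detected = score >= threshold, threshold = threshold, zCrit = zCrit,
    markers = markers)
}

## Contiguous runs of indices with z >= zCrit, as a list of c(start, end).
.zRuns <- function(z, zCrit) {
  r <- rle(z >= zCrit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- Map(function(s, e) c(s, e), starts[r$values], ends[r$values])
  unname(out)
}

#' Detect an arc interruption
#'
#' Detection rule: disruption score at or above the operating threshold
#' (default the 11% operating point). Markers are the contiguous runs of
#' points with z >= zCrit, localizing the potential disruption.
#'
#' @param assessment an [ArcAssessment-class].
#' @param threshold operating threshold (defaults to the assessment's).
#' @param config optional [ThresholdConfig-class]; when given, its
#'   `arcDetectionThreshold` is used.
#' @return List with `detected`, `score` and `markers`.
#' @export
detectInterruption <- function(assessment, threshold = NULL, config = NULL) {
  if (!is.null(config)) threshold <- config@arcDetectionThreshold
  if (is.null(threshold)) threshold <- assessment@threshold
  list(detected = assessment@score >= threshold,
       score = assessment@score, markers = assessment@markers)
}

#' Render the arc heatmap overlay
#'
#' Color-codes the 100 points of each arc by z-score (cool to warm) over
#' the study image and draws the displacement vectors as small tails from
#' the reconstructed toward the observed positions. A vertical colorbar
#' strip at the right edge maps the color scale (z = 0 at the bottom to
#' `zMax` at the top). The output raster has the size of the input image.
#'
#' @param assessment an [ArcAssessment-class].
#' @param background label or grayscale image matrix (rows x cols).
#' @param spacingMmPerPx pixel spacing of the background.
#' @param path optional PNG output path.
#' @param zMax z-score mapped to the warmest color (default 6).
#' @return rows x cols x 3 RGB array with values in 0..1, invisibly when `path` is
#'   given.
#' @export
renderHeatmap <- function(assessment, background, spacingMmPerPx,
                          path = NULL, zMax = 6) {
  bg <- background / max(1, max(background))
  gray <- 0.15 + 0.45 * bg
  H <- nrow(bg); W <- ncol(bg)
  img <- array(rep(gray, 3), dim = c(H, W, 3))
  ramp <- grDevices::colorRamp(c("#20208c", "#2e8bc0", "#ffd700",
                                 "#ff2000"))
  zcol <- function(z) ramp(pmin(1, pmax(0, z / zMax)))[1, ] / 255
  setPx <- function(r, c, col) {
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    if (!any(ok)) return(invisible())
    for (ch in 1:3) img[cbind(r[ok], c[ok], ch)] <<- col[ch]
  }
  drawDisk <- function(r0, c0, rad, col) {
    dr <- rep(-rad:rad, times = 2 * rad + 1)
    dc <- rep(-rad:rad, each = 2 * rad + 1)
    keep <- dr^2 + dc^2 <= rad^2
    setPx(r0 + dr[keep], c0 + dc[keep], col)
  }
  drawLine <- function(p0, p1, col) {
    len <- max(abs(p1 - p0))
    if (len < 1) return(invisible())
    t <- seq(0, 1, length.out = max(2, ceiling(len) + 1))
    setPx(round(p0[1] + t * (p1[1] - p0[1])),
          round(p0[2] + t * (p1[2] - p0[2])), col)
  }
  toPx <- function(xy) c(round(xy[2] / spacingMmPerPx) + 1,
                         round(xy[1] / spacingMmPerPx) + 1)
  for (nm in names(assessment@zscores)) {
    z <- assessment@zscores[[nm]]
    if (is.null(z)) next
    obs <- assessment@observed@arcs[[nm]]
    rec <- assessment@reconstructed@arcs[[nm]]
    for (i in seq_along(z)) {
      col <- zcol(z[i])
      drawLine(toPx(rec[i, ]), toPx(obs[i, ]), col * 0.8)
      p <- toPx(obs[i, ])
      drawDisk(p[1], p[2], 2, col)
    }
  }
  ## colorbar legend strip (z = 0 bottom to zMax top)
  barCols <- max(1, W - 11):max(1, W - 4)
  for (r in seq_len(H)) {
    col <- zcol(zMax * (H - r) / (H - 1))
    for (ch in 1:3) img[r, barCols, ch] <- col[ch]
  }
  if (!is.null(path)) {
    png::writePNG(img, path)
    return(invisible(img))
  }
  img
}
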