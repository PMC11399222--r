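## Label-mask and contour IO. Pixels never leak past this module: every
## geometric quantity downstream is in millimetres.

.readMaskImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported mask format '%s' (PNG/TIFF only)", ext)))
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Read a study sidecar
#'
#' JSON sidecar carrying the calibration and context every measurement rule
#' depends on. A missing pixel spacing is fatal: measurements are in mm.
#'
#' @param path path to the sidecar JSON.
#' @return A [StudyMeta-class].
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop(sprintf("sidecar not found: %s", path))
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(sc$spacing_mm_per_px))
    stop(sprintf("sidecar %s lacks spacing_mm_per_px; measurements are in mm",
                 path))
  StudyMeta(spacingMmPerPx = as.numeric(sc$spacing_mm_per_px),
            view = if (is.null(sc$view)) "neutral_ap_pa" else sc$view,
            ageYears = if (is.null(sc$age_years)) 40 else
              as.numeric(sc$age_years),
            studyId = if (is.null(sc$study_id)) "" else sc$study_id)
}

#' Read a label mask with its sidecar
#'
#' Splits an integer label image into per-bone binary masks. Bones missing
#' from the image are reported, not fatal: measurements that need them are
#' flagged unavailable downstream.
#'
#' @param path path to a PNG/TIFF label image; the sidecar is looked up as
#'   the same path with a .json extension unless given.
#' @param labelTable named integer vector mapping bone names to labels
#'   (default [boneLabelTable()]).
#' @param sidecarPath optional explicit sidecar path.
#' @return List with `masks` (named list of 0/1 integer matrices), `meta`
#'   (a [StudyMeta-class]) and `missing` (character vector of absent
#'   bones).
#' @export
readLabelMask <- function(path, labelTable = boneLabelTable(),
                          sidecarPath = NULL) {
  if (!file.exists(path)) stop(sprintf("mask not found: %s", path))
  if (is.null(sidecarPath))
    sidecarPath <- sub("\\.(png|tif|tiff)$", ".json", path,
                       ignore.case = TRUE)
  meta <- readSidecar(sidecarPath)
  img <- .readMaskImage(path)
  masks <- list()
  missing <- character(0)
  for (bone in names(labelTable)) {
    m <- (img == labelTable[[bone]]) * 1L
    if (any(m > 0)) masks[[bone]] <- m else missing <- c(missing, bone)
  }
  list(masks = masks, meta = meta, missing = missing)
}

#' Extract a calibrated sub-pixel contour from a binary mask
#'
#' Boundary at the 0.5 iso-level of the binary image (marching-squares
#' style via [grDevices::contourLines]), in mm, counter-clockwise. The mask
#' must contain exactly one substantial connected foreground component;
#' speck components up to max(`speckPx` pixels, 0.5% of the foreground)
#' are discarded as rasterization/segmentation debris, but a
#' second substantial component signals a failed segmentation and raises
#' an error, mirroring a study-exclusion rule.
#'
#' @param mask 0/1 integer matrix (rows = y, cols = x).
#' @param spacingMmPerPx pixel spacing (mm/px).
#' @param bone bone name recorded on the contour.
#' @param speckPx maximum pixel count of a component discarded as a speck
#'   (default 9).
#' @return A [Contour-class] in mm.
#' @examples
#' m <- matrix(0L, 20, 20); m[5:15, 5:15] <- 1L
#' ct <- extractContour(m, 0.5, "lunate")
#' @export
extractContour <- function(mask, spacingMmPerPx, bone = "lunate",
                           speckPx = 9) {
  stopifnot(spacingMmPerPx > 0)
  npix <- sum(mask > 0)
  if (npix == 0) stop("empty mask: no foreground")
  if (npix < 4) stop("degenerate mask: fewer than 4 foreground pixels")
  ## crop to the foreground bounding box (coordinates mapped back below):
  ## the iso-contour and component labelling only need the local patch
  rr <- range(which(rowSums(mask > 0) > 0))
  cr <- range(which(colSums(mask > 0) > 0))
  sub <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  lab <- EBImage::bwlabel(sub > 0)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    main <- which.max(sizes)
    speckLimit <- max(speckPx, floor(0.005 * sum(sizes)))
    if (any(sizes[-main] > speckLimit))
      stop(sprintf(
        "mask has %d substantial connected components; expected one (failed segmentation?)",
        sum(sizes > speckLimit)))
    sub <- (lab == main) * 1L
  }
  ## pad with background so boundary loops close, then contour at 0.5;
  ## contourLines indexes z[i, j] against x[i], y[j], so pass the transpose
  ## with x = column centers, y = row centers (0-based centers, in mm)
  padded <- matrix(0L, nrow(sub) + 2, ncol(sub) + 2)
  padded[2:(nrow(sub) + 1), 2:(ncol(sub) + 1)] <- sub
  xs <- (seq_len(ncol(padded)) - 3 + cr[1]) * spacingMmPerPx
  ys <- (seq_len(nrow(padded)) - 3 + rr[1]) * spacingMmPerPx
  cl <- grDevices::contourLines(x = xs, y = ys, z = t(padded), levels = 0.5)
  if (!length(cl)) stop("no iso-contour found")
  lens <- vapply(cl, function(p) length(p$x), integer(1))
  loop <- cl[[which.max(lens)]]
  pts <- cbind(loop$x, loop$y)
  if (isTRUE(all.equal(pts[1, ], pts[nrow(pts), ])))
    pts <- pts[-nrow(pts), , drop = FALSE]
  keep <- c(TRUE, rowSums(diff(pts)^2) > 1e-20)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3) stop("degenerate contour")
  Contour(bone, pts)
}

#' Resample a polyline uniformly in arc length
#'
#' Produces n points equally spaced in cumulative arc length. For open
#' polylines the endpoints are preserved. For closed contours the n samples
#' divide the full perimeter, starting at the first vertex shifted by
#' `offset` sample spacings (fractional offsets supported; used by the
#' cyclic correspondence search).
#'
#' @param pts n x 2 matrix, or a [Contour-class] (treated as closed).
#' @param n number of output points (>= 2).
#' @param closed whether the polyline closes back to its first point.
#' @param offset start offset for closed contours, in units of the output
#'   sample spacing (may be fractional).
#' @return n x 2 matrix of resampled points.
#' @examples
#' resampleArclength(rbind(c(0, 0), c(1, 0)), 3)
#' @export
resampleArclength <- function(pts, n, closed = FALSE, offset = 0) {
  if (methods::is(pts, "Contour")) { closed <- TRUE; pts <- coords(pts) }
  pts <- as.matrix(pts)
  stopifnot(n >= 2)
  if (closed) pts <- rbind(pts, pts[1, ])
  tcum <- cumArcLength(pts)
  L <- tcum[length(tcum)]
  if (L <= 0) stop("zero-length polyline")
  ## drop zero-length steps so approx() sees strictly increasing abscissae
  keep <- c(TRUE, diff(tcum) > 0)
  tcum <- tcum[keep]; pts <- pts[keep, , drop = FALSE]
  tout <- if (closed) ((offset * L / n) + (seq_len(n) - 1) * L / n) %% L
          else seq(0, L, length.out = n)
  cbind(stats::approx(tcum, pts[, 1], xout = tout)$y,
        stats::approx(tcum, pts[, 2], xout = tout)$y)
}

#' Write a measurement report
#'
#' JSON (one study) and optionally CSV (one row per study) with a versioned
#' schema: sl_distance_mm, sl_angle_deg, cl_angle_deg, arcs, zscores,
#' disruption_score, detections, thresholds_used. Numbers are formatted at
#' fixed precision so identical analyses yield byte-identical reports.
#'
#' @param results named list as produced by [runStudy()] (or any list
#'   following the schema).
#' @param jsonPath output JSON path.
#' @param csvPath optional CSV path; scalar fields only.
#' @return Invisibly, `jsonPath`.
#' @export
writeReport <- function(results, jsonPath, csvPath = NULL) {
  results$format_version <- "1.0"
  jsonlite::write_json(results, jsonPath, auto_unbox = TRUE, digits = I(10),
                       na = "null", null = "null", pretty = TRUE)
  if (!is.null(csvPath)) {
    scalars <- Filter(function(x) is.atomic(x) && length(x) == 1, results)
    utils::write.csv(as.data.frame(scalars), csvPath, row.names = FALSE)
  }
  invisible(jsonPath)
}

#' Read a measurement report written by [writeReport()]
#' @param jsonPath path to the report JSON.
#' @return Named list.
#' @export
readReport <- function(jsonPath) {
  jsonlite::read_json(jsonPath, simplifyVector = TRUE)
}
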