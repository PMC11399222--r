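## Point distribution model machinery: generalized Procrustes alignment,
## PCA shape model, template-to-contour fitting with facet-label transfer.
## 2-D shapes are handled as complex vectors, where the optimal similarity
## (rotation + scale) aligning z to w is the single complex coefficient
## sum(Conj(z) w) / sum(|z|^2).

.toComplex <- function(pts) complex(real = pts[, 1], imaginary = pts[, 2])
.fromComplex <- function(z) cbind(Re(z), Im(z))

## Flatten n x 2 landmarks to the interleaved (x1, y1, x2, y2, ...) vector
## used by the PCA, and back.
.flattenShape <- function(pts) as.vector(t(pts))
.unflattenShape <- function(v) matrix(v, ncol = 2, byrow = TRUE)

#' Generalized Procrustes alignment of 2-D shapes
#'
#' Similarity alignment (translation, rotation, scale) of corresponding
#' landmark sets to an iteratively re-estimated mean. The consensus mean is
#' centered at the origin with unit centroid size.
#'
#' @param shapes list of n x 2 matrices with corresponding rows (>= 2
#'   shapes, n >= 3).
#' @param maxIter,tol iteration control for the mean re-estimation.
#' @return List with `aligned` (list of n x 2 matrices, unit centroid
#'   size), `meanShape` (n x 2), `meanSize` (mean original centroid size,
#'   mm) and `transforms` (per shape: scale, rotationDeg, translation
#'   mapping the original into the aligned frame).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' ga <- procrustesAlign(list(sq, sq * 2 + 5))
#' ga$meanSize
#' @export
procrustesAlign <- function(shapes, maxIter = 20, tol = 1e-12) {
  stopifnot(length(shapes) >= 2)
  n <- nrow(shapes[[1]])
  stopifnot(n >= 3, all(vapply(shapes, nrow, 0L) == n))
  z <- lapply(shapes, function(s) .toComplex(as.matrix(s)))
  centroids <- vapply(z, mean, complex(1))
  zc <- mapply(function(zi, ci) zi - ci, z, centroids, SIMPLIFY = FALSE)
  sizes <- vapply(zc, function(zi) sqrt(sum(Mod(zi)^2)), 0)
  if (any(sizes < 1e-12)) stop("degenerate shape: all landmarks coincide")
  zu <- mapply(function(zi, si) zi / si, zc, sizes, SIMPLIFY = FALSE)

  mu <- zu[[1]]
  rot <- rep(complex(real = 1), length(zu))
  for (iter in seq_len(maxIter)) {
    rot <- vapply(zu, function(zi) {
      a <- sum(Conj(zi) * mu)
      a / Mod(a)
    }, complex(1))
    aligned <- mapply(function(zi, ai) zi * ai, zu, rot, SIMPLIFY = FALSE)
    newMu <- Reduce(`+`, aligned) / length(aligned)
    newMu <- newMu - mean(newMu)
    newMu <- newMu / sqrt(sum(Mod(newMu)^2))
    if (sum(Mod(newMu - mu)^2) < tol) { mu <- newMu; break }
    mu <- newMu
  }
  aligned <- mapply(function(zi, ai) zi * ai, zu, rot, SIMPLIFY = FALSE)
  transforms <- mapply(function(ci, si, ai) {
    list(scale = 1 / si, rotationDeg = Arg(ai) * 180 / pi,
         translation = c(-Re(ci), -Im(ci)))
  }, centroids, sizes, rot, SIMPLIFY = FALSE)
  list(aligned = lapply(aligned, .fromComplex),
       meanShape = .fromComplex(mu),
       meanSize = mean(sizes),
       transforms = transforms)
}

#' Build a point distribution model (PDM)
#'
#' Procrustes-aligns the training shapes, rescales the aligned frame to the
#' mean training centroid size (so the model frame is in mm), and runs PCA
#' on the flattened landmark vectors. The mode count k is the smallest
#' number of modes reaching `varianceTarget`, capped at min(2n - 4, m - 1).
#' Per-landmark residual scales are the RMS magnitudes of the training
#' reconstruction residuals with k modes, floored at
#' max(`residualFloorMm`, observed) to avoid infinite z-scores.
#'
#' @param shapes list of n x 2 corresponding landmark matrices (>= 3).
#' @param varianceTarget fraction of variance to retain, in (0, 1].
#' @param facets facet index ranges transferred to fitted shapes.
#' @param residualFloorMm floor on the per-landmark residual scale (mm).
#' @param closed whether the landmarks form a closed outline.
#' @param name model name.
#' @return A [ShapeModel-class].
#' @examples
#' sq <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
#' shapes <- lapply(1:5, function(i) sq * (1 + 0.05 * i))
#' buildPDM(shapes, name = "toy")
#' @export
buildPDM <- function(shapes, varianceTarget = 0.95, facets = list(),
                     residualFloorMm = 0.05, closed = TRUE, name = "shape") {
  stopifnot(length(shapes) >= 3, varianceTarget > 0, varianceTarget <= 1)
  ga <- procrustesAlign(shapes)
  m <- length(shapes)
  n <- nrow(ga$meanShape)
  X <- t(vapply(ga$aligned, function(s) .flattenShape(s * ga$meanSize),
                numeric(2 * n)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  S <- crossprod(Xc) / (m - 1)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  kmax <- min(2 * n - 4, m - 1)
  if (total < 1e-16) {
    k <- 0L
    retained <- 1
  } else {
    frac <- cumsum(ev) / total
    k <- min(which(frac >= varianceTarget - 1e-12))
    k <- min(k, kmax)
    retained <- if (k == 0) 0 else frac[k]
  }
  modes <- eig$vectors[, seq_len(k), drop = FALSE]
  B <- Xc %*% modes
  R <- Xc - B %*% t(modes)
  mag2 <- R[, 2 * seq_len(n) - 1, drop = FALSE]^2 +
          R[, 2 * seq_len(n), drop = FALSE]^2
  resSD <- pmax(residualFloorMm, sqrt(colMeans(mag2)))
  methods::new("ShapeModel", name = name,
               meanShape = .unflattenShape(mu), modes = modes,
               eigenvalues = ev[seq_len(k)],
               retainedVariance = retained, residualSD = resSD,
               facets = facets, meanSize = ga$meanSize, closed = closed)
}

## Best similarity (a, t) mapping reference r onto target z (complex,
## least squares): z ~ a r + t.
.similarityTo <- function(r, z) {
  rc <- r - mean(r); zc <- z - mean(z)
  a <- sum(Conj(rc) * zc) / sum(Mod(rc)^2)
  list(a = a, t = mean(z) - a * mean(r))
}

## Project a model-frame shape (complex) onto the mode subspace with
## +/- 3 sqrt(eigenvalue) clamping.
.projectClamped <- function(model, w) {
  muF <- .flattenShape(model@meanShape)
  v <- .flattenShape(.fromComplex(w)) - muF
  if (length(model@eigenvalues) == 0)
    return(list(recon = .toComplex(model@meanShape), coeffs = numeric(0)))
  b <- drop(crossprod(model@modes, v))
  lim <- 3 * sqrt(model@eigenvalues)
  b <- pmin(pmax(b, -lim), lim)
  recon <- muF + drop(model@modes %*% b)
  list(recon = .toComplex(.unflattenShape(recon)), coeffs = b)
}

#' Fit a PDM to a new contour
#'
#' Resamples the contour to the model's landmark count, finds the cyclic
#' correspondence (all integer start offsets, both orientations, then a
#' fractional refinement) minimizing the similarity-invariant Procrustes
#' distance to the model mean, and alternates pose estimation with
#' clamped mode projection. The returned landmarks are the regularized
#' model reconstruction mapped into the image frame, with the model's
#' facet index ranges transferred. The model's landmarks are assumed to be
#' (approximately) uniformly spaced in arc length along the outline, as
#' they are for models trained from resampled contours.
#'
#' @param model a [ShapeModel-class] with `closed = TRUE`.
#' @param contour a [Contour-class] (or n x 2 matrix, mm).
#' @param maxIter maximum pose/projection iterations.
#' @param tol convergence tolerance on the landmark update (mm).
#' @param maxRotationDeg candidate correspondences implying a pose
#'   rotation beyond this are rejected: radiographs arrive upright with a
#'   known view, so a bone cannot be upside down, and the constraint keeps
#'   near-symmetric outlines from locking onto a flipped correspondence.
#'   Set to 180 to disable.
#' @return List with `shape` (a [LandmarkedShape-class]), `residualMm`
#'   (RMS distance between matched contour points and fitted landmarks),
#'   `coeffs`, `pose` (scale, rotationDeg, translation), `modelFrame`
#'   (n x 2 pose-normalized observation) and `converged`.
#' @export
fitToContour <- function(model, contour, maxIter = 15, tol = 1e-9,
                         maxRotationDeg = 135) {
  bone <- if (methods::is(contour, "Contour")) boneName(contour) else "lunate"
  pts <- if (methods::is(contour, "Contour")) coords(contour) else
    as.matrix(contour)
  n <- nrow(model@meanShape)
  mu <- .toComplex(model@meanShape)
  muC <- mu - mean(mu)
  muN2 <- sum(Mod(muC)^2)

  candidates <- list(fwd = pts, rev = pts[rev(seq_len(nrow(pts))), ])
  rotOK <- function(a) abs(Arg(a)) * 180 / pi <= maxRotationDeg
  best <- list(score = -Inf, orient = "fwd", offset = 0)
  for (o in names(candidates)) {
    base <- resampleArclength(candidates[[o]], n, closed = TRUE)
    zc <- .toComplex(base)
    zc <- zc - mean(zc)
    zn2 <- sum(Mod(zc)^2)
    for (k in 0:(n - 1)) {
      idx <- c(seq(k + 1, n), seq_len(k))[seq_len(n)]
      a <- sum(Conj(muC) * zc[idx])  # pose rotation = Arg(a)
      if (!rotOK(a)) next
      sc <- Mod(a)^2 / (zn2 * muN2)
      if (sc > best$score ||
          (sc == best$score && o == "fwd" && k < best$offset))
        best <- list(score = sc, orient = o, offset = k)
    }
  }
  if (!is.finite(best$score) || best$score < 0) {
    ## all candidates rejected (should not happen): fall back unconstrained
    base <- resampleArclength(candidates$fwd, n, closed = TRUE)
    zc <- .toComplex(base); zc <- zc - mean(zc)
    scores <- vapply(0:(n - 1), function(k) {
      idx <- c(seq(k + 1, n), seq_len(k))[seq_len(n)]
      Mod(sum(Conj(muC) * zc[idx]))^2
    }, numeric(1))
    best <- list(score = max(scores), orient = "fwd",
                 offset = which.max(scores) - 1)
  }
  ## fractional refinement of the start offset
  for (f in seq(-0.9, 0.9, by = 0.1)) {
    cand <- resampleArclength(candidates[[best$orient]], n, closed = TRUE,
                              offset = best$offset + f)
    zc <- .toComplex(cand); zc <- zc - mean(zc)
    a <- sum(Conj(muC) * zc)
    if (!rotOK(a)) next
    sc <- Mod(a)^2 / (sum(Mod(zc)^2) * muN2)
    if (sc > best$score) best <- list(score = sc, orient = best$orient,
                                      offset = best$offset + f)
  }
  z <- .toComplex(resampleArclength(candidates[[best$orient]], n,
                                    closed = TRUE, offset = best$offset))

  recon <- mu
  coeffs <- numeric(0)
  converged <- FALSE
  landmarksC <- recon
  for (iter in seq_len(maxIter)) {
    pose <- .similarityTo(recon, z)
    w <- (z - pose$t) / pose$a
    pr <- .projectClamped(model, w)
    recon <- pr$recon
    coeffs <- pr$coeffs
    newLandmarks <- pose$a * recon + pose$t
    delta <- sqrt(mean(Mod(newLandmarks - landmarksC)^2))
    landmarksC <- newLandmarks
    if (iter > 1 && delta < tol) { converged <- TRUE; break }
  }
  pose <- .similarityTo(recon, z)
  landmarks <- .fromComplex(pose$a * recon + pose$t)
  res <- sqrt(mean(Mod(z - .toComplex(landmarks))^2))
  list(shape = LandmarkedShape(bone, landmarks, model@facets),
       residualMm = res, coeffs = coeffs,
       pose = list(scale = Mod(pose$a),
                   rotationDeg = Arg(pose$a) * 180 / pi,
                   translation = c(Re(pose$t), Im(pose$t))),
       modelFrame = .fromComplex((z - pose$t) / pose$a),
       converged = converged)
}

#' Arc-length midpoint of a named facet
#'
#' The point at half the cumulative arc length of the facet's polyline.
#' Facet midpoints anchor the SL distance and the facet-based bone axes.
#'
#' @param shape a [LandmarkedShape-class].
#' @param facetName facet name present in `facetRanges(shape)`.
#' @return Length-2 numeric (x, y) in mm.
#' @examples
#' sh <- LandmarkedShape("lunate", cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)),
#'                       list(bottom = c(1, 2)))
#' facetMidpoint(sh, "bottom")
#' @export
facetMidpoint <- function(shape, facetName) {
  r <- shape@facets[[facetName]]
  if (is.null(r))
    stop(sprintf("facet '%s' missing on %s", facetName, shape@bone))
  pts <- shape@landmarks[r[1]:r[2], , drop = FALSE]
  if (nrow(pts) == 1) return(as.numeric(pts))
  tcum <- cumArcLength(pts)
  L <- tcum[length(tcum)]
  if (L <= 0) return(as.numeric(pts[1, ]))
  keep <- c(TRUE, diff(tcum) > 0)
  tcum <- tcum[keep]; pts <- pts[keep, , drop = FALSE]
  c(stats::approx(tcum, pts[, 1], xout = L / 2)$y,
    stats::approx(tcum, pts[, 2], xout = L / 2)$y)
}

#' Write / read a shape model file
#'
#' Portable JSON container holding the landmark arrays (mean, modes,
#' eigenvalues, residual scales) together with the metadata (facet ranges,
#' landmark count, model frame size).
#'
#' @param model a [ShapeModel-class].
#' @param path file path (.json).
#' @return `writeShapeModel`: invisibly the path; `readShapeModel`: the
#'   [ShapeModel-class].
#' @export
writeShapeModel <- function(model, path) {
  ## arrays are stored flat (column-major) with explicit dimensions so the
  ## container stays portable and k = 0 is unambiguous
  out <- list(format_version = "1.0", name = model@name,
              n = nrow(model@meanShape), k = ncol(model@modes),
              closed = model@closed, meanSize = model@meanSize,
              retainedVariance = model@retainedVariance,
              meanShape = as.vector(model@meanShape),
              modes = as.vector(model@modes),
              eigenvalues = model@eigenvalues,
              residualSD = model@residualSD, facets = model@facets)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(raw$n)
  k <- as.integer(raw$k)
  facets <- if (length(raw$facets)) lapply(raw$facets, as.integer) else list()
  methods::new("ShapeModel", name = raw$name,
               meanShape = matrix(as.numeric(raw$meanShape), ncol = 2),
               modes = matrix(as.numeric(unlist(raw$modes)), nrow = 2 * n,
                              ncol = k),
               eigenvalues = as.numeric(unlist(raw$eigenvalues)),
               retainedVariance = raw$retainedVariance,
               residualSD = as.numeric(raw$residualSD), facets = facets,
               meanSize = raw$meanSize, closed = raw$closed)
}
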