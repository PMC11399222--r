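## A small asymmetric pentagon used as a base shape throughout.
.penta <- rbind(c(0, 0), c(4, 0.5), c(5, 3), c(2, 5), c(-1, 2.5))

test_that("Procrustes alignment is similarity-invariant and recovers a known mean", {
  ga <- procrustesAlign(list(.penta, .penta))
  expect_lt(max(abs(ga$aligned[[1]] - ga$aligned[[2]])), 1e-12)

  rot <- .penta %*% t(carpalign:::rotationMatrix(90)) * 2 + 7
  ga2 <- procrustesAlign(list(.penta, rot))
  expect_lt(sqrt(mean((ga2$aligned[[1]] - ga2$aligned[[2]])^2)), 1e-9)

  ## three noisy squares: consensus mean within the noise SD of the square
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  set.seed(31)
  noisy <- lapply(1:6, function(i) sq + matrix(rnorm(8, sd = 0.02), 4, 2))
  ga3 <- procrustesAlign(noisy)
  ref <- procrustesAlign(list(sq, sq))$meanShape
  ## compare shapes in the common normalized frame, up to rotation
  a <- carpalign:::.toComplex(ga3$meanShape)
  b <- carpalign:::.toComplex(ref)
  rotAlign <- sum(Conj(a) * b); rotAlign <- rotAlign / Mod(rotAlign)
  expect_lt(max(Mod(a * rotAlign - b)), 0.02)

  expect_error(procrustesAlign(list(matrix(1, 4, 2), matrix(1, 4, 2))),
               "degenerate")
})

test_that("PDM on identical shapes collapses to the mean with zero modes", {
  ## smooth blob: arc-length resampling is then self-consistent (a sharp
  ## polygon corner would add corner-cutting discretization error)
  th <- 2 * pi * (0:255) / 256
  blob <- cbind((3 + 0.6 * cos(th) + 0.4 * sin(2 * th)) * cos(th),
                (3 + 0.6 * cos(th) + 0.4 * sin(2 * th)) * sin(th))
  pu <- resampleArclength(blob, 24, closed = TRUE)
  model <- buildPDM(list(pu, pu, pu), name = "const")
  expect_identical(length(modelEigenvalues(model)), 0L)
  expect_identical(model@retainedVariance, 1)
  fit <- fitToContour(model, Contour("lunate", pu * 3 + 5))
  expect_lt(fit$residualMm, 0.01)
})

test_that("a single synthetic mode yields one nonzero eigenvalue matching the covariance oracle", {
  ## vary the pentagon along one direction only, with small amplitudes so
  ## the Procrustes size normalization stays linear to rounding
  dirv <- matrix(0, 5, 2); dirv[3, ] <- c(0.06, 0.02); dirv[1, ] <- c(-0.04, 0.03)
  amps <- c(-1.5, -0.5, 0, 0.5, 1.5, 1, -1) / 10
  shapes <- lapply(amps, function(a) .penta + a * dirv)
  model <- buildPDM(shapes, varianceTarget = 0.999999, name = "onemode")
  ev <- modelEigenvalues(model)
  expect_identical(sum(ev / sum(ev) > 1e-6), 1L)
  ## oracle: eigendecomposition of the aligned data covariance
  ga <- procrustesAlign(shapes)
  X <- t(vapply(ga$aligned, function(s)
    as.vector(t(s * ga$meanSize)), numeric(10)))
  ec <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(ev[1], ec[1], tolerance = 1e-8)
  expect_lt(ec[2] / ec[1], 1e-6)
})

test_that("full-variance PDM reconstructs training shapes to numerical precision", {
  ## octagon: 2n - 4 = 12 >= m - 1 = 7, so the mode cap cannot bind and
  ## full variance reconstructs the training set exactly
  th <- 2 * pi * (0:7) / 8
  oct <- cbind(3 * cos(th), 2 * sin(th))
  set.seed(77)
  shapes <- lapply(1:8, function(i) oct + matrix(rnorm(16, sd = 0.1), 8, 2))
  model <- buildPDM(shapes, varianceTarget = 1.0, name = "full")
  ga <- procrustesAlign(shapes)
  mu <- as.vector(t(model@meanShape))
  for (s in ga$aligned) {
    x <- as.vector(t(s * ga$meanSize))
    b <- drop(crossprod(modelModes(model), x - mu))
    recon <- mu + drop(modelModes(model) %*% b)
    expect_lt(sqrt(mean((recon - x)^2)), 1e-8)
  }
  ## mode coefficients of training shapes have variance = eigenvalues
  B <- t(vapply(ga$aligned, function(s)
    drop(crossprod(modelModes(model),
                   as.vector(t(s * ga$meanSize)) - mu)), numeric(ncol(modelModes(model)))))
  keep <- modelEigenvalues(model) > 1e-12
  expect_equal(unname(apply(B, 2, var))[keep],
               unname(modelEigenvalues(model))[keep], tolerance = 1e-6)
  ## mode count cap
  expect_lte(length(modelEigenvalues(model)), min(2 * 8 - 4, 8 - 1))
})

test_that("fitting the model mean returns the mean with near-zero coefficients", {
  ## landmarks must be arc-length-uniform for template fitting, as they
  ## are for models trained from contours
  set.seed(12)
  shapes <- lapply(1:6, function(i)
    resampleArclength(.penta + matrix(rnorm(10, sd = 0.05), 5, 2), 24,
                      closed = TRUE))
  model <- buildPDM(shapes, name = "m")
  dense <- resampleArclength(modelMean(model), 200, closed = TRUE)
  fit <- fitToContour(model, Contour("lunate", dense))
  ## small discretization slack: the consensus mean is only approximately
  ## arc-length uniform
  expect_lt(sqrt(mean((coords(fit$shape) - modelMean(model))^2)), 0.05)
  if (length(fit$coeffs)) expect_lt(max(abs(fit$coeffs)),
                                    sqrt(modelEigenvalues(model)[1]))
})

test_that("fitToContour is equivariant under similarity transforms", {
  models <- testTruthModels()
  model <- models$bonesAP$lunate
  case <- generateCase(wristParams(slGapMm = 2.2, seed = 19),
                       rasterize = FALSE)
  ct <- case@contoursAP$lunate
  fit0 <- fitToContour(model, ct)
  R <- carpalign:::rotationMatrix(25)
  pts2 <- coords(ct) %*% t(R) * 1.4 + matrix(c(3, -2), nrow(coords(ct)), 2,
                                             byrow = TRUE)
  fit2 <- fitToContour(model, Contour("lunate", pts2))
  mapped <- coords(fit0$shape) %*% t(R) * 1.4 +
    matrix(c(3, -2), 64, 2, byrow = TRUE)
  expect_lt(max(abs(coords(fit2$shape) - mapped)), 0.05)
})

test_that("fitting a training-like bone recovers facet midpoints within 0.5 mm", {
  models <- testTruthModels()
  case <- generateCase(wristParams(slGapMm = 2.3, globalScale = 1.04,
                                   rotationDeg = 5, seed = 23),
                       rasterize = FALSE)
  truth <- truthLandmarks(case, "ap")
  for (bone in c("scaphoid", "lunate")) {
    fit <- fitToContour(models$bonesAP[[bone]], case@contoursAP[[bone]])
    for (f in names(facetRanges(fit$shape))) {
      got <- facetMidpoint(fit$shape, f)
      want <- facetMidpoint(truth[[bone]], f)
      expect_lt(sqrt(sum((got - want)^2)), 0.5)
    }
  }
})

test_that("facet midpoints are arc-length midpoints", {
  sh <- LandmarkedShape("lunate", rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)),
                        list(bottom = c(1, 2), right = c(2, 3)))
  expect_equal(facetMidpoint(sh, "bottom"), c(1, 0))
  sh3 <- LandmarkedShape("lunate", rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 2)),
                         list(f = c(1, 3)))
  expect_equal(facetMidpoint(sh3, "f"), c(1, 0))
  th <- seq(0, pi / 2, length.out = 400)
  qc <- cbind(10 * cos(th), 10 * sin(th))
  shq <- LandmarkedShape("lunate", rbind(qc, c(0, 0)),
                         list(arc = c(1, 400)))
  got <- facetMidpoint(shq, "arc")
  want <- c(10 * cos(pi / 4), 10 * sin(pi / 4))
  expect_lt(sqrt(sum((got - want)^2)), 1e-3)
  expect_error(facetMidpoint(sh, "nope"), "missing")
})

test_that("shape model files round trip", {
  td <- withr::local_tempdir()
  set.seed(5)
  shapes <- lapply(1:5, function(i) .penta + matrix(rnorm(10, sd = 0.05), 5, 2))
  model <- buildPDM(shapes, facets = list(f1 = c(1L, 3L)), name = "rt")
  p <- file.path(td, "m.json")
  writeShapeModel(model, p)
  back <- readShapeModel(p)
  expect_equal(modelMean(back), modelMean(model), tolerance = 1e-12)
  expect_equal(modelModes(back), modelModes(model), tolerance = 1e-12)
  expect_equal(modelEigenvalues(back), modelEigenvalues(model),
               tolerance = 1e-12)
  expect_identical(facetRanges(back), facetRanges(model))
  expect_identical(back@closed, model@closed)
})
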