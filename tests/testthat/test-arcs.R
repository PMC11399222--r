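## A k = 0 toy arc model: straight-line mean, fixed residual scale. The
## reconstruction of any observation is then the posed mean, which makes
## z-score semantics directly checkable.
toyArcModel <- function(n = 100, sd = 0.5) {
  mean <- cbind(seq(-20, 20, length.out = n), 0)
  methods::new("ShapeModel", name = "toy", meanShape = mean,
               modes = matrix(0, 2 * n, 0), eigenvalues = numeric(0),
               retainedVariance = 1, residualSD = rep(sd, n),
               facets = list(), meanSize = sqrt(sum(mean^2)),
               closed = FALSE)
}

test_that("arcs are built radial-to-ulnar with 100 points and smooth joints", {
  case <- generateCase(wristParams(slGapMm = 2.5, seed = 31),
                       rasterize = FALSE)
  arcs <- buildArcs(truthLandmarks(case, "ap"))
  for (nm in c("proximal", "middle", "distal")) {
    a <- coords(arcs)[[nm]]
    expect_identical(nrow(a), 100L)
    expect_true(all(diff(a[, 1]) > 0))  # radial -> ulnar, monotone in x
    ## turning angle stays small along a normal arc
    seg <- diff(a)
    ang <- abs(diff(atan2(seg[, 2], seg[, 1]))) * 180 / pi
    expect_lt(max(ang), 10)
  }
  expect_error(buildArcs(truthLandmarks(case, "ap"), view = "lateral"),
               "neutral")
})

test_that("a proximal capitate shift translates arc III and leaves arcs I/II unchanged", {
  base <- generateCase(wristParams(slGapMm = 4, seed = 33),
                       rasterize = FALSE)
  shifted <- generateCase(wristParams(slGapMm = 4, subluxationMm = 3,
                                      seed = 33), rasterize = FALSE)
  a0 <- coords(buildArcs(truthLandmarks(base, "ap")))
  a1 <- coords(buildArcs(truthLandmarks(shifted, "ap")))
  expect_equal(a1$proximal, a0$proximal, tolerance = 1e-12)
  expect_equal(a1$middle, a0$middle, tolerance = 1e-12)
  expect_gt(max(abs(a1$distal - a0$distal)), 2.5)
})

test_that("missing bones make only the affected arcs unavailable", {
  case <- generateCase(wristParams(seed = 34), rasterize = FALSE)
  shapes <- truthLandmarks(case, "ap")
  shapes$hamate <- NULL
  arcs <- buildArcs(shapes)
  expect_null(coords(arcs)$distal)
  expect_false(is.null(coords(arcs)$proximal))
  expect_false(is.null(coords(arcs)$middle))
})

test_that("training arcs reconstruct inside the residual floor; the mean is a fixed point", {
  models <- testTruthModels()
  coh <- generateCohort(12, widenedFrac = 0.3, seed = 902,
                        rasterize = FALSE)
  normal <- coh[[1]]
  obs <- buildArcs(truthLandmarks(normal, "ap", 64))
  recon <- reconstructNormal(obs, models$arcs)
  for (nm in c("proximal", "middle", "distal")) {
    rmsd <- sqrt(mean((coords(obs)[[nm]] - coords(recon)[[nm]])^2))
    expect_lt(rmsd, 0.05)
  }
  ## a posed model mean reconstructs to itself
  m <- models$arcs$proximal
  posed <- modelMean(m) %*% t(carpalign:::rotationMatrix(12)) * 1.3 + 5
  arcsM <- methods::new("ArcSet",
                        arcs = list(proximal = posed, middle = NULL,
                                    distal = NULL), view = "neutral_ap_pa")
  rec <- reconstructNormal(arcsM, models$arcs)
  expect_lt(max(abs(coords(rec)$proximal - posed)), 1e-6)
})

test_that("a local step is reconstructed away and flagged by displacement", {
  models <- testTruthModels()
  case <- generateCohort(12, widenedFrac = 0.3, seed = 902,
                         rasterize = FALSE)[[2]]
  obs <- coords(buildArcs(truthLandmarks(case, "ap", 64)))$distal
  stepped <- obs
  stepped[55:100, 2] <- stepped[55:100, 2] + 3
  arcs <- methods::new("ArcSet",
                       arcs = list(proximal = NULL, middle = NULL,
                                   distal = stepped),
                       view = "neutral_ap_pa")
  rec <- coords(reconstructNormal(arcs, models$arcs))$distal
  disp <- sqrt(rowSums((stepped - rec)^2))
  expect_gt(max(disp[50:60]), 1.5)
  ## the reconstruction itself stays smooth (no 3 mm jump survives)
  expect_lt(max(sqrt(rowSums(diff(rec)^2))), 3 * stats::median(
    sqrt(rowSums(diff(rec)^2))))
})

test_that("z-scores follow their definition on a toy model", {
  toy <- toyArcModel(sd = 0.5)
  models <- list(proximal = toy, middle = toy, distal = toy)
  mean <- modelMean(toy)
  obs0 <- methods::new("ArcSet", arcs = list(proximal = mean, middle = mean,
                                             distal = mean),
                       view = "neutral_ap_pa")
  z0 <- arcZscores(obs0, NULL, models)
  expect_true(all(unlist(z0) < 1e-9))
  ## one point displaced by exactly 1 residual SD -> z ~ 1 there
  disp <- mean; disp[50, 2] <- disp[50, 2] + 0.5
  obs1 <- methods::new("ArcSet", arcs = list(proximal = disp, middle = mean,
                                             distal = mean),
                       view = "neutral_ap_pa")
  z1 <- arcZscores(obs1, NULL, models)
  expect_equal(z1$proximal[50], 1, tolerance = 0.03)
  expect_lt(max(z1$proximal[-50]), 0.2)
})

test_that("disruption score is a fraction of exceeding points and monotone", {
  expect_identical(disruptionScore(list(rep(0, 100), rep(0, 100),
                                        rep(0, 100))), 0)
  z <- list(rep(0, 100), c(rep(3, 33), rep(0, 67)), rep(0, 100))
  expect_equal(disruptionScore(z), 0.11)
  expect_true(disruptionScore(z) >= 0.11)  # detected at the 11% threshold
  expect_equal(disruptionScore(list(c(rep(3, 30), rep(0, 70)), rep(0, 100),
                                    rep(0, 100))), 0.10)
  ## monotone non-decreasing in every z value
  set.seed(9)
  for (i in 1:25) {
    za <- stats::runif(300, 0, 4)
    zb <- za
    j <- sample(300, 1)
    zb[j] <- zb[j] + stats::runif(1, 0, 2)
    expect_gte(disruptionScore(zb), disruptionScore(za))
  }
  expect_true(all(vapply(1:10, function(i)
    disruptionScore(stats::runif(300, 0, 5)), numeric(1)) <= 1))
})

test_that("assessment detection and markers localize exceeding runs", {
  models <- testTruthModels()
  case <- generateCohort(12, widenedFrac = 0.3, seed = 902,
                         rasterize = FALSE)[[3]]
  obs <- buildArcs(truthLandmarks(case, "ap", 64))
  a <- assessArcs(obs, models$arcs)
  expect_false(isDetected(a))
  expect_identical(arcScore(a), disruptionScore(arcZ(a)))
  det <- detectInterruption(a)
  expect_false(det$detected)
  expect_true(all(lengths(det$markers) == 0))
  ## markers appear where a step is injected
  stepped <- coords(obs)$distal
  stepped[40:100, 2] <- stepped[40:100, 2] + 3
  obs2 <- methods::new("ArcSet",
                       arcs = list(proximal = coords(obs)$proximal,
                                   middle = coords(obs)$middle,
                                   distal = stepped),
                       view = "neutral_ap_pa")
  a2 <- assessArcs(obs2, models$arcs)
  expect_true(isDetected(a2))
  expect_gt(length(arcMarkers(a2)$distal), 0)
})

test_that("the disruption score is invariant to global similarity transforms", {
  models <- testTruthModels()
  case <- generateCohort(12, widenedFrac = 0.3, seed = 902,
                         rasterize = FALSE)[[4]]
  obs <- buildArcs(truthLandmarks(case, "ap", 64))
  R <- carpalign:::rotationMatrix(-17)
  moved <- lapply(coords(obs), function(a)
    a %*% t(R) * 0.8 + matrix(c(4, 9), 100, 2, byrow = TRUE))
  obsT <- methods::new("ArcSet", arcs = moved, view = "neutral_ap_pa")
  z1 <- unlist(arcZscores(obs, NULL, models$arcs))
  z2 <- unlist(arcZscores(obsT, NULL, models$arcs))
  expect_equal(z1, z2, tolerance = 1e-6)
})

test_that("interrupted cases stand out from the normal score distribution", {
  models <- testTruthModels()
  normals <- generateCohort(12, widenedFrac = 0.3, seed = 911,
                            rasterize = FALSE)
  interrupted <- generateCohort(6, interruptedFrac = 1, seed = 912,
                                rasterize = FALSE)
  maxZ <- function(cs) {
    rep <- runStudy(models = models, case = cs)
    max(unlist(arcZ(attr(rep, "assessment"))))
  }
  zn <- vapply(normals, maxZ, numeric(1))
  zi <- vapply(interrupted, maxZ, numeric(1))
  expect_gt(min(zi), stats::quantile(zn, 0.95))
})

test_that("heatmap rendering preserves image size and encodes z", {
  models <- testTruthModels()
  case <- generateCase(wristParams(slGapMm = 4, subluxationMm = 3,
                                   seed = 44), spacingMmPerPx = 0.3,
                       views = "ap")
  rep <- runStudy(models = models, case = case)
  a <- attr(rep, "assessment")
  img <- renderHeatmap(a, case@maskAP, 0.3)
  expect_identical(dim(img)[1:2], dim(case@maskAP))
  expect_true(all(img >= 0 & img <= 1))
  ## interrupted case: warm (red-dominant) pixels outside the colorbar
  body <- img[, 1:(ncol(case@maskAP) - 15), ]
  warm <- body[, , 1] > 0.8 & body[, , 3] < 0.3
  expect_gt(sum(warm), 0)
  td <- withr::local_tempdir()
  renderHeatmap(a, case@maskAP, 0.3, path = file.path(td, "o.png"))
  expect_identical(dim(png::readPNG(file.path(td, "o.png")))[1:2],
                   dim(case@maskAP))
})
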