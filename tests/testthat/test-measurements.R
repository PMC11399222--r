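test_that("principal axis follows the second-moment major eigenvector", {
  rect <- rbind(c(0, 0), c(4, 0), c(4, 1), c(0, 1))
  ax <- principalAxis(LandmarkedShape("capitate", rect))
  expect_equal(abs(ax@direction), c(1, 0), tolerance = 1e-9)

  ## moment-matrix oracle: ellipse point cloud rotated 30 degrees
  th <- 2 * pi * (0:63) / 64
  ell <- cbind(10 * cos(th), 3 * sin(th)) %*%
    t(carpalign:::rotationMatrix(30))
  ax2 <- principalAxis(LandmarkedShape("scaphoid", ell))
  want <- c(cos(30 * pi / 180), sin(30 * pi / 180))
  ang <- acos(min(1, abs(sum(ax2@direction * want)))) * 180 / pi
  expect_lt(ang, 0.5)

  circ <- cbind(cos(th), sin(th))
  expect_error(principalAxis(LandmarkedShape("capitate", circ)),
               "ambiguous")
})

test_that("principal axis is oriented distally", {
  ## vertical bar with a distal facet at the top (smaller y)
  bar <- rbind(c(0, 10), c(1, 10), c(1, 0), c(0, 0))
  sh <- LandmarkedShape("scaphoid", bar, list(distal_surface = c(3, 4)))
  expect_lt(principalAxis(sh)@direction[2], 0)
  ## without a facet, orientation defaults toward smaller y
  sh2 <- LandmarkedShape("scaphoid", bar)
  expect_lt(principalAxis(sh2)@direction[2], 0)
})

test_that("facet axes join facet midpoints, proximal to distal", {
  sh <- LandmarkedShape("capitate",
                        rbind(c(-1, 0), c(1, 0), c(1, -4), c(-1, -4)),
                        list(capitate_lunate = c(1, 2),
                             capitate_mc3 = c(3, 4)))
  ax <- facetAxis(sh, "capitate_lunate", "capitate_mc3")
  expect_equal(ax@direction, c(0, -1))
  expect_equal(ax@anchor, c(0, -2))
  bad <- LandmarkedShape("capitate", rbind(c(0, 0), c(2, 0), c(1, 1)),
                         list(a = c(1, 2), b = c(1, 2)))
  expect_error(facetAxis(bad, "a", "b"), "coincident")
})

test_that("angleBetween is the unsigned angle between oriented axes", {
  down <- Axis(c(0, 0), c(0, -1))
  expect_equal(angleBetween(down, Axis(c(0, 0), c(sin(pi / 4), -cos(pi / 4)))),
               45, tolerance = 1e-9)
  expect_equal(angleBetween(down, down), 0)
  expect_warning(angleBetween(down, Axis(c(0, 0), c(0, 1))), "opposed")
  ## symmetric and invariant to a common rotation
  set.seed(2)
  for (i in 1:20) {
    d1 <- Axis(c(0, 0), rnorm(2)); d2 <- Axis(c(0, 0), rnorm(2))
    a12 <- angleBetween(d1, d2)
    expect_equal(a12, angleBetween(d2, d1))
    R <- carpalign:::rotationMatrix(runif(1, -180, 180))
    expect_equal(a12, angleBetween(Axis(c(0, 0), drop(R %*% d1@direction)),
                                   Axis(c(0, 0), drop(R %*% d2@direction))),
                 tolerance = 1e-9)
  }
})

test_that("SL distance is the distance between the facing facet midpoints", {
  sca <- LandmarkedShape("scaphoid", rbind(c(9, 4), c(10, 4), c(10, 6), c(9, 6)),
                         list(scaphoid_lunate = c(2, 3)))
  lun <- LandmarkedShape("lunate", rbind(c(12, 6), c(12, 4), c(13, 4), c(13, 6)),
                         list(lunate_scaphoid = c(1, 2)))
  ## midpoints (10, 5) and (12, 5)
  expect_equal(slDistance(sca, lun), 2)
  lun0 <- LandmarkedShape("lunate", rbind(c(10, 6), c(10, 4), c(11, 4), c(11, 6)),
                          list(lunate_scaphoid = c(1, 2)))
  sca0 <- LandmarkedShape("scaphoid", rbind(c(9, 4), c(10, 4), c(10, 6), c(9, 6)),
                          list(scaphoid_lunate = c(2, 3)))
  expect_equal(slDistance(sca0, lun0), 0)
})

test_that("threshold semantics follow the reference rules exactly", {
  cfg <- defaultThresholds()
  expect_true(classifyMeasurement("sl_distance", 3.5, "neutral_ap_pa", 40,
                                  cfg)$abnormal)
  expect_false(classifyMeasurement("sl_distance", 3.5,
                                   "ulnar_deviated_ap_pa", 40, cfg)$abnormal)
  expect_false(classifyMeasurement("sl_distance", 3.0, "neutral_ap_pa", 40,
                                   cfg)$abnormal)
  expect_false(classifyMeasurement("sl_angle", 45, "lateral", 40,
                                   cfg)$abnormal)
  expect_true(classifyMeasurement("sl_angle", 61, "lateral", 40,
                                  cfg)$abnormal)
  expect_false(classifyMeasurement("sl_angle", 30, "lateral", 40,
                                   cfg)$abnormal)
  expect_true(classifyMeasurement("sl_angle", 29.9, "lateral", 40,
                                  cfg)$abnormal)
  expect_false(classifyMeasurement("cl_angle", 30.0, "lateral", 40,
                                   cfg)$abnormal)
  expect_true(classifyMeasurement("cl_angle", 30.1, "lateral", 40,
                                  cfg)$abnormal)
  ## clenched fist falls back to the neutral limit, flagged in the rule
  cf <- classifyMeasurement("sl_distance", 3.5, "clenched_fist_ap_pa", 40,
                            cfg)
  expect_true(cf$abnormal)
  expect_match(cf$thresholdRule, "clenched")
})

test_that("classification is monotone in the SL distance", {
  cfg <- defaultThresholds()
  vals <- seq(0.5, 6, by = 0.1)
  flags <- vapply(vals, function(v)
    classifyMeasurement("sl_distance", v, "neutral_ap_pa", 40, cfg)$abnormal,
    logical(1))
  expect_true(all(diff(flags) >= 0))
})

test_that("pediatric classification requires a user-supplied table", {
  cfg <- defaultThresholds()
  out <- classifyMeasurement("sl_distance", 2.5, "neutral_ap_pa", 9, cfg)
  expect_true(is.na(out$abnormal))
  expect_match(out$thresholdRule, "unclassifiable")
  tab <- data.frame(ageMin = 6, ageMax = 10, slDistanceMm = 4.5)
  cfg2 <- defaultThresholds(pediatricTable = tab)
  expect_false(classifyMeasurement("sl_distance", 4.0, "neutral_ap_pa", 9,
                                   cfg2)$abnormal)
  expect_true(classifyMeasurement("sl_distance", 4.6, "neutral_ap_pa", 9,
                                  cfg2)$abnormal)
  expect_true(is.na(classifyMeasurement("sl_distance", 2.0, "neutral_ap_pa",
                                        13, cfg2)$abnormal))
})

test_that("measurements enforce view compatibility", {
  cfg <- defaultThresholds()
  expect_error(classifyMeasurement("sl_distance", 3, "lateral", 40, cfg),
               "AP/PA")
  expect_error(classifyMeasurement("cl_angle", 20, "neutral_ap_pa", 40, cfg),
               "lateral")
})
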