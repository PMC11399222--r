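test_that("measurement agreement matches closed forms", {
  a <- measurementAgreement(c(1, 2, 3), c(1, 1, 1), ci = FALSE)
  expect_equal(a$mae, 1); expect_equal(a$bias, 1)

  d <- c(0.2, -0.2, 0.4, -0.4)
  a2 <- measurementAgreement(d, rep(0, 4), ci = FALSE)
  expect_equal(a2$bias, 0)
  expect_equal(a2$loaUpper, 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(a2$loaUpper, 0.7157, tolerance = 1e-4)
  expect_equal(a2$loaLower, -0.7157, tolerance = 1e-4)

  a3 <- measurementAgreement(c(2, 3, 4), c(2, 3, 4), ci = FALSE)
  expect_equal(a3$mae, 0)
  expect_equal(c(a3$loaLower, a3$loaUpper), c(0, 0))

  a4 <- measurementAgreement(rnorm(20) + 40, rnorm(20) + 40,
                             strataWidth = 10, seed = 3)
  expect_true(a4$maeCI[1] <= a4$mae && a4$mae <= a4$maeCI[2])
  expect_true(a4$loaLower <= a4$bias && a4$bias <= a4$loaUpper)
})

test_that("discrete Frechet distance matches printed toy cases", {
  l1 <- cbind(0:2, 0)
  expect_identical(discreteFrechet(l1, l1), 0)
  expect_equal(discreteFrechet(l1, cbind(0:2, 1)), 1)
  vee <- rbind(c(0, 0), c(1, 1), c(2, 0))
  expect_equal(discreteFrechet(rbind(c(0, 0), c(2, 0)), vee), sqrt(2))
})

test_that("discrete Frechet equals exhaustive coupling enumeration", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    a <- matrix(rnorm(2 * n), n, 2)
    b <- matrix(rnorm(2 * m), m, 2)
    f <- discreteFrechet(a, b)
    expect_equal(f, bruteFrechet(a, b), tolerance = 1e-12)
    ## invariants: symmetric, >= Hausdorff, 0 iff identical
    expect_equal(f, discreteFrechet(b, a))
    expect_gte(f + 1e-12, carpalign:::hausdorffDistance(a, b))
  }
  expect_error(discreteFrechet(matrix(0, 0, 2), matrix(0, 1, 2)), "empty")
})

test_that("mean Frechet distance averages per-pair distances", {
  p <- list(cbind(0:3, 0), cbind(0:3, 0))
  t <- list(cbind(0:3, 1), cbind(0:3, 3))
  mf <- meanFrechet(p, t, ci = FALSE)
  expect_equal(mf$mfd, 2)
  expect_equal(mf$perCase, c(1, 3))
})

test_that("AUC equals the Mann-Whitney statistic on random instances", {
  r <- rocAnalysis(c(0.9, 0.4, 0.3, 0.5), c(TRUE, TRUE, FALSE, FALSE),
                   ci = FALSE)
  expect_equal(r$auc, 0.75)
  expect_equal(rocAnalysis(c(1, 2, 3, 10), c(FALSE, FALSE, TRUE, TRUE),
                           ci = FALSE)$auc, 1)
  expect_equal(rocAnalysis(rep(0.3, 8), rep(c(TRUE, FALSE), 4),
                           ci = FALSE)$auc, 0.5)
  set.seed(23)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    scores <- round(rnorm(n), sample(c(1, 2), 1))  # force some ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- rocAnalysis(scores, labels, ci = FALSE)
    expect_equal(r$auc, pairwiseAUC(scores, labels), tolerance = 1e-12)
    u <- suppressWarnings(stats::wilcox.test(scores[labels],
                                             scores[!labels]))$statistic
    expect_equal(r$auc, unname(u) / (sum(labels) * sum(!labels)),
                 tolerance = 1e-12)
  }
})

test_that("the operating threshold maximizes Youden's J with ties at the lowest threshold", {
  scores <- c(0.1, 0.2, 0.6, 0.7, 0.8)
  labels <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- rocAnalysis(scores, labels, ci = FALSE)
  expect_equal(r$operatingThreshold, 0.6)
  expect_equal(r$sensitivity, 1); expect_equal(r$specificity, 1)
  expect_equal(r$youdenJ, r$sensitivity + r$specificity - 1)
  expect_error(rocAnalysis(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  scores <- rnorm(60) + rep(c(0, 1), 30)
  labels <- rep(c(FALSE, TRUE), 30)
  r <- rocAnalysis(scores, labels, ci = FALSE)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("stratified bootstrap keeps stratum sizes and covers the estimate", {
  expect_equal(stratifiedBootstrapCI(rep(3, 20), mean, rep(1, 20),
                                     iters = 50, seed = 1), c(3, 3))
  set.seed(7)
  hits <- 0
  for (i in 1:60) {
    x <- rnorm(40, mean = 5)
    strata <- rep(1:2, each = 20)
    ci <- stratifiedBootstrapCI(x, mean, strata, iters = 200, seed = i)
    if (ci[1] <= mean(x) && mean(x) <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 57)  # the point estimate sits inside nearly always
  ## stratum sizes preserved: a statistic counting stratum-1 draws is constant
  data <- c(rep(0, 10), rep(1, 30))
  ci <- stratifiedBootstrapCI(data, function(v) sum(v == 0), data,
                              iters = 100, seed = 2)
  expect_equal(ci, c(10, 10))
  expect_error(stratifiedBootstrapCI(numeric(0), mean, numeric(0)))
})

test_that("bootstrap CIs for the mean have near-nominal coverage", {
  set.seed(99)
  trueMean <- 1.5
  covered <- vapply(1:500, function(r) {
    x <- rnorm(100, mean = trueMean)
    ci <- stratifiedBootstrapCI(x, mean, rep(1, 100), iters = 300,
                                seed = 1000 + r)
    ci[1] <= trueMean && trueMean <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.91)
  expect_lte(mean(covered), 0.99)
})

test_that("paired permutation test matches exhaustive sign-flip enumeration", {
  out <- pairedPermutationTest(c(1, 2, 3), c(1, 2, 3), iters = 100, seed = 1)
  expect_equal(out$p, 1)
  a <- c(0.8, -0.3, 1.2); b <- c(0.1, 0.2, 0.3)
  d <- a - b
  ## oracle: all 2^3 sign patterns, smoothed two-sided p
  signs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  tperm <- abs(apply(signs, 1, function(s) mean(d * s)))
  pOracle <- (1 + sum(tperm >= abs(mean(d)) - 1e-12)) / (1 + 8)
  got <- pairedPermutationTest(a, b, exhaustive = TRUE)
  expect_equal(got$p, pOracle)
  ## sampled version approximates the exhaustive one
  ps <- pairedPermutationTest(a, b, iters = 4000, seed = 5)$p
  expect_lt(abs(ps - pOracle), 0.1)
  expect_error(pairedPermutationTest(1:3, 1:4))
})

test_that("permutation p-values are roughly uniform under the null", {
  set.seed(55)
  ps <- vapply(1:400, function(i) {
    a <- rnorm(12); b <- rnorm(12)
    pairedPermutationTest(a, b, iters = 99, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(ps < 0.5), 0.35); expect_lt(mean(ps < 0.5), 0.65)
})

test_that("DeLong test: identity, antisymmetry, and variance against a bootstrap oracle", {
  labels <- rep(c(TRUE, FALSE), each = 20)
  s <- c(rnorm(20, 1), rnorm(20))
  same <- delongTest(s, s, labels)
  expect_equal(same$delta, 0); expect_equal(same$p, 1)

  set.seed(61)
  sA <- rnorm(40) + labels * 1.2
  sB <- 0.6 * sA + 0.4 * rnorm(40) + labels * 0.5
  ab <- delongTest(sA, sB, labels)
  ba <- delongTest(sB, sA, labels)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)

  ## bootstrap oracle for var(AUC_A - AUC_B) on a larger paired sample
  set.seed(62)
  n <- 200
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  xA <- rnorm(n) + lab * 1.0
  xB <- 0.7 * xA + 0.3 * rnorm(n) + lab * 0.3
  dl <- delongTest(xA, xB, lab)
  deltas <- vapply(1:400, function(b) {
    set.seed(7000 + b)
    idx <- c(sample(which(lab), sum(lab), TRUE),
             sample(which(!lab), sum(!lab), TRUE))
    pairwiseAUC(xA[idx], lab[idx]) - pairwiseAUC(xB[idx], lab[idx])
  }, numeric(1))
  expect_lt(abs(dl$varDelta - stats::var(deltas)) / stats::var(deltas), 0.2)
})

test_that("DeLong p-values agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(71)
  lab <- rep(c(TRUE, FALSE), each = 30)
  sA <- rnorm(60) + lab * 1.1
  sB <- 0.5 * sA + 0.5 * rnorm(60) + lab * 0.4
  dl <- delongTest(sA, sB, lab)
  rocA <- pROC::roc(lab, sA, direction = "<", quiet = TRUE)
  rocB <- pROC::roc(lab, sB, direction = "<", quiet = TRUE)
  ref <- pROC::roc.test(rocA, rocB, method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-6)
})
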