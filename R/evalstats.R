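## Evaluation stack: MAE / Bland-Altman agreement, discrete Frechet
## distance, ROC with Youden operating point, stratified bootstrap CIs,
## paired permutation tests, DeLong test for correlated AUCs.

#' Measurement agreement (MAE and Bland-Altman)
#'
#' Differences are prediction minus truth. MAE is the mean absolute
#' difference; bias the mean difference; limits of agreement (LoA) are
#' bias +/- 1.96 SD of the differences (sample SD, n - 1). Bias and LoA
#' confidence intervals use the standard Bland-Altman normal
#' approximations (SE(bias) = SD/sqrt(n), SE(LoA) = SD*sqrt(3/n)); the MAE
#' CI comes from a stratified bootstrap (strata of 1 mm for distances, 10
#' degrees for angles; see `strataOf`).
#'
#' @param pred,truth equal-length numeric vectors (n >= 2 for LoA).
#' @param strataWidth stratum width used for the bootstrap MAE CI (1 for
#'   mm, 10 for degrees); strata are floor(truth / strataWidth).
#' @param iters bootstrap iterations (default 1000).
#' @param seed bootstrap seed.
#' @param ci compute CIs (disable for speed).
#' @return List with mae, bias, loaLower, loaUpper, sd, n and (when `ci`)
#'   maeCI, biasCI, loaLowerCI, loaUpperCI.
#' @examples
#' measurementAgreement(c(1, 2, 3), c(1, 1, 1), ci = FALSE)
#' @export
measurementAgreement <- function(pred, truth, strataWidth = 1, iters = 1000,
                                 seed = 1L, ci = TRUE) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  d <- pred - truth
  n <- length(d)
  s <- stats::sd(d)
  out <- list(mae = mean(abs(d)), bias = mean(d),
              loaLower = mean(d) - 1.96 * s, loaUpper = mean(d) + 1.96 * s,
              sd = s, n = n)
  if (ci) {
    out$biasCI <- out$bias + c(-1, 1) * 1.96 * s / sqrt(n)
    seLoa <- s * sqrt(3 / n)
    out$loaLowerCI <- out$loaLower + c(-1, 1) * 1.96 * seLoa
    out$loaUpperCI <- out$loaUpper + c(-1, 1) * 1.96 * seLoa
    strata <- floor(truth / strataWidth)
    out$maeCI <- stratifiedBootstrapCI(abs(d), mean, strata, iters = iters,
                                       seed = seed)
  }
  out
}

#' Discrete Frechet distance between two polylines
#'
#' Dynamic program over all order-preserving couplings of the two point
#' sequences; the arcs are defined as fixed-size point sets, so the
#' discrete (not continuous) variant applies.
#'
#' @param a,b n x 2 and m x 2 point matrices (non-empty).
#' @return The discrete Frechet distance.
#' @examples
#' discreteFrechet(cbind(0:2, 0), cbind(0:2, 1))
#' @export
discreteFrechet <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) stop("empty polyline")
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  for (i in seq_len(n)[-1]) {
    ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
    for (j in seq_len(m)[-1])
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      d[i, j])
  }
  ca[n, m]
}

#' Mean Frechet distance over paired polylines
#'
#' @param predList,truthList equal-length lists of point matrices.
#' @param iters,seed bootstrap control for the CI.
#' @param ci compute a percentile bootstrap CI (cases resampled, binary
#'   strata not applicable - one stratum).
#' @return List with mfd, n and optionally mfdCI.
#' @export
meanFrechet <- function(predList, truthList, iters = 1000, seed = 1L,
                        ci = TRUE) {
  stopifnot(length(predList) == length(truthList), length(predList) >= 1)
  ds <- mapply(discreteFrechet, predList, truthList)
  out <- list(mfd = mean(ds), n = length(ds), perCase = ds)
  if (ci && length(ds) >= 2)
    out$mfdCI <- stratifiedBootstrapCI(ds, mean, rep(1, length(ds)),
                                       iters = iters, seed = seed)
  out
}

#' ROC analysis with Youden operating point
#'
#' AUC is the probability that a random positive scores above a random
#' negative, with half credit for ties (the Mann-Whitney statistic divided
#' by n+ * n-). Candidate thresholds are the observed score values; a case
#' is called positive when its score is at or above the threshold. The
#' operating threshold maximizes Youden's J = sensitivity + specificity -
#' 1; ties take the lowest threshold.
#'
#' @param scores numeric scores (higher = more abnormal).
#' @param labels logical (or 0/1) true labels; both classes must be
#'   present.
#' @param iters,seed,ci bootstrap control for CIs (stratified by label).
#' @return List with auc, operatingThreshold, sensitivity, specificity,
#'   youdenJ, rocCurve (data.frame threshold/sens/spec) and optional CIs.
#' @examples
#' rocAnalysis(c(0.9, 0.4, 0.3, 0.5), c(TRUE, TRUE, FALSE, FALSE),
#'             ci = FALSE)$auc
#' @export
rocAnalysis <- function(scores, labels, iters = 1000, seed = 1L, ci = TRUE) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present for ROC analysis")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), 0)
  j <- sens + spec - 1
  iBest <- which(j == max(j))[1]  # ties -> lowest threshold
  out <- list(auc = auc, operatingThreshold = thr[iBest],
              sensitivity = sens[iBest], specificity = spec[iBest],
              youdenJ = j[iBest],
              rocCurve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec))
  if (ci) {
    idx <- seq_along(scores)
    aucStat <- function(ii) {
      l <- labels[ii]; s <- scores[ii]
      rr <- rank(s, ties.method = "average")
      np <- sum(l); nn <- sum(!l)
      if (np == 0 || nn == 0) return(NA_real_)
      (sum(rr[l]) - np * (np + 1) / 2) / (np * nn)
    }
    out$aucCI <- stratifiedBootstrapCI(idx, aucStat, labels, iters = iters,
                                       seed = seed)
    t0 <- thr[iBest]
    out$sensitivityCI <- stratifiedBootstrapCI(
      scores[labels], function(s) mean(s >= t0), rep(1, nPos),
      iters = iters, seed = seed)
    out$specificityCI <- stratifiedBootstrapCI(
      scores[!labels], function(s) mean(s < t0), rep(1, nNeg),
      iters = iters, seed = seed + 1L)
  }
  out
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples within strata with replacement, preserving stratum sizes
#' (grouping per 1 mm for distances, 10 degrees for angles, and binary
#' labels for detections), and returns the 2.5/97.5 percentiles of the
#' statistic over `iters` replicates.
#'
#' @param data vector the statistic consumes (values or indices).
#' @param statistic function of a resampled `data` vector.
#' @param strata stratum id per element (non-empty strata).
#' @param iters bootstrap iterations (>= 1, default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return Length-2 numeric CI.
#' @examples
#' stratifiedBootstrapCI(rnorm(50), mean, rep(1, 50), iters = 200, seed = 1)
#' @export
stratifiedBootstrapCI <- function(data, statistic, strata, iters = 1000,
                                  seed = 1L, conf = 0.95) {
  stopifnot(iters >= 1, length(strata) == length(data))
  if (length(data) == 0) stop("empty stratum: no data to resample")
  groups <- split(seq_along(data), strata)
  if (any(lengths(groups) == 0)) stop("empty stratum")
  stats <- withSeed(seed, vapply(seq_len(iters), function(b) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    statistic(data[idx])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  unname(stats::quantile(stats, c(alpha, 1 - alpha), na.rm = TRUE))
}

#' Two-sided paired permutation test
#'
#' Sign-flip permutation of the paired differences: under the null the
#' sign of each paired difference is exchangeable. The two-sided p-value
#' is the smoothed proportion of permuted |statistic| at or above the
#' observed |statistic| ((1 + count) / (1 + iters), avoiding p = 0).
#'
#' @param errorsA,errorsB paired equal-length numeric vectors.
#' @param statistic function of the difference vector (default mean).
#' @param iters permutation iterations (default 1000).
#' @param seed RNG seed.
#' @param exhaustive enumerate all 2^n sign patterns instead of sampling
#'   (n <= 20).
#' @return List with p, observed statistic and n.
#' @examples
#' pairedPermutationTest(c(1, 2, 3), c(1, 2, 3))$p
#' @export
pairedPermutationTest <- function(errorsA, errorsB, statistic = mean,
                                  iters = 1000, seed = 1L,
                                  exhaustive = FALSE) {
  stopifnot(length(errorsA) == length(errorsB))
  d <- errorsA - errorsB
  n <- length(d)
  t0 <- abs(statistic(d))
  if (exhaustive) {
    stopifnot(n <= 20)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tperm <- abs(apply(signs, 1, function(s) statistic(d * s)))
    p <- (1 + sum(tperm >= t0 - 1e-12)) / (1 + nrow(signs))
  } else {
    tperm <- withSeed(seed, vapply(seq_len(iters), function(b)
      abs(statistic(d * sample(c(-1, 1), n, replace = TRUE))), numeric(1)))
    p <- (1 + sum(tperm >= t0 - 1e-12)) / (1 + iters)
  }
  list(p = min(p, 1), observed = statistic(d), n = n)
}

## Placement values: for each positive, the fraction of negatives it
## outscores (ties half); and symmetrically for negatives.
.placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of the AUCs of two score sets on the same cases,
#' using the DeLong placement-value covariance estimate and a two-sided
#' normal p-value on the AUC difference.
#'
#' @param scoresA,scoresB scores of the two systems on the same cases.
#' @param labels true labels (both classes present).
#' @return List with aucA, aucB, delta (A - B), varDelta, z and p.
#' @examples
#' delongTest(c(1, 2, 3, 4), c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$p
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scoresA) == length(scoresB),
            length(labels) == length(scoresA))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  pa <- .placements(scoresA, labels)
  pb <- .placements(scoresB, labels)
  m <- sum(labels); n <- sum(!labels)
  delta <- pa$auc - pb$auc
  if (m < 2 || n < 2) stop("need at least 2 cases per class")
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  varDelta <- s10 / m + s01 / n
  if (varDelta <= 0) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(varDelta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(aucA = pa$auc, aucB = pb$auc, delta = delta, varDelta = varDelta,
       z = z, p = p)
}
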