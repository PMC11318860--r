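test_that("two-ROI partial correlation without shrinkage is plain Pearson", {
  set.seed(1)
  x <- matrix(rnorm(200), 100L, 2L)
  x[, 2L] <- x[, 1L] * 0.6 + x[, 2L]
  colnames(x) <- c("a", "b")
  pc <- partialCorrMatrix(x, shrinkage = 0)
  expect_equal(pc["a", "b"], cor(x)[1L, 2L], tolerance = 1e-10)
  expect_equal(diag(pc), c(a = 1, b = 1))
})

test_that("partial correlations converge to the analytic precision-matrix values", {
  ## equicorrelated trivariate: partial r(1,2|3) = 1/3 analytically
  sig <- matrix(0.5, 3L, 3L); diag(sig) <- 1
  set.seed(42)
  x <- matrix(rnorm(5000 * 3), 5000L, 3L) %*% chol(sig)
  colnames(x) <- c("a", "b", "c")
  pc <- partialCorrMatrix(x, shrinkage = 0)
  expect_equal(pc["a", "b"], 1 / 3, tolerance = 0.05)
  ## independent columns: off-diagonals near zero
  set.seed(7)
  z <- matrix(rnorm(4000 * 4), 4000L, 4L)
  colnames(z) <- letters[1:4]
  pcz <- partialCorrMatrix(z, shrinkage = 0)
  expect_lt(max(abs(pcz[upper.tri(pcz)])), 3 / sqrt(4000))
})

test_that("constant ROI signals are rejected by name and auto shrinkage is recorded", {
  x <- cbind(rnorm(30), rep(1, 30)); colnames(x) <- c("ok", "flat")
  expect_error(partialCorrMatrix(x), "flat")
  set.seed(2)
  y <- matrix(rnorm(20 * 30), 20L, 30L)
  colnames(y) <- sprintf("r%02d", 1:30)
  pc <- partialCorrMatrix(y, "auto")
  expect_true(attr(pc, "shrinkage") > 0 && attr(pc, "shrinkage") <= 1)
  expect_true(all(abs(pc) <= 1 + 1e-12))
})

test_that("ROI permutation permutes the partial-correlation matrix consistently", {
  set.seed(3)
  x <- matrix(rnorm(50 * 5), 50L, 5L)
  colnames(x) <- letters[1:5]
  perm <- c(3L, 1L, 5L, 2L, 4L)
  pc1 <- partialCorrMatrix(x, 0.1)
  pc2 <- partialCorrMatrix(x[, perm], 0.1)
  expect_equal(pc2, pc1[perm, perm], tolerance = 1e-10,
               ignore_attr = "shrinkage")
})

test_that("Fisher transform is odd, increasing and clips |r| >= 1 with a warning", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_warning(z1 <- fisherZ(1), "clipped")
  expect_true(is.finite(z1))
})

test_that("edge selection produces the documented feature counts", {
  parc <- simulateParcellation()
  mat <- diag(288); dimnames(mat) <- list(roiIds(parc), roiIds(parc))
  mat[] <- 0.1; diag(mat) <- 1
  expect_length(featureValues(selectEdges(mat, parc, "network_pair")), 96L)
  expect_length(featureValues(
    selectEdges(mat, parc, "hemispheric",
                networks = c("auditory", "reward"), side = "R")), 45L)
  expect_length(featureValues(selectEdges(mat, parc, "whole_brain")),
                288L * 287L / 2L)
  expect_error(selectEdges(mat, parc, "network_pair",
                           networks = c("auditory", "nope")), "unknown")
})

test_that("feature values are keyed to ROI identities, not input order", {
  parc <- simulateParcellation(c(auditory = 2L, reward = 2L, other = 2L))
  set.seed(4)
  x <- matrix(rnorm(60 * 6), 60L, 6L)
  colnames(x) <- roiIds(parc)
  f1 <- selectEdges(partialCorrMatrix(x, 0.1), parc)
  perm <- sample(6L)
  f2 <- selectEdges(partialCorrMatrix(x[, perm], 0.1), parc)
  expect_identical(edgeIds(f1), edgeIds(f2))
  expect_equal(featureValues(f1), featureValues(f2), tolerance = 1e-10)
})

test_that("network pairs enumerate to C(K,2) with the auditory split", {
  parc <- simulateParcellation()
  pairs <- listNetworkPairs(parc)
  expect_equal(nrow(pairs), 78L)
  expect_equal(sum(pairs$hasAuditory), 12L)
  expect_equal(sum(!pairs$hasAuditory), 66L)
  tiny <- simulateParcellation(c(auditory = 2L, reward = 2L))
  expect_equal(nrow(listNetworkPairs(tiny)), 1L)
})

test_that("trial averaging is an elementwise mean that tracks missingness", {
  parc <- simulateParcellation(c(auditory = 2L, reward = 2L))
  mk <- function(vals) {
    mat <- matrix(0, 4L, 4L, dimnames = list(roiIds(parc), roiIds(parc)))
    mat[upper.tri(mat)] <- tanh(vals); mat <- mat + t(mat); diag(mat) <- 1
    selectEdges(mat, parc)
  }
  f <- mk(rep(0.3, 6))
  expect_equal(featureValues(averageFeatures(list(f))), featureValues(f))
  fneg <- mk(rep(-0.3, 6))
  expect_equal(featureValues(averageFeatures(list(f, fneg))), rep(0, 4L))
  avg <- averageFeatures(c(rep(list(f), 7), list(NULL)))
  expect_equal(avg@nTrials, 7)
  expect_error(averageFeatures(list(NULL, NULL)), "empty average")
})

test_that("random intrinsic-rest windows are seeded, feasible and converge toward full-series features", {
  parc <- simulateParcellation(c(auditory = 2L, reward = 2L))
  sig <- matrix(0.2, 4L, 4L); diag(sig) <- 1
  set.seed(5)
  x <- matrix(rnorm(300 * 4), 300L, 4L) %*% chol(sig)
  colnames(x) <- roiIds(parc)
  s <- roiSeries(x, tr = 2, epoch = "intrinsic_rest")
  a <- sampleIntrinsicWindows(s, parc, k = 4L, window = 18, reps = 3L,
                              seed = 9L, shrinkage = 0.1)
  b <- sampleIntrinsicWindows(s, parc, k = 4L, window = 18, reps = 3L,
                              seed = 9L, shrinkage = 0.1)
  expect_equal(featureValues(a), featureValues(b))
  expect_error(sampleIntrinsicWindows(s, parc, k = 40L, window = 18),
               "sampling error")
  ## more repetitions shrink the gap to the full-series estimate
  full <- selectEdges(partialCorrMatrix(detrendLinear(s), 0.1), parc)
  few <- sampleIntrinsicWindows(s, parc, k = 4L, window = 18, reps = 2L,
                                seed = 1L, shrinkage = 0.1)
  many <- sampleIntrinsicWindows(s, parc, k = 4L, window = 18, reps = 30L,
                                 seed = 1L, shrinkage = 0.1)
  gap <- function(f) mean(abs(featureValues(f) - featureValues(full)))
  expect_lt(gap(many), gap(few) + 0.05)
})
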