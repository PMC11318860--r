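test_that("exact correlation p-values behave at the extremes and at the n=11 boundary", {
  x <- 1:10
  perfect <- pearsonRP(x, 2 * x + 3)
  expect_equal(perfect$statistic, 1)
  expect_lt(perfect$p, 1e-10)

  set.seed(20)
  a <- rnorm(10)
  b <- residuals(lm(rnorm(10) ~ a))  # constructed orthogonal
  orth <- pearsonRP(a, b, sided = "two")
  expect_equal(orth$statistic, 0, tolerance = 1e-10)
  expect_equal(orth$p, 1, tolerance = 1e-6)

  ## replication boundary: r = 0.52 at n = 11, one-sided, sits at p ~ .05
  set.seed(21)
  x11 <- rnorm(11L)
  e <- residuals(lm(rnorm(11L) ~ x11))
  y11 <- 0.52 * scale(x11)[, 1L] + sqrt(1 - 0.52^2) * scale(e)[, 1L]
  bnd <- pearsonRP(x11, y11, sided = "one")
  expect_equal(bnd$statistic, 0.52, tolerance = 1e-10)
  expect_gt(bnd$p, 0.045)
  expect_lt(bnd$p, 0.055)

  deg <- pearsonRP(rep(1, 5L), rnorm(5L))
  expect_true(deg$degenerate)
})

test_that("two-sided p equals twice the one-sided p for positive correlations", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(15L); y <- x + rnorm(15L, 0, 2)
    if (cor(x, y) <= 0) next
    expect_equal(pearsonRP(x, y, "two")$p,
                 2 * pearsonRP(x, y, "one")$p, tolerance = 1e-12)
  }
})

test_that("critical correlations invert the exact test", {
  expect_equal(round(criticalR(11, 0.05, "one"), 2), 0.52)
  expect_equal(criticalR(100, 0.5, "one"), 0, tolerance = 1e-6)
  expect_equal(round(criticalR(3, 0.05, "one"), 3), 0.988)
  ## consistency: p at the critical r equals alpha
  for (n in c(5L, 11L, 40L)) {
    rc <- criticalR(n, 0.05, "two")
    expect_equal(chillconn:::rToP(rc, n, 0.05, "two"), 0.05,
                 tolerance = 1e-5)
  }
})

test_that("minimal-n search matches brute force and errors when out of range", {
  expect_equal(minNForR(0.53, 0.05, "one"), 11L)
  expect_equal(minNForR(0.9999, 0.05, "one"), 3L)
  ## brute-force cross-check on a mid-size correlation
  r <- 0.3
  nBrute <- 3L
  while (criticalR(nBrute, 0.05, "one") > r) nBrute <- nBrute + 1L
  expect_equal(minNForR(r, 0.05, "one"), nBrute)
  expect_error(minNForR(0.01, 0.05, "one", nMax = 20L), "bounded-search")
})

test_that("permutation p has the +1 correction and is seeded", {
  cvFun <- function(X, y) cor(X[, 1L], y)
  set.seed(23)
  X <- matrix(rnorm(20), 20L, 1L)
  y <- X[, 1L] * 3 + rnorm(20, 0, 0.01)  # observed beats every permutation
  pt <- permutationTest(cvFun, X, y, nPerm = 99L, seed = 3L)
  expect_equal(pt$p, 1 / 100)
  pt2 <- permutationTest(cvFun, X, y, nPerm = 99L, seed = 3L)
  expect_equal(pt$null, pt2$null)
  expect_gt(pt$p, 0)
})

test_that("BH step-up agrees with a brute-force implementation on short p-vectors", {
  bruteBH <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    thresh <- which(p[o] <= alpha * seq_len(m) / m)
    reject <- logical(m)
    if (length(thresh)) reject[o[seq_len(max(thresh))]] <- TRUE
    reject
  }
  grid <- c(0.005, 0.02, 0.05, 0.2, 0.6, 1)
  set.seed(24)
  for (len in 1:6) {
    for (rep in 1:40) {
      p <- sample(grid, len, replace = TRUE)
      mine <- bhFdr(p, 0.05)
      expect_identical(mine$reject, bruteBH(p, 0.05))
      expect_true(all(diff(sort(mine$pAdjusted)[order(order(p))][order(p)]) >= -1e-12))
    }
  }
  expect_true(all(bhFdr(c(0.01, 0.02, 0.03, 0.04), 0.05)$reject))
  expect_identical(bhFdr(0.03)$pAdjusted, 0.03)
  expect_false(any(bhFdr(rep(1, 5L))$reject))
})

test_that("bootstrap comparison of dependent accuracies covers zero for identical models", {
  set.seed(25)
  y <- rnorm(38L)
  yhat <- y + rnorm(38L, 0, 0.5)
  same <- bootstrapCorrDiff(y, yhat, yhat, nBoot = 200L, seed = 5L)
  expect_equal(same$statistic, 0)
  expect_true(same$ci[1L] <= 0 && same$ci[2L] >= 0)

  strong <- y + rnorm(38L, 0, 0.2)
  noise <- rnorm(38L)
  excl <- vapply(1:10, function(b) {
    yb <- rnorm(38L)
    db <- bootstrapCorrDiff(yb, yb + rnorm(38L, 0, 0.2), rnorm(38L),
                            nBoot = 300L, seed = b)
    db$ci[1L] > 0
  }, TRUE)
  expect_gte(mean(excl), 0.8)

  r1 <- bootstrapCorrDiff(y, strong, noise, nBoot = 100L, seed = 9L)
  r2 <- bootstrapCorrDiff(y, strong, noise, nBoot = 100L, seed = 9L)
  expect_equal(r1$null, r2$null)
})

test_that("the accuracy-over-duration trend matches closed-form regression", {
  x <- seq(20, 40, by = 2)
  exact <- linearTrendR2(x, 0.01 * x + 0.1)
  expect_equal(exact$statistic, 1, tolerance = 1e-10)
  expect_equal(linearTrendR2(x, rep(0.4, 11L))$statistic, 0)
  set.seed(26)
  y <- 0.01 * x + rnorm(11L, 0, 0.02)
  res <- linearTrendR2(x, y)
  ## normal equations by hand
  b <- cov(x, y) / var(x); a <- mean(y) - b * mean(x)
  ssRes <- sum((y - a - b * x)^2); ssTot <- sum((y - mean(y))^2)
  expect_equal(res$statistic, 1 - ssRes / ssTot, tolerance = 1e-10)
  expect_equal(res$slope, b, tolerance = 1e-10)
})

test_that("per-edge paired tests flag only genuinely shifted edges", {
  parc <- simulateParcellation(c(auditory = 2L, reward = 2L))
  mkF <- function(vals) {
    mat <- matrix(0, 4L, 4L, dimnames = list(roiIds(parc), roiIds(parc)))
    mat[upper.tri(mat)] <- tanh(vals); mat <- mat + t(mat); diag(mat) <- 1
    selectEdges(mat, parc, "whole_brain")
  }
  set.seed(27)
  n <- 12L
  base <- lapply(seq_len(n), function(i) mkF(rnorm(6L, 0, 0.05)))
  same <- pairedEdgeTest(base, base)
  expect_false(any(same$reject))

  shifted <- lapply(base, function(f) {
    v <- featureValues(f)
    v[2L] <- v[2L] + 0.5 + rnorm(1L, 0, 0.05)
    mkF(v)
  })
  res <- pairedEdgeTest(base, shifted)
  expect_true(res$reject[2L])
  expect_equal(sum(res$reject), 1L)
  ## t equals the hand formula
  A <- t(vapply(base, featureValues, numeric(6L)))
  B <- t(vapply(shifted, featureValues, numeric(6L)))
  d <- (A - B)[, 2L]
  expect_equal(res$t[2L], mean(d) / (sd(d) / sqrt(n)), tolerance = 1e-10)
})
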