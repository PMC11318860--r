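test_that("extreme penalties give the null and least-squares solutions", {
  set.seed(10)
  X <- matrix(rnorm(30 * 4), 30L, 4L)
  colnames(X) <- letters[1:4]
  y <- rnorm(30, 10, 3)
  big <- lassoFit(X, y, 1e6)
  expect_equal(unname(modelWeights(big)), rep(0, 4L))
  expect_equal(big@intercept, mean(y))

  ols <- lassoFit(X, y, 0)
  xs <- scale(X, scale = apply(X, 2L, function(c) sqrt(mean((c - mean(c))^2))))
  ref <- coef(lm(y ~ xs))
  expect_equal(unname(modelWeights(ols)), unname(ref[-1L]), tolerance = 1e-5)
  expect_equal(predict(ols, X), unname(fitted(lm(y ~ xs))), tolerance = 1e-5)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  n <- 64L
  ## zero-mean orthogonal columns with unit population SD: standardisation
  ## inside the fit is then the identity and the subgradient solution is
  ## exactly the soft threshold of the per-feature OLS coefficients
  set.seed(30)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 6), n, 6L))))[, -1L]
  X <- Q * sqrt(n)
  colnames(X) <- sprintf("f%d", 1:6)
  set.seed(11)
  y <- rnorm(n, 0, 2)
  beta <- crossprod(X, y - mean(y)) / n
  for (lam in c(0.01, 0.1, 0.5)) {
    fit <- lassoFit(X, y, lam)
    softRef <- sign(beta) * pmax(abs(beta) - lam, 0)
    expect_equal(unname(modelWeights(fit)), as.numeric(softRef),
                 tolerance = 1e-4)
  }
})

test_that("the coordinate-descent objective matches an independent LASSO solver", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  X <- matrix(rnorm(40 * 10), 40L, 10L)
  colnames(X) <- sprintf("f%d", 1:10)
  y <- X[, 1L] * 2 + rnorm(40)
  lam <- 0.2
  mine <- lassoFit(X, y, lam)
  obj <- function(w, b) {
    xs <- sweep(sweep(X, 2L, mine@center), 2L, mine@scale, "/")
    mean((y - b - xs %*% w)^2) / 2 + lam * sum(abs(w))
  }
  g <- glmnet::glmnet(X, y, lambda = lam, standardize = TRUE,
                      thresh = 1e-12)
  ## compare achieved objective values, not raw coefficients (scalers differ)
  xs <- sweep(sweep(X, 2L, mine@center), 2L, mine@scale, "/")
  objG <- mean((y - predict(g, X))^2) / 2 +
    lam * sum(abs(as.numeric(coef(g))[-1L] * apply(X, 2L, function(c)
      sqrt(mean((c - mean(c))^2)))))
  expect_equal(obj(mine@weights, mine@intercept), objG, tolerance = 1e-4)
})

test_that("nested leave-one-out recovers a strong single-feature signal", {
  set.seed(13)
  n <- 38L
  X <- matrix(rnorm(n * 38L), n, 38L)
  colnames(X) <- sprintf("f%d", 1:38)
  y <- 3 * X[, 1L] + rnorm(n, 0, 0.3)
  cv <- nestedLoocv(X, y)
  expect_gt(accuracyR(cv), 0.9)
  expect_length(cv@yPred, n)
  expect_true(all(cv@foldLambdas %in% defaultLambdaGrid()))
})

test_that("null designs give near-zero mean accuracy across replicates", {
  set.seed(14)
  accs <- vapply(1:12, function(b) {
    X <- matrix(rnorm(20 * 10), 20L, 10L)
    colnames(X) <- sprintf("f%d", 1:10)
    acc <- accuracyR(nestedLoocv(X, rnorm(20), control = fastCvControl()))
    ifelse(is.na(acc), 0, acc)
  }, 0)
  expect_gt(mean(accs), -0.25)
  expect_lt(mean(accs), 0.25)
})

test_that("held-out predictions never depend on the held-out target", {
  set.seed(15)
  n <- 12L
  X <- matrix(rnorm(n * 5), n, 5L)
  colnames(X) <- sprintf("f%d", 1:5)
  y <- X[, 1L] + rnorm(n, 0, 0.2)
  p1 <- nestedLoocv(X, y)@yPred
  yMut <- y; yMut[4L] <- yMut[4L] + 50
  p2 <- nestedLoocv(X, yMut)@yPred
  expect_equal(p1[4L], p2[4L], tolerance = 1e-10)
})

test_that("duplicated trials get identical predictions from the trial-level model", {
  set.seed(16)
  X <- matrix(rnorm(10 * 4), 10L, 4L)
  colnames(X) <- sprintf("f%d", 1:4)
  y <- X[, 1L] + rnorm(10, 0, 0.1)
  Xd <- rbind(X, X[3L, , drop = FALSE])
  rownames(Xd) <- NULL
  cv <- nestedLotocv(Xd, c(y, y[3L]), unitIds = sprintf("t%02d", 1:11))
  expect_equal(cv@yPred[3L], cv@yPred[11L], tolerance = 1e-6)
})

test_that("the trial outlier screen is one-sided at +3 SD", {
  expect_true(all(trialOutlierFilter(rep(5, 10L))))
  y <- c(rnorm(300, 50, 5), 300)
  mask <- trialOutlierFilter(y)
  expect_false(mask[301L])
  expect_true(all(mask[1:300]))
  yLow <- c(rnorm(300, 50, 5), -300)
  expect_true(trialOutlierFilter(yLow)[301L])  # low extremes kept
})

test_that("the transfer model exports the planted support and round-trips exactly", {
  set.seed(17)
  n <- 38L; p <- 20L
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("edge%02d", seq_len(p))
  y <- 2 * X[, 1L] + 2 * X[, 2L] + rnorm(n, 0, 0.5)
  fit <- fitTransferModel(X, y)
  w <- modelWeights(fit)
  expect_true(all(w[c("edge01", "edge02")] != 0))
  expect_gt(mean(abs(w[1:2])), mean(abs(w[-(1:2)])))

  ## a model fit to noise targets carries no transferable signal
  yNull <- rnorm(n)
  null <- fitTransferModel(X, yNull)
  X2 <- matrix(rnorm(n * p), n, p); colnames(X2) <- colnames(X)
  expect_lt(abs(safeCorOr0(predict(null, X2), rnorm(n))), 0.4)

  path <- withr::local_tempfile(fileext = ".json")
  exportModel(fit, path)
  back <- importModel(path)
  expect_equal(modelWeights(back), w)
  expect_equal(back@lambda, fit@lambda)
  expect_equal(predict(back, X), predict(fit, X))
})

test_that("transfer prediction is a scaler-aware dot product with strict edge alignment", {
  set.seed(18)
  X <- matrix(rnorm(20 * 5), 20L, 5L)
  colnames(X) <- sprintf("e%d", 1:5)
  y <- X[, 2L] + rnorm(20, 0, 0.2)
  fit <- fitTransferModel(X, y)
  expect_equal(transferPredict(fit, X), predict(fit, X))
  ## column order must not matter
  expect_equal(transferPredict(fit, X[, 5:1]), predict(fit, X))
  bad <- X[, 1:4]
  expect_error(transferPredict(fit, bad), "alignment")
  zero <- lassoFit(X, y, 1e6)
  expect_equal(sd(predict(zero, X)), 0)
})

test_that("window sweeps produce the documented window families", {
  coh <- .sharedCohort
  cum <- windowSweep(coh, durations = seq(20, 40, by = 2),
                     control = fastCvControl())
  expect_equal(nrow(cum), 11L)
  expect_equal(cum$duration, seq(20, 40, by = 2))
  expect_equal(cum$end, rep(40, 11L))

  sli <- windowSweep(coh, mode = "sliding", width = 26, step = 2,
                     control = fastCvControl())
  expect_equal(nrow(sli), 8L)
  expect_equal(sli$start, seq(0, 14, by = 2))
  expect_equal(sli$end, seq(26, 40, by = 2))
  expect_error(windowSweep(coh, durations = 60), "range")

  ## degenerate single full-epoch window equals plain nested CV
  one <- windowSweep(coh, durations = 40, control = fastCvControl())
  X <- participantFeatureMatrix(coh, window = c(0, 40))
  ref <- nestedLoocv(X, chillsTargets(coh)$participant,
                     control = fastCvControl())
  expect_equal(one$accuracy_r, accuracyR(ref), tolerance = 1e-10)
})

test_that("the learning curve at fraction 1 reproduces the full nested CV and is seeded", {
  coh <- .sharedCohort
  X <- participantFeatureMatrix(coh)
  y <- chillsTargets(coh)$participant
  lc <- learningCurve(X, y, fractions = c(0.5, 1), reps = 3L, seed = 4L,
                      control = fastCvControl())
  full <- accuracyR(nestedLoocv(X, y, control = fastCvControl()))
  expect_equal(lc$mean_accuracy[lc$fraction == 1], full)
  lc2 <- learningCurve(X, y, fractions = c(0.5, 1), reps = 3L, seed = 4L,
                       control = fastCvControl())
  expect_equal(lc, lc2)
})

test_that("trial-level epoch variants produce the documented trial counts", {
  coh <- .sharedCohort  # 16 participants x 4 trials, one session of 4
  pre <- trialFeatureMatrix(coh, variant = "rest_preceding")
  expect_equal(nrow(pre$X), 16L * 4L)
  expect_equal(ncol(pre$X), 16L)  # 4 auditory x 4 reward edges

  mus <- trialFeatureMatrix(coh, variant = "music_fc")
  expect_equal(nrow(mus$X), 16L * 4L)
  expect_identical(colnames(mus$X), colnames(pre$X))

  ## the last trial of each session has no following rest epoch
  post <- trialFeatureMatrix(coh, variant = "rest_following",
                             sessionSize = 2L)
  expect_equal(nrow(post$X), 16L * 2L)
  expect_false(any(grepl("trial-02$|trial-04$", post$units)))

  ## trial-level targets line up with the planted effect direction
  tgt <- chillsTargets(coh)
  yTrial <- as.numeric(t(tgt$trial))
  expect_gt(cor(rowMeans(pre$X), yTrial), 0.2)
})

test_that("across replicate cohorts the planted pair outranks every other network pair", {
  accs <- NULL
  for (s in c(61L, 62L, 63L, 64L, 65L, 66L)) {
    coh <- simulateCohort(simulationConfig(roisPerNetwork = deskNetworkCounts(),
                                           seed = s), physio = FALSE)
    zl <- participantZMatrices(coh)
    y <- chillsTargets(coh)$participant
    pairs <- listNetworkPairs(parcellation(coh))
    a <- vapply(seq_len(nrow(pairs)), function(k) {
      X <- edgeFeatureMatrix(zl, parcellation(coh),
                             networks = c(pairs$netA[k], pairs$netB[k]))
      r <- accuracyR(nestedLoocv(X, y, control = fastCvControl()))
      ifelse(is.na(r), 0, r)
    }, 0)
    accs <- rbind(accs, a)
  }
  meanAcc <- colMeans(accs)
  pairs <- listNetworkPairs(simulateParcellation(deskNetworkCounts()))
  ar <- which(pairs$netA == "auditory" & pairs$netB == "reward")
  expect_equal(which.max(meanAcc), ar)
  expect_gt(meanAcc[ar], max(meanAcc[-ar]))
})
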