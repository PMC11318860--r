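test_that("linear detrending removes trends exactly and is an orthogonal projection", {
  n <- 40L
  tt <- seq_len(n)
  x <- cbind(2 * tt + 5, rnorm(n))
  s <- roiSeries(x)
  out <- signalMatrix(detrendLinear(s))
  expect_equal(max(abs(out[, 1L])), 0, tolerance = 1e-10)
  expect_equal(sum(out[, 2L]), 0, tolerance = 1e-8)
  expect_equal(sum(out[, 2L] * tt), 0, tolerance = 1e-6)
  expect_equal(signalMatrix(detrendLinear(detrendLinear(s))),
               signalMatrix(detrendLinear(s)), tolerance = 1e-10)
  expect_error(detrendLinear(roiSeries(x[1:2, , drop = FALSE])),
               "insufficient")
})

test_that("band-pass keeps the passband, kills the stopband and removes DC", {
  tr <- 2; n <- 500L
  tt <- (seq_len(n) - 1L) * tr
  mk <- function(f) roiSeries(matrix(sin(2 * pi * f * tt), n, 1L), tr = tr)
  inBand <- signalMatrix(bandpass(mk(0.05), 0.008, 0.09))[, 1L]
  expect_gt(fftAmp(inBand, 0.05, tr), 0.95)
  expect_lt(fftAmp(inBand, 0.05, tr), 1.05)
  outBand <- signalMatrix(bandpass(mk(0.2), 0.008, 0.09))[, 1L]
  expect_lt(fftAmp(outBand, 0.2, tr), 0.2)
  const <- signalMatrix(bandpass(roiSeries(matrix(1, n, 1L), tr = tr)))[, 1L]
  expect_lt(max(abs(const)), 1e-6)
  expect_error(bandpass(mk(0.05), 0.008, 0.3), "Nyquist")
})

test_that("high-pass removes constants, keeps slow passband content, can restore mean levels", {
  tr <- 2; n <- 500L
  tt <- (seq_len(n) - 1L) * tr
  const <- roiSeries(matrix(5, n, 1L), tr = tr)
  expect_lt(max(abs(signalMatrix(highpass(const, 0.008)))), 1e-6)
  s <- roiSeries(matrix(100 + sin(2 * pi * 0.05 * tt), n, 1L), tr = tr)
  y <- signalMatrix(highpass(s, 0.008))[, 1L]
  expect_gt(fftAmp(y, 0.05, tr), 0.95)
  yk <- signalMatrix(highpass(s, 0.008, keepMean = TRUE))[, 1L]
  expect_equal(mean(yk), 100, tolerance = 0.5)
  expect_error(highpass(s, 0.3), "band")
})

test_that("confound regression projects onto the orthogonal complement", {
  n <- 30L
  x <- matrix(rnorm(n * 2), n, 2L)
  s <- roiSeries(x)
  expect_lt(max(abs(signalMatrix(regressConfounds(s, x)))), 1e-8)
  expect_identical(signalMatrix(regressConfounds(s, matrix(0, n, 0L))),
                   signalMatrix(s))
  c1 <- rnorm(n)
  e <- residuals(lm(rnorm(n) ~ 0 + c1))
  y <- roiSeries(matrix(3 * c1 + e, n, 1L))
  out <- signalMatrix(regressConfounds(y, matrix(c1)))[, 1L]
  expect_equal(out, as.numeric(e), tolerance = 1e-8)
  expect_warning(regressConfounds(s, cbind(c1, 2 * c1)), "rank-deficient")
})

test_that("window extraction follows the half-open onset-time convention", {
  s <- roiSeries(matrix(rnorm(25 * 2), 25L, 2L), tr = 2)
  expect_equal(nrow(signalMatrix(extractWindow(s, 10, 50))), 20L)
  expect_equal(nrow(signalMatrix(extractWindow(s, 0, 2))), 1L)
  expect_error(extractWindow(s, 0, 0), "range")
  expect_error(extractWindow(s, 10, 60), "range")
  ## a volume belongs to the window containing its onset
  expect_equal(signalMatrix(extractWindow(s, 2, 6)),
               signalMatrix(s)[2:3, , drop = FALSE])
})

test_that("physiological band filtering behaves like the BOLD filters at native rate", {
  rate <- 100; n <- 5000L
  tt <- (seq_len(n) - 1L) / rate
  mk <- function(f) new("PhysioTrace", channel = "ppg", rate = rate,
                        samples = sin(2 * pi * f * tt))
  y <- filterPhysio(mk(5), 1, 35)@samples
  expect_gt(fftAmp(y, 5, 1 / rate), 0.95)
  y2 <- filterPhysio(mk(0.2), 1, 35)@samples
  expect_lt(fftAmp(y2, 0.2, 1 / rate), 0.2)
  const <- new("PhysioTrace", channel = "eda", rate = rate,
               samples = rep(2, n))
  expect_lt(max(abs(filterPhysio(const, 0.05, 1)@samples)), 1e-6)
  expect_error(filterPhysio(mk(5), 1, 60), "Nyquist")
})

test_that("temporal operators are linear and phase-free", {
  tr <- 2; n <- 300L
  x1 <- matrix(rnorm(n), n, 1L); x2 <- matrix(rnorm(n), n, 1L)
  f <- function(x) signalMatrix(bandpass(roiSeries(x, tr = tr), 0.008, 0.09))
  lhs <- f(2 * x1 + 3 * x2)
  rhs <- 2 * f(x1) + 3 * f(x2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  ## zero-phase: cross-correlation peak of a passband sinusoid at lag 0
  tt <- (seq_len(n) - 1L) * tr
  x <- matrix(sin(2 * pi * 0.05 * tt), n, 1L)
  y <- f(x)[, 1L]
  cc <- ccf(y, x[, 1L], lag.max = 4, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})
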