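pulseTrace <- function(beatTimes, dur, rate = 100) {
  n <- floor(dur * rate)
  imp <- numeric(n)
  imp[pmax(1L, pmin(n, round(beatTimes * rate) + 1L))] <- 1
  kt <- seq(-0.2, 0.2, by = 1 / rate)
  kern <- exp(-0.5 * (kt / 0.04)^2)
  pad <- c(numeric(length(kern)), imp, numeric(length(kern)))
  v <- as.numeric(stats::filter(pad, kern, sides = 2))[length(kern) + seq_len(n)]
  new("PhysioTrace", channel = "ppg", rate = rate, samples = v)
}

test_that("constant inter-beat intervals recover the programmed heart rate", {
  tr60 <- pulseTrace(seq(0.5, 59.5, by = 1), 60)
  hr <- rateFromPeaks(tr60)
  expect_equal(hr@measure, "hr")
  expect_lt(max(abs(featureValues(hr) - 60)), 0.1)

  tr120 <- pulseTrace(seq(0.25, 59.75, by = 0.5), 60)
  expect_lt(max(abs(featureValues(rateFromPeaks(tr120)) - 120)), 0.1)
})

test_that("drifting inter-beat intervals give a monotone rate series", {
  ibis <- seq(0.6, 1.2, length.out = 40L)
  beats <- cumsum(c(0.5, ibis))
  tr <- pulseTrace(beats, max(beats) + 1)
  hr <- featureValues(rateFromPeaks(tr))
  expect_lt(mean(diff(hr) > 0), 0.05)  # rate falls as IBI grows
  expect_error(rateFromPeaks(pulseTrace(c(1, 2), 4)), "insufficient peaks")
})

test_that("the phasic driver inverts its own forward model and keeps the threshold rule", {
  rate <- 10
  n <- 600L
  zero <- new("PhysioTrace", channel = "eda", rate = rate,
              samples = rep(0, n))
  expect_equal(featureValues(scrPhasicDriver(zero)), rep(0, n))

  kern <- scrImpulseResponse(seq(0, 20, by = 1 / rate), 0.75, 2,
                             normalize = "peak")
  mkResponse <- function(amp, at) {
    imp <- numeric(n); imp[round(at * rate) + 1L] <- amp
    pad <- stats::filter(c(numeric(length(kern)), imp), kern, sides = 1)
    new("PhysioTrace", channel = "eda", rate = rate,
        samples = as.numeric(pad)[length(kern) + seq_len(n)])
  }
  drv <- scrPhasicDriver(mkResponse(0.5, 30))
  d <- featureValues(drv)
  expect_gt(max(d), 0)
  tPeak <- (which.max(d) - 1L) / rate
  expect_lt(abs(tPeak - 30), 0.5)
  rec <- attr(drv, "reconstruction")
  x <- mkResponse(0.5, 30)@samples
  expect_lt(sqrt(sum((rec - (x - min(x)))^2)) / sqrt(sum(x^2)), 0.1)

  sub <- scrPhasicDriver(mkResponse(0.02, 30))
  expect_equal(max(featureValues(sub)), 0)
  expect_error(scrPhasicDriver(zero, tau1 = 2, tau2 = 1), "tau1 < tau2")
})

test_that("event-locked sums are baseline-corrected, outlier-screened and additive", {
  rate <- 10
  n <- 1200L
  tt <- (seq_len(n) - 1L) / rate
  mkSeries <- function(v) new("RateSeries", rate = rate, values = v,
                              start = 0, measure = "hr")
  ev3 <- eventTrain(c(10, 40, 70), c(10, 10, 10), rep("chill", 3L), 120)

  const <- eventLockedSum(mkSeries(rep(70, n)), ev3)
  expect_equal(const$perEvent$response, rep(0, 3L))
  expect_equal(const$total, 0)

  step <- rep(70, n)
  step[tt >= 10 & tt < 20] <- 71
  one <- eventLockedSum(mkSeries(step), eventTrain(10, 10, "chill", 120))
  expect_equal(one$perEvent$response, 100)  # 10 s x 10 Hz x 1 unit

  ## an extreme event is excluded by the 3-SD screen (enough events that a
  ## single outlier cannot mask itself by inflating the SD)
  set.seed(1)
  base <- 70 + rnorm(n, 0, 0.01)
  onsets <- seq(4, 109, by = 7)  # 16 events
  evs <- eventTrain(onsets, rep(4, length(onsets)),
                    rep("chill", length(onsets)), 120)
  spiky <- base
  spiky[tt >= onsets[8L] & tt < onsets[8L] + 4] <-
    spiky[tt >= onsets[8L] & tt < onsets[8L] + 4] + 50
  res <- eventLockedSum(mkSeries(spiky), evs)
  expect_true(res$perEvent$excluded[8L])
  expect_equal(sum(res$perEvent$excluded), 1L)

  ## additivity over disjoint events
  two <- eventLockedSum(mkSeries(step), ev3)
  singles <- vapply(c(10, 40, 70), function(o)
    eventLockedSum(mkSeries(step), eventTrain(o, 10, "chill", 120))$perEvent$response, 0)
  expect_equal(two$perEvent$response, singles)

  ## early events are skipped with a warning; SCR totals can be log(1+x)
  expect_warning(sk <- eventLockedSum(mkSeries(step),
                                      eventTrain(0.5, 5, "chill", 120)),
                 "skipped")
  expect_true(sk$perEvent$skipped[1L])
  lg <- eventLockedSum(mkSeries(step), eventTrain(10, 10, "chill", 120),
                       logTransform = TRUE)
  expect_equal(lg$total, log1p(100))
})
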