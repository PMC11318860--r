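## Heart-rate / respiration-rate derivation, a simplified phasic
## skin-conductance deconvolution, and event-locked quantification.

findSignalPeaks <- function(x, rate, minDistance) {
  thr <- mean(x) + 0.5 * sd(x)
  n <- length(x)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                x[2:(n - 1L)] >= x[3:n] &
                x[2:(n - 1L)] > thr) + 1L
  if (!length(cand)) return(integer(0))
  ## greedy minimum-distance enforcement, keeping the larger peak
  keep <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(keep) || all(abs(i - keep) >= minDistance * rate))
      keep <- c(keep, i)
  }
  sort(keep)
}

#' Instantaneous rate series from a peak-bearing trace
#'
#' Detects successive peaks (pulse waves or breaths) in a filtered trace,
#' converts inter-event intervals to an instantaneous rate
#' (60000 / IBI_ms, i.e. bpm or breaths/min) located at the closing peak
#' of each interval, and cubic-spline interpolates onto a uniform grid
#' (10 Hz by default).
#'
#' @param trace a filtered \linkS4class{PhysioTrace}.
#' @param minDistance minimum peak separation, seconds (default 0.3 for
#'   ppg, 1.5 otherwise).
#' @param outRate output grid rate in Hz.
#' @return a \linkS4class{RateSeries} covering the detected-peak span.
#' @export
rateFromPeaks <- function(trace, minDistance = NULL, outRate = 10) {
  if (is.null(minDistance))
    minDistance <- if (trace@channel == "ppg") 0.3 else 1.5
  pk <- findSignalPeaks(trace@samples, trace@rate, minDistance)
  if (length(pk) < 3L)
    stop("insufficient peaks: found ", length(pk), ", need >= 3")
  tpk <- (pk - 1L) / trace@rate
  ibiMs <- diff(tpk) * 1000
  rateVals <- 60000 / ibiMs
  tRate <- tpk[-1L]
  grid <- seq(tRate[1L], tRate[length(tRate)], by = 1 / outRate)
  vals <- splinefun(tRate, rateVals, method = "natural")(grid)
  measure <- switch(trace@channel, ppg = "hr", respiration = "rr", "rate")
  if (measure == "hr" && any(vals < 20 | vals > 250))
    warning("heart-rate values outside the (20, 250) bpm plausibility band")
  new("RateSeries", rate = outRate, values = vals, start = grid[1L],
      measure = measure)
}

## running-minimum tonic baseline, then lightly smoothed
tonicBaseline <- function(x, rate, window = 20, smooth = 5) {
  n <- length(x)
  half <- max(1L, round(window * rate / 2))
  runmin <- vapply(seq_len(n), function(i)
    min(x[max(1L, i - half):min(n, i + half)]), 0)
  k <- max(1L, round(smooth * rate))
  kern <- rep(1 / k, k)
  pad <- c(rep(runmin[1L], k), runmin, rep(runmin[n], k))
  as.numeric(stats::filter(pad, kern, sides = 2))[seq_len(n) + k]
}

convCausal <- function(x, kern) {
  pad <- length(kern)
  y <- stats::filter(c(numeric(pad), x), kern, sides = 1)
  as.numeric(y)[pad + seq_along(x)]
}

#' Phasic skin-conductance driver by regularised deconvolution
#'
#' A documented simplified stand-in for continuous decomposition analysis:
#' after low-pass filtering (1 Hz), downsampling to 10 Hz and removal of a
#' running-minimum tonic baseline, the nonnegative driver minimising
#' \code{||K d - x||^2 + lambda ||D d||^2} (K = convolution with the
#' Bateman impulse response, D = first differences) is found by projected
#' accelerated gradient descent. Driver excursions whose reconvolved
#' response peak falls below \code{threshold} (default 0.05 microsiemens,
#' the conventional minimum for an unambiguous response) are zeroed.
#'
#' @param trace an eda \linkS4class{PhysioTrace}.
#' @param tau1,tau2 Bateman rise/decay constants, seconds.
#' @param threshold minimum response amplitude retained, microsiemens.
#' @param lambda Tikhonov smoothing weight.
#' @param maxIter gradient iterations.
#' @return a \linkS4class{RateSeries} (10 Hz) holding the thresholded
#'   driver, with the reconvolved phasic signal in
#'   \code{attr(, "reconstruction")}.
#' @export
scrPhasicDriver <- function(trace, tau1 = 0.75, tau2 = 2, threshold = 0.05,
                            lambda = 1e-2, maxIter = 400L) {
  if (!(tau1 > 0 && tau2 > tau1))
    stop("invalid config: need 0 < tau1 < tau2")
  if (trace@channel != "eda") stop("expected an eda trace")
  x <- trace@samples; rate <- trace@rate
  if (rate > 10) {
    if (rate > 2.5) {
      filt <- signal::butter(2, min(1, rate / 2 * 0.9) / (rate / 2), "low")
      x <- zeroPhaseFilter(matrix(x), filt)[, 1L]
    }
    idx <- seq(1, length(x), by = rate / 10)
    x <- approx(seq_along(trace@samples), x, idx)$y
    rate <- 10
  }
  if (all(abs(x - x[1L]) < 1e-12)) {
    d <- numeric(length(x))
    out <- new("RateSeries", rate = rate, values = d, start = 0,
               measure = "scr")
    attr(out, "reconstruction") <- d
    return(out)
  }
  phasic <- x - tonicBaseline(x, rate)
  kern <- scrImpulseResponse(seq(0, 20, by = 1 / rate), tau1, tau2,
                             normalize = "peak")
  Kf <- function(d) convCausal(d, kern)
  Kt <- function(z) rev(convCausal(rev(z), kern))
  n <- length(phasic)
  ## Lipschitz bound via power iteration on K^T K + lambda D^T D
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  L <- 1
  for (i in 1:12) {
    w <- Kt(Kf(v)) + lambda * diffPenaltyGrad(v)
    L <- sqrt(sum(w^2)); v <- w / max(L, 1e-12)
  }
  L <- max(L * 1.2, 1e-6)
  d <- numeric(n); y <- d; tPrev <- 1
  for (it in seq_len(maxIter)) {
    grad <- Kt(Kf(y) - phasic) + lambda * diffPenaltyGrad(y)
    dNew <- pmax(0, y - grad / L)
    tNew <- (1 + sqrt(1 + 4 * tPrev^2)) / 2
    y <- dNew + (tPrev - 1) / tNew * (dNew - d)
    d <- dNew; tPrev <- tNew
  }
  ## zero excursions whose reconvolved peak is below threshold
  active <- d > max(d, 0) * 1e-3
  if (any(active)) {
    runs <- rle(active)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (g in which(runs$values)) {
      seg <- numeric(n)
      seg[starts[g]:ends[g]] <- d[starts[g]:ends[g]]
      if (max(Kf(seg)) < threshold) d[starts[g]:ends[g]] <- 0
    }
  }
  out <- new("RateSeries", rate = rate, values = d, start = 0,
             measure = "scr")
  attr(out, "reconstruction") <- Kf(d)
  out
}

diffPenaltyGrad <- function(d) {
  ## gradient of ||D d||^2 / 2 with D = first differences
  n <- length(d)
  dd <- diff(d)
  c(-dd, 0) + c(0, dd)
}

#' Event-locked baseline-corrected response totals
#'
#' For each event of the requested label: the mean of the series in the
#' 1-s window before onset is the baseline, and the response is the sum of
#' (value - baseline) over the event window. Events whose response deviates
#' more than \code{outlierSd} SDs from the mean response (across events)
#' are excluded; exclusions are recorded, not silently dropped. SCR totals
#' may be log(1+x) transformed.
#'
#' @param series a \linkS4class{RateSeries}.
#' @param events an \linkS4class{EventTrain}.
#' @param label event label to quantify (default "chill").
#' @param baselineWindow pre-onset baseline length, seconds.
#' @param outlierSd exclusion threshold in SD units.
#' @param logTransform apply log(1 + x) to the surviving-event total.
#' @return list with perEvent (onset, response, excluded, skipped), total,
#'   nUsed, logTransformed.
#' @export
eventLockedSum <- function(series, events, label = "chill",
                           baselineWindow = 1, outlierSd = 3,
                           logTransform = FALSE) {
  ev <- events@events
  ev <- ev[ev$label == label, , drop = FALSE]
  n <- length(series@values)
  tEnd <- series@start + (n - 1L) / series@rate
  resp <- rep(NA_real_, nrow(ev)); skipped <- logical(nrow(ev))
  for (e in seq_len(nrow(ev))) {
    if (ev$onset[e] - baselineWindow < series@start - 1e-9) {
      warning("event at ", ev$onset[e],
              " s starts too early for its baseline window; skipped")
      skipped[e] <- TRUE
      next
    }
    idx <- function(t0, t1) {
      i <- which(series@start + (seq_len(n) - 1L) / series@rate >= t0 - 1e-9 &
                 series@start + (seq_len(n) - 1L) / series@rate < t1 - 1e-9)
      i
    }
    base <- mean(series@values[idx(ev$onset[e] - baselineWindow, ev$onset[e])])
    win <- idx(ev$onset[e], min(ev$onset[e] + ev$duration[e], tEnd + 1 / series@rate))
    resp[e] <- sum(series@values[win] - base)
  }
  ok <- !skipped
  excluded <- logical(nrow(ev))
  if (sum(ok) >= 3L) {
    m <- mean(resp[ok]); s <- sd(resp[ok])
    if (is.finite(s) && s > 0)
      excluded[ok] <- abs(resp[ok] - m) > outlierSd * s
  }
  used <- ok & !excluded
  total <- sum(resp[used])
  if (logTransform) total <- log1p(max(total, 0))
  list(perEvent = data.frame(onset = ev$onset, duration = ev$duration,
                             response = resp, excluded = excluded,
                             skipped = skipped),
       total = total, nUsed = sum(used), logTransformed = logTransform)
}
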