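## Synthetic cohorts with a known planted coupling between pre-listening
## auditory-reward connectivity and the duration of music-evoked chills.

#' Default network sizes of the study parcellation
#'
#' 288 ROIs across 13 functional networks, including 12 auditory ROIs
#' (6 per hemisphere) and 8 reward ROIs (4 per hemisphere).
#'
#' @return named integer vector of ROI counts per network.
#' @export
defaultNetworkCounts <- function() {
  c(auditory = 12L, reward = 8L, visual = 39L, somatomotor = 38L,
    default_mode = 40L, frontoparietal = 28L, cingulo_opercular = 30L,
    dorsal_attention = 22L, ventral_attention = 18L, salience = 16L,
    subcortical = 17L, cerebellum = 12L, medial_temporal = 8L)
}

#' Construct a SimulationConfig
#'
#' Defaults encode the study conditions the simulator emulates: 38
#' participants, 8 trials, TR = 2 s, 40-s pre-listening rest, 270-s music
#' epochs, and a linear coupling between a participant-level latent
#' auditory-reward connectivity score and chills duration (baseline 50 s).
#'
#' @param nParticipants,nTrials cohort size and trials per participant.
#' @param tr repetition time, seconds.
#' @param restDuration,musicDuration epoch durations, seconds.
#' @param roisPerNetwork named counts of ROIs per network; must contain
#'   \code{auditory} (even count) and \code{reward}.
#' @param effectSize planted slope, seconds of chills per z-unit of coupling.
#' @param couplingSd between-participant SD of the latent coupling.
#' @param trialCouplingSd within-participant (trial-level) SD of the coupling.
#' @param baselineDuration mean chills duration (s) at zero coupling.
#' @param obsNoiseSd per-trial behavioural noise SD, seconds.
#' @param physioRate physiological sampling rate, Hz.
#' @param seed integer seed controlling all randomness.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nParticipants = 38L, nTrials = 8L, tr = 2,
                             restDuration = 40, musicDuration = 270,
                             roisPerNetwork = defaultNetworkCounts(),
                             effectSize = 30, couplingSd = 1,
                             trialCouplingSd = 0.3, baselineDuration = 50,
                             obsNoiseSd = 30, physioRate = 100, seed = 1L) {
  cfg <- new("SimulationConfig", nParticipants = as.integer(nParticipants),
             nTrials = as.integer(nTrials), tr = tr,
             restDuration = restDuration, musicDuration = musicDuration,
             roisPerNetwork = setNames(as.integer(roisPerNetwork),
                                       names(roisPerNetwork)),
             effectSize = effectSize, couplingSd = couplingSd,
             obsNoiseSd = obsNoiseSd, physioRate = physioRate,
             seed = as.integer(seed))
  attr(cfg, "trialCouplingSd") <- trialCouplingSd
  attr(cfg, "baselineDuration") <- baselineDuration
  cfg
}

#' Simulate a parcellation
#'
#' Assigns ROI identifiers to networks and hemispheres. Auditory ROIs are
#' split evenly between left and right; other networks alternate L/R.
#' Ordering is deterministic given the input map and seed.
#'
#' @param roisPerNetwork named counts of ROIs per network.
#' @param seed integer (kept for interface stability; the assignment is
#'   fully deterministic).
#' @return a \linkS4class{ParcellationSpec}.
#' @export
simulateParcellation <- function(roisPerNetwork = defaultNetworkCounts(),
                                 seed = 1L) {
  if (!length(roisPerNetwork) || is.null(names(roisPerNetwork)))
    stop("roisPerNetwork must be a nonempty named vector")
  if ("auditory" %in% names(roisPerNetwork) &&
      roisPerNetwork[["auditory"]] %% 2L != 0L)
    stop("invalid config: auditory ROI count must be even ",
         "(split across hemispheres)")
  ids <- character(0); nets <- character(0); hemis <- character(0)
  for (net in names(roisPerNetwork)) {
    k <- as.integer(roisPerNetwork[[net]])
    if (k < 1L) stop("invalid config: every network needs >= 1 ROI")
    h <- if (net == "auditory") rep(c("L", "R"), each = k %/% 2L)
         else rep_len(c("L", "R"), k)
    cnt <- stats::ave(seq_len(k), h, FUN = seq_along)
    ids <- c(ids, sprintf("%s_%s_%02d", net, h, cnt))
    nets <- c(nets, rep(net, k))
    hemis <- c(hemis, h)
  }
  new("ParcellationSpec", roiIds = ids, network = nets, hemisphere = hemis)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Standard two-gamma HRF (peak near 5 s, undershoot near 15 s), zero at
#' t = 0 and decaying to zero for large t. Used to convolve chill-event
#' trains into simulated BOLD responses.
#'
#' @param t time in seconds (vectorised), t >= 0.
#' @return unitless response values.
#' @export
canonicalHrf <- function(t) {
  stopifnot(all(t >= 0))
  a1 <- 6; a2 <- 16; b <- 1; c <- 1 / 6
  g <- function(t, a) ifelse(t <= 0, 0,
    t^(a - 1) * b^a * exp(-b * t) / gamma(a))
  g(t, a1) - c * g(t, a2)
}

#' Biexponential (Bateman) skin-conductance impulse response
#'
#' \code{exp(-t/tau2) - exp(-t/tau1)} with rise constant \code{tau1} <
#' decay constant \code{tau2}; zero at t = 0 and nonnegative. The peak sits
#' at \code{log(tau2/tau1) * tau1 * tau2 / (tau2 - tau1)} seconds.
#'
#' @param t time in seconds (vectorised), t >= 0.
#' @param tau1,tau2 rise and decay time constants, 0 < tau1 < tau2.
#' @param normalize if \code{"peak"}, scale to unit peak amplitude so that
#'   impulse amplitudes are response amplitudes in the same units.
#' @return unitless (or unit-peak) response values.
#' @export
scrImpulseResponse <- function(t, tau1 = 0.75, tau2 = 2,
                               normalize = c("none", "peak")) {
  normalize <- match.arg(normalize)
  if (!(tau1 > 0 && tau2 > tau1))
    stop("invalid config: need 0 < tau1 < tau2")
  y <- exp(-t / tau2) - exp(-t / tau1)
  y[t < 0] <- 0
  if (normalize == "peak") {
    tpk <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
    y <- y / (exp(-tpk / tau2) - exp(-tpk / tau1))
  }
  y
}

## ---- internal generative pieces ----

## Base covariance: within-network r = 0.3, cross-network r = 0 (the
## planted auditory-reward edges sit at 0.1 before modulation). A dense
## cross-network base would let the planted perturbation leak into every
## network pair's partial correlations through the precision matrix,
## destroying the localisation the decoding analysis is meant to detect.
baseCovarianceTemplate <- function(parc) {
  net <- parc@network
  same <- outer(net, net, "==")
  sig <- matrix(0, length(net), length(net))
  sig[same] <- 0.3
  diag(sig) <- 1
  sig[plantedEdgeIndices(parc)] <- 0.1
  sig[plantedEdgeIndices(parc)[, c(2, 1)]] <- 0.1
  dimnames(sig) <- list(parc@roiIds, parc@roiIds)
  sig
}

## Cross auditory-reward edges as index pairs (i < j in parcellation order).
plantedEdgeIndices <- function(parc) {
  aud <- which(parc@network == "auditory")
  rew <- which(parc@network == "reward")
  idx <- expand.grid(i = aud, j = rew)
  cbind(pmin(idx$i, idx$j), pmax(idx$i, idx$j))
}

## Latent coupling acts multiplicatively on the cross-network base entry of
## the planted auditory-reward edges, clipped to the largest uniform
## cross-block correlation the within-network structure can support: for
## blocks of nA and nB ROIs with within-network r = w, the uniform modes
## give PD iff rho^2 nA nB < (1 + (nA-1) w)(1 + (nB-1) w).
modulatedCovariance <- function(sigBase, planted, coupling, within = 0.3) {
  nA <- length(unique(planted[, 1L])); nB <- length(unique(planted[, 2L]))
  rMax <- 0.95 * sqrt((1 + (nA - 1) * within) * (1 + (nB - 1) * within) /
                      (nA * nB))
  r <- pmin(pmax(0.1 * (1 + coupling), -rMax), rMax)
  sig <- sigBase
  sig[planted] <- r
  sig[planted[, c(2, 1), drop = FALSE]] <- r
  jit <- 0
  for (k in 0:6) {
    ch <- tryCatch(chol(sig + diag(jit, nrow(sig))), error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, sigma = sig))
    jit <- max(jit * 10, 1e-6)
  }
  stop("generation error: covariance not positive definite")
}

mvnEpoch <- function(nVol, cholSig, roiIds, tr, epoch, pid, tid) {
  z <- matrix(rnorm(nVol * ncol(cholSig)), nVol)
  x <- z %*% cholSig
  colnames(x) <- roiIds
  new("RoiTimeSeries", data = x, tr = tr, epoch = epoch,
      participantId = pid, trialId = tid)
}

## Build one trial's event train realising a target chills duration.
simulateEventTrain <- function(target, musicDuration) {
  if (target > musicDuration)
    stop("generation error: chills target exceeds music duration")
  ev <- data.frame(onset = numeric(0), duration = numeric(0),
                   label = character(0))
  if (target >= 1.5) {
    k <- max(1L, rpois(1L, 3))
    ## each chill must survive the 1-s cleaning rule with margin
    while (k > 1L && target / k < 3) k <- k - 1L
    d <- rlnorm(k, log(10), 0.6)
    d <- d * target / sum(d)
    gaps <- rexp(k + 1L)
    gaps <- gaps / sum(gaps) * (musicDuration - target)
    on <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(d))[seq_len(k)]
    ev <- data.frame(onset = on, duration = d, label = "chill")
    ## occasional co-occurring tears (permitted simultaneity), kept inside
    ## the chill press so they overlap nothing else
    tear <- runif(k) < 0.15 & d >= 2.5
    if (any(tear))
      ev <- rbind(ev, data.frame(onset = on[tear],
                                 duration = pmax(1.5, d[tear] * 0.6),
                                 label = "tear"))
    ## fill inter-chill gaps: participants always press one button
    bounds <- rbind(c(0, on[1L]),
                    if (k > 1L) cbind(on[-k] + d[-k], on[-1L]),
                    c(on[k] + d[k], musicDuration))
    for (g in seq_len(nrow(bounds))) {
      len <- bounds[g, 2L] - bounds[g, 1L]
      if (len >= 1.5)
        ev <- rbind(ev, data.frame(
          onset = bounds[g, 1L] + 0.1, duration = len - 0.2,
          label = sample(c("pleasure", "neutral"), 1L, prob = c(0.6, 0.4))))
    }
  } else {
    ev <- data.frame(onset = 0.1, duration = musicDuration - 0.2,
                     label = sample(c("pleasure", "neutral"), 1L,
                                    prob = c(0.6, 0.4)))
  }
  ev <- ev[order(ev$onset), , drop = FALSE]
  ev$duration <- pmin(ev$duration, musicDuration - ev$onset)
  rownames(ev) <- NULL
  new("EventTrain", events = ev, trialDuration = musicDuration)
}

## HRF responses at chill onsets added to designated response (reward) ROIs.
simulateMusicEpoch <- function(parc, cholSig, events, tr, musicDuration,
                               amplitude, pid, tid) {
  nVol <- floor(musicDuration / tr)
  ts <- mvnEpoch(nVol, cholSig, parc@roiIds, tr, "music", pid, tid)
  x <- ts@data + 100  # raw-scale baseline so percent signal change is defined
  ev <- events@events
  chills <- ev[ev$label == "chill", , drop = FALSE]
  if (nrow(chills)) {
    tgrid <- (seq_len(nVol) - 1L) * tr
    resp <- numeric(nVol)
    for (e in seq_len(nrow(chills))) {
      tt <- tgrid - chills$onset[e]
      on <- tt >= 0 & tt <= chills$duration[e] + 30
      ## boxcar of the event convolved with the HRF (trapezoid integral):
      ## a sustained response plateauing near 1% of the 100-unit baseline
      step <- tr / 2
      hseq <- seq(0, chills$duration[e], by = step)
      resp[on] <- resp[on] + vapply(tt[on], function(u)
        sum(canonicalHrf(pmax(u - hseq, 0))) * step * 1.2, 0)
    }
    rew <- parc@network == "reward"
    x[, rew] <- x[, rew] + outer(resp, rep(amplitude, sum(rew)))
  }
  ts@data <- x
  ts
}

## centered convolution of an impulse train with a Gaussian bump
gaussianBumpTrain <- function(times, n, rate, width, amp = 1) {
  imp <- numeric(n)
  idx <- pmax(1L, pmin(n, round(times * rate) + 1L))
  imp[idx] <- amp
  kt <- seq(-4 * width, 4 * width, by = 1 / rate)
  kern <- exp(-0.5 * (kt / width)^2)
  half <- length(kern) %/% 2
  pad <- c(numeric(length(kern)), imp, numeric(length(kern)))
  out <- as.numeric(stats::filter(pad, kern, sides = 2))
  out[length(kern) + seq_len(n)]
}

## causal convolution with zero-padded history (no leading NAs)
convCausalPad <- function(x, kern) {
  pad <- length(kern)
  y <- stats::filter(c(numeric(pad), x), kern, sides = 1)
  as.numeric(y)[pad + seq_len(length(x))]
}

simulatePhysio <- function(events, musicDuration, rate, meanIbi = 0.9) {
  n <- floor(musicDuration * rate)
  tgrid <- (seq_len(n) - 1L) / rate
  ## PPG: pulse bumps with slightly variable inter-beat interval
  beats <- numeric(0); t0 <- 0.2
  while (t0 < musicDuration - 0.2) {
    beats <- c(beats, t0)
    t0 <- t0 + meanIbi * exp(rnorm(1L, 0, 0.03))
  }
  ppg <- gaussianBumpTrain(beats, n, rate, 0.04) + rnorm(n, 0, 0.02)
  ## respiration: slow oscillation ~0.25 Hz
  resp <- sin(2 * pi * 0.25 * tgrid + runif(1L, 0, 2 * pi)) + rnorm(n, 0, 0.05)
  ## EDA: tonic drift plus event-locked phasic responses at chill onsets
  ev <- events@events
  chills <- ev[ev$label == "chill", , drop = FALSE]
  eda <- 2 + 0.2 * sin(2 * pi * tgrid / 180 + runif(1L, 0, 2 * pi)) +
    cumsum(rnorm(n, 0, 0.0005))
  if (nrow(chills)) {
    lat <- chills$onset + runif(nrow(chills), 0.5, 1.5)  # sudomotor latency
    amp <- pmax(0.08, rlnorm(nrow(chills), log(0.3), 0.4))
    kt <- seq(0, 20, by = 1 / rate)
    kern <- scrImpulseResponse(kt, 0.75, 2, normalize = "peak")
    imp <- numeric(n)
    idx <- pmax(1L, pmin(n, round(lat * rate) + 1L))
    for (e in seq_along(idx)) imp[idx[e]] <- imp[idx[e]] + amp[e]
    eda <- eda + convCausalPad(imp, kern)
  }
  eda <- eda + rnorm(n, 0, 0.003)
  list(ppg = new("PhysioTrace", channel = "ppg", rate = rate, samples = ppg),
       respiration = new("PhysioTrace", channel = "respiration", rate = rate,
                         samples = resp),
       eda = new("PhysioTrace", channel = "eda", rate = rate, samples = eda))
}

#' Simulate a complete cohort with a planted auditory-reward coupling
#'
#' Rest epochs are drawn from a multivariate normal whose auditory-reward
#' cross-edge covariances are modulated multiplicatively by a latent
#' per-participant (plus per-trial) coupling score; the per-trial chills
#' duration is a clamped linear function of the same score plus noise.
#' Music epochs carry HRF-convolved responses at chill onsets in the reward
#' ROIs; the electrodermal trace carries event-locked Bateman responses.
#' All randomness flows from \code{config@seed}; the caller's RNG state is
#' left untouched.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param physio generate physiological traces (memory-heavy at scale).
#' @param intrinsic also generate a per-participant 10-min intrinsic rest
#'   epoch with coupling-free (template) covariance.
#' @param intrinsicDuration intrinsic epoch length, seconds.
#' @return a \linkS4class{CohortDataset} with ground truth attached.
#' @export
simulateCohort <- function(config, physio = TRUE, intrinsic = FALSE,
                           intrinsicDuration = 600) {
  validObject(config)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(config@seed)

  parc <- simulateParcellation(config@roisPerNetwork, config@seed)
  sigBase <- baseCovarianceTemplate(parc)
  planted <- plantedEdgeIndices(parc)
  baseline <- attr(config, "baselineDuration") %||% 50
  trialSd <- attr(config, "trialCouplingSd") %||% 0.3

  nP <- config@nParticipants; nT <- config@nTrials
  restVol <- floor(config@restDuration / config@tr)
  coupling <- rnorm(nP, 0, config@couplingSd)
  pids <- sprintf("sub-%02d", seq_len(nP))
  trials <- vector("list", nP); names(trials) <- pids
  intrinsicList <- list()
  trueTarget <- matrix(0, nP, nT, dimnames = list(pids, NULL))
  trialCoupling <- matrix(0, nP, nT, dimnames = list(pids, NULL))

  for (p in seq_len(nP)) {
    ptrials <- vector("list", nT)
    for (tix in seq_len(nT)) {
      cTrial <- coupling[p] + rnorm(1L, 0, trialSd)
      trialCoupling[p, tix] <- cTrial
      mod <- modulatedCovariance(sigBase, planted, cTrial)
      tid <- sprintf("trial-%02d", tix)
      rest <- mvnEpoch(restVol, mod$chol, parc@roiIds, config@tr,
                       "task_rest", pids[p], tid)
      tgt <- baseline + config@effectSize * cTrial +
        rnorm(1L, 0, config@obsNoiseSd)
      tgt <- min(max(tgt, 0), config@musicDuration)
      trueTarget[p, tix] <- tgt
      events <- simulateEventTrain(tgt, config@musicDuration)
      amp <- max(0.2, 1 + 0.5 * cTrial)
      music <- simulateMusicEpoch(parc, mod$chol, events, config@tr,
                                  config@musicDuration, amp, pids[p], tid)
      ph <- if (physio)
        simulatePhysio(events, config@musicDuration, config@physioRate)
      else list()
      ptrials[[tix]] <- list(rest = rest, music = music, events = events,
                             physio = ph)
    }
    names(ptrials) <- sprintf("trial-%02d", seq_len(nT))
    trials[[p]] <- ptrials
    if (intrinsic) {
      chB <- chol(sigBase)
      intrinsicList[[pids[p]]] <- mvnEpoch(
        floor(intrinsicDuration / config@tr), chB, parc@roiIds, config@tr,
        "intrinsic_rest", pids[p], NA_character_)
    }
  }
  gt <- list(latentCoupling = setNames(coupling, pids),
             trialCoupling = trialCoupling,
             plantedEdges = cbind(parc@roiIds[planted[, 1L]],
                                  parc@roiIds[planted[, 2L]]),
             trueTarget = trueTarget)
  new("CohortDataset", parcellation = parc, trials = trials,
      intrinsic = intrinsicList, groundTruth = gt, config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
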