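#' @import methods
#' @importFrom stats approx coef cor cov fft lm median pnorm pt qt quantile
#'   rbinom rlnorm rnorm rpois runif sd setNames splinefun var p.adjust
#'   cor.test
#' @importFrom utils head read.delim tail write.table
#' @useDynLib chillconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_EPOCHS  <- c("task_rest", "music", "intrinsic_rest")
VALID_LABELS  <- c("neutral", "pleasure", "chill", "tear")
VALID_CHANNELS <- c("ppg", "respiration", "eda")

#' ParcellationSpec: ROI-to-network assignment
#'
#' Describes a whole-brain parcellation: an ordered set of ROI identifiers,
#' each assigned to exactly one functional network and one hemisphere
#' (\code{"L"}, \code{"R"} or \code{"mid"}). The default study parcellation
#' has 288 ROIs in 13 networks, with 12 auditory ROIs (6 per hemisphere)
#' and 8 reward ROIs (4 per hemisphere).
#'
#' @slot roiIds ordered character vector of unique ROI identifiers.
#' @slot network character vector, per-ROI network name.
#' @slot hemisphere character vector, per-ROI hemisphere.
#' @export
setClass("ParcellationSpec",
  representation(roiIds = "character", network = "character",
                 hemisphere = "character"))

setValidity("ParcellationSpec", function(object) {
  n <- length(object@roiIds)
  if (anyDuplicated(object@roiIds)) return("duplicate ROI ids")
  if (length(object@network) != n) return("network length != number of ROIs")
  if (length(object@hemisphere) != n) return("hemisphere length != number of ROIs")
  if (!all(object@hemisphere %in% c("L", "R", "mid")))
    return("hemisphere must be one of L, R, mid")
  TRUE
})

#' RoiTimeSeries: one epoch of ROI-averaged BOLD signals
#'
#' A volumes-by-ROIs matrix of ROI-averaged BOLD signal for a single epoch
#' (pre-listening task rest, music listening, or a long intrinsic rest),
#' together with its sampling interval (TR, seconds) and provenance.
#'
#' @slot data numeric matrix, volumes x ROIs; column names are ROI ids.
#' @slot tr sampling interval in seconds (TR).
#' @slot epoch one of \code{"task_rest"}, \code{"music"}, \code{"intrinsic_rest"}.
#' @slot participantId,trialId provenance tokens (trialId may be \code{NA}).
#' @export
setClass("RoiTimeSeries",
  representation(data = "matrix", tr = "numeric", epoch = "character",
                 participantId = "character", trialId = "character"))

setValidity("RoiTimeSeries", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("data contains missing or non-finite values")
  if (is.null(colnames(object@data))) return("data must have ROI ids as colnames")
  if (length(object@tr) != 1L || object@tr <= 0) return("tr must be a positive scalar")
  if (!object@epoch %in% VALID_EPOCHS)
    return(sprintf("epoch must be one of %s", paste(VALID_EPOCHS, collapse = ", ")))
  TRUE
})

#' PhysioTrace: one raw physiological channel
#'
#' @slot channel one of \code{"ppg"}, \code{"respiration"}, \code{"eda"}.
#' @slot rate sampling rate in Hz.
#' @slot samples numeric vector of raw samples.
#' @export
setClass("PhysioTrace",
  representation(channel = "character", rate = "numeric", samples = "numeric"))

setValidity("PhysioTrace", function(object) {
  if (!object@channel %in% VALID_CHANNELS)
    return(sprintf("channel must be one of %s", paste(VALID_CHANNELS, collapse = ", ")))
  if (length(object@rate) != 1L || object@rate <= 0) return("rate must be positive")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    return("samples contain non-finite values")
  TRUE
})

#' EventTrain: button-press events for one trial
#'
#' Online emotion ratings: ordered (onset, duration, label) triples with
#' label in neutral/pleasure/chill/tear, onsets in seconds from music onset.
#'
#' @slot events data.frame with columns onset, duration, label.
#' @slot trialDuration trial (music epoch) duration in seconds.
#' @export
setClass("EventTrain",
  representation(events = "data.frame", trialDuration = "numeric"))

setValidity("EventTrain", function(object) {
  ev <- object@events
  if (!all(c("onset", "duration", "label") %in% names(ev)))
    return("events needs columns onset, duration, label")
  if (nrow(ev)) {
    if (is.unsorted(ev$onset)) return("event onsets must be nondecreasing")
    if (any(ev$duration <= 0)) return("event durations must be positive")
    if (any(ev$onset + ev$duration > object@trialDuration + 1e-9))
      return("events extend past trial duration")
    if (!all(ev$label %in% VALID_LABELS))
      return(sprintf("labels must be in {%s}", paste(VALID_LABELS, collapse = ", ")))
  }
  TRUE
})

#' ConnectivityFeatures: Fisher-z partial-correlation edge vector
#'
#' An edge-indexed feature vector in Fisher-z units, with explicit edge
#' identities (pairs of ROI ids, canonical order), window provenance, and
#' the covariance shrinkage coefficient used.
#'
#' @slot values numeric vector, one Fisher-z value per edge.
#' @slot edges character matrix with two columns (roi_i, roi_j), i before j
#'   in parcellation order; rows align with \code{values}.
#' @slot window list(start, end, epoch) describing the signal window used.
#' @slot shrinkage covariance shrinkage coefficient in [0, 1].
#' @slot nTrials number of trials averaged into the values.
#' @export
setClass("ConnectivityFeatures",
  representation(values = "numeric", edges = "matrix", window = "list",
                 shrinkage = "numeric", nTrials = "numeric"))

setValidity("ConnectivityFeatures", function(object) {
  if (nrow(object@edges) != length(object@values))
    return("edges rows must match values length")
  if (ncol(object@edges) != 2L) return("edges must have 2 columns")
  if (any(!is.finite(object@values))) return("values must be finite")
  ids <- paste(object@edges[, 1L], object@edges[, 2L], sep = "--")
  if (anyDuplicated(ids)) return("duplicate edges")
  TRUE
})

#' RateSeries: uniformly resampled physiological rate or driver
#'
#' Heart rate (bpm), respiration rate (breaths/min), or the phasic
#' skin-conductance driver (microsiemens), on a uniform grid (10 Hz default).
#'
#' @slot rate sampling rate of the resampled series in Hz.
#' @slot values numeric values on the uniform grid.
#' @slot start time (s) of the first sample.
#' @slot measure token, e.g. "hr", "rr", "scr".
#' @export
setClass("RateSeries",
  representation(rate = "numeric", values = "numeric", start = "numeric",
                 measure = "character"))

setValidity("RateSeries", function(object) {
  if (object@rate <= 0) return("rate must be positive")
  if (anyNA(object@values)) return("values must be finite")
  TRUE
})

#' LassoFit: an L1-regularised linear decoder
#'
#' Weights are in (Fisher-z units)^-1 times target units and apply to
#' features standardised by the stored training means and SDs. The edge
#' identities make the weight vector portable across cohorts.
#'
#' @slot weights per-feature weights (standardised scale).
#' @slot intercept intercept in target units.
#' @slot lambda L1 penalty used.
#' @slot center,scale per-feature standardisation statistics from training.
#' @slot featureIds character identifiers (edge ids) aligning the weights.
#' @export
setClass("LassoFit",
  representation(weights = "numeric", intercept = "numeric", lambda = "numeric",
                 center = "numeric", scale = "numeric", featureIds = "character"))

setValidity("LassoFit", function(object) {
  p <- length(object@weights)
  if (length(object@center) != p || length(object@scale) != p)
    return("scaler length must match weights")
  if (length(object@featureIds) != p) return("featureIds must match weights")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  if (object@lambda < 0) return("lambda must be >= 0")
  TRUE
})

#' CvResult: held-out predictions from nested leave-one-out CV
#'
#' @slot unitIds identifiers of the held-out units (participants or trials).
#' @slot yActual,yPred actual and held-out predicted targets.
#' @slot foldLambdas per-outer-fold selected penalty.
#' @slot accuracyR Pearson correlation of predictions vs actuals (NA if
#'   degenerate, see \code{degenerate}).
#' @slot degenerate TRUE when predictions were constant.
#' @export
setClass("CvResult",
  representation(unitIds = "character", yActual = "numeric", yPred = "numeric",
                 foldLambdas = "numeric", accuracyR = "numeric",
                 degenerate = "logical"))

setValidity("CvResult", function(object) {
  n <- length(object@unitIds)
  if (length(object@yActual) != n || length(object@yPred) != n ||
      length(object@foldLambdas) != n)
    return("per-unit slots must have equal length")
  if (anyDuplicated(object@unitIds)) return("one prediction per unit required")
  TRUE
})

#' SimulationConfig: synthetic-cohort study conditions
#'
#' Defaults mirror the study design: 38 participants, 8 trials each,
#' TR = 2 s, 40-s pre-listening rest epochs and ~270-s music epochs, with a
#' planted linear coupling between auditory-reward connectivity and the
#' duration of chills.
#'
#' @slot nParticipants,nTrials counts.
#' @slot tr repetition time in seconds.
#' @slot restDuration,musicDuration epoch durations in seconds.
#' @slot roisPerNetwork named integer vector, ROIs per network.
#' @slot effectSize planted slope (seconds of chills per z-unit of coupling).
#' @slot couplingSd between-participant SD of the latent coupling.
#' @slot obsNoiseSd SD (s) of behavioural noise on chills duration.
#' @slot physioRate physiological sampling rate in Hz.
#' @slot seed integer seed.
#' @export
setClass("SimulationConfig",
  representation(nParticipants = "integer", nTrials = "integer", tr = "numeric",
                 restDuration = "numeric", musicDuration = "numeric",
                 roisPerNetwork = "integer", effectSize = "numeric",
                 couplingSd = "numeric", obsNoiseSd = "numeric",
                 physioRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nParticipants < 1L || object@nTrials < 1L) return("counts must be >= 1")
  if (object@tr <= 0) return("tr must be positive")
  if (object@restDuration < object@tr) return("rest epoch shorter than one TR")
  rn <- object@roisPerNetwork
  if (is.null(names(rn)) || !all(c("auditory", "reward") %in% names(rn)))
    return("parcellation must contain 'auditory' and 'reward' networks")
  if (rn[["auditory"]] %% 2L != 0L)
    return("auditory ROI count must be even (split across hemispheres)")
  if (object@effectSize < 0) return("effect size must be >= 0")
  if (object@physioRate <= 0) return("physio rate must be positive")
  TRUE
})

#' CohortDataset: a complete (synthetic or loaded) cohort
#'
#' @slot parcellation a \linkS4class{ParcellationSpec}.
#' @slot trials nested list: per participant, per trial, a list with
#'   elements \code{rest}, \code{music} (RoiTimeSeries), \code{events}
#'   (EventTrain) and \code{physio} (named list of PhysioTrace).
#' @slot intrinsic named list of per-participant long intrinsic-rest
#'   RoiTimeSeries (possibly empty).
#' @slot groundTruth list with latentCoupling, plantedEdges, trueTarget
#'   (empty for loaded real-format cohorts).
#' @slot config the \linkS4class{SimulationConfig} used (or a placeholder).
#' @export
setClass("CohortDataset",
  representation(parcellation = "ParcellationSpec", trials = "list",
                 intrinsic = "list", groundTruth = "list", config = "ANY"))

## ---- show methods ----

setMethod("show", "ParcellationSpec", function(object) {
  tab <- table(object@network)
  cat(sprintf("ParcellationSpec: %d ROIs in %d networks\n",
              length(object@roiIds), length(tab)))
  cat("  ", paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries [%s]: %d volumes x %d ROIs, TR = %gs (%gs)\n",
              object@epoch, nrow(object@data), ncol(object@data), object@tr,
              nrow(object@data) * object@tr))
})

setMethod("show", "PhysioTrace", function(object) {
  cat(sprintf("PhysioTrace [%s]: %d samples at %g Hz (%.1fs)\n", object@channel,
              length(object@samples), object@rate,
              length(object@samples) / object@rate))
})

setMethod("show", "EventTrain", function(object) {
  tab <- table(factor(object@events$label, levels = VALID_LABELS))
  cat(sprintf("EventTrain: %d events over %gs (%s)\n", nrow(object@events),
              object@trialDuration,
              paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = " ")))
})

setMethod("show", "ConnectivityFeatures", function(object) {
  w <- object@window
  cat(sprintf(
    "ConnectivityFeatures: %d edges, window [%g, %g)s [%s], shrinkage %.3f, n = %g trial(s)\n",
    length(object@values), w$start, w$end, w$epoch, object@shrinkage,
    object@nTrials))
})

setMethod("show", "RateSeries", function(object) {
  cat(sprintf("RateSeries [%s]: %d samples at %g Hz from t = %gs\n",
              object@measure, length(object@values), object@rate, object@start))
})

setMethod("show", "LassoFit", function(object) {
  cat(sprintf("LassoFit: %d features (%d nonzero), lambda = %g, intercept = %.3f\n",
              length(object@weights), sum(object@weights != 0), object@lambda,
              object@intercept))
})

setMethod("show", "CvResult", function(object) {
  cat(sprintf("CvResult: %d held-out units, accuracy r = %s%s\n",
              length(object@unitIds),
              ifelse(is.na(object@accuracyR), "NA", sprintf("%.3f", object@accuracyR)),
              if (object@degenerate) " (degenerate: constant predictions)" else ""))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d participants x %d trials, TR = %gs, rest %gs, music %gs, effect %g s/z, seed %d\n",
    object@nParticipants, object@nTrials, object@tr, object@restDuration,
    object@musicDuration, object@effectSize, object@seed))
})

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf("CohortDataset: %d participants x %d trials, %d ROIs%s\n",
              length(object@trials),
              if (length(object@trials)) length(object@trials[[1L]]) else 0L,
              length(object@parcellation@roiIds),
              if (length(object@intrinsic)) ", with intrinsic rest" else ""))
})
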