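## Cohort-level feature and target extraction: per-trial preprocessing,
## partial-correlation features, trial averaging, and behavioural targets.

preprocessRest <- function(series, applyBandpass = TRUE,
                           low = 0.008, high = 0.09) {
  out <- detrendLinear(series)
  if (applyBandpass && high < 1 / (2 * series@tr))
    out <- bandpass(out, low, high)
  out
}

#' Per-participant connectivity feature matrix
#'
#' For every trial: detrend (and band-pass) the pre-listening rest epoch,
#' optionally restrict it to a window, compute the shrinkage partial
#' correlation over all ROIs, select edges, Fisher-transform; then average
#' the per-trial feature vectors within participant.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param window NULL for the full epoch, else c(start, end) seconds.
#' @param mode,networks,side edge selection, see \code{\link{selectEdges}}.
#' @param shrinkage passed to \code{\link{partialCorrMatrix}}.
#' @param applyBandpass band-pass the rest epochs (0.008-0.09 Hz).
#' @return participants x edges matrix (dimnames set); the edge matrix is
#'   attached as \code{attr(, "edges")}.
#' @export
participantFeatureMatrix <- function(cohort, window = NULL,
                                     mode = "network_pair",
                                     networks = c("auditory", "reward"),
                                     side = "R", shrinkage = "pooled",
                                     applyBandpass = TRUE) {
  zl <- participantZMatrices(cohort, window = window, shrinkage = shrinkage,
                             applyBandpass = applyBandpass)
  edgeFeatureMatrix(zl, cohort@parcellation, mode = mode,
                    networks = networks, side = side)
}

#' Per-participant averaged Fisher-z partial-correlation matrices
#'
#' Computes the full ROI x ROI Fisher-z partial-correlation matrix per
#' trial (after detrending/band-pass and optional windowing) and averages
#' it across trials within participant. Computing this once and slicing
#' edge sets out of it (\code{\link{edgeFeatureMatrix}}) avoids repeating
#' the precision-matrix work for every network pair.
#'
#' @inheritParams participantFeatureMatrix
#' @details The default \code{shrinkage = "pooled"} estimates the
#'   Ledoit-Wolf coefficient per trial and then applies the cohort median
#'   to every trial. A per-trial ("auto") coefficient adapts to each
#'   trial's covariance dispersion, which couples the global scale of all
#'   edges to any condition-dependent covariance structure and injects
#'   target information into unrelated edges; a pooled coefficient keeps
#'   the feature map identical across units.
#' @return named list of z matrices, one per participant, with the
#'   shrinkage used in \code{attr(, "shrinkage")}.
#' @export
participantZMatrices <- function(cohort, window = NULL,
                                 shrinkage = "pooled",
                                 applyBandpass = TRUE) {
  prep <- lapply(cohort@trials, function(ptr) {
    lapply(ptr, function(trial) {
      s <- preprocessRest(trial$rest, applyBandpass)
      if (!is.null(window)) s <- extractWindow(s, window[1L], window[2L])
      s
    })
  })
  if (identical(shrinkage, "pooled")) {
    rhos <- unlist(lapply(prep, function(ptr)
      vapply(ptr, function(s) ledoitWolfRho(s@data), 0)))
    shrinkage <- median(rhos)
  }
  shr <- numeric(0)
  zl <- lapply(prep, function(ptr) {
    zs <- lapply(ptr, function(s) {
      pc <- partialCorrMatrix(s, shrinkage)
      shr <<- c(shr, attr(pc, "shrinkage"))
      diag(pc) <- 0  # off-diagonal edges only; keeps atanh finite
      fisherZ(pc)
    })
    Reduce(`+`, zs) / length(zs)
  })
  attr(zl, "shrinkage") <- mean(shr)
  attr(zl, "window") <- window
  zl
}

#' Edge features sliced from cached z matrices
#'
#' @param zl list from \code{\link{participantZMatrices}}.
#' @param parc the \linkS4class{ParcellationSpec}.
#' @param mode,networks,side,edges edge selection as in
#'   \code{\link{selectEdges}}.
#' @return participants x edges matrix with edge ids as colnames and the
#'   edge matrix in \code{attr(, "edges")}.
#' @export
edgeFeatureMatrix <- function(zl, parc, mode = "network_pair",
                              networks = c("auditory", "reward"),
                              side = "R", edges = NULL) {
  edgeMat <- edgeSetFor(parc, mode, networks, side, edges)
  vals <- t(vapply(zl, function(z) z[cbind(edgeMat[, 1L], edgeMat[, 2L])],
                   numeric(nrow(edgeMat))))
  rownames(vals) <- names(zl)
  colnames(vals) <- edgeIdsOf(edgeMat)
  attr(vals, "edges") <- edgeMat
  vals
}

#' Per-trial connectivity feature matrix for trial-level decoding
#'
#' Supports the three epoch variants of the trial-by-trial model: the rest
#' epoch preceding each piece of music (\code{"rest_preceding"}),
#' connectivity during music listening itself (\code{"music_fc"}), or the
#' rest epoch following the music (\code{"rest_following"}; the last trial
#' of each session has no following rest and is excluded).
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param variant epoch variant, see above.
#' @param sessionSize trials per session (following-rest bookkeeping).
#' @param window,mode,networks,side,shrinkage,applyBandpass as in
#'   \code{\link{participantFeatureMatrix}}.
#' @return list with \code{X} (trials x edges), \code{units}
#'   ("participant/trial" ids), \code{participant} factor.
#' @export
trialFeatureMatrix <- function(cohort,
                               variant = c("rest_preceding", "music_fc",
                                           "rest_following"),
                               sessionSize = 4L, window = NULL,
                               mode = "network_pair",
                               networks = c("auditory", "reward"),
                               side = "R", shrinkage = "pooled",
                               applyBandpass = TRUE) {
  variant <- match.arg(variant)
  parc <- cohort@parcellation
  serList <- list(); units <- character(0); pids <- character(0)
  for (pid in names(cohort@trials)) {
    ptr <- cohort@trials[[pid]]
    nT <- length(ptr)
    for (tix in seq_len(nT)) {
      src <- switch(variant,
        rest_preceding = ptr[[tix]]$rest,
        music_fc = ptr[[tix]]$music,
        rest_following = {
          lastOfSession <- tix %% sessionSize == 0L || tix == nT
          if (lastOfSession) NULL else ptr[[tix + 1L]]$rest
        })
      if (is.null(src)) next
      s <- if (variant == "music_fc") {
        highpass(detrendLinear(src), 0.008)
      } else preprocessRest(src, applyBandpass)
      if (!is.null(window)) s <- extractWindow(s, window[1L], window[2L])
      serList[[length(serList) + 1L]] <- s
      units <- c(units, paste0(pid, "/", names(ptr)[tix]))
      pids <- c(pids, pid)
    }
  }
  if (identical(shrinkage, "pooled"))
    shrinkage <- median(vapply(serList, function(s) ledoitWolfRho(s@data), 0))
  featList <- lapply(serList, function(s)
    selectEdges(partialCorrMatrix(s, shrinkage), parc, mode = mode,
                networks = networks, side = side,
                window = list(start = window[1L] %||% 0,
                              end = window[2L] %||% epochDuration(s),
                              epoch = s@epoch)))
  X <- t(vapply(featList, featureValues,
                numeric(length(featureValues(featList[[1L]])))))
  rownames(X) <- units
  colnames(X) <- edgeIds(featList[[1L]])
  attr(X, "edges") <- featList[[1L]]@edges
  list(X = X, units = units, participant = factor(pids))
}

#' Behavioural targets from the cohort's event trains
#'
#' Cleans every trial's button presses, totals per-label durations, and
#' returns both the trial-level and the participant-mean targets.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param label which emotion to target (default "chill").
#' @param minDuration cleaning threshold, seconds.
#' @return list with \code{trial} (participants x trials matrix) and
#'   \code{participant} (named per-participant means).
#' @export
chillsTargets <- function(cohort, label = "chill", minDuration = 1) {
  pids <- names(cohort@trials)
  nT <- length(cohort@trials[[1L]])
  trial <- matrix(NA_real_, length(pids), nT,
                  dimnames = list(pids, names(cohort@trials[[1L]])))
  for (pid in pids) {
    for (tix in seq_len(nT)) {
      clean <- cleanPresses(cohort@trials[[pid]][[tix]]$events, minDuration)
      durs <- emotionDurations(clean)
      trial[pid, tix] <- durs$duration[durs$label == label]
    }
  }
  list(trial = trial, participant = rowMeans(trial))
}
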