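## Event-locked BOLD percent-signal-change quantification.

#' Percent signal change around a chill onset
#'
#' The event time axis is shifted by \code{shift} seconds (default 4 s) to
#' account for the haemodynamic delay. The per-ROI baseline is the mean of
#' the two volumes at onset - 2 and onset + 2 volumes (the onset-adjacent
#' +/-1 volumes are excluded); with \code{baselineMode = "adjacent"} the
#' onset +/- 1 volumes are used instead. PSC = 100 (x - baseline)/baseline.
#'
#' @param series a music-epoch \linkS4class{RoiTimeSeries}, high-pass
#'   filtered with mean level retained (see \code{\link{highpass}}).
#' @param onset event onset in seconds (pre-shift).
#' @param shift haemodynamic delay in seconds.
#' @param baselineMode \code{"skip_adjacent"} (default) or \code{"adjacent"}.
#' @return list with \code{psc} (volumes x ROIs percent-signal matrix over
#'   the whole epoch), \code{onsetVolume} (1-based shifted onset volume)
#'   and \code{baseline} (per ROI).
#' @export
percentSignalChange <- function(series, onset, shift = 4,
                                baselineMode = c("skip_adjacent",
                                                 "adjacent")) {
  baselineMode <- match.arg(baselineMode)
  x <- series@data; tr <- series@tr
  v0 <- floor((onset + shift) / tr) + 1L  # 1-based shifted onset volume
  off <- if (baselineMode == "skip_adjacent") 2L else 1L
  if (v0 - off < 1L || v0 + off > nrow(x)) {
    warning("event at ", onset, " s too close to the epoch edge; skipped")
    return(NULL)
  }
  baseline <- (x[v0 - off, ] + x[v0 + off, ]) / 2
  if (any(baseline <= 0))
    stop("undefined percent signal change: nonpositive baseline in ROI ",
         paste(colnames(x)[baseline <= 0], collapse = ", "))
  psc <- 100 * sweep(sweep(x, 2L, baseline), 2L, baseline, "/")
  list(psc = psc, onsetVolume = v0, baseline = baseline)
}

#' Per-ROI event-locked BOLD response totals
#'
#' For every event of the requested label, percent signal change is summed
#' over the event's (shifted) duration; the per-ROI total is taken over
#' events surviving a 3-SD exclusion (within ROI, across events).
#'
#' @param series music-epoch \linkS4class{RoiTimeSeries} (mean level
#'   retained).
#' @param events an \linkS4class{EventTrain}.
#' @param label event label (default "chill").
#' @param shift haemodynamic delay, seconds.
#' @param outlierSd exclusion threshold in SD units.
#' @param baselineMode see \code{\link{percentSignalChange}}.
#' @return list with \code{total} (per-ROI summed PSC), \code{perEvent}
#'   (events x ROIs matrix), \code{excluded} (events x ROIs logical) and
#'   \code{nEvents}.
#' @export
roiEventResponse <- function(series, events, label = "chill", shift = 4,
                             outlierSd = 3,
                             baselineMode = "skip_adjacent") {
  ev <- events@events
  ev <- ev[ev$label == label, , drop = FALSE]
  p <- ncol(series@data); tr <- series@tr
  roiNames <- colnames(series@data)
  if (!nrow(ev))
    return(list(total = setNames(numeric(p), roiNames),
                perEvent = matrix(0, 0, p, dimnames = list(NULL, roiNames)),
                excluded = matrix(FALSE, 0, p), nEvents = 0L))
  per <- matrix(NA_real_, nrow(ev), p, dimnames = list(NULL, roiNames))
  for (e in seq_len(nrow(ev))) {
    res <- percentSignalChange(series, ev$onset[e], shift, baselineMode)
    if (is.null(res)) next
    vEnd <- min(nrow(series@data),
                floor((ev$onset[e] + ev$duration[e] + shift) / tr))
    win <- res$onsetVolume:vEnd
    per[e, ] <- colSums(res$psc[win, , drop = FALSE])
  }
  ok <- !is.na(per[, 1L])
  excluded <- matrix(FALSE, nrow(ev), p, dimnames = dimnames(per))
  if (sum(ok) >= 3L) {
    m <- colMeans(per[ok, , drop = FALSE])
    s <- apply(per[ok, , drop = FALSE], 2L, sd)
    dev <- abs(sweep(per[ok, , drop = FALSE], 2L, m))
    excluded[ok, ] <- sweep(dev, 2L, outlierSd * pmax(s, .Machine$double.eps),
                            ">") & matrix(s > 0, sum(ok), p, byrow = TRUE)
  }
  use <- per
  use[excluded | is.na(per)] <- 0
  list(total = colSums(use), perEvent = per, excluded = excluded,
       nEvents = sum(ok))
}
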