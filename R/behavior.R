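## Button-press cleaning and emotion-duration targets.

#' Construct an EventTrain
#'
#' @param onset,duration numeric vectors, seconds from music onset.
#' @param label character vector in {neutral, pleasure, chill, tear}.
#' @param trialDuration trial length in seconds.
#' @return an \linkS4class{EventTrain}.
#' @export
eventTrain <- function(onset, duration, label, trialDuration) {
  o <- order(onset)
  new("EventTrain",
      events = data.frame(onset = as.numeric(onset)[o],
                          duration = as.numeric(duration)[o],
                          label = as.character(label)[o]),
      trialDuration = trialDuration)
}

#' Clean a raw button-press train
#'
#' Applies the rating-cleaning rules in order: presses shorter than
#' \code{minDuration} (default 1 s) are dropped as likely mis-presses, then
#' consecutive same-label presses are concatenated into one event whose
#' duration is the sum of the merged durations (repeat presses of the same
#' button are treated as one sustained response). A sub-threshold press
#' between two same-label presses therefore bridges them. Chill and tear
#' may legitimately co-occur; other overlaps raise a validation warning but
#' are kept.
#'
#' @param raw an \linkS4class{EventTrain}.
#' @param minDuration minimum press duration kept, seconds.
#' @return cleaned \linkS4class{EventTrain}.
#' @export
cleanPresses <- function(raw, minDuration = 1) {
  ev <- raw@events
  ev <- ev[ev$duration >= minDuration, , drop = FALSE]
  if (nrow(ev) > 1L) {
    grp <- cumsum(c(TRUE, ev$label[-1L] != ev$label[-nrow(ev)]))
    ev <- do.call(rbind, lapply(split(ev, grp), function(g)
      data.frame(onset = g$onset[1L], duration = sum(g$duration),
                 label = g$label[1L])))
  }
  rownames(ev) <- NULL
  if (nrow(ev) > 1L) {
    ends <- ev$onset + ev$duration
    olap <- which(ev$onset[-1L] < ends[-nrow(ev)] - 1e-9)
    bad <- olap[!((ev$label[olap] == "chill" & ev$label[olap + 1L] == "tear") |
                  (ev$label[olap] == "tear" & ev$label[olap + 1L] == "chill"))]
    if (length(bad))
      warning("overlapping different-label presses kept as-is (",
              length(bad), " case(s))")
  }
  new("EventTrain", events = ev, trialDuration = raw@trialDuration)
}

#' Per-label duration totals and event counts for one trial
#'
#' @param clean a cleaned \linkS4class{EventTrain}.
#' @return data.frame with one row per label (neutral, pleasure, chill,
#'   tear): total duration (s) and event count; absent labels give 0.
#' @export
emotionDurations <- function(clean) {
  ev <- clean@events
  lab <- factor(ev$label, levels = VALID_LABELS)
  data.frame(label = VALID_LABELS,
             duration = as.numeric(tapply(ev$duration, lab, sum,
                                          default = 0)),
             count = as.integer(table(lab)),
             row.names = NULL)
}

#' Per-participant mean durations across trials
#'
#' The behavioural targets of the participant-level model: the arithmetic
#' mean of each label's per-trial duration total across all trials.
#'
#' @param summaries list of per-trial data.frames from
#'   \code{\link{emotionDurations}}.
#' @return data.frame with per-label mean duration and mean count.
#' @export
participantMeans <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  dur <- rowMeans(vapply(summaries, function(s) s$duration,
                         numeric(length(VALID_LABELS))))
  cnt <- rowMeans(vapply(summaries, function(s) as.numeric(s$count),
                         numeric(length(VALID_LABELS))))
  data.frame(label = VALID_LABELS, duration = dur, count = cnt,
             row.names = NULL)
}

#' Read / write BIDS-style events tables
#'
#' Tab-separated \code{events.tsv} with columns onset, duration, trial_type
#' (seconds, time origin at music onset).
#'
#' @param path file path.
#' @param trialDuration trial length in seconds (reading only).
#' @return \code{readEvents}: an \linkS4class{EventTrain}.
#' @export
readEvents <- function(path, trialDuration) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(tab)))
    stop("validation error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  if (nrow(tab) && (!is.numeric(tab$onset) || !is.numeric(tab$duration)))
    stop("validation error in ", path, ": onset/duration must be numeric")
  eventTrain(tab$onset, tab$duration, tab$trial_type, trialDuration)
}

#' @rdname readEvents
#' @param train an \linkS4class{EventTrain} to write.
#' @export
writeEvents <- function(train, path) {
  ev <- train@events
  write.table(data.frame(onset = ev$onset, duration = ev$duration,
                         trial_type = ev$label),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
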