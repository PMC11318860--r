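## Temporal preprocessing of ROI signals and physiological channels.
## Filters are 2nd-order Butterworth applied forward-backward (zero phase),
## the standard convention for resting-state connectivity pipelines.

newRoiTimeSeries <- function(data, tr, epoch = "task_rest",
                             participantId = "sub-01",
                             trialId = NA_character_) {
  new("RoiTimeSeries", data = data, tr = tr, epoch = epoch,
      participantId = participantId, trialId = trialId)
}

withData <- function(series, data) {
  colnames(data) <- colnames(series@data)
  series@data <- data
  series
}

#' Remove per-ROI linear trends
#'
#' Least-squares removal of an intercept and linear trend from every ROI
#' column; output columns have zero mean and are orthogonal to time.
#'
#' @param series a \linkS4class{RoiTimeSeries} with at least 3 volumes.
#' @return the detrended \linkS4class{RoiTimeSeries}.
#' @export
detrendLinear <- function(series) {
  x <- series@data
  if (nrow(x) < 3L)
    stop("insufficient data: need >= 3 volumes to detrend")
  tt <- seq_len(nrow(x))
  basis <- cbind(1, tt - mean(tt))
  fit <- basis %*% qr.solve(basis, x)
  withData(series, x - fit)
}

butterSos <- function(n, w, type) signal::butter(n, w, type = type)

padCoef <- function(v, len) c(v, rep(0, len - length(v)))

## steady-state initial filter state for a unit step (direct form II
## transposed), so a constant input produces its steady output immediately
lfilterZi <- function(b, a) {
  len <- max(length(a), length(b))
  b <- padCoef(b, len); a <- padCoef(a, len)
  b <- b / a[1L]; a <- a / a[1L]
  m <- len - 1L
  A <- matrix(0, m, m)
  A[, 1L] <- -a[-1L]
  if (m > 1L) A[cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)] <- 1
  solve(diag(m) - A, b[-1L] - a[-1L] * b[1L])
}

## direct-form-II-transposed IIR down a matrix, vectorised across columns;
## ziScale rows initialise the state from the first input row
iirFilterMatrix <- function(b, a, x, zi = NULL) {
  len <- max(length(a), length(b))
  b <- padCoef(b, len); a <- padCoef(a, len)
  b <- b / a[1L]; a <- a / a[1L]
  n <- nrow(x); p <- ncol(x); m <- len - 1L
  z <- if (is.null(zi)) matrix(0, m, p) else zi %o% x[1L, ]
  y <- matrix(0, n, p)
  for (t in seq_len(n)) {
    xt <- x[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (m > 1L)
      for (k in seq_len(m - 1L))
        z[k, ] <- b[k + 1L] * xt - a[k + 1L] * yt + z[k + 1L, ]
    z[m, ] <- b[m + 1L] * xt - a[m + 1L] * yt
    y[t, ] <- yt
  }
  y
}

## zero-phase filtering: odd-reflection padding, steady-state initial
## conditions, forward then time-reversed pass; vectorised over columns
zeroPhaseFilter <- function(x, filt) {
  x <- as.matrix(x)
  b <- filt$b; a <- filt$a
  n <- nrow(x)
  pad <- min(3L * max(length(a), length(b)), n - 1L)
  top <- 2 * matrix(x[1L, ], pad, ncol(x), byrow = TRUE) -
    x[pad + 2L - seq_len(pad), , drop = FALSE]
  bot <- 2 * matrix(x[n, ], pad, ncol(x), byrow = TRUE) -
    x[n - seq_len(pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  zi <- lfilterZi(b, a)
  y <- iirFilterMatrix(b, a, ext, zi)
  y <- iirFilterMatrix(b, a, y[nrow(y):1L, , drop = FALSE], zi)
  y <- y[nrow(y):1L, , drop = FALSE]
  y[pad + seq_len(n), , drop = FALSE]
}

#' Zero-phase band-pass filter for ROI signals
#'
#' The resting-state convention (0.008-0.09 Hz) applied forward-backward so
#' no phase shift is introduced. \code{low = 0} degrades to a low-pass.
#'
#' @param series a \linkS4class{RoiTimeSeries}.
#' @param low,high band edges in Hz; \code{0 <= low < high < 1/(2 tr)}.
#' @return filtered \linkS4class{RoiTimeSeries}.
#' @export
bandpass <- function(series, low = 0.008, high = 0.09) {
  nyq <- 1 / (2 * series@tr)
  if (!(low >= 0 && low < high)) stop("invalid band: need 0 <= low < high")
  if (high >= nyq)
    stop(sprintf("invalid band: high edge %.3g Hz >= Nyquist %.3g Hz", high, nyq))
  filt <- if (low > 0) butterSos(2, c(low, high) / nyq, "pass")
          else butterSos(2, high / nyq, "low")
  withData(series, zeroPhaseFilter(series@data, filt))
}

#' Zero-phase high-pass filter for ROI signals
#'
#' Drift removal for music-listening epochs (cutoff 0.008 Hz = 125 s); no
#' low-pass is applied so event-locked activity is preserved. With
#' \code{keepMean = TRUE} the per-ROI mean signal level is restored after
#' filtering, as needed for percent-signal-change baselines.
#'
#' @param series a \linkS4class{RoiTimeSeries}.
#' @param cutoff high-pass edge in Hz, below Nyquist.
#' @param keepMean restore pre-filter column means (default FALSE).
#' @return filtered \linkS4class{RoiTimeSeries}.
#' @export
highpass <- function(series, cutoff = 0.008, keepMean = FALSE) {
  nyq <- 1 / (2 * series@tr)
  if (!(cutoff > 0 && cutoff < nyq))
    stop(sprintf("invalid band: cutoff %.3g Hz must lie in (0, %.3g) Hz",
                 cutoff, nyq))
  filt <- butterSos(2, cutoff / nyq, "high")
  out <- zeroPhaseFilter(series@data, filt)
  if (keepMean)
    out <- sweep(out, 2L, colMeans(series@data), "+")
  withData(series, out)
}

#' Regress nuisance confounds out of ROI signals
#'
#' Projects every ROI column onto the orthogonal complement of the confound
#' columns (an intercept is not added automatically). Rank-deficient
#' confound matrices are handled by a reduced-rank projection with a warning.
#'
#' @param series a \linkS4class{RoiTimeSeries}.
#' @param confounds numeric matrix, volumes x K (K may be 0).
#' @return residual \linkS4class{RoiTimeSeries}, orthogonal to confounds.
#' @export
regressConfounds <- function(series, confounds) {
  x <- series@data
  confounds <- as.matrix(confounds)
  if (length(confounds) && nrow(confounds) != nrow(x))
    stop("confound rows must equal the number of volumes")
  if (!length(confounds) || ncol(confounds) == 0L) return(series)
  if (ncol(confounds) >= nrow(x))
    stop("need fewer confounds than volumes")
  qrC <- qr(confounds)
  if (qrC$rank < ncol(confounds))
    warning("rank-deficient confounds; using pseudo-inverse projection")
  q <- qr.Q(qrC)[, seq_len(qrC$rank), drop = FALSE]
  withData(series, x - q %*% crossprod(q, x))
}

#' Extract a time window from an epoch
#'
#' Half-open second-based window [start, end); a volume belongs to the
#' window when its onset time (0-based, volume k starts at k*tr) falls
#' inside it.
#'
#' @param series a \linkS4class{RoiTimeSeries}.
#' @param start,end window bounds in seconds, 0 <= start < end <= duration.
#' @return the windowed \linkS4class{RoiTimeSeries}.
#' @export
extractWindow <- function(series, start, end) {
  dur <- nrow(series@data) * series@tr
  if (!(start >= 0 && start < end && end <= dur + 1e-9))
    stop(sprintf("range error: window [%g, %g) outside epoch [0, %g)",
                 start, end, dur))
  onset <- (seq_len(nrow(series@data)) - 1L) * series@tr
  keep <- onset >= start - 1e-9 & onset < end - 1e-9
  out <- series
  out@data <- series@data[keep, , drop = FALSE]
  out
}

#' Zero-phase band filtering of a physiological trace
#'
#' Band conventions follow the quantification pipeline: pulse 1-35 Hz,
#' respiration 0.05-1 Hz; \code{low = 0} gives a pure low-pass.
#'
#' @param trace a \linkS4class{PhysioTrace}.
#' @param low,high band edges in Hz at the trace's native rate.
#' @return filtered \linkS4class{PhysioTrace}.
#' @export
filterPhysio <- function(trace, low, high) {
  nyq <- trace@rate / 2
  if (!(low >= 0 && low < high && high < nyq))
    stop(sprintf("invalid band: need 0 <= low < high < Nyquist (%.3g Hz)", nyq))
  filt <- if (low > 0) butterSos(2, c(low, high) / nyq, "pass")
          else butterSos(2, high / nyq, "low")
  trace@samples <- zeroPhaseFilter(matrix(trace@samples), filt)[, 1L]
  trace
}
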