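## Fisher-z partial-correlation features over configurable edge sets.
##
## With short windows (20 volumes) and 288 ROIs the "adjust for all other
## ROIs" partial correlation is rank-deficient, so the sample covariance is
## shrunk toward a scaled identity (Ledoit-Wolf) before inversion; the
## coefficient used is recorded on the feature object.

ledoitWolfRho <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))
  s <- crossprod(xc) / n
  m <- sum(diag(s)) / p
  d2 <- sum((s - diag(m, p))^2) / p
  if (d2 < .Machine$double.eps) return(0)
  b2bar <- (sum(rowSums(xc^2)^2) - n * sum(s^2)) / n^2 / p
  min(1, max(0, min(b2bar, d2) / d2))
}

#' Shrinkage-regularised partial-correlation matrix
#'
#' Entry (i, j) is \code{-P_ij / sqrt(P_ii P_jj)} where P is the inverse of
#' the shrinkage-regularised sample covariance \code{(1 - rho) S + rho m I}
#' (m = mean variance): the correlation between ROI i and j after adjusting
#' for all other ROIs in the matrix.
#'
#' @param series a \linkS4class{RoiTimeSeries} (or plain volumes x ROIs
#'   matrix) with >= 3 volumes and >= 2 ROIs.
#' @param shrinkage \code{"auto"} for the Ledoit-Wolf coefficient, or an
#'   explicit value in [0, 1] (0 = plain inversion, for large-n work).
#' @return symmetric ROIs x ROIs matrix, unit diagonal, values in [-1, 1],
#'   with the coefficient used in \code{attr(, "shrinkage")}.
#' @export
partialCorrMatrix <- function(series, shrinkage = "auto") {
  x <- if (is(series, "RoiTimeSeries")) series@data else as.matrix(series)
  if (nrow(x) < 3L) stop("need >= 3 volumes")
  if (ncol(x) < 2L) stop("need >= 2 ROIs")
  v <- apply(x, 2L, var)
  if (any(v <= .Machine$double.eps))
    stop("undefined correlation: constant signal in ROI ",
         paste(colnames(x)[v <= .Machine$double.eps], collapse = ", "))
  rho <- if (identical(shrinkage, "auto")) ledoitWolfRho(x)
         else {
           stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
           shrinkage
         }
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2L, colMeans(x))
  s <- crossprod(xc) / n
  m <- sum(diag(s)) / p
  sig <- (1 - rho) * s + diag(rho * m, p)
  prec <- tryCatch(chol2inv(chol(sig)), error = function(e)
    stop("covariance not invertible; increase shrinkage"))
  d <- sqrt(diag(prec))
  pc <- -prec / tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(x), colnames(x))
  attr(pc, "shrinkage") <- rho
  pc
}

#' Fisher r-to-z transform
#'
#' \code{atanh(r)}; values with |r| >= 1 are clipped to +/-(1 - 1e-7) with
#' a warning.
#'
#' @param r correlations.
#' @return z values.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) {
    warning("correlations with |r| >= 1 clipped before Fisher transform")
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  }
  atanh(r)
}

edgeIdsOf <- function(edges) paste(edges[, 1L], edges[, 2L], sep = "--")

## canonical edge order: row-major upper triangle in parcellation ROI order
upperTriEdges <- function(ids) {
  k <- length(ids)
  i <- rep(seq_len(k - 1L), times = (k - 1L):1L)
  j <- sequence((k - 1L):1L) + i
  cbind(ids[i], ids[j])
}

#' Select connectivity edges as a feature vector
#'
#' Extracts Fisher-z features from a partial-correlation matrix:
#' \describe{
#'   \item{network_pair}{only cross-network edges between \code{networks[1]}
#'     and \code{networks[2]} (e.g. 12 auditory x 8 reward = 96 features).}
#'   \item{hemispheric}{the full upper triangle (within + between network)
#'     of the selected networks' ROIs on one \code{side} (6 auditory + 4
#'     reward per hemisphere = C(10,2) = 45 features).}
#'   \item{whole_brain}{the full upper triangle of all ROIs.}
#'   \item{explicit}{a caller-supplied two-column matrix of ROI id pairs.}
#' }
#' Edge order is the row-major upper triangle in parcellation ROI order,
#' fixed so weight vectors are portable across runs and cohorts.
#'
#' @param mat partial-correlation matrix (from \code{\link{partialCorrMatrix}}).
#' @param parc the \linkS4class{ParcellationSpec}.
#' @param mode selection mode, see above.
#' @param networks two network names (network_pair) or a character vector
#'   of networks (hemispheric).
#' @param side \code{"L"} or \code{"R"} for hemispheric mode.
#' @param edges explicit two-column ROI-id matrix for explicit mode.
#' @param window list(start, end, epoch) provenance attached to the result.
#' @return a \linkS4class{ConnectivityFeatures}.
#' @export
selectEdges <- function(mat, parc,
                        mode = c("network_pair", "hemispheric",
                                 "whole_brain", "explicit"),
                        networks = c("auditory", "reward"), side = "R",
                        edges = NULL,
                        window = list(start = NA_real_, end = NA_real_,
                                      epoch = "task_rest")) {
  mode <- match.arg(mode)
  edgeMat <- edgeSetFor(parc, mode, networks, side, edges)
  vals <- fisherZ(mat[cbind(edgeMat[, 1L], edgeMat[, 2L])])
  new("ConnectivityFeatures", values = as.numeric(vals), edges = edgeMat,
      window = window,
      shrinkage = attr(mat, "shrinkage") %||% NA_real_,
      nTrials = 1)
}

## shared edge-set construction (canonical parcellation order)
edgeSetFor <- function(parc, mode, networks = c("auditory", "reward"),
                       side = "R", edges = NULL) {
  net <- networkOf(parc)
  ids <- roiIds(parc)
  if (mode %in% c("network_pair", "hemispheric")) {
    unknown <- setdiff(networks, unique(parc@network))
    if (length(unknown))
      stop("unknown network: ", paste(unknown, collapse = ", "))
  }
  pos <- setNames(seq_along(ids), ids)
  switch(mode,
    network_pair = {
      a <- ids[net[ids] == networks[1L]]
      b <- ids[net[ids] == networks[2L]]
      eg <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      flip <- pos[eg[, 1L]] > pos[eg[, 2L]]
      eg[flip, ] <- eg[flip, c(2L, 1L)]
      eg
    },
    hemispheric = {
      sel <- ids[net[ids] %in% networks & hemisphereOf(parc)[ids] == side]
      upperTriEdges(sel)
    },
    whole_brain = upperTriEdges(ids),
    explicit = {
      stopifnot(!is.null(edges), ncol(edges) == 2L)
      eg <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
      flip <- pos[eg[, 1L]] > pos[eg[, 2L]]
      eg[flip, ] <- eg[flip, c(2L, 1L)]
      eg
    })
}

#' Enumerate unordered network pairs
#'
#' All C(K, 2) pairs in deterministic order (first appearance in the
#' parcellation), flagged by whether they involve the auditory network.
#' The default 13-network parcellation yields 78 pairs, 12 of which
#' contain auditory.
#'
#' @param parc a \linkS4class{ParcellationSpec} with >= 2 networks.
#' @return data.frame with columns netA, netB, hasAuditory.
#' @export
listNetworkPairs <- function(parc) {
  nets <- unique(parc@network)
  if (length(nets) < 2L) stop("need >= 2 networks")
  idx <- utils::combn(seq_along(nets), 2L)
  data.frame(netA = nets[idx[1L, ]], netB = nets[idx[2L, ]],
             hasAuditory = nets[idx[1L, ]] == "auditory" |
                           nets[idx[2L, ]] == "auditory")
}

#' Average feature vectors across trials
#'
#' Elementwise mean over available (non-NULL) trials sharing an identical
#' edge set; the number of trials used is recorded.
#'
#' @param features list of \linkS4class{ConnectivityFeatures}; missing
#'   trials may be NULL.
#' @return averaged \linkS4class{ConnectivityFeatures}.
#' @export
averageFeatures <- function(features) {
  keep <- !vapply(features, is.null, TRUE)
  if (!any(keep)) stop("empty average: all trials missing")
  features <- features[keep]
  ref <- edgeIds(features[[1L]])
  for (f in features[-1L])
    if (!identical(edgeIds(f), ref))
      stop("edge sets differ across trials")
  vals <- rowMeans(vapply(features, featureValues,
                          numeric(length(ref))))
  out <- features[[1L]]
  out@values <- vals
  out@nTrials <- length(features)
  out@shrinkage <- mean(vapply(features, function(f) f@shrinkage, 0))
  out
}

#' Random short-window features from a long intrinsic rest epoch
#'
#' Each repetition draws \code{k} non-overlapping windows of \code{window}
#' seconds uniformly at random from the epoch, computes partial-correlation
#' features per window, and averages them; the result is the mean feature
#' vector over repetitions. Matches the procedure that compares 8 sampled
#' 18-s intrinsic-rest windows against pre-listening task rest.
#'
#' @param series long-rest \linkS4class{RoiTimeSeries}.
#' @param parc the \linkS4class{ParcellationSpec}.
#' @param k windows per repetition.
#' @param window window length in seconds.
#' @param reps repetitions (the study uses 10,000; desk-scale runs use fewer).
#' @param seed integer seed.
#' @param shrinkage passed to \code{\link{partialCorrMatrix}}.
#' @param ... edge-selection arguments passed to \code{\link{selectEdges}}.
#' @return averaged \linkS4class{ConnectivityFeatures}.
#' @export
sampleIntrinsicWindows <- function(series, parc, k = 8L, window = 18,
                                   reps = 100L, seed = 1L,
                                   shrinkage = "auto", ...) {
  dur <- epochDuration(series)
  if (k * window > dur)
    stop("sampling error: cannot pack ", k, " non-overlapping ", window,
         "-s windows into ", dur, " s")
  if (reps < 1L) stop("reps must be >= 1")
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  free <- dur - k * window
  repFeatures <- vector("list", reps)
  for (r in seq_len(reps)) {
    u <- sort(runif(k, 0, free))
    starts <- u + (seq_len(k) - 1L) * window
    wins <- lapply(starts, function(s0) {
      sub <- extractWindow(series, s0, s0 + window)
      selectEdges(partialCorrMatrix(detrendLinear(sub), shrinkage), parc,
                  window = list(start = s0, end = s0 + window,
                                epoch = series@epoch), ...)
    })
    repFeatures[[r]] <- averageFeatures(wins)
  }
  out <- averageFeatures(repFeatures)
  out@nTrials <- k
  out
}
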