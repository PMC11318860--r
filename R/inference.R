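## Significance machinery: exact correlation tests, minimal-n calculation,
## permutation nulls, BH-FDR, bootstrap model comparison, trend tests, and
## the per-edge paired comparison of rest conditions.

#' Pearson correlation with its exact null p-value
#'
#' The p-value comes from the exact null distribution of r (equivalently
#' the t transform with n - 2 df, or the beta distribution of r^2).
#' One-sided tests take the positive direction as the alternative.
#'
#' @param x,y numeric vectors, n >= 3, finite.
#' @param sided \code{"two"} or \code{"one"}.
#' @return list with statistic (r), p, n, df, method, degenerate.
#' @export
pearsonRP <- function(x, y, sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = n, df = n - 2L,
                method = "pearson", degenerate = TRUE))
  r <- cor(x, y)
  df <- n - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- if (sided == "two") 2 * pt(-abs(tstat), df)
       else pt(tstat, df, lower.tail = FALSE)
  list(statistic = r, p = min(p, 1), n = n, df = df, method = "pearson",
       degenerate = FALSE)
}

rToP <- function(r, n, alpha, sided) {
  df <- n - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  if (sided == "two") 2 * pt(-abs(tstat), df)
  else pt(tstat, df, lower.tail = FALSE)
}

#' Smallest significant correlation at a given sample size
#'
#' The inverse of the exact correlation test: the smallest r with
#' p <= alpha at sample size n (root-found to 1e-6). At n = 11 and
#' one-sided alpha = .05 this is 0.52, the minimal-sample boundary used to
#' size an independent validation cohort.
#'
#' @param n sample size >= 3.
#' @param alpha significance level.
#' @param sided \code{"one"} or \code{"two"}.
#' @return the critical correlation.
#' @export
criticalR <- function(n, alpha = 0.05, sided = c("one", "two")) {
  sided <- match.arg(sided)
  stopifnot(n >= 3L, alpha > 0, alpha < 1)
  f <- function(r) rToP(r, n, alpha, sided) - alpha
  if (f(1 - 1e-9) > 0) return(NA_real_)
  if (abs(f(0)) < 1e-12) return(0)
  ## two-sided p is symmetric in r, so the inverse lives on r >= 0;
  ## one-sided p spans the whole range
  lo <- if (sided == "two") 0 else -1 + 1e-9
  uniroot(f, c(lo, 1 - 1e-9), tol = 1e-6)$root
}

#' Minimal sample size for a target correlation
#'
#' The smallest n at which a correlation of size r reaches significance:
#' the smallest integer with \code{criticalR(n) <= r}.
#'
#' @param r the correlation expected to replicate.
#' @param alpha significance level.
#' @param sided \code{"one"} or \code{"two"}.
#' @param nMax search bound.
#' @return integer sample size.
#' @export
minNForR <- function(r, alpha = 0.05, sided = c("one", "two"),
                     nMax = 10000L) {
  sided <- match.arg(sided)
  stopifnot(r > 0, r < 1)
  for (n in 3:nMax) {
    cr <- criticalR(n, alpha, sided)
    if (!is.na(cr) && cr <= r) return(n)
  }
  stop("bounded-search error: no n <= ", nMax, " reaches significance at r = ", r)
}

#' Permutation test of cross-validated prediction accuracy
#'
#' Builds the null distribution of the accuracy statistic by re-running the
#' full cross-validation with targets permuted without replacement;
#' p = (1 + #\{null >= observed\}) / (1 + nPerm), which never returns 0.
#'
#' @param cvFun function(X, y) returning an accuracy (Pearson r).
#' @param X units x features matrix.
#' @param y targets.
#' @param nPerm number of permutations (the study uses 10,000; desk-scale
#'   default 1,000).
#' @param seed integer seed.
#' @return list with statistic (observed accuracy), p, null (vector),
#'   nPerm, seed.
#' @export
permutationTest <- function(cvFun, X, y, nPerm = 1000L, seed = 1L) {
  stopifnot(nPerm >= 1L)
  observed <- cvFun(X, y)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(b) cvFun(X, sample(y)), 0)
  exceed <- sum(!is.na(null) & null >= observed)
  list(statistic = observed, p = (1 + exceed) / (1 + nPerm), null = null,
       nPerm = nPerm, seed = seed, method = "permutation")
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure via \code{p.adjust}; returns the rejection
#' mask and adjusted p-values.
#'
#' @param pvals raw p-values.
#' @param alpha FDR level.
#' @return list with reject (logical), pAdjusted.
#' @export
bhFdr <- function(pvals, alpha = 0.05) {
  adj <- p.adjust(pvals, method = "BH")
  list(reject = !is.na(adj) & adj <= alpha, pAdjusted = adj)
}

#' Bootstrap comparison of two dependent prediction accuracies
#'
#' Resamples units with replacement and recomputes
#' r(y, yhatA) - r(y, yhatB) per resample; reports the percentile CI and
#' the two-sided p-value by CI inversion. Degenerate resamples (constant
#' vectors) are skipped and counted.
#'
#' @param y actual targets.
#' @param yhatA,yhatB two sets of predictions for the same units.
#' @param nBoot bootstrap resamples (the study uses 10,000).
#' @param seed integer seed.
#' @param conf CI coverage.
#' @return list with statistic (observed difference), ci, p, nSkipped.
#' @export
bootstrapCorrDiff <- function(y, yhatA, yhatB, nBoot = 2000L, seed = 1L,
                              conf = 0.95) {
  n <- length(y)
  stopifnot(length(yhatA) == n, length(yhatB) == n, n >= 3L)
  obs <- safeCor(y, yhatA) - safeCor(y, yhatB)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  diffs <- rep(NA_real_, nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ra <- safeCor(y[idx], yhatA[idx]); rb <- safeCor(y[idx], yhatB[idx])
    if (!is.na(ra) && !is.na(rb)) diffs[b] <- ra - rb
  }
  ok <- diffs[!is.na(diffs)]
  nSkipped <- nBoot - length(ok)
  ci <- quantile(ok, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  pLo <- (1 + sum(ok <= 0)) / (1 + length(ok))
  pHi <- (1 + sum(ok >= 0)) / (1 + length(ok))
  list(statistic = obs, ci = ci, p = min(1, 2 * min(pLo, pHi)),
       null = ok, nSkipped = nSkipped, seed = seed, method = "bootstrap")
}

#' Linear trend of accuracy over window duration
#'
#' r^2 and slope p-value of the simple linear regression of accuracy on
#' window duration (used to show accuracy rising linearly from 20 to 40 s).
#'
#' @param x window durations.
#' @param y accuracies.
#' @return list with statistic (r^2), p, slope.
#' @export
linearTrendR2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(y) == 0)
    return(list(statistic = 0, p = 1, slope = 0))
  r <- cor(x, y)
  df <- length(x) - 2L
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(statistic = r^2, p = min(1, 2 * pt(-abs(tstat), df)),
       slope = cov(x, y) / var(x))
}

#' Per-edge paired comparison of two rest conditions
#'
#' A paired t test per edge on participant-level condition means (a
#' documented simplification of a trial-level mixed model), with BH-FDR
#' across edges. Trial-level values should be averaged per participant
#' before calling.
#'
#' @param fcA,fcB lists of \linkS4class{ConnectivityFeatures}, one per
#'   participant, matched order, identical edge sets.
#' @param alpha FDR level.
#' @return data.frame with edge, meanDiff, t, p, pAdjusted, reject.
#' @export
pairedEdgeTest <- function(fcA, fcB, alpha = 0.05) {
  stopifnot(length(fcA) == length(fcB), length(fcA) >= 3L)
  ids <- edgeIds(fcA[[1L]])
  for (f in c(fcA, fcB))
    if (!identical(edgeIds(f), ids)) stop("edge sets must match")
  A <- t(vapply(fcA, featureValues, numeric(length(ids))))
  B <- t(vapply(fcB, featureValues, numeric(length(ids))))
  d <- A - B
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2L, sd)
  tstat <- m / (s / sqrt(n))
  tstat[s == 0 & m == 0] <- 0
  p <- 2 * pt(-abs(tstat), n - 1L)
  p[s == 0 & m == 0] <- 1
  fdr <- bhFdr(p, alpha)
  data.frame(edge = ids, meanDiff = m, t = tstat, p = p,
             pAdjusted = fdr$pAdjusted, reject = fdr$reject,
             row.names = NULL)
}
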