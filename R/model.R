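## Nested cross-validated LASSO decoding and its variants.

#' The study's L1 penalty grid
#' @return numeric vector \code{c(0.001, 0.01, 0.1, 1, 10, 100, 1000)}.
#' @export
defaultLambdaGrid <- function() c(0.001, 0.01, 0.1, 1, 10, 100, 1000)

checkDesign <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y)))
    stop("validation error: non-finite values in design or target")
  if (nrow(X) != length(y)) stop("X rows must match length(y)")
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  X
}

safeCor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Fit a LASSO decoder at a fixed penalty
#'
#' Minimises \code{(1/2n) sum((y - b - Xs w)^2) + lambda sum(|w|)} by
#' coordinate descent (tolerance 1e-6) on features standardised to zero
#' mean and unit (population) SD; deterministic.
#'
#' @param X units x features numeric matrix (no missing values, >= 2 units).
#' @param y numeric targets.
#' @param lambda L1 penalty >= 0.
#' @return a \linkS4class{LassoFit}; weights are on the standardised scale.
#' @export
lassoFit <- function(X, y, lambda) {
  X <- checkDesign(X, y)
  if (nrow(X) < 2L) stop("need >= 2 units")
  fit <- cppLassoFit(X, y, lambda)
  new("LassoFit", weights = fit$weights, intercept = fit$intercept,
      lambda = lambda, center = fit$center, scale = fit$scale,
      featureIds = colnames(X))
}

#' Predict from a LassoFit
#'
#' @param object a \linkS4class{LassoFit}.
#' @param newdata units x features matrix whose columns cover the model's
#'   feature ids (matched by identity, not position).
#' @param ... ignored.
#' @return numeric predictions in target units.
#' @export
setMethod("predict", "LassoFit", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata)) &&
      ncol(newdata) == length(object@featureIds))
    colnames(newdata) <- object@featureIds
  missing <- setdiff(object@featureIds, colnames(newdata))
  if (length(missing))
    stop("alignment error: features absent from new data: ",
         paste(head(missing, 8L), collapse = ", "),
         if (length(missing) > 8L) " ...")
  xs <- sweep(sweep(newdata[, object@featureIds, drop = FALSE], 2L,
                    object@center), 2L, object@scale, "/")
  as.numeric(xs %*% object@weights) + object@intercept
})

makeCvResult <- function(unitIds, y, pred, lambdas) {
  degenerate <- sd(pred) == 0
  new("CvResult", unitIds = as.character(unitIds), yActual = as.numeric(y),
      yPred = as.numeric(pred), foldLambdas = as.numeric(lambdas),
      accuracyR = if (degenerate) NA_real_ else cor(pred, y),
      degenerate = degenerate)
}

#' Convergence settings for nested cross-validation
#'
#' The outer refits use a tight coordinate-descent tolerance; the inner
#' leave-one-out loop only ranks penalties, so it tolerates a relaxed
#' tolerance and tighter sweep caps. \code{fastCvControl()} is the preset
#' used for permutation-scale work (hundreds to thousands of full nested
#' CV re-runs), where the relaxation is applied identically to observed
#' and permuted targets. Tolerances are scaled internally by the SD of the
#' training targets.
#'
#' @param tol,maxSweep outer-refit coordinate-descent tolerance and sweep cap.
#' @param innerTol,innerMaxSweep,innerMaxActive inner-loop tolerance, full
#'   sweeps, and active-set iteration cap.
#' @return list of settings.
#' @export
cvControl <- function(tol = 1e-6, maxSweep = 100L, innerTol = 1e-3,
                      innerMaxSweep = 10L, innerMaxActive = 30L) {
  list(tol = tol, maxSweep = as.integer(maxSweep), innerTol = innerTol,
       innerMaxSweep = as.integer(innerMaxSweep),
       innerMaxActive = as.integer(innerMaxActive))
}

#' @rdname cvControl
#' @export
fastCvControl <- function() cvControl(tol = 1e-4, maxSweep = 30L,
                                      innerTol = 1e-2, innerMaxSweep = 3L,
                                      innerMaxActive = 10L)

#' Nested leave-one-out cross-validated LASSO
#'
#' For each held-out unit, an inner leave-one-out loop over the remaining
#' units scores every penalty in \code{lambdaGrid} by the Pearson
#' correlation between inner held-out predictions and actuals; the best
#' penalty (ties broken toward stronger shrinkage) is refit on the full
#' training set to predict the held-out unit. Standardisation statistics
#' are learned within each training set only, so no information leaks from
#' the held-out unit.
#'
#' @param X units x features matrix (participants for the participant-level
#'   model, trials for the trial-level one).
#' @param y numeric targets (e.g. chills durations, seconds).
#' @param lambdaGrid candidate penalties.
#' @param unitIds unit identifiers (default rownames of X).
#' @param control convergence settings, see \code{\link{cvControl}}.
#' @return a \linkS4class{CvResult}.
#' @export
nestedLoocv <- function(X, y, lambdaGrid = defaultLambdaGrid(),
                        unitIds = rownames(X), control = cvControl()) {
  X <- checkDesign(X, y)
  if (nrow(X) < 4L) stop("nested leave-one-out needs >= 4 units")
  if (is.null(unitIds)) unitIds <- sprintf("unit%03d", seq_len(nrow(X)))
  res <- cppNestedLoocv(X, y, lambdaGrid, control$tol, control$maxSweep,
                        control$innerTol, control$innerMaxSweep,
                        control$innerMaxActive)
  if (isTRUE(res$innerDegenerate))
    warning("inner accuracy undefined in some fold(s); ",
            "largest-lambda tie-break applied")
  makeCvResult(unitIds, y, res$pred, res$lambda)
}

#' @rdname nestedLoocv
#' @details \code{nestedLotocv} is the trial-level variant: identical
#'   machinery with trials as units (leave one trial out).
#' @export
nestedLotocv <- nestedLoocv

#' One-sided trial outlier screen
#'
#' Flags trials whose target exceeds mean + \code{sdLimit} SDs (the screen
#' is one-sided: only excessive durations are removed).
#'
#' @param y trial-level targets.
#' @param sdLimit threshold in SD units.
#' @return logical mask, TRUE = keep.
#' @export
trialOutlierFilter <- function(y, sdLimit = 3) {
  s <- sd(y)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(y)))
  y <= mean(y) + sdLimit * s
}

#' Fit the full transfer model
#'
#' The penalty is chosen by a plain leave-one-out over all units, then one
#' LASSO is fit on every unit; the resulting single weight vector (plus its
#' training scaler and edge identities) is what crosses cohorts.
#'
#' @param X units x features matrix with edge ids as colnames.
#' @param y targets.
#' @param lambdaGrid candidate penalties.
#' @return a \linkS4class{LassoFit}.
#' @export
fitTransferModel <- function(X, y, lambdaGrid = defaultLambdaGrid()) {
  X <- checkDesign(X, y)
  acc <- cppLoocvAccuracy(X, y, lambdaGrid)
  lam <- attr(acc, "lambda")
  acc[is.na(acc)] <- 0  # intercept-only predictions express no relationship
  best <- lam[which.max(acc)]  # descending grid: largest lambda wins ties
  lassoFit(X, y, best)
}

#' Apply a frozen model to a new cohort
#'
#' The transfer prediction is the dot product of the new cohort's features
#' (standardised by the training scaler) with the frozen weights. Features
#' are matched by edge identity; mismatches are an error.
#'
#' @param model a \linkS4class{LassoFit}.
#' @param Xnew new-cohort units x features matrix with edge-id colnames.
#' @return predicted targets for the new units.
#' @export
transferPredict <- function(model, Xnew) predict(model, Xnew)

#' Prediction accuracy across connectivity windows
#'
#' Re-runs feature extraction and nested CV for a family of rest-epoch
#' windows: cumulative windows anchored at the end of the rest epoch
#' (immediately before music onset), e.g. 20, 22, ..., 40 s; or sliding
#' windows of fixed width stepping through the epoch (26-s windows every
#' 2 s give 0-26 ... 14-40 s).
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param durations cumulative window lengths, seconds (cumulative mode).
#' @param mode \code{"cumulative"} or \code{"sliding"}.
#' @param width,step sliding-window width and step, seconds.
#' @param level \code{"participant"} (LOPOCV) or \code{"trial"} (LOTOCV).
#' @param lambdaGrid candidate penalties.
#' @param control convergence settings, see \code{\link{cvControl}}.
#' @param ... passed to the feature extractor (networks, shrinkage, ...).
#' @return data.frame with window bounds, accuracy r and its correlation p.
#' @export
windowSweep <- function(cohort, durations = seq(20, 40, by = 2),
                        mode = c("cumulative", "sliding"), width = 26,
                        step = 2, level = c("participant", "trial"),
                        lambdaGrid = defaultLambdaGrid(),
                        control = cvControl(), ...) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  restDur <- epochDuration(cohort@trials[[1L]][[1L]]$rest)
  wins <- if (mode == "cumulative") {
    if (any(durations > restDur + 1e-9))
      stop("range error: window exceeds the rest epoch")
    lapply(durations, function(d) c(restDur - d, restDur))
  } else {
    if (width > restDur + 1e-9)
      stop("range error: window exceeds the rest epoch")
    starts <- seq(0, restDur - width, by = step)
    lapply(starts, function(s0) c(s0, s0 + width))
  }
  tgt <- chillsTargets(cohort)
  out <- lapply(wins, function(w) {
    if (level == "participant") {
      X <- participantFeatureMatrix(cohort, window = w, ...)
      cv <- nestedLoocv(X, tgt$participant, lambdaGrid, control = control)
    } else {
      tf <- trialFeatureMatrix(cohort, window = w, ...)
      yTrial <- as.numeric(t(tgt$trial))[match(tf$units, paste0(
        rep(rownames(tgt$trial), each = ncol(tgt$trial)), "/",
        rep(colnames(tgt$trial), nrow(tgt$trial))))]
      cv <- nestedLotocv(tf$X, yTrial, lambdaGrid, control = control)
    }
    r <- accuracyR(cv)
    p <- if (is.na(r)) NA_real_
         else pearsonRP(cv@yPred, cv@yActual, sided = "one")$p
    data.frame(start = w[1L], end = w[2L], duration = w[2L] - w[1L],
               accuracy_r = r, p = p)
  })
  do.call(rbind, out)
}

#' Learning curve by repeated subsampling
#'
#' Repeatedly subsamples training units at each fraction and reports the
#' mean and SD of nested-CV accuracy, to check that accuracy has converged
#' by the full sample size.
#'
#' @param X units x features matrix.
#' @param y targets.
#' @param fractions training-set fractions in (0, 1].
#' @param reps random subsamples per fraction (fraction 1 runs once).
#' @param seed integer seed.
#' @param lambdaGrid candidate penalties.
#' @param control convergence settings, see \code{\link{cvControl}}.
#' @return data.frame with fraction, n, mean and SD accuracy.
#' @export
learningCurve <- function(X, y, fractions = c(0.4, 0.6, 0.8, 1), reps = 10L,
                          seed = 1L, lambdaGrid = defaultLambdaGrid(),
                          control = cvControl()) {
  X <- checkDesign(X, y)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  n <- nrow(X)
  out <- lapply(fractions, function(f) {
    m <- max(4L, floor(f * n))
    rr <- if (m >= n) 1L else reps
    accs <- vapply(seq_len(rr), function(b) {
      idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
      accuracyR(nestedLoocv(X[idx, , drop = FALSE], y[idx], lambdaGrid,
                              control = control))
    }, 0)
    data.frame(fraction = f, n = m, mean_accuracy = mean(accs, na.rm = TRUE),
               sd_accuracy = if (rr > 1L) sd(accs, na.rm = TRUE) else 0)
  })
  do.call(rbind, out)
}
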