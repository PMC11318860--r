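## End-to-end orchestration: one config in, a run directory of tables,
## a JSON manifest and a plain-text report out.

## FNV-1a in double arithmetic (R integers are 32-bit signed)
fnv1aHash <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    lowByte <- h %% 256
    h <- h - lowByte + bitwXor(as.integer(lowByte), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Run the full decoding pipeline
#'
#' Orchestrates: cohort input (a directory in the package's plain-text
#' layout, or simulation from config), behavioural targets, per-network-pair
#' connectivity features, nested leave-one-out LASSO decoding, correlation
#' p-values with BH-FDR across pairs, and (optionally) permutation tests
#' for FDR-surviving pairs. Deterministic given the config and seed.
#'
#' Config (list or YAML path) sections:
#' \describe{
#'   \item{cohort}{either \code{dir}, or \code{simulate} = TRUE plus any
#'     \code{\link{simulationConfig}} arguments.}
#'   \item{features}{\code{window} (NULL or c(start, end)), \code{shrinkage},
#'     \code{bandpass} (logical).}
#'   \item{model}{\code{pairs} ("auditory", "all", or a list of 2-vectors),
#'     \code{lambda_grid}, \code{target} label.}
#'   \item{inference}{\code{alpha}, \code{n_perm} (0 disables permutation).}
#'   \item{out}{run directory.}
#'   \item{seed}{integer.}
#' }
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a list with the per-pair results table, the fitted
#'   transfer model for the auditory-reward pair, and the run directory.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$out %||% stop("config needs an 'out' directory")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  cohortCfg <- config$cohort %||% list()
  cohort <- if (!is.null(cohortCfg$dir)) {
    readCohort(cohortCfg$dir)
  } else {
    simArgs <- cohortCfg[setdiff(names(cohortCfg), c("simulate", "physio"))]
    simArgs$seed <- simArgs$seed %||% seed
    simCfg <- do.call(simulationConfig, simArgs)
    simulateCohort(simCfg, physio = isTRUE(cohortCfg$physio))
  }

  featCfg <- config$features %||% list()
  window <- if (!is.null(featCfg$window)) as.numeric(featCfg$window) else NULL
  shrinkage <- featCfg$shrinkage %||% "auto"
  useBp <- featCfg$bandpass %||% TRUE

  modCfg <- config$model %||% list()
  lambdaGrid <- as.numeric(modCfg$lambda_grid %||% defaultLambdaGrid())
  targetLabel <- modCfg$target %||% "chill"
  infCfg <- config$inference %||% list()
  alpha <- infCfg$alpha %||% 0.05
  nPerm <- as.integer(infCfg$n_perm %||% 0L)

  tgt <- chillsTargets(cohort, label = targetLabel)
  writeTsv(data.frame(participant = names(tgt$participant),
                      target = tgt$participant),
           file.path(outDir, "targets.tsv"))

  pairSpec <- modCfg$pairs %||% "auditory"
  allPairs <- listNetworkPairs(cohort@parcellation)
  pairs <- if (identical(pairSpec, "all")) {
    allPairs[, c("netA", "netB")]
  } else if (identical(pairSpec, "auditory")) {
    ap <- allPairs[allPairs$hasAuditory, c("netA", "netB")]
    ap
  } else {
    do.call(rbind, lapply(pairSpec, function(p)
      data.frame(netA = p[[1L]], netB = p[[2L]])))
  }

  results <- list(); fits <- list()
  for (k in seq_len(nrow(pairs))) {
    nets <- c(pairs$netA[k], pairs$netB[k])
    X <- participantFeatureMatrix(cohort, window = window,
                                  networks = nets, shrinkage = shrinkage,
                                  applyBandpass = useBp)
    cv <- nestedLoocv(X, tgt$participant, lambdaGrid)
    r <- accuracyR(cv)
    p <- if (is.na(r)) NA_real_
         else pearsonRP(cv@yPred, cv@yActual, sided = "one")$p
    results[[k]] <- data.frame(netA = nets[1L], netB = nets[2L],
                               n_features = ncol(X), accuracy_r = r, p = p)
    fits[[k]] <- list(X = X, cv = cv)
    writeTsv(predictions(cv),
             file.path(outDir, sprintf("predictions_%s-%s.tsv",
                                       nets[1L], nets[2L])))
  }
  tab <- do.call(rbind, results)
  fdr <- bhFdr(tab$p, alpha)
  tab$p_fdr <- fdr$pAdjusted
  tab$significant_fdr <- fdr$reject
  tab$perm_p <- NA_real_
  if (nPerm > 0L) {
    for (k in which(tab$significant_fdr)) {
      pt <- permutationTest(function(X, y)
        accuracyR(nestedLoocv(X, y, lambdaGrid)),
        fits[[k]]$X, tgt$participant, nPerm = nPerm, seed = seed + k)
      tab$perm_p[k] <- pt$p
    }
  }
  writeTsv(tab, file.path(outDir, "network_pair_results.tsv"))

  ## transfer model for the headline auditory-reward pair (when present)
  model <- NULL
  arIdx <- which((tab$netA == "auditory" & tab$netB == "reward") |
                 (tab$netA == "reward" & tab$netB == "auditory"))
  if (length(arIdx)) {
    model <- fitTransferModel(fits[[arIdx[1L]]]$X, tgt$participant,
                              lambdaGrid)
    exportModel(model, file.path(outDir, "model_auditory-reward.json"))
    writeTsv(data.frame(edge = edgeIds(model),
                        weight = model@weights),
             file.path(outDir, "weights_auditory-reward.tsv"))
  }

  manifest <- list(package = "chillconn",
                   version = as.character(utils::packageVersion("chillconn")),
                   seed = seed, alpha = alpha, n_perm = nPerm,
                   lambda_grid = lambdaGrid,
                   target = targetLabel,
                   window = window %||% "full epoch",
                   shrinkage = shrinkage,
                   decisions = c(
                     "fold-internal standardisation",
                     "lambda ties broken toward stronger shrinkage",
                     "Ledoit-Wolf shrinkage partial correlation"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  rep <- c("Network-pair decoding of emotion duration",
           sprintf("%-18s %-18s %5s %9s %9s %9s %4s", "network A",
                   "network B", "k", "r", "p", "p(FDR)", "sig"),
           sprintf("%-18s %-18s %5d %9.3f %9.4f %9.4f %4s",
                   tab$netA, tab$netB, tab$n_features, tab$accuracy_r,
                   tab$p, tab$p_fdr, ifelse(tab$significant_fdr, "*", "")))
  writeLines(rep, file.path(outDir, "report.txt"))
  invisible(list(results = tab, model = model, dir = outDir,
                 cohort = cohort))
}

#' Export / import a fitted decoder as JSON
#'
#' Serialises weights, intercept, penalty, training scaler and edge
#' identities with a provenance hash; import validates the hash and edge
#' identities.
#'
#' @param fit a \linkS4class{LassoFit}.
#' @param path JSON file path.
#' @return \code{exportModel}: the path, invisibly; \code{importModel}:
#'   the \linkS4class{LassoFit}.
#' @export
exportModel <- function(fit, path) {
  payload <- list(weights = fit@weights, intercept = fit@intercept,
                  lambda = fit@lambda, center = fit@center,
                  scale = fit@scale, featureIds = fit@featureIds)
  body <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  obj <- list(payload = payload, hash = fnv1aHash(as.character(body)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname exportModel
#' @export
importModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pl <- obj$payload
  body <- jsonlite::toJSON(
    list(weights = pl$weights, intercept = pl$intercept, lambda = pl$lambda,
         center = pl$center, scale = pl$scale, featureIds = pl$featureIds),
    auto_unbox = TRUE, digits = NA)
  if (!identical(fnv1aHash(as.character(body)), obj$hash))
    warning("provenance hash mismatch: model file may have been edited")
  new("LassoFit", weights = pl$weights, intercept = pl$intercept,
      lambda = pl$lambda, center = pl$center, scale = pl$scale,
      featureIds = pl$featureIds)
}
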