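## Cohort directory layout: plain-text, BIDS-flavoured.
##   parcellation.tsv                      roi_id, network, hemisphere
##   sub-XX_trial-YY_epoch-taskrest_bold.tsv   volumes x ROIs, ROI-id header
##   sub-XX_trial-YY_epoch-music_bold.tsv
##   sub-XX_trial-YY_events.tsv            onset, duration, trial_type
##   sub-XX_trial-YY_physio.tsv            time, ppg, resp, eda
##   sub-XX_epoch-intrinsic_bold.tsv       optional long rest
##   ground_truth.json                     simulator ground truth
##   cohort.json                           tr, durations, rates

writeTsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Write a cohort to a directory of plain-text files
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  parc <- cohort@parcellation
  writeTsv(data.frame(roi_id = parc@roiIds, network = parc@network,
                      hemisphere = parc@hemisphere),
           file.path(dir, "parcellation.tsv"))
  meta <- list(tr = cohort@trials[[1L]][[1L]]$rest@tr,
               participants = names(cohort@trials),
               trials = names(cohort@trials[[1L]]))
  for (pid in names(cohort@trials)) {
    for (tid in names(cohort@trials[[pid]])) {
      trial <- cohort@trials[[pid]][[tid]]
      stem <- file.path(dir, paste0(pid, "_", tid))
      writeTsv(as.data.frame(signalMatrix(trial$rest)),
               paste0(stem, "_epoch-taskrest_bold.tsv"))
      writeTsv(as.data.frame(signalMatrix(trial$music)),
               paste0(stem, "_epoch-music_bold.tsv"))
      writeEvents(trial$events, paste0(stem, "_events.tsv"))
      if (length(trial$physio)) {
        rate <- trial$physio$ppg@rate
        n <- length(trial$physio$ppg@samples)
        writeTsv(data.frame(time = (seq_len(n) - 1L) / rate,
                            ppg = trial$physio$ppg@samples,
                            resp = trial$physio$respiration@samples,
                            eda = trial$physio$eda@samples),
                 paste0(stem, "_physio.tsv"))
        meta$physio_rate <- rate
      }
    }
    if (!is.null(cohort@intrinsic[[pid]]))
      writeTsv(as.data.frame(signalMatrix(cohort@intrinsic[[pid]])),
               file.path(dir, paste0(pid, "_epoch-intrinsic_bold.tsv")))
  }
  if (length(cohort@groundTruth)) {
    gt <- cohort@groundTruth
    jsonlite::write_json(
      list(latentCoupling = as.list(gt$latentCoupling),
           plantedEdges = apply(gt$plantedEdges, 1L, paste, collapse = "--"),
           trueTarget = as.data.frame(gt$trueTarget)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

readBoldTsv <- function(path, tr, epoch, pid, tid) {
  tab <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("validation error in ", path, ": non-numeric BOLD")
  newRoiTimeSeries(m, tr, epoch, pid, tid)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir cohort directory.
#' @return a \linkS4class{CohortDataset} (ground truth attached when the
#'   directory carries it).
#' @export
readCohort <- function(dir) {
  metaPath <- file.path(dir, "cohort.json")
  parcPath <- file.path(dir, "parcellation.tsv")
  for (f in c(metaPath, parcPath))
    if (!file.exists(f)) stop("missing input: ", f)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  parcTab <- read.delim(parcPath, sep = "\t", stringsAsFactors = FALSE)
  parc <- new("ParcellationSpec", roiIds = parcTab$roi_id,
              network = parcTab$network, hemisphere = parcTab$hemisphere)
  trials <- list(); intrinsic <- list()
  for (pid in meta$participants) {
    ptr <- list()
    for (tid in meta$trials) {
      stem <- file.path(dir, paste0(pid, "_", tid))
      restPath <- paste0(stem, "_epoch-taskrest_bold.tsv")
      musicPath <- paste0(stem, "_epoch-music_bold.tsv")
      evPath <- paste0(stem, "_events.tsv")
      for (f in c(restPath, musicPath, evPath))
        if (!file.exists(f)) stop("missing input: ", f)
      music <- readBoldTsv(musicPath, meta$tr, "music", pid, tid)
      physio <- list()
      phPath <- paste0(stem, "_physio.tsv")
      if (file.exists(phPath)) {
        ph <- read.delim(phPath, sep = "\t")
        rate <- meta$physio_rate %||% (1 / median(diff(ph$time)))
        physio <- list(
          ppg = new("PhysioTrace", channel = "ppg", rate = rate,
                    samples = ph$ppg),
          respiration = new("PhysioTrace", channel = "respiration",
                            rate = rate, samples = ph$resp),
          eda = new("PhysioTrace", channel = "eda", rate = rate,
                    samples = ph$eda))
      }
      ptr[[tid]] <- list(
        rest = readBoldTsv(restPath, meta$tr, "task_rest", pid, tid),
        music = music,
        events = readEvents(evPath, epochDuration(music)),
        physio = physio)
    }
    trials[[pid]] <- ptr
    intPath <- file.path(dir, paste0(pid, "_epoch-intrinsic_bold.tsv"))
    if (file.exists(intPath))
      intrinsic[[pid]] <- readBoldTsv(intPath, meta$tr, "intrinsic_rest",
                                      pid, NA_character_)
  }
  gt <- list()
  gtPath <- file.path(dir, "ground_truth.json")
  if (file.exists(gtPath)) {
    raw <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    gt <- list(latentCoupling = unlist(raw$latentCoupling),
               plantedEdges = do.call(rbind,
                 strsplit(raw$plantedEdges, "--", fixed = TRUE)),
               trueTarget = as.matrix(raw$trueTarget))
  }
  new("CohortDataset", parcellation = parc, trials = trials,
      intrinsic = intrinsic, groundTruth = gt, config = NULL)
}
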