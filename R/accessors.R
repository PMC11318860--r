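#' Accessors for chillconn classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("roiIds", function(x) standardGeneric("roiIds"))
#' @rdname accessors
#' @export
setMethod("roiIds", "ParcellationSpec", function(x) x@roiIds)
#' @rdname accessors
#' @export
setMethod("roiIds", "RoiTimeSeries", function(x) colnames(x@data))

#' @rdname accessors
#' @export
setGeneric("networkOf", function(x) standardGeneric("networkOf"))
#' @rdname accessors
#' @export
setMethod("networkOf", "ParcellationSpec",
          function(x) setNames(x@network, x@roiIds))

#' @rdname accessors
#' @export
setGeneric("hemisphereOf", function(x) standardGeneric("hemisphereOf"))
#' @rdname accessors
#' @export
setMethod("hemisphereOf", "ParcellationSpec",
          function(x) setNames(x@hemisphere, x@roiIds))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "RoiTimeSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("samplingInterval", function(x) standardGeneric("samplingInterval"))
#' @rdname accessors
#' @export
setMethod("samplingInterval", "RoiTimeSeries", function(x) x@tr)

#' @rdname accessors
#' @export
setGeneric("epochRole", function(x) standardGeneric("epochRole"))
#' @rdname accessors
#' @export
setMethod("epochRole", "RoiTimeSeries", function(x) x@epoch)

#' @rdname accessors
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))
#' @rdname accessors
#' @export
setMethod("epochDuration", "RoiTimeSeries", function(x) nrow(x@data) * x@tr)

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
#' @rdname accessors
#' @export
setMethod("eventTable", "EventTrain", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "ConnectivityFeatures", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureValues", "RateSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("edgeIds", function(x) standardGeneric("edgeIds"))
#' @rdname accessors
#' @export
setMethod("edgeIds", "ConnectivityFeatures",
          function(x) paste(x@edges[, 1L], x@edges[, 2L], sep = "--"))
#' @rdname accessors
#' @export
setMethod("edgeIds", "LassoFit", function(x) x@featureIds)

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))
#' @rdname accessors
#' @export
setMethod("modelWeights", "LassoFit",
          function(x) setNames(x@weights, x@featureIds))

#' @rdname accessors
#' @export
setGeneric("accuracyR", function(x) standardGeneric("accuracyR"))
#' @rdname accessors
#' @export
setMethod("accuracyR", "CvResult", function(x) x@accuracyR)

#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
#' @rdname accessors
#' @export
setMethod("predictions", "CvResult", function(x)
  data.frame(unit = x@unitIds, actual = x@yActual, predicted = x@yPred,
             lambda = x@foldLambdas))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "CohortDataset", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("parcellation", function(x) standardGeneric("parcellation"))
#' @rdname accessors
#' @export
setMethod("parcellation", "CohortDataset", function(x) x@parcellation)

#' @rdname accessors
#' @export
setGeneric("cohortTrials", function(x) standardGeneric("cohortTrials"))
#' @rdname accessors
#' @export
setMethod("cohortTrials", "CohortDataset", function(x) x@trials)

#' @rdname accessors
#' @export
setGeneric("intrinsicRest", function(x) standardGeneric("intrinsicRest"))
#' @rdname accessors
#' @export
setMethod("intrinsicRest", "CohortDataset", function(x) x@intrinsic)
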