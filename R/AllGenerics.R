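#' Accessors for nirsmvpa classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @param x an object (for `[[`-style accessors).
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("designRegressor", function(object) standardGeneric("designRegressor"))
#' @rdname accessors
#' @export
setMethod("designRegressor", "TaskDesign", function(object) object@regressor)

#' @rdname accessors
#' @export
setGeneric("designBoxcar", function(object) standardGeneric("designBoxcar"))
#' @rdname accessors
#' @export
setMethod("designBoxcar", "TaskDesign", function(object) object@boxcar)

#' @rdname accessors
#' @export
setGeneric("cohortMeta", function(object) standardGeneric("cohortMeta"))
#' @rdname accessors
#' @export
setMethod("cohortMeta", "Cohort", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))
#' @rdname accessors
#' @export
setMethod("cohortSubjects", "Cohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setGeneric("cohortDesign", function(object) standardGeneric("cohortDesign"))
#' @rdname accessors
#' @export
setMethod("cohortDesign", "Cohort", function(object) object@design)

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setMethod("cohortTruth", "Cohort", function(object)
  list(maps = object@truthMaps, u = object@meta$u,
       severity = object@meta$severity))

#' @rdname accessors
#' @export
setGeneric("pcScores", function(object) standardGeneric("pcScores"))
#' @rdname accessors
#' @export
setMethod("pcScores", "PCModel", function(object) object@scores)

#' @rdname accessors
#' @export
setGeneric("pcComponents", function(object) standardGeneric("pcComponents"))
#' @rdname accessors
#' @export
setMethod("pcComponents", "PCModel", function(object) object@components)

#' @rdname accessors
#' @export
setGeneric("pcMeanMap", function(object) standardGeneric("pcMeanMap"))
#' @rdname accessors
#' @export
setMethod("pcMeanMap", "PCModel", function(object) object@meanMap)

#' @rdname accessors
#' @export
setGeneric("explainedFraction", function(object) standardGeneric("explainedFraction"))
#' @rdname accessors
#' @export
setMethod("explainedFraction", "PCModel", function(object) object@explainedFraction)

#' @rdname accessors
#' @export
setGeneric("rankOrder", function(object) standardGeneric("rankOrder"))
#' @rdname accessors
#' @export
setMethod("rankOrder", "PCRanking", function(object) object@order)

#' @rdname accessors
#' @export
setGeneric("rankTValues", function(object) standardGeneric("rankTValues"))
#' @rdname accessors
#' @export
setMethod("rankTValues", "PCRanking", function(object) object@tValues)

#' @rdname accessors
#' @export
setGeneric("svmWeights", function(object) standardGeneric("svmWeights"))
#' @rdname accessors
#' @export
setMethod("svmWeights", "LinearSVMModel", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("cvAccuracy", function(object) standardGeneric("cvAccuracy"))
#' @rdname accessors
#' @export
setMethod("cvAccuracy", "CVResult", function(object) object@accuracy)
#' @rdname accessors
#' @export
setMethod("cvAccuracy", "TuningCurve", function(object) object@accuracy)

#' @rdname accessors
#' @export
setGeneric("cvTable", function(object) standardGeneric("cvTable"))
#' @rdname accessors
#' @export
setMethod("cvTable", "CVResult", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("decisionScores", function(object) standardGeneric("decisionScores"))
#' @rdname accessors
#' @export
setMethod("decisionScores", "CVResult", function(object)
  setNames(object@table$score, object@table$subject_id))

#' @rdname accessors
#' @export
setGeneric("rankLists", function(object) standardGeneric("rankLists"))
#' @rdname accessors
#' @export
setMethod("rankLists", "CVResult", function(object) object@rankLists)

#' @rdname accessors
#' @export
setGeneric("bestK", function(object) standardGeneric("bestK"))
#' @rdname accessors
#' @export
setMethod("bestK", "TuningCurve", function(object) object@bestK)

#' @rdname accessors
#' @export
setGeneric("kValues", function(object) standardGeneric("kValues"))
#' @rdname accessors
#' @export
setMethod("kValues", "TuningCurve", function(object) object@kValues)

#' @rdname accessors
#' @export
setGeneric("nullAccuracies", function(object) standardGeneric("nullAccuracies"))
#' @rdname accessors
#' @export
setMethod("nullAccuracies", "PermutationNull", function(object) object@accuracies)

#' @rdname accessors
#' @export
setGeneric("severityR", function(object) standardGeneric("severityR"))
#' @rdname accessors
#' @export
setMethod("severityR", "SeverityPrediction", function(object) object@r)

#' @rdname accessors
#' @export
setGeneric("severityP", function(object) standardGeneric("severityP"))
#' @rdname accessors
#' @export
setMethod("severityP", "SeverityPrediction", function(object) object@p)

#' @rdname accessors
#' @export
setGeneric("severityTable", function(object) standardGeneric("severityTable"))
#' @rdname accessors
#' @export
setMethod("severityTable", "SeverityPrediction", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("severityTransform", function(object) standardGeneric("severityTransform"))
#' @rdname accessors
#' @export
setMethod("severityTransform", "SeverityPrediction", function(object) object@transform)
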