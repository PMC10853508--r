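#' Block task design with hemodynamic regressor
#'
#' Holds the sampling grid of one run, the binary task boxcar (1 during
#' task blocks, 0 during rest) and the model regressor obtained by
#' convolving the boxcar with the canonical HRF and rescaling to unit peak.
#'
#' @slot sampleRate samples per second.
#' @slot totalDuration run length in seconds.
#' @slot taskEpoch,restEpoch block lengths in seconds.
#' @slot boxcar binary vector, one entry per sample.
#' @slot regressor HRF-convolved boxcar, unit maximum.
#' @slot truncatedFinal `TRUE` when the final block was cut short because
#'   the block period does not divide the run length.
#'
#' @seealso [makeDesign()]
#' @export
setClass("TaskDesign",
  representation(
    sampleRate = "numeric", totalDuration = "numeric",
    taskEpoch = "numeric", restEpoch = "numeric",
    boxcar = "numeric", regressor = "numeric", truncatedFinal = "logical"
  )
)

setValidity("TaskDesign", function(object) {
  n <- round(object@sampleRate * object@totalDuration)
  if (length(object@boxcar) != n)
    return(sprintf("boxcar length %d != sampleRate * totalDuration = %d",
                   length(object@boxcar), n))
  if (!all(object@boxcar %in% c(0, 1))) return("boxcar must be binary")
  if (length(object@regressor) != length(object@boxcar))
    return("regressor and boxcar lengths differ")
  TRUE
})

#' Synthetic-cohort simulation settings
#'
#' Parameters of the generative model for fNIRS-like two-chromophore
#' cohorts: a group-dependent spatial activation pattern superposed on
#' shared global physiology, slow drift and sensor noise, with severity
#' scores coupled to per-subject pattern expression in the affected group.
#' Defaults mirror the acquisition geometry the pipeline targets
#' (54 channels, 19 control vs 17 affected subjects).
#'
#' @seealso [simConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
  representation(
    nChannels = "integer", nTD = "integer", nASD = "integer",
    baselineMap = "numeric", effectPattern = "numeric",
    effectScale = "numeric", uShape = "numeric",
    noiseSD = "numeric", globalSD = "numeric", driftSD = "numeric",
    globalAR = "numeric", oxyDeoxyRatio = "numeric",
    severityIntercept = "numeric", severitySlope = "numeric",
    severityNoiseSD = "numeric", subEpochs = "logical", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  if (object@nTD < 1L || object@nASD < 1L) return("group counts must be >= 1")
  if (length(object@effectPattern) != object@nChannels)
    return("effectPattern length != nChannels")
  if (length(object@baselineMap) != object@nChannels)
    return("baselineMap length != nChannels")
  if (any(c(object@noiseSD, object@globalSD, object@driftSD,
            object@severityNoiseSD) < 0))
    return("noise SDs must be >= 0")
  if (object@oxyDeoxyRatio >= 0)
    return("oxyDeoxyRatio must be negative (HbR anticorrelated with HbO)")
  TRUE
})

#' Two-chromophore channel time series for one subject
#'
#' @slot oxy,deoxy channels x samples matrices of HbO / HbR concentration
#'   change (arbitrary units).
#' @slot subjectId subject identifier.
#' @slot group diagnostic label.
#' @export
setClass("SubjectTimeSeries",
  representation(oxy = "matrix", deoxy = "matrix",
                 subjectId = "character", group = "character")
)

setValidity("SubjectTimeSeries", function(object) {
  if (!all(dim(object@oxy) == dim(object@deoxy)))
    return("oxy and deoxy must have identical dimensions")
  if (!all(is.finite(object@oxy)) || !all(is.finite(object@deoxy)))
    return("time series must be finite")
  TRUE
})

#' A simulated (or loaded) cohort of subjects
#'
#' Bundles the per-subject time series, the shared task design, and -- for
#' simulated cohorts -- the generative ground truth (injected amplitude
#' maps, pattern-expression factors and severity parameters) used by
#' recovery tests.
#'
#' @slot subjects list of [SubjectTimeSeries-class] objects.
#' @slot design the shared [TaskDesign-class].
#' @slot meta `DataFrame` with columns `subject_id`, `group`, `severity`
#'   (`NA` for the unaffected group) and, when simulated, the expression
#'   factor `u`.
#' @slot truthMaps subjects x channels matrix of injected amplitude maps
#'   (zero-row matrix when unknown).
#' @export
setClass("Cohort",
  representation(subjects = "list", design = "TaskDesign",
                 meta = "DataFrame", truthMaps = "matrix")
)

setValidity("Cohort", function(object) {
  ids <- object@meta$subject_id
  if (anyDuplicated(ids)) return("duplicate subject ids")
  if (length(object@subjects) != length(ids))
    return("subjects list and metadata row count differ")
  if (nlevels(factor(object@meta$group)) != 2L)
    return("cohort must contain exactly two groups")
  TRUE
})

#' Principal-component model of across-subject beta maps
#'
#' Centered PCA of the subjects x channels beta matrix: orthonormal
#' component maps, per-subject component scores, the centering map and
#' per-component explained-variance fractions.
#'
#' @slot components nPC x nFeatures orthonormal matrix (rows are component
#'   maps in channel space).
#' @slot scores nSubjects x nPC matrix of subject coordinates.
#' @slot meanMap centering offset (one value per feature).
#' @slot explainedFraction fraction of total centered variance captured by
#'   each retained component (non-increasing).
#' @slot subjectIds,featureNames dimension names.
#' @seealso [fitPCA()], [reconstructMap()]
#' @export
setClass("PCModel",
  representation(components = "matrix", scores = "matrix",
                 meanMap = "numeric", explainedFraction = "numeric",
                 subjectIds = "character", featureNames = "character")
)

setValidity("PCModel", function(object) {
  cc <- object@components %*% t(object@components)
  if (max(abs(cc - diag(nrow(cc)))) > 1e-8)
    return("components are not orthonormal")
  ef <- object@explainedFraction
  if (any(ef < -1e-12 | ef > 1 + 1e-12)) return("explainedFraction outside [0,1]")
  if (any(diff(ef) > 1e-12)) return("explainedFraction must be non-increasing")
  if (sum(ef) > 1 + 1e-8) return("explainedFraction sums to more than 1")
  TRUE
})

#' t-score ranking of principal components
#'
#' @slot order permutation of component indices, decreasing \eqn{|t|},
#'   ties broken by the lower index.
#' @slot tValues two-sample t statistic per component.
#' @slot fittedOn identifiers of the subjects the t tests were computed on
#'   (kept for leakage auditing).
#' @export
setClass("PCRanking",
  representation(order = "integer", tValues = "numeric",
                 fittedOn = "character")
)

#' Univariate threshold classifier
#'
#' The one-dimensional linear rule: predict the first class when
#' `w * x + b > 0`, with orientation `w` restricted to +1/-1 and threshold
#' `b` fitted by exhaustive search over training-data midpoints.
#' @export
setClass("UnivariateModel",
  representation(w = "numeric", b = "numeric", levels = "character",
                 trainingAccuracy = "numeric")
)

#' Soft-margin linear SVM
#'
#' @slot weights hyperplane normal in the (standardized) input space.
#' @slot bias intercept; the decision score is
#'   `weights . standardize(x) + bias`, positive scores predicting the
#'   second class level.
#' @slot cost regularization constant C.
#' @slot center,scale per-feature standardization parameters frozen at fit
#'   time.
#' @slot levels the two class levels (score sign convention: positive =
#'   second level).
#' @seealso [fitLinearSVM()]
#' @export
setClass("LinearSVMModel",
  representation(weights = "numeric", bias = "numeric", cost = "numeric",
                 center = "numeric", scale = "numeric", levels = "character")
)

#' Leave-one-out cross-validation result
#'
#' @slot table per-subject data.frame: `subject_id`, `true`, `predicted`,
#'   `score` (continuous decision value of the held-out fold).
#' @slot accuracy fraction of correct held-out predictions.
#' @slot mode `"nested"` (fold-internal feature ranking) or `"pooled"`
#'   (ranking on all subjects, the leaky comparator).
#' @slot k number of selected features.
#' @slot rankLists nSubjects x nFeatures matrix; row i is the feature
#'   ranking used in subject i's fold.
#' @export
setClass("CVResult",
  representation(table = "data.frame", accuracy = "numeric",
                 mode = "character", k = "integer", rankLists = "matrix")
)

setValidity("CVResult", function(object) {
  ok <- mean(object@table$predicted == object@table$true)
  if (abs(ok - object@accuracy) > 1e-12)
    return("accuracy does not equal mean(predicted == true)")
  TRUE
})

#' Accuracy as a function of the number of selected components
#' @slot kValues grid of subset sizes.
#' @slot accuracy leave-one-out accuracy at each k.
#' @slot mode selection mode used.
#' @slot bestK smallest k attaining the maximum accuracy.
#' @export
setClass("TuningCurve",
  representation(kValues = "integer", accuracy = "numeric",
                 mode = "character", bestK = "integer")
)

#' Permutation null distribution of classification accuracy
#' @slot accuracies one accuracy per label permutation.
#' @slot config pipeline settings the null was generated under (mode, k or
#'   kRange, cost).
#' @slot seed RNG seed used.
#' @export
setClass("PermutationNull",
  representation(accuracies = "numeric", config = "list", seed = "integer")
)

#' Severity prediction from SVM decision scores
#' @slot table per-subject observed severity, decision score and the
#'   affine-transformed score (display-scale predicted severity).
#' @slot r Pearson correlation between decision scores and observed
#'   severity.
#' @slot p significance of r (permutation test by default).
#' @slot transform least-squares slope and intercept mapping scores to
#'   severity units (visualization only).
#' @export
setClass("SeverityPrediction",
  representation(table = "data.frame", r = "numeric", p = "numeric",
                 transform = "numeric", nPerm = "integer", method = "character")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "TaskDesign", function(object) {
  cat("TaskDesign:", object@totalDuration, "s at", object@sampleRate,
      "samples/s |", object@taskEpoch, "s task /", object@restEpoch,
      "s rest blocks\n")
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@meta$group)
  cat("Cohort of", length(object@subjects), "subjects (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  cat("  channels:", nrow(object@subjects[[1]]@oxy),
      " samples:", ncol(object@subjects[[1]]@oxy), "\n")
})

setMethod("show", "PCModel", function(object) {
  cat("PCModel:", nrow(object@components), "components over",
      ncol(object@components), "features,", nrow(object@scores),
      "subjects\n")
  ef <- object@explainedFraction
  cat(sprintf("  explained variance: PC1 %.1f%%, top-%d total %.1f%%\n",
              100 * ef[1], length(ef), 100 * sum(ef)))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult (leave-one-out, %s selection, k = %d): accuracy %.3f over %d subjects\n",
              object@mode, object@k, object@accuracy, nrow(object@table)))
})

setMethod("show", "TuningCurve", function(object) {
  cat(sprintf("TuningCurve (%s): k in [%d, %d], best k = %d (accuracy %.3f)\n",
              object@mode, min(object@kValues), max(object@kValues),
              object@bestK, max(object@accuracy)))
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf("PermutationNull: %d permutations, mean accuracy %.3f (mode %s)\n",
              length(object@accuracies), mean(object@accuracies),
              object@config$mode))
})

setMethod("show", "SeverityPrediction", function(object) {
  cat(sprintf("SeverityPrediction: r = %.3f (p = %.4g, %s, n = %d)\n",
              object@r, object@p, object@method, nrow(object@table)))
})
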