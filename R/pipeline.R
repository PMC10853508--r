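#' Pipeline configuration with study-standard defaults
#'
#' Collects every tunable of the analysis chain in one list. The defaults
#' reproduce the acquisition and analysis settings the pipeline targets:
#' 54 channels at 30 samples/s, 180-s runs of 18-s task / 12-s rest
#' blocks, 19 + 17 subjects, 32 retained principal components, 10 selected
#' components, nested selection, C = 1, 1000 permutations and significance
#' levels 0.05 / 0.005.
#'
#' @param ... overrides of the default entries (unknown names are an
#'   error).
#' @return a named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(nPerm = 50, seed = 7)
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    nChannels = 54L, sampleRate = 30, totalDuration = 180,
    taskEpoch = 18, restEpoch = 12,
    nTD = 19L, nASD = 17L,
    effectScale = 0.05,
    hrf = hrfParams(),
    cutoffPeriod = 128,
    detrend = TRUE, globalFilter = TRUE, useHbdiff = TRUE,
    nPC = 32L, k = 10L, kRange = NULL, mode = "nested", C = 1,
    nPerm = 1000L, alphas = c(0.05, 0.005),
    severityPerm = 10000L,
    cohortDir = NULL, outDir = NULL, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  defaults[names(dots)] <- dots
  structure(defaults, class = "PipelineConfig")
}

#' Run the full decoding pipeline
#'
#' Chains every stage: cohort simulation (or loading, when
#' `config$cohortDir` is set) -> signal preprocessing to betas -> PCA ->
#' leave-one-out SVM classification (and a tuning curve when `kRange` is
#' set) -> permutation null, p value and significance thresholds ->
#' severity prediction from the held-out decision scores. A fixed seed
#' makes the whole report reproducible bit for bit. When `config$outDir`
#' is set, all artifacts (cohort, beta TSV, PC tables, CV tables, null
#' distribution, severity tables) and a JSON report are written there.
#'
#' @param config a [pipelineConfig()] list.
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the cohort, beta
#'   `SummarizedExperiment`, [PCModel-class], [CVResult-class], optional
#'   [TuningCurve-class], [PermutationNull-class],
#'   [SeverityPrediction-class] and the `report` list (accuracy, p, r,
#'   thresholds, bestK, seed).
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  t0 <- Sys.time()

  if (is.null(config$cohortDir)) {
    say("simulate", "cohort of %d + %d subjects (seed %d)",
        config$nTD, config$nASD, config$seed)
    design <- makeDesign(config$sampleRate, config$totalDuration,
                         config$taskEpoch, config$restEpoch, config$hrf)
    cfg <- simConfig(nChannels = config$nChannels, nTD = config$nTD,
                     nASD = config$nASD, effectScale = config$effectScale,
                     seed = config$seed)
    cohort <- simulateCohort(cfg, design)
  } else {
    say("load", "cohort from %s", config$cohortDir)
    cohort <- readCohort(config$cohortDir)
  }

  say("preprocess", "detrend=%s global=%s hbdiff=%s", config$detrend,
      config$globalFilter, config$useHbdiff)
  se <- preprocessCohort(cohort, detrend = config$detrend,
                         globalFilter = config$globalFilter,
                         useHbdiff = config$useHbdiff,
                         cutoffPeriod = config$cutoffPeriod)
  labels <- colData(se)$group

  say("decompose", "PCA with %d components", config$nPC)
  pca <- fitPCA(se, nPC = config$nPC)

  say("classify", "LOO SVM, mode=%s, k=%d", config$mode, config$k)
  cv <- looSVM(pca, labels, k = config$k, mode = config$mode, C = config$C)
  curve <- NULL
  if (!is.null(config$kRange)) {
    say("tune", "k in [%d, %d]", min(config$kRange), max(config$kRange))
    curve <- tuningCurve(pca, labels, config$kRange, mode = config$mode,
                         C = config$C)
  }

  say("permute", "%d label permutations", config$nPerm)
  null <- permutationNull(pca, labels,
                          config = list(mode = config$mode, k = config$k,
                                        C = config$C),
                          nPerm = config$nPerm, seed = config$seed)
  p <- pValue(cv@accuracy, null, mode = "conservative")
  thr <- significanceThresholds(null, config$alphas)

  say("severity", "decision-score correlation on the affected group")
  sev <- predictSeverity(cv, cohortMeta(cohort), nPerm = config$severityPerm,
                         seed = config$seed)

  report <- list(
    accuracy = cv@accuracy, p = p, r = sev@r, severity_p = sev@p,
    thresholds = as.list(thr),
    bestK = if (is.null(curve)) config$k else curve@bestK,
    k = config$k, mode = config$mode, nPC = config$nPC,
    nPerm = config$nPerm, seed = config$seed,
    version = as.character(utils::packageVersion("nirsmvpa")))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    say("write", "artifacts to %s", config$outDir)
    writeCohort(cohort, file.path(config$outDir, "cohort"))
    writeBetaMatrix(se, file.path(config$outDir, "betas.tsv"))
    write.table(data.frame(PC = seq_along(pca@explainedFraction),
                           explained_fraction = pca@explainedFraction),
                file.path(config$outDir, "explained_fraction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(PC = rownames(pca@components), pca@components,
                           check.names = FALSE),
                file.path(config$outDir, "pc_components.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(subject_id = rownames(pca@scores), pca@scores,
                           check.names = FALSE),
                file.path(config$outDir, "pc_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeCVResult(cv, file.path(config$outDir, "cv_result"))
    write.table(data.frame(accuracy = null@accuracies),
                file.path(config$outDir, "null_accuracies.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sev@table, file.path(config$outDir, "severity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("done", "accuracy %.3f, p %.4g, severity r %.3f (%.1f s)",
      cv@accuracy, p, sev@r, as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(cohort = cohort, betas = se, pca = pca, cv = cv,
                 curve = curve, null = null, severity = sev,
                 report = report))
}
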