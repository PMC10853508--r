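#' Write / read a cohort on disk
#'
#' Layout: `metadata.tsv` (subject_id, group, severity, u),
#' `design.tsv` (sample, boxcar, regressor) with the scalar design
#' parameters in `design.json`, `truth_maps.tsv` when ground truth is
#' known, and one Parquet file per subject under `subjects/` holding the
#' two chromophore matrices (columns `chromophore`, `sample`,
#' `channel_01`...). Parquet stores doubles losslessly, so a round trip is
#' exact.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  meta <- as.data.frame(cohort@meta)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  d <- cohort@design
  write.table(data.frame(sample = seq_along(d@boxcar), boxcar = d@boxcar,
                         regressor = d@regressor),
              file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(sampleRate = d@sampleRate,
                            totalDuration = d@totalDuration,
                            taskEpoch = d@taskEpoch, restEpoch = d@restEpoch,
                            truncatedFinal = d@truncatedFinal),
                       file.path(dir, "design.json"), auto_unbox = TRUE,
                       digits = NA)
  if (nrow(cohort@truthMaps) > 0)
    write.table(data.frame(subject_id = rownames(cohort@truthMaps),
                           cohort@truthMaps, check.names = FALSE),
                file.path(dir, "truth_maps.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  for (s in cohort@subjects) {
    wide <- function(m, chrom) {
      df <- data.frame(chromophore = chrom, sample = seq_len(ncol(m)),
                       t(m), check.names = FALSE)
      colnames(df)[-(1:2)] <- .channel_names(nrow(m))
      df
    }
    arrow::write_parquet(rbind(wide(s@oxy, "oxy"), wide(s@deoxy, "deoxy")),
                         file.path(dir, "subjects",
                                   paste0(s@subjectId, ".parquet")))
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @param regressor optional regressor override when reading; by default
#'   the stored design table is used as-is.
#' @export
readCohort <- function(dir) {
  metaPath <- file.path(dir, "metadata.tsv")
  if (!file.exists(metaPath)) stop("missing metadata.tsv in ", dir)
  meta <- read.table(metaPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(meta)) stop("metadata.tsv lacks column '", col, "'")
  if (anyDuplicated(meta$subject_id))
    stop("duplicate subject ids in metadata.tsv")
  if (length(unique(meta$group)) != 2)
    stop("group labels must span exactly two classes")
  dj <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  dt <- read.table(file.path(dir, "design.tsv"), header = TRUE, sep = "\t")
  design <- new("TaskDesign", sampleRate = dj$sampleRate,
                totalDuration = dj$totalDuration, taskEpoch = dj$taskEpoch,
                restEpoch = dj$restEpoch, boxcar = dt$boxcar,
                regressor = dt$regressor, truncatedFinal = dj$truncatedFinal)
  lv <- unique(meta$group) # cohort file order defines the level order
  if (all(c("TD", "ASD") %in% lv)) lv <- c("TD", "ASD")
  subjects <- lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, "subjects", paste0(meta$subject_id[i], ".parquet"))
    if (!file.exists(f))
      stop("no time-series file for subject '", meta$subject_id[i], "'")
    df <- as.data.frame(arrow::read_parquet(f))
    mat <- function(chrom) {
      sub <- df[df$chromophore == chrom, , drop = FALSE]
      sub <- sub[order(sub$sample), , drop = FALSE]
      t(as.matrix(sub[, -(1:2), drop = FALSE]))
    }
    new("SubjectTimeSeries", oxy = mat("oxy"), deoxy = mat("deoxy"),
        subjectId = meta$subject_id[i], group = meta$group[i])
  })
  tm <- file.path(dir, "truth_maps.tsv")
  truth <- if (file.exists(tm)) {
    df <- read.table(tm, header = TRUE, sep = "\t", check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- df$subject_id; m
  } else matrix(numeric(0), 0, 0)
  metaDF <- S4Vectors::DataFrame(
    subject_id = meta$subject_id,
    group = factor(meta$group, levels = lv),
    severity = if ("severity" %in% names(meta)) meta$severity else NA_real_,
    u = if ("u" %in% names(meta)) meta$u else NA_real_)
  new("Cohort", subjects = subjects, design = design, meta = metaDF,
      truthMaps = truth)
}

#' Write / read a beta matrix as TSV
#'
#' One row per subject: `subject_id`, `group`, `severity`, then one column
#' per channel.
#'
#' @param se `SummarizedExperiment` from [preprocessCohort()].
#' @param path TSV file path.
#' @return `path` / a `SummarizedExperiment`.
#' @export
writeBetaMatrix <- function(se, path) {
  cd <- colData(se)
  df <- data.frame(subject_id = cd$subject_id,
                   group = as.character(cd$group),
                   severity = cd$severity,
                   t(assay(se, "beta")), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBetaMatrix
#' @export
readBetaMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (col in c("subject_id", "group"))
    if (!col %in% names(df)) stop("beta table lacks column '", col, "'")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject ids in beta table")
  lv <- unique(df$group)
  if (length(lv) != 2) stop("group labels must span exactly two classes")
  if (all(c("TD", "ASD") %in% lv)) lv <- c("TD", "ASD")
  chan <- setdiff(names(df), c("subject_id", "group", "severity", "u"))
  beta <- t(as.matrix(df[, chan, drop = FALSE]))
  colnames(beta) <- df$subject_id
  cd <- S4Vectors::DataFrame(
    subject_id = df$subject_id, group = factor(df$group, levels = lv),
    severity = if ("severity" %in% names(df)) df$severity else NA_real_)
  SummarizedExperiment(assays = list(beta = beta), colData = cd)
}

#' Write a cross-validation result
#'
#' Per-subject TSV (`subject_id`, `true`, `predicted`, `score`) plus a JSON
#' summary (accuracy, mode, k).
#'
#' @param cvResult a [CVResult-class].
#' @param path base path; `.tsv` and `.json` suffixes are appended.
#' @export
writeCVResult <- function(cvResult, path) {
  write.table(cvResult@table, paste0(path, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(accuracy = cvResult@accuracy,
                            mode = cvResult@mode, k = cvResult@k),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
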