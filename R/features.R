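# internal: coerce PCModel / SummarizedExperiment / matrix to a feature matrix
.feature_matrix <- function(x) {
  if (is(x, "PCModel")) return(x@scores)
  if (is(x, "SummarizedExperiment")) return(betaMatrix(x))
  if (is.matrix(x)) return(x)
  stop("expected a matrix, SummarizedExperiment or PCModel")
}

# internal: validated two-level factor
.two_level <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes")
  f
}

# internal: pooled or Welch two-sample t per column (level1 - level2)
.col_t <- function(x, f, flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  g1 <- f == levels(f)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per class")
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, var)
  if (flavor == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
  }
  d <- m1 - m2
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * 1e300))
  as.numeric(t)
}

#' Principal-component decomposition of a beta matrix
#'
#' Centered (unscaled) PCA of the subjects x features activation matrix:
#' the matrix is decomposed into orthonormal component maps and per-subject
#' scores so that row i reconstructs as
#' `meanMap + sum_j scores[i, j] * components[j, ]`. Channels share units,
#' so no per-feature standardization is applied.
#'
#' @param x subjects x features matrix, or a `SummarizedExperiment` from
#'   [preprocessCohort()].
#' @param nPC number of components to retain; at most
#'   `min(nSubjects - 1, nFeatures)`.
#' @return a [PCModel-class].
#' @examples
#' tab <- simulateFeatureTable(10, 10, 6, seed = 1)
#' fitPCA(tab$features, nPC = 4)
#' @export
fitPCA <- function(x, nPC = 32L) {
  X <- .feature_matrix(x)
  n <- nrow(X); p <- ncol(X)
  nPC <- as.integer(nPC)
  if (nPC < 1L || nPC > min(n - 1L, p))
    stop("nPC must lie in [1, min(nSubjects - 1, nFeatures)]")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total <- sum(Xc^2)
  if (total == 0) stop("constant matrix: no variance to decompose")
  sv <- svd(Xc)
  comps <- t(sv$v[, seq_len(nPC), drop = FALSE])
  scores <- Xc %*% t(comps)
  ef <- (sv$d^2 / total)[seq_len(nPC)]
  ids <- rownames(X); if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  feats <- colnames(X); if (is.null(feats)) feats <- .channel_names(p)
  dimnames(scores) <- list(ids, sprintf("PC%02d", seq_len(nPC)))
  dimnames(comps) <- list(sprintf("PC%02d", seq_len(nPC)), feats)
  new("PCModel", components = comps, scores = scores, meanMap = setNames(mu, feats),
      explainedFraction = ef, subjectIds = ids, featureNames = feats)
}

#' Reconstruct a subject's map from its leading components
#'
#' `meanMap + sum_{j<=k} score[i, j] * component[j, ]`; at full rank this
#' reproduces the original row to numerical precision, and `k = 0` returns
#' the mean map.
#'
#' @param model a [PCModel-class].
#' @param subject row index or subject id.
#' @param k number of leading components (0..nPC).
#' @return named feature vector.
#' @export
reconstructMap <- function(model, subject, k = nrow(model@components)) {
  i <- if (is.character(subject)) match(subject, model@subjectIds) else subject
  if (is.na(i) || i < 1 || i > nrow(model@scores))
    stop("subject index out of range")
  if (k < 0 || k > nrow(model@components)) stop("k out of range")
  out <- model@meanMap
  if (k > 0)
    out <- out + as.numeric(model@scores[i, seq_len(k), drop = FALSE] %*%
                              model@components[seq_len(k), , drop = FALSE])
  out
}

#' Rank components by group-difference t score
#'
#' Two-sample t statistic per component score computed on the given subject
#' subset only (the mechanism that makes cross-validation "nested" when the
#' subset excludes the held-out subject), ordered by decreasing `|t|`, ties
#' broken by the lower component index.
#'
#' @param x score matrix or [PCModel-class].
#' @param labels two-class factor over all subjects.
#' @param subset row indices (or subject ids, for a PCModel) to compute the
#'   t tests on; default all subjects.
#' @param flavor `"pooled"` (default) or `"welch"` t statistic.
#' @return a [PCRanking-class].
#' @export
rankPCs <- function(x, labels, subset = NULL, flavor = c("pooled", "welch")) {
  X <- .feature_matrix(x)
  f <- .two_level(labels)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (is.null(subset)) subset <- seq_len(nrow(X))
  if (is.character(subset)) subset <- match(subset, ids)
  t <- .col_t(X[subset, , drop = FALSE], f[subset], flavor)
  ord <- order(-abs(t), seq_along(t))
  new("PCRanking", order = as.integer(ord), tValues = t,
      fittedOn = ids[subset])
}

#' Per-feature group contrast
#'
#' Mean difference (first level minus second level; with the default
#' cohort labels, control minus affected, so positive values mark features
#' where the control group is greater) and its two-sample t statistic for
#' every feature.
#'
#' @param x beta matrix, `SummarizedExperiment`, or [PCModel-class] scores.
#' @param labels two-class factor.
#' @param flavor t statistic flavor, see [rankPCs()].
#' @return data.frame with `feature`, `meanDiff`, `t`.
#' @export
groupContrast <- function(x, labels, flavor = c("pooled", "welch")) {
  X <- .feature_matrix(x)
  f <- .two_level(labels)
  if (min(table(f)) == 0) stop("one class is empty")
  g1 <- f == levels(f)[1]
  d <- colMeans(X[g1, , drop = FALSE]) - colMeans(X[!g1, , drop = FALSE])
  t <- .col_t(X, f, flavor)
  feats <- colnames(X); if (is.null(feats)) feats <- .channel_names(ncol(X))
  data.frame(feature = feats, meanDiff = as.numeric(d), t = t)
}

#' Render a fitted SVM as a feature-space weight map
#'
#' The classifier trained on selected component scores is expressed in the
#' original feature (channel) space as the weighted sum of its component
#' maps, `sum_j w_j * PC_{selected[j]}`. Projecting the map back onto the
#' selected components recovers the SVM weights exactly (the components are
#' orthonormal).
#'
#' @param svmModel a [LinearSVMModel-class] trained on exactly
#'   `selectedPCs` (in that order).
#' @param pcModel the [PCModel-class] the scores came from.
#' @param selectedPCs component indices the SVM was trained on.
#' @return named feature-space weight vector.
#' @export
svmWeightMap <- function(svmModel, pcModel, selectedPCs) {
  w <- svmModel@weights
  if (length(w) != length(selectedPCs))
    stop("svmModel was not trained on length(selectedPCs) features")
  if (any(selectedPCs < 1 | selectedPCs > nrow(pcModel@components)))
    stop("selectedPCs out of range")
  as.numeric(w %*% pcModel@components[selectedPCs, , drop = FALSE]) |>
    setNames(pcModel@featureNames)
}
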