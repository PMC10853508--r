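#' Permutation null distribution of cross-validated accuracy
#'
#' Reruns the full selection + SVM + leave-one-out pipeline `nPerm` times
#' with the diagnostic labels permuted uniformly at random (group sizes
#' preserved) and records each accuracy. With `kRange` set, each
#' replicate's accuracy is the maximum of its tuning curve -- the
#' "tune-then-report" rule whose optimism the null quantifies; with a fixed
#' `k` the accuracy at that k is stored.
#'
#' @param x [PCModel-class], feature matrix, or `SummarizedExperiment`.
#' @param labels two-class factor.
#' @param config list with `mode` (`"nested"`/`"pooled"`), and either `k`
#'   (fixed subset size) or `kRange` (maximize over the grid); optional
#'   `C`.
#' @param nPerm number of permutations.
#' @param seed RNG seed (the permutations are its only use).
#' @param permutations optional list of explicit index permutations,
#'   overriding the random draws (e.g. the identity permutation recovers
#'   the observed accuracy exactly).
#' @return a [PermutationNull-class].
#' @examples
#' tab <- simulateFeatureTable(8, 8, 6, seed = 2)
#' permutationNull(tab$features, tab$labels,
#'                 config = list(mode = "nested", k = 3),
#'                 nPerm = 20, seed = 1)
#' @export
permutationNull <- function(x, labels, config = list(mode = "nested", k = 10L),
                            nPerm = 1000L, seed = NULL, permutations = NULL) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  X <- .feature_matrix(x)
  f <- .two_level(labels)
  mode <- match.arg(config$mode, c("nested", "pooled"))
  C <- if (is.null(config$C)) 1 else config$C
  ks <- if (!is.null(config$kRange)) as.integer(config$kRange)
        else as.integer(config$k)
  if (any(ks < 1L | ks > ncol(X))) stop("k out of range")
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(permutations))
    permutations <- lapply(seq_len(nPerm), function(i) sample.int(n))
  truthLv <- levels(f)
  acc <- vapply(permutations[seq_len(nPerm)], function(pm) {
    fp <- f[pm]
    g <- .loo_grid(X, fp, ks, mode, C)
    tr <- as.character(fp)
    max(apply(g$scores, 2, function(s) mean(truthLv[(s > 0) + 1] == tr)))
  }, numeric(1))
  new("PermutationNull", accuracies = acc,
      config = list(mode = mode, k = if (is.null(config$kRange)) ks else NULL,
                    kRange = config$kRange, C = C),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

.null_acc <- function(null) {
  if (is(null, "PermutationNull")) null@accuracies else as.numeric(null)
}

#' Permutation p value for an observed accuracy
#'
#' `"literal"` mode is the plain exceedance fraction
#' `#\{null > observed\} / nPerm`; `"conservative"` mode is the
#' add-one rule `(1 + #\{null >= observed\}) / (1 + nPerm)`, which counts
#' ties against the observation and can never return zero -- the
#' statistically recommended choice. The two modes bracket each other
#' (conservative >= literal).
#'
#' @param observed observed accuracy.
#' @param null a [PermutationNull-class] or numeric vector.
#' @param mode `"literal"` or `"conservative"`.
#' @return scalar p value in \[0, 1\].
#' @export
pValue <- function(observed, null, mode = c("literal", "conservative")) {
  mode <- match.arg(mode)
  a <- .null_acc(null)
  if (length(a) == 0) stop("empty null distribution")
  if (mode == "literal") mean(a > observed)
  else (1 + sum(a >= observed)) / (1 + length(a))
}

#' Accuracy thresholds for significance
#'
#' Nearest-rank empirical `(1 - alpha)` quantiles of the null accuracies:
#' the accuracy an observed result must exceed to be significant at each
#' alpha.
#'
#' @param null a [PermutationNull-class] or numeric vector.
#' @param alphas significance levels in (0, 1).
#' @return named numeric vector of thresholds (monotone decreasing in
#'   alpha).
#' @export
significanceThresholds <- function(null, alphas = c(0.05, 0.005)) {
  a <- sort(.null_acc(null))
  n <- length(a)
  if (n == 0) stop("empty null distribution")
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  idx <- pmin(pmax(ceiling((1 - alphas) * n), 1L), n)
  setNames(a[idx], sprintf("alpha_%g", alphas))
}

#' @describeIn significanceThresholds histogram of a permutation null with
#'   threshold markers.
#' @param x a `PermutationNull`.
#' @param y ignored.
#' @param alphas significance levels to mark.
#' @param ... passed to `hist`.
#' @export
setMethod("plot", signature("PermutationNull", "missing"),
          function(x, y, alphas = c(0.05, 0.005), ...) {
  hist(x@accuracies, xlab = "null accuracy", main = "Permutation null", ...)
  thr <- significanceThresholds(x, alphas)
  abline(v = thr, lty = c(2, 3)[seq_along(thr)])
  invisible(x)
})

#' Selection-leakage bias experiment on null data
#'
#' Generates a label-independent feature table, permutes its labels
#' `nPerm` times, and evaluates the leave-one-out SVM accuracy at every
#' subset size `k` under both nested (fold-internal) and pooled
#' (all-subject) ranking, using the same permutations for both modes. The
#' summary gives, per mode and k, the mean null accuracy and the
#' nearest-rank significance thresholds -- the machinery that exposes how
#' pooled selection inflates accuracy on random data while nested
#' selection stays at chance.
#'
#' @param nPerGroup two group sizes.
#' @param nFeatures number of iid standard-normal features.
#' @param kRange subset sizes to scan.
#' @param nPerm permutations per mode.
#' @param C SVM regularization constant.
#' @param seed RNG seed (dataset and permutations).
#' @param alphas significance levels for the thresholds.
#' @return data.frame with columns `mode`, `k`, `mean_acc`, and one
#'   threshold column per alpha.
#' @export
cvBiasExperiment <- function(nPerGroup = c(19L, 17L), nFeatures = 32L,
                             kRange = seq_len(nFeatures), nPerm = 200L,
                             C = 1, seed = 1L, alphas = c(0.05, 0.005)) {
  set.seed(seed)
  tab <- simulateFeatureTable(nPerGroup[1], nPerGroup[2], nFeatures)
  n <- sum(nPerGroup)
  perms <- lapply(seq_len(nPerm), function(i) sample.int(n))
  kRange <- as.integer(kRange)
  truthLv <- levels(tab$labels)
  run_mode <- function(mode) {
    acc <- matrix(NA_real_, nPerm, length(kRange))
    for (i in seq_len(nPerm)) {
      fp <- tab$labels[perms[[i]]]
      g <- .loo_grid(tab$features, fp, kRange, mode, C)
      tr <- as.character(fp)
      acc[i, ] <- apply(g$scores, 2, function(s)
        mean(truthLv[(s > 0) + 1] == tr))
    }
    acc
  }
  out <- lapply(c("nested", "pooled"), function(mode) {
    acc <- run_mode(mode)
    thr <- apply(acc, 2, function(a)
      significanceThresholds(a, alphas))
    df <- data.frame(mode = mode, k = kRange, mean_acc = colMeans(acc))
    for (j in seq_along(alphas))
      df[[sprintf("thr_%g", alphas[j])]] <- thr[j, ]
    df
  })
  do.call(rbind, out)
}

#' Predict symptom severity from SVM decision scores
#'
#' Correlates the continuous held-out decision scores of a classification
#' run with observed severity scores on the affected subjects (severity
#' was never seen during training, so the association is an independent
#' generalization check). A least-squares affine transform of the scores
#' into severity units is returned for display; the correlation is
#' invariant to it. Significance is assessed by permuting the severity
#' values (two-sided, add-one rule), or by the t-distribution formula with
#' `method = "t"`.
#'
#' @param cvResult a [CVResult-class] with held-out decision scores.
#' @param severity named numeric vector of observed severity scores, or a
#'   data.frame/`DataFrame` with `subject_id` and `severity` columns
#'   (e.g. `cohortMeta(cohort)`).
#' @param subset subject ids to use; default: all subjects with a
#'   non-missing severity score (the affected group, in generated
#'   cohorts).
#' @param nPerm permutations for the significance test.
#' @param method `"permutation"` or `"t"`.
#' @param seed RNG seed for the permutation test.
#' @return a [SeverityPrediction-class].
#' @export
predictSeverity <- function(cvResult, severity, subset = NULL,
                            nPerm = 10000L, method = c("permutation", "t"),
                            seed = NULL) {
  method <- match.arg(method)
  if (is(severity, "DataFrame") || is.data.frame(severity))
    severity <- setNames(as.numeric(severity$severity), severity$subject_id)
  scores <- decisionScores(cvResult)
  if (is.null(subset))
    subset <- names(severity)[!is.na(severity)]
  subset <- intersect(subset, names(scores))
  if (length(subset) < 3) stop("need at least 3 subjects with severity scores")
  s <- scores[subset]
  v <- severity[subset]
  if (anyNA(v)) stop("missing severity values in the requested subset")
  if (sd(s) == 0) stop("zero-variance decision scores")
  if (sd(v) == 0) stop("zero-variance severity scores")
  r <- cor(s, v)
  fit <- lm(v ~ s)
  transform <- c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
  predicted <- transform["intercept"] + transform["slope"] * s
  if (method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    rstar <- vapply(seq_len(nPerm), function(i) cor(s, sample(v)), numeric(1))
    p <- (1 + sum(abs(rstar) >= abs(r) - 1e-15)) / (1 + nPerm)
  } else {
    n <- length(s)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tab <- data.frame(subject_id = subset, observed = as.numeric(v),
                    score = as.numeric(s), predicted = as.numeric(predicted))
  new("SeverityPrediction", table = tab, r = r, p = p,
      transform = transform, nPerm = as.integer(nPerm), method = method)
}
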