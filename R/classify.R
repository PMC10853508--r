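#' Fit the univariate threshold classifier
#'
#' The one-dimensional linear rule `Y = w * x + b` with orientation
#' `w` restricted to +1/-1, predicting the first class level when `Y > 0`.
#' Training is an exhaustive search over both orientations and all
#' thresholds at midpoints of consecutive sorted distinct training values
#' (plus the two all-one-class sentinels), keeping the pair with the
#' highest training accuracy; ties are broken towards the smallest `|b|`,
#' then towards `w = +1`.
#'
#' @param x numeric measurements, one per subject.
#' @param labels two-class factor (first level is predicted for `Y > 0`).
#' @return a [UnivariateModel-class].
#' @examples
#' m <- fitUnivariate(c(1, 2, 8, 9), factor(c("A", "A", "B", "B")))
#' c(m@w, m@b)   # orientation -1, boundary at the midpoint 5
#' @export
fitUnivariate <- function(x, labels) {
  if (length(x) == 0) stop("empty input")
  f <- if (is.factor(labels)) labels else factor(labels)
  lv <- levels(f)                 # declared levels are kept even if unused
  if (length(lv) == 1) lv <- c(lv, ".other")
  y1 <- f == lv[1]
  mids <- unique(sort(x))
  mids <- if (length(mids) > 1) (head(mids, -1) + mids[-1]) / 2 else numeric(0)
  best <- list(acc = -1, w = 1, b = Inf)
  for (w in c(1, -1)) {
    bs <- c(-w * mids, Inf * w, -Inf * w) # midpoints plus sentinels
    for (b in bs) {
      acc <- mean((w * x + b > 0) == y1)
      better <- acc > best$acc + 1e-12 ||
        (abs(acc - best$acc) <= 1e-12 &&
           (abs(b) < abs(best$b) - 1e-12 ||
              (abs(abs(b) - abs(best$b)) <= 1e-12 && w > best$w)))
      if (better) best <- list(acc = acc, w = w, b = b)
    }
  }
  new("UnivariateModel", w = best$w, b = best$b, levels = lv,
      trainingAccuracy = best$acc)
}

#' @describeIn fitUnivariate predict labels (or continuous scores, with
#'   `type = "score"`; positive scores point to the first class level).
#' @param object fitted model.
#' @param newdata numeric vector.
#' @param type `"class"` or `"score"`.
#' @export
setMethod("predict", "UnivariateModel",
          function(object, newdata, type = c("class", "score")) {
  type <- match.arg(type)
  s <- object@w * newdata + object@b
  if (type == "score") return(s)
  factor(ifelse(s > 0, object@levels[1], object@levels[2]),
         levels = object@levels)
})

#' Univariate classification under leave-one-out cross-validation
#'
#' For each held-out subject the threshold rule (or a logistic-regression
#' scorer) is fitted on the remaining subjects and applied to the held-out
#' value. Continuous scores are retained: for the threshold scorer the
#' signed value `w * x + b` (positive towards the first level), for the
#' logistic scorer the linear predictor (positive towards the second
#' level).
#'
#' @param x numeric measurements, one per subject.
#' @param labels two-class factor.
#' @param scorer `"threshold"` (exhaustive rule) or `"logistic"`.
#' @return a [CVResult-class] with `k = 1`.
#' @export
univariateLOO <- function(x, labels, scorer = c("threshold", "logistic")) {
  scorer <- match.arg(scorer)
  f <- .two_level(labels)
  if (min(table(f)) < 2) stop("need at least 2 subjects per class")
  n <- length(x)
  ids <- names(x); if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    xt <- x[-i]; ft <- f[-i]
    if (scorer == "threshold") {
      m <- fitUnivariate(xt, ft)
      score[i] <- predict(m, x[i], type = "score")
      pred[i] <- as.character(predict(m, x[i]))
    } else {
      fit <- suppressWarnings(glm(ft ~ xt, family = binomial()))
      eta <- coef(fit)[1] + coef(fit)[2] * x[i]
      if (anyNA(eta)) eta <- coef(fit)[1]
      score[i] <- eta
      pred[i] <- levels(f)[(eta > 0) + 1]
    }
  }
  tab <- data.frame(subject_id = ids, true = as.character(f),
                    predicted = pred, score = score)
  new("CVResult", table = tab, accuracy = mean(pred == as.character(f)),
      mode = paste0("univariate-", scorer), k = 1L,
      rankLists = matrix(1L, n, 1))
}

#' Fit a soft-margin linear SVM
#'
#' Solves the C-SVC quadratic program (hinge loss, L2 penalty,
#' regularization constant `C`) exactly via SMO on inputs standardized with
#' training means and SDs. The decision score
#' `weights . standardize(x) + bias` is positive for the second class
#' level; the margin between the classes is maximized subject to the
#' soft-margin penalty.
#'
#' @param x subjects x features matrix.
#' @param labels two-class factor; scores are oriented positive towards the
#'   second level.
#' @param C regularization constant (default 1).
#' @param standardize z-score features with training statistics.
#' @param tol KKT gap tolerance of the solver.
#' @param maxit iteration cap.
#' @return a [LinearSVMModel-class].
#' @examples
#' m <- fitLinearSVM(matrix(c(-1, 1)), factor(c("A", "B")), C = 100)
#' predict(m, matrix(c(-2, 2)), type = "score")
#' @export
fitLinearSVM <- function(x, labels, C = 1, standardize = TRUE,
                         tol = 1e-6, maxit = 100000L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  f <- .two_level(labels)
  if (min(table(f)) == 0) stop("both classes must be present")
  y <- ifelse(f == levels(f)[2], 1L, -1L)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd); scl[scl <= 0] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  fit <- .cpp_svm_fit(z, as.integer(y), C, tol, as.integer(maxit))
  new("LinearSVMModel", weights = as.numeric(fit$weights), bias = fit$bias,
      cost = C, center = ctr, scale = scl, levels = levels(f))
}

#' @describeIn fitLinearSVM decision scores or predicted labels for new
#'   data (rows are subjects).
#' @param object fitted model.
#' @param newdata matrix with the same feature columns as training.
#' @param type `"class"` or `"score"`.
#' @export
setMethod("predict", "LinearSVMModel",
          function(object, newdata, type = c("class", "score")) {
  type <- match.arg(type)
  nd <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  z <- sweep(sweep(nd, 2, object@center), 2, object@scale, "/")
  s <- as.numeric(z %*% object@weights + object@bias)
  if (type == "score") return(s)
  factor(object@levels[(s > 0) + 1], levels = object@levels)
})

# internal: leave-one-out decision scores over a k grid, via the C++ core.
# Returns list(scores = n x length(ks), orders = n x p).
.loo_grid <- function(X, f, ks, mode, C = 1, tol = 1e-6, maxit = 100000L) {
  y <- ifelse(f == levels(f)[2], 1L, -1L)
  .cpp_loo_grid(X, as.integer(y), as.integer(ks), mode == "nested",
                C, tol, as.integer(maxit))
}

#' Leave-one-out SVM classification with t-score feature selection
#'
#' For every held-out subject, the top-`k` components by `|t|` are selected
#' and a linear SVM (fold-internal standardization) is fitted on the
#' remaining subjects and applied to the held-out one. Two selection modes
#' are provided: `"nested"` recomputes the t ranking within each training
#' fold (the held-out subject never touches feature selection), while
#' `"pooled"` ranks once using all subjects including the held-out one --
#' the leaky scheme whose optimism the permutation machinery quantifies.
#'
#' @param x [PCModel-class], feature matrix, or `SummarizedExperiment`.
#' @param labels two-class factor; decision scores are positive towards the
#'   second level.
#' @param k number of selected components.
#' @param mode `"nested"` or `"pooled"`.
#' @param C SVM regularization constant.
#' @return a [CVResult-class]; `rankLists` row i is the feature ranking
#'   used in subject i's fold.
#' @examples
#' tab <- simulateFeatureTable(10, 10, 8, effectVector = c(3, rep(0, 7)),
#'                             seed = 1)
#' looSVM(tab$features, tab$labels, k = 2)
#' @export
looSVM <- function(x, labels, k = 10L, mode = c("nested", "pooled"), C = 1) {
  mode <- match.arg(mode)
  X <- .feature_matrix(x)
  f <- .two_level(labels)
  if (min(table(f)) < 2) stop("need at least 2 subjects per class")
  k <- as.integer(k)
  if (k < 1L || k > ncol(X)) stop("k out of range")
  g <- .loo_grid(X, f, k, mode, C)
  score <- g$scores[, 1]
  pred <- levels(f)[(score > 0) + 1]
  ids <- rownames(X); if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(X)))
  tab <- data.frame(subject_id = ids, true = as.character(f),
                    predicted = pred, score = score)
  new("CVResult", table = tab, accuracy = mean(pred == as.character(f)),
      mode = mode, k = k, rankLists = g$orders)
}

#' Accuracy as a function of the number of selected components
#'
#' Runs [looSVM()] at every `k` in `kRange` (sharing the per-fold rankings
#' and Gram updates, so the grid costs little more than a single run) and
#' records the accuracy curve; `bestK` is the smallest `k` attaining the
#' maximum.
#'
#' @inheritParams looSVM
#' @param kRange increasing vector of subset sizes.
#' @return a [TuningCurve-class].
#' @export
tuningCurve <- function(x, labels, kRange = NULL,
                        mode = c("nested", "pooled"), C = 1) {
  mode <- match.arg(mode)
  X <- .feature_matrix(x)
  f <- .two_level(labels)
  if (min(table(f)) < 2) stop("need at least 2 subjects per class")
  if (is.null(kRange)) kRange <- seq_len(ncol(X))
  kRange <- as.integer(kRange)
  if (length(kRange) == 0 || any(kRange < 1L | kRange > ncol(X)))
    stop("kRange out of bounds")
  g <- .loo_grid(X, f, kRange, mode, C)
  truth <- as.character(f)
  acc <- apply(g$scores, 2, function(s)
    mean(levels(f)[(s > 0) + 1] == truth))
  new("TuningCurve", kValues = kRange, accuracy = as.numeric(acc),
      mode = mode, bestK = min(kRange[acc >= max(acc) - 1e-12]))
}

#' @describeIn tuningCurve plot the accuracy curve.
#' @param x a `TuningCurve`.
#' @param y ignored.
#' @param ... passed to `plot`.
#' @export
setMethod("plot", signature("TuningCurve", "missing"), function(x, y, ...) {
  graphics::plot(x@kValues, x@accuracy, type = "b", xlab = "number of PCs",
                 ylab = "LOO accuracy", ylim = c(0, 1),
                 main = sprintf("%s selection", x@mode), ...)
  abline(v = x@bestK, lty = 3)
  invisible(x)
})
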