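test_that("univariate trainer matches the exhaustive threshold oracle", {
  # the canonical worked case: perfect split at the midpoint 5
  m <- fitUnivariate(c(1, 2, 8, 9), factor(c("A", "A", "B", "B")))
  expect_equal(m@trainingAccuracy, 1)
  expect_equal(abs(m@b), 5)
  # all instances up to 8 points: best accuracy equals brute force
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    x <- round(rnorm(n), 2)
    labels <- factor(sample(c("A", "B"), n, replace = TRUE),
                     levels = c("A", "B"))
    m <- fitUnivariate(x, labels)
    expect_equal(m@trainingAccuracy, univariate_oracle_best_acc(x, labels))
    # the returned rule reproduces its own training accuracy
    expect_equal(mean(predict(m, x) == labels), m@trainingAccuracy)
  }
  # interleaved balanced classes cap the achievable accuracy
  x <- 1:8
  f <- factor(rep(c("A", "B"), 4))
  expect_equal(fitUnivariate(x, f)@trainingAccuracy,
               univariate_oracle_best_acc(x, f))
  # one-class input is fit with a sentinel threshold
  m1 <- fitUnivariate(c(1, 2, 3), factor(c("A", "A", "A")))
  expect_equal(m1@trainingAccuracy, 1)
  expect_true(is.infinite(m1@b))
  expect_error(fitUnivariate(numeric(0), factor(character(0))), "empty")
})

test_that("univariate LOO is perfect on well-separated groups and fold-honest", {
  x <- c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1))
  f <- factor(rep(c("A", "B"), each = 8))
  cv <- univariateLOO(x, f)
  expect_equal(cvAccuracy(cv), 1)
  # each fold refits from scratch: recompute fold 3 by hand
  m3 <- fitUnivariate(x[-3], f[-3])
  expect_equal(cvTable(cv)$predicted[3], as.character(predict(m3, x[3])))
  # logistic scorer available
  cvl <- univariateLOO(x, f, scorer = "logistic")
  expect_equal(cvAccuracy(cvl), 1)
})

test_that("univariate LOO sits at or just below chance on random data", {
  set.seed(13)
  acc <- replicate(500, {
    x <- rnorm(36)
    f <- factor(rep(c("A", "B"), c(19, 17)))
    cvAccuracy(univariateLOO(x, f))
  })
  expect_gt(mean(acc), 0.42)
  expect_lt(mean(acc), 0.54)
})

test_that("SVM solves the symmetric two-point problem exactly", {
  m <- fitLinearSVM(matrix(c(-1, 1)), factor(c("A", "B")), C = 100,
                    standardize = FALSE)
  s <- predict(m, matrix(c(-1, 0, 1)), type = "score")
  expect_equal(s, c(-1, 0, 1), tolerance = 1e-5)
})

test_that("SVM puts its weight on the separating axis", {
  set.seed(140)
  x <- cbind(c(-2, -1.5, -1.8, 2, 1.5, 1.8), rnorm(6, 0, 0.1))
  f <- factor(rep(c("A", "B"), each = 3))
  m <- fitLinearSVM(x, f, C = 10, standardize = FALSE)
  expect_gt(abs(svmWeights(m)[1]) / abs(svmWeights(m)[2]), 10)
})

test_that("duplicating every training point leaves the boundary unchanged", {
  set.seed(14)
  x <- rbind(matrix(rnorm(8, -2), 4, 2), matrix(rnorm(8, 2), 4, 2))
  f <- factor(rep(c("A", "B"), each = 4))
  m1 <- fitLinearSVM(x, f, C = 1)
  m2 <- fitLinearSVM(rbind(x, x), factor(c(f, f), labels = levels(f)), C = 1)
  expect_equal(predict(m1, x, type = "score"), predict(m2, x, type = "score"),
               tolerance = 1e-6)
})

test_that("SMO solution matches the e1071 QP oracle", {
  skip_if_not_installed("e1071")
  set.seed(15)
  # separable toys: direction cosine to 1e-4
  for (rep in 1:10) {
    n <- 6; p <- 2
    x <- rbind(matrix(rnorm(n / 2 * p, -3), n / 2, p),
               matrix(rnorm(n / 2 * p, 3), n / 2, p))
    f <- factor(rep(c("A", "B"), each = n / 2))
    z <- scale(x)
    m <- fitLinearSVM(x, f, C = 1)
    em <- e1071::svm(z, f, kernel = "linear", cost = 1, scale = FALSE,
                     tolerance = 1e-6)
    ew <- drop(t(em$coefs) %*% em$SV)
    if (sum(ew * svmWeights(m)) < 0) ew <- -ew
    cosang <- sum(ew * svmWeights(m)) /
      sqrt(sum(ew^2) * sum(svmWeights(m)^2))
    expect_gt(cosang, 1 - 1e-4)
  }
  # general problems: our primal objective never exceeds e1071's
  for (rep in 1:15) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1); p <- sample(2:6, 1)
    x <- matrix(rnorm((n1 + n2) * p), n1 + n2, p)
    x[(n1 + 1):(n1 + n2), 1] <- x[(n1 + 1):(n1 + n2), 1] + runif(1, 0, 2)
    f <- factor(rep(c("A", "B"), c(n1, n2)))
    Cc <- sample(c(0.5, 1, 5), 1)
    z <- scale(x); y <- ifelse(f == "B", 1, -1)
    m <- fitLinearSVM(x, f, C = Cc)
    em <- e1071::svm(z, f, kernel = "linear", cost = Cc, scale = FALSE)
    ew <- drop(t(em$coefs) %*% em$SV); eb <- -em$rho
    if (sum(ew * svmWeights(m)) < 0) { ew <- -ew; eb <- -eb }
    expect_lte(svm_primal(svmWeights(m), m@bias, z, y, Cc),
               svm_primal(ew, eb, z, y, Cc) + 1e-6)
  }
})

test_that("swapping class labels negates all LOO decision scores", {
  tab <- simulateFeatureTable(10, 9, 8, effectVector = 0.5, seed = 16)
  f <- tab$labels
  fsw <- factor(as.character(f), levels = rev(levels(f)))
  for (mode in c("nested", "pooled")) {
    cv <- looSVM(tab$features, f, k = 4, mode = mode)
    cvs <- looSVM(tab$features, fsw, k = 4, mode = mode)
    # negated up to the solver's KKT tolerance
    expect_equal(decisionScores(cvs), -decisionScores(cv), tolerance = 1e-4)
    expect_equal(cvAccuracy(cvs), cvAccuracy(cv))
  }
})

test_that("selection is vacuous at k = p: nested equals pooled", {
  tab <- simulateFeatureTable(9, 8, 6, seed = 17)
  a <- looSVM(tab$features, tab$labels, k = 6, mode = "nested")
  b <- looSVM(tab$features, tab$labels, k = 6, mode = "pooled")
  # identical up to solver tolerance: the feature *sets* coincide, but the
  # two modes add columns in different orders
  expect_equal(decisionScores(a), decisionScores(b), tolerance = 1e-4)
  expect_equal(cvAccuracy(a), cvAccuracy(b))
})

test_that("strong signal is decoded at high accuracy in both modes", {
  tab <- simulateFeatureTable(19, 17, 32,
                              effectVector = c(rep(3, 4), rep(0, 28)),
                              seed = 18)
  for (mode in c("nested", "pooled"))
    expect_gte(cvAccuracy(looSVM(tab$features, tab$labels, k = 10,
                                 mode = mode)), 0.9)
})

test_that("nested fold rankings use only the training subjects", {
  tab <- simulateFeatureTable(8, 8, 5, seed = 19)
  cv <- looSVM(tab$features, tab$labels, k = 2, mode = "nested")
  for (i in c(1, 9)) {
    r <- rankPCs(tab$features, tab$labels, subset = setdiff(1:16, i))
    expect_equal(unname(rankLists(cv)[i, ]), rankOrder(r))
  }
  # pooled rankings are the all-subject ranking in every fold
  cvp <- looSVM(tab$features, tab$labels, k = 2, mode = "pooled")
  rall <- rankPCs(tab$features, tab$labels)
  expect_true(all(apply(rankLists(cvp), 1, function(o)
    identical(as.integer(o), rankOrder(rall)))))
})

test_that("pooled selection inflates accuracy on label-independent data", {
  accN <- accP <- numeric(200)
  for (i in 1:200) {
    tab <- simulateFeatureTable(19, 17, 32, seed = 3000 + i)
    accN[i] <- cvAccuracy(looSVM(tab$features, tab$labels, k = 10, "nested"))
    accP[i] <- cvAccuracy(looSVM(tab$features, tab$labels, k = 10, "pooled"))
  }
  expect_gte(mean(accP) - mean(accN), 0.05)
  expect_lt(t.test(accP, accN, alternative = "greater")$p.value, 0.01)
  # chance calibration of the nested mode
  expect_gt(mean(accN), 0.46)
  expect_lt(mean(accN), 0.54)
})

test_that("tuning curve is consistent with standalone runs and flat for a
           dominant component", {
  tab <- simulateFeatureTable(10, 9, 6, effectVector = c(4, rep(0, 5)),
                              seed = 20)
  tc <- tuningCurve(tab$features, tab$labels, 1:6, mode = "nested")
  expect_true(all(cvAccuracy(tc) >= 0.9))
  for (k in c(1, 3, 6))
    expect_equal(cvAccuracy(tc)[k],
                 cvAccuracy(looSVM(tab$features, tab$labels, k, "nested")))
  expect_equal(bestK(tc), min(kValues(tc)[cvAccuracy(tc) == max(cvAccuracy(tc))]))
  expect_error(tuningCurve(tab$features, tab$labels, 0:3), "bounds")
})
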