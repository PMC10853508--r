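test_that("block design arithmetic matches the run layout", {
  d <- makeDesign(30, 180, 18, 12)
  box <- designBoxcar(d)
  expect_length(box, 5400)
  expect_true(all(box %in% c(0, 1)))
  expect_equal(sum(box), 6 * 540) # six 18-s on-blocks of 540 samples
  # alternation: runs of on/off have the stated lengths, starting with task
  r <- rle(box)
  expect_equal(r$values[1], 1)
  expect_true(all(r$lengths[r$values == 1] == 540))
  expect_true(all(r$lengths[r$values == 0] == 360))
  expect_equal(max(designRegressor(d)), 1)
})

test_that("degenerate no-rest design gives an all-ones boxcar", {
  d <- makeDesign(1, 10, 10, 0)
  expect_equal(designBoxcar(d), rep(1, 10))
  kern <- canonicalHRF(1)
  step <- nirsmvpa:::.convolve_causal(rep(1, 10), kern)
  expect_equal(designRegressor(d), step / max(step), tolerance = 1e-12)
})

test_that("regressor is normalized to unit maximum", {
  d <- makeDesign(30, 30, 18, 12)
  expect_equal(max(designRegressor(d)), 1)
})

test_that("design rejects bad inputs and flags truncation", {
  expect_error(makeDesign(0, 180, 18, 12), "sampleRate")
  expect_error(makeDesign(30, -1, 18, 12), "positive")
  expect_warning(makeDesign(10, 100, 18, 12), "truncated")
})

test_that("sub-epoch switch carves 3-s gaze epochs out of task blocks", {
  d <- makeDesign(10, 60, 18, 12, subEpoch = 3)
  full <- makeDesign(10, 60, 18, 12)
  expect_equal(sum(designBoxcar(d)), sum(designBoxcar(full)) / 2)
  expect_true(all(designBoxcar(d) <= designBoxcar(full)))
})

test_that("noiseless subject is exactly amplitude times regressor", {
  cfg <- simConfig(nChannels = 5, noiseSD = 0, globalSD = 0, driftSD = 0)
  d <- tiny_design()
  a <- c(1, -2, 0, 0.5, 3)
  s <- simulateSubject(cfg, d, amplitudeMap = a)
  expect_equal(s@oxy, a %o% designRegressor(d))
  expect_equal(s@deoxy, -0.5 * a %o% designRegressor(d))
})

test_that("with zero amplitude the signal is uncorrelated with the task", {
  cfg <- simConfig(nChannels = 1, noiseSD = 1, globalSD = 0, driftSD = 0)
  d <- tiny_design()
  reg <- designRegressor(d)
  set.seed(404)
  r <- replicate(100, cor(simulateSubject(cfg, d, amplitudeMap = 0)@oxy[1, ],
                          reg))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- simConfig(nChannels = 4, nTD = 2, nASD = 2)
  d <- tiny_design()
  s1 <- simulateSubject(cfg, d, amplitudeMap = rep(1, 4), seed = 9)
  s2 <- simulateSubject(cfg, d, amplitudeMap = rep(1, 4), seed = 9)
  expect_identical(s1@oxy, s2@oxy)
  expect_identical(s1@deoxy, s2@deoxy)
  c1 <- simulateCohort(cfg, d, seed = 5)
  c2 <- simulateCohort(cfg, d, seed = 5)
  expect_identical(c1@truthMaps, c2@truthMaps)
  expect_identical(c1@subjects[[3]]@oxy, c2@subjects[[3]]@oxy)
  expect_identical(cohortMeta(c1)$severity, cohortMeta(c2)$severity)
})

test_that("null configuration injects identical amplitude maps in both groups", {
  coh <- simulateCohort(simConfig(nChannels = 8, nTD = 3, nASD = 3,
                                  effectScale = 0), tiny_design(), seed = 2)
  maps <- cohortTruth(coh)$maps
  expect_true(all(apply(maps, 2, function(col) all(col == col[1]))))
})

test_that("noiseless severity coupling is exactly affine in u", {
  coh <- noiseless_cohort(nASD = 6, seed = 13)
  tr <- cohortTruth(coh)
  ok <- !is.na(tr$severity)
  expect_equal(cor(tr$severity[ok], tr$u[ok]), 1)
  expect_equal(tr$severity[ok], 2 + 10 * tr$u[ok])
})

test_that("strong effect separates the groups' pattern-support betas completely", {
  cfg <- simConfig(effectScale = 3, seed = 31)
  coh <- simulateCohort(cfg, makeDesign(10, 180, 18, 12))
  se <- preprocessCohort(coh)
  B <- betaMatrix(se)
  sup <- which(cfg@effectPattern != 0)
  m <- rowMeans(B[, sup])
  grp <- cohortMeta(coh)$group
  expect_lt(max(m[grp == "ASD"]), min(m[grp == "TD"]))
})

test_that("feature tables have the advertised shape and null behavior", {
  tab <- simulateFeatureTable(19, 17, 32, seed = 3)
  expect_equal(dim(tab$features), c(36, 32))
  expect_equal(as.vector(table(tab$labels)), c(19, 17))
  d <- colMeans(tab$features[tab$labels == "TD", ]) -
    colMeans(tab$features[tab$labels == "ASD", ])
  se <- sqrt(1 / 19 + 1 / 17)
  expect_true(all(abs(d) < 3 * se))
  expect_identical(tab$features,
                   simulateFeatureTable(19, 17, 32, seed = 3)$features)
})

test_that("a 10-sigma feature shift produces t statistics above 10", {
  # analytic: t ~ 10/sqrt(1/19+1/17) / spread >> 10; check across seeds
  t1 <- vapply(1:40, function(s) {
    tab <- simulateFeatureTable(19, 17, 4, effectVector = c(10, 0, 0, 0),
                                seed = 500 + s)
    abs(nirsmvpa:::.col_t(tab$features, tab$labels))[1]
  }, numeric(1))
  expect_gte(mean(t1 > 10), 0.95)
})

test_that("null cohorts drive the full pipeline to chance accuracy", {
  # effect scale 0: signal chain + PCA + nested LOO over 200 cohorts
  design <- makeDesign(5, 180, 18, 12)
  acc <- vapply(1:200, function(i) {
    coh <- simulateCohort(simConfig(effectScale = 0, seed = 40000 + i),
                          design)
    se <- preprocessCohort(coh)
    cvAccuracy(looSVM(fitPCA(se, nPC = 32), cohortMeta(coh)$group,
                      k = 10, mode = "nested"))
  }, numeric(1))
  expect_gte(mean(acc), 0.46)
  expect_lte(mean(acc), 0.54)
})
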