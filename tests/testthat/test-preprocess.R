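test_that("canonical HRF has the documented shape", {
  k <- canonicalHRF(30)
  expect_equal(max(k), 1)
  expect_equal(k[1], 0)
  # peak at the gamma-density mode (shape 6, scale 1 -> mode at 5 s)
  expect_equal(which.max(k), 5 * 30 + 1, tolerance = 0)
  expect_error(canonicalHRF(0), "positive")
  expect_error(hrfParams(peakDelay = -1), "positive")
})

test_that("detrending removes a linear ramp almost completely", {
  # cutoff well below the series length so the cosine set covers the ramp
  n <- 600 * 10
  ramp <- seq(0, 1, length.out = n)
  out <- detrendSeries(ramp, sampleRate = 10, cutoffPeriod = 32)
  expect_lt(max(abs(out)), 0.01)          # < 1% of the ramp range
  expect_equal(mean(out), 0, tolerance = 1e-10)
})

test_that("detrending preserves task-band content (FFT oracle)", {
  rate <- 10; dur <- 360; n <- rate * dur
  tt <- (seq_len(n) - 1) / rate
  s <- sin(2 * pi * tt / 30)              # block-frequency sinusoid, 30-s period
  out <- detrendSeries(s, rate, 128)
  amp_at <- function(x, period) {
    sp <- Mod(fft(x)) / (length(x) / 2)
    sp[round(length(x) / (period * rate)) + 1]
  }
  expect_equal(amp_at(out, 30), amp_at(s, 30), tolerance = 0.05)
  # superposition: the filter is a linear projection, so drift and signal
  # separate additively, and a ramp contributes nothing at the task band
  mix <- s + seq(0, 1.5, length.out = n)
  out_mix <- detrendSeries(mix, rate, 128)
  expect_equal(out_mix,
               detrendSeries(s, rate, 128) +
                 detrendSeries(seq(0, 1.5, length.out = n), rate, 128),
               tolerance = 1e-10)
  expect_equal(amp_at(out_mix, 30), amp_at(s, 30), tolerance = 0.05)
  expect_error(detrendSeries(1:5, 10, 128), "too short")
})

test_that("a protected regressor passes through the detrend untouched", {
  d <- tiny_design()
  reg <- designRegressor(d)
  out <- detrendSeries(3 * reg, 10, 128, protect = reg)
  expect_equal(out, 3 * reg, tolerance = 1e-10)
})

test_that("global filter removes a shared series exactly and spares unique ones", {
  set.seed(76)
  n <- 600
  g <- 3 * (sin(seq(0, 20, length.out = n)) + rnorm(n))
  m <- rbind(g, g, g, g)                   # identical on all channels
  out <- removeGlobal(m)
  expect_lt(max(abs(out)), 1e-8 * max(abs(g)))
  # global everywhere + unique orthogonal signals on a few of many
  # channels (rank-1 removal leaks the cross-channel average of the
  # unique signals, so localized activity among 54 channels survives)
  set.seed(77)
  nc <- 54
  uniq <- matrix(0, n, nc)
  uniq[, 1:3] <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))[, 1:3] * 2
  m2 <- t(g + uniq)                        # channel c = g + its unique signal
  out2 <- removeGlobal(m2)
  for (c in 1:3) {
    rel <- sqrt(mean((out2[c, ] - (uniq[, c] - mean(uniq[, c])))^2)) /
      sqrt(mean(uniq[, c]^2))
    expect_lt(rel, 0.10)
  }
  # channel-mean variance drops below 5% of the input's
  expect_lt(var(colMeans(out2)), 0.05 * var(colMeans(m2)))
  expect_equal(removeGlobal(matrix(0, 3, 10)), matrix(0, 3, 10))
  expect_error(removeGlobal(matrix(1, 1, 10)), "2 channels")
  expect_error(removeGlobal(matrix(1, 3, 10)), "constant")
})

test_that("hbdiff is the elementwise difference", {
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(hbDiff(x, -x), 2 * x)
  expect_equal(hbDiff(x, x), matrix(0, 4, 5))
  expect_error(hbDiff(x, t(x)), "shape")
})

test_that("GLM betas recover noiseless amplitudes exactly", {
  d <- tiny_design()
  reg <- designRegressor(d)
  a <- c(2, -1, 0.5)
  oxy <- a %o% reg
  deoxy <- -0.5 * a %o% reg
  beta <- glmBetas(hbDiff(oxy, deoxy), d)
  expect_equal(unname(beta), 1.5 * a, tolerance = 1e-10)
  # orthogonal signal -> zero beta; the regressor itself -> beta 1
  orth <- rnorm(length(reg))
  orth <- orth - mean(orth) -
    sum(orth * (reg - mean(reg))) / sum((reg - mean(reg))^2) * (reg - mean(reg))
  expect_lt(abs(glmBetas(matrix(orth, 1), d)), 1e-8)
  expect_equal(unname(glmBetas(matrix(reg, 1), d)), 1, tolerance = 1e-10)
  expect_error(glmBetas(matrix(NA_real_, 1, length(reg)), d), "missing")
})

test_that("noiseless cohort passes the full chain exactly", {
  coh <- noiseless_cohort(nTD = 4, nASD = 4, nChannels = 10)
  truth <- cohortTruth(coh)$maps
  full <- betaMatrix(preprocessCohort(coh))
  expect_equal(full, 1.5 * truth, tolerance = 1e-10)
  # GLM-only path agrees with the full pipeline on noiseless data
  glm_only <- betaMatrix(preprocessCohort(coh, detrend = FALSE,
                                          globalFilter = FALSE))
  expect_equal(full, glm_only, tolerance = 1e-8)
  expect_error(preprocessCohort(new("Cohort",
    subjects = list(), design = coh@design,
    meta = S4Vectors::DataFrame(subject_id = character(0),
                                group = character(0)),
    truthMaps = matrix(numeric(0), 0, 0))))
})

test_that("beta recovery is unbiased at high SNR", {
  # noise SD = 10% of the injected amplitude
  cfg <- simConfig(nChannels = 2, nTD = 2, nASD = 2, noiseSD = 0.1,
                   globalSD = 0.05, driftSD = 0.002)
  d <- tiny_design(rate = 10, duration = 180)
  set.seed(99)
  betas <- replicate(100, {
    s <- simulateSubject(cfg, d, amplitudeMap = c(1, 1))
    glmBetas(hbDiff(removeGlobal(detrendSeries(t(s@oxy), 10, 128,
                                               designRegressor(d)) |> t(),
                                 designRegressor(d)),
                    removeGlobal(detrendSeries(t(s@deoxy), 10, 128,
                                               designRegressor(d)) |> t(),
                                 designRegressor(d))), d)[1]
  })
  expect_equal(mean(betas), 1.5, tolerance = 0.05)
})

test_that("permuting cohort order permutes beta rows identically", {
  coh <- strong_cohort(seed = 41, duration = 60)
  B <- betaMatrix(preprocessCohort(coh))
  perm <- rev(seq_along(coh@subjects))
  coh2 <- new("Cohort", subjects = coh@subjects[perm], design = coh@design,
              meta = coh@meta[perm, ], truthMaps = coh@truthMaps[perm, ])
  B2 <- betaMatrix(preprocessCohort(coh2))
  expect_equal(B2, B[perm, ], tolerance = 1e-12)
})
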