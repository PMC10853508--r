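# Shared fixtures: small designs and cohorts built in code.

# compact design: 10 samples/s keeps block structure while staying fast
tiny_design <- function(rate = 10, duration = 60)
  makeDesign(rate, duration, 18, 12)

# noiseless cohort -- exact algebra throughout the signal chain
noiseless_cohort <- function(nTD = 3, nASD = 3, seed = 11, rate = 10,
                             duration = 60, nChannels = 12, ...) {
  cfg <- simConfig(nChannels = nChannels, nTD = nTD, nASD = nASD,
                   noiseSD = 0, globalSD = 0, driftSD = 0,
                   severityNoiseSD = 0, seed = seed, ...)
  simulateCohort(cfg, tiny_design(rate, duration))
}

# strong, clearly separable cohort (effect far above the beta noise floor,
# which is ~0.15 per channel: residual drift plus task-correlated global)
strong_cohort <- function(seed = 21, rate = 10, duration = 180, ...) {
  cfg <- simConfig(effectScale = 3, noiseSD = 0.5, globalSD = 0.3,
                   driftSD = 0.01, seed = seed, ...)
  simulateCohort(cfg, makeDesign(rate, duration, 18, 12))
}

# brute-force oracle for the univariate threshold rule: evaluate every
# orientation and every candidate threshold by direct counting
univariate_oracle_best_acc <- function(x, labels) {
  f <- factor(labels)
  y1 <- f == levels(f)[1]
  cand <- sort(unique(x))
  thr <- c(-Inf, if (length(cand) > 1)
    (cand[-length(cand)] + cand[-1]) / 2 else NULL, Inf)
  best <- 0
  for (m in thr)
    for (w in c(1, -1))
      best <- max(best, mean((w * (x - m) > 0) == y1))
  best
}

# primal objective of the soft-margin linear SVM on standardized inputs
svm_primal <- function(w, b, Z, y, C)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (drop(Z %*% w) + b)))
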