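#' Simulation settings for synthetic fNIRS cohorts
#'
#' Builds a [SimulationConfig-class]. The generative model is
#' \deqn{HbO_c(t) = a_c r(t) + g(t) + d_c(t) + \epsilon_c(t)}
#' per channel c, where `r(t)` is the unit-peak task regressor, `a_c` the
#' injected activation amplitude, `g(t)` a single global systemic series
#' shared by all channels (AR(1)), `d_c` an integrated-noise drift and
#' `eps_c` white sensor noise; HbR carries the amplitude scaled by the
#' (negative) `oxyDeoxyRatio` with independent noise terms of the same SDs.
#' Control ("TD") subjects receive `baselineMap`; affected ("ASD") subjects
#' receive `baselineMap - effectScale * effectPattern * u_i` with a
#' per-subject expression factor `u_i ~ Gamma(uShape, uShape)` (mean 1), and
#' a severity score `severityIntercept + severitySlope * u_i + noise`.
#'
#' @param nChannels number of measurement channels.
#' @param nTD,nASD group sizes (control / affected).
#' @param baselineMap per-channel baseline activation amplitude; recycled.
#' @param effectPattern per-channel group-difference map; the default puts
#'   a unit effect on an 8-channel contiguous support (channels 20--27) and
#'   zero elsewhere.
#' @param effectScale multiplier on `effectPattern` (0 = null cohort).
#' @param uShape Gamma shape (= rate) of the expression factor; larger
#'   values concentrate `u_i` around 1.
#' @param noiseSD,globalSD,driftSD white-noise SD, marginal SD of the
#'   global AR(1) series, and per-sample SD of the integrated drift.
#' @param globalAR AR(1) coefficient of the global series.
#' @param oxyDeoxyRatio HbR/HbO task-amplitude ratio; must be negative.
#' @param severityIntercept,severitySlope,severityNoiseSD affine coupling of
#'   the severity score to `u_i` (affected group only).
#' @param subEpochs model the task block as alternating 3-s gaze sub-epochs
#'   instead of one continuous on-block.
#' @param seed default RNG seed used by [simulateCohort()].
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(nTD = 4, nASD = 4)
#' @export
simConfig <- function(nChannels = 54L, nTD = 19L, nASD = 17L,
                      baselineMap = 0.5,
                      effectPattern = NULL,
                      effectScale = 0.05,
                      uShape = 10,
                      noiseSD = 0.5, globalSD = 0.3, driftSD = 0.01,
                      globalAR = 0.95, oxyDeoxyRatio = -0.5,
                      severityIntercept = 2, severitySlope = 10,
                      severityNoiseSD = 1,
                      subEpochs = FALSE, seed = 1L) {
  nChannels <- as.integer(nChannels)
  if (is.null(effectPattern)) {
    effectPattern <- numeric(nChannels)
    sup <- intersect(20:27, seq_len(nChannels))
    effectPattern[sup] <- 1
  }
  new("SimulationConfig",
      nChannels = nChannels, nTD = as.integer(nTD), nASD = as.integer(nASD),
      baselineMap = rep_len(baselineMap, nChannels),
      effectPattern = effectPattern, effectScale = effectScale,
      uShape = uShape, noiseSD = noiseSD, globalSD = globalSD,
      driftSD = driftSD, globalAR = globalAR, oxyDeoxyRatio = oxyDeoxyRatio,
      severityIntercept = severityIntercept, severitySlope = severitySlope,
      severityNoiseSD = severityNoiseSD, subEpochs = subEpochs,
      seed = as.integer(seed))
}

#' Build a block task design with its hemodynamic regressor
#'
#' Alternating task/rest blocks starting with a task block; the regressor is
#' the boxcar convolved with the canonical double-gamma HRF and rescaled to
#' unit maximum.
#'
#' @param sampleRate samples per second.
#' @param totalDuration run length (s).
#' @param taskEpoch,restEpoch block durations (s); `restEpoch = 0` gives a
#'   degenerate always-on design.
#' @param hrfParams HRF parameters, see [hrfParams()].
#' @param subEpoch optional gaze sub-epoch length (s); when given, each task
#'   block alternates on/off sub-epochs of this length (starting on),
#'   approximating brief instructed gaze shifts within a block.
#' @return a [TaskDesign-class] object. If the block period does not divide
#'   the run length the final block is truncated and flagged.
#' @examples
#' d <- makeDesign(30, 180, 18, 12)
#' sum(designBoxcar(d))   # 6 blocks x 540 samples
#' @export
makeDesign <- function(sampleRate = 30, totalDuration = 180,
                       taskEpoch = 18, restEpoch = 12,
                       hrfParams = nirsmvpa::hrfParams(),
                       subEpoch = NULL) {
  if (sampleRate <= 0) stop("sampleRate must be positive")
  if (totalDuration <= 0 || taskEpoch <= 0 || restEpoch < 0)
    stop("durations must be positive (restEpoch may be zero)")
  n <- round(sampleRate * totalDuration)
  period <- taskEpoch + restEpoch
  tt <- (seq_len(n) - 1) / sampleRate
  phase <- tt %% period
  boxcar <- as.numeric(phase < taskEpoch)
  if (!is.null(subEpoch)) {
    sub <- (phase %/% subEpoch) %% 2 == 0
    boxcar <- boxcar * as.numeric(sub)
  }
  truncated <- abs(totalDuration %% period) > 1e-9
  if (truncated)
    warning("block period does not divide the run length; final block truncated")
  kern <- canonicalHRF(sampleRate, hrfParams)
  reg <- .convolve_causal(boxcar, kern)
  mx <- max(reg)
  if (mx <= 0) stop("degenerate design: regressor has no positive peak")
  reg <- reg / mx
  new("TaskDesign", sampleRate = sampleRate, totalDuration = totalDuration,
      taskEpoch = taskEpoch, restEpoch = restEpoch, boxcar = boxcar,
      regressor = reg, truncatedFinal = truncated)
}

# causal convolution truncated to the input length
.convolve_causal <- function(x, kernel) {
  n <- length(x)
  stats::convolve(x, rev(kernel), type = "open")[seq_len(n)]
}

#' Simulate one subject's two-chromophore time series
#'
#' Draws, in fixed order, the HbO global/drift/noise terms and then the HbR
#' terms, so a fixed RNG state reproduces the subject bit for bit.
#'
#' @param config a [SimulationConfig-class].
#' @param design a [TaskDesign-class].
#' @param group diagnostic label to record.
#' @param amplitudeMap per-channel task amplitude for this subject.
#' @param subjectId identifier.
#' @param seed optional seed; the default (`NULL`) uses the current RNG
#'   stream (as [simulateCohort()] does).
#' @return a [SubjectTimeSeries-class].
#' @export
simulateSubject <- function(config, design, group = "TD",
                            amplitudeMap = config@baselineMap,
                            subjectId = "s01", seed = NULL) {
  if (length(amplitudeMap) != config@nChannels)
    stop("amplitudeMap length must equal nChannels")
  if (!is.null(seed)) set.seed(seed)
  reg <- design@regressor
  n <- length(reg)
  C <- config@nChannels

  none <- matrix(numeric(0), 0, 0)
  chromophore <- function(amp) {
    ginnov <- if (config@globalSD > 0) rnorm(n) else numeric(n)
    drift <- if (config@driftSD > 0)
      matrix(rnorm(C * n, 0, config@driftSD), C, n) else none
    noise <- if (config@noiseSD > 0)
      matrix(rnorm(C * n, 0, config@noiseSD), C, n) else none
    .cpp_assemble_chrom(amp, reg, ginnov, config@globalSD, config@globalAR,
                        drift, noise)
  }
  oxy <- chromophore(amplitudeMap)
  deoxy <- chromophore(config@oxyDeoxyRatio * amplitudeMap)
  new("SubjectTimeSeries", oxy = oxy, deoxy = deoxy,
      subjectId = subjectId, group = group)
}

#' Simulate a two-group cohort with known ground truth
#'
#' Control subjects receive the baseline amplitude map; affected subjects
#' receive `baseline - effectScale * effectPattern * u_i` with expression
#' factors `u_i ~ Gamma(uShape, uShape)`, and a severity score affine in
#' `u_i`. The injected maps, `u_i` and severity parameters are retained in
#' the cohort ground truth for recovery tests.
#'
#' @param config a [SimulationConfig-class].
#' @param design a [TaskDesign-class]; defaults to the 30 samples/s,
#'   18 s / 12 s block run the configuration targets.
#' @param seed RNG seed; defaults to the seed stored in `config`.
#' @return a [Cohort-class].
#' @examples
#' coh <- simulateCohort(simConfig(nTD = 3, nASD = 3, seed = 7),
#'                       makeDesign(5, 60, 18, 12))
#' cohortMeta(coh)
#' @export
simulateCohort <- function(config, design = makeDesign(), seed = config@seed) {
  if (config@nTD < 1L || config@nASD < 1L) stop("group counts must be >= 1")
  set.seed(seed)
  nA <- config@nASD
  u <- rgamma(nA, shape = config@uShape, rate = config@uShape)
  severity <- config@severityIntercept + config@severitySlope * u +
    rnorm(nA, 0, config@severityNoiseSD)
  ids <- c(sprintf("TD%02d", seq_len(config@nTD)),
           sprintf("ASD%02d", seq_len(nA)))
  groups <- rep(c("TD", "ASD"), c(config@nTD, nA))
  maps <- matrix(rep(config@baselineMap, each = length(ids)),
                 nrow = length(ids),
                 dimnames = list(ids, .channel_names(config@nChannels)))
  for (i in seq_len(nA))
    maps[config@nTD + i, ] <- config@baselineMap -
      config@effectScale * config@effectPattern * u[i]
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids))
    subjects[[i]] <- simulateSubject(config, design, groups[i], maps[i, ],
                                     subjectId = ids[i])
  meta <- S4Vectors::DataFrame(
    subject_id = ids,
    group = factor(groups, levels = c("TD", "ASD")),
    severity = c(rep(NA_real_, config@nTD), severity),
    u = c(rep(NA_real_, config@nTD), u))
  new("Cohort", subjects = subjects, design = design, meta = meta,
      truthMaps = maps)
}

.channel_names <- function(p) sprintf("channel_%02d", seq_len(p))

#' Fast-path synthetic feature tables
#'
#' Generates a subjects x features matrix of iid standard-normal features
#' with an optional mean shift added to the second group -- the direct
#' analogue of PC-score inputs, used for chance-calibration and
#' selection-leakage experiments where the signal chain itself is not under
#' study. With `effectVector = 0` the labels are independent of the
#' features.
#'
#' @param n1,n2 group sizes (first / second class).
#' @param nFeatures number of feature columns.
#' @param effectVector per-feature shift added to group-2 rows; recycled.
#' @param seed optional RNG seed.
#' @param levels the two class labels.
#' @return list with `features` (matrix) and `labels` (factor).
#' @examples
#' tab <- simulateFeatureTable(19, 17, 32, seed = 1)
#' dim(tab$features)
#' @export
simulateFeatureTable <- function(n1, n2, nFeatures, effectVector = 0,
                                 seed = NULL, levels = c("TD", "ASD")) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  if (nFeatures < 1) stop("nFeatures must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  x <- matrix(rnorm(n * nFeatures), n, nFeatures,
              dimnames = list(NULL, sprintf("PC%02d", seq_len(nFeatures))))
  eff <- rep_len(effectVector, nFeatures)
  x[(n1 + 1):n, ] <- sweep(x[(n1 + 1):n, , drop = FALSE], 2, eff, "+")
  list(features = x,
       labels = factor(rep(levels, c(n1, n2)), levels = levels))
}
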