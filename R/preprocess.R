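#' Canonical double-gamma HRF parameters
#'
#' Defaults are the de-facto canonical values: response peak at 6 s,
#' undershoot at 16 s, unit dispersions, peak/undershoot ratio 6, 32-s
#' kernel.
#'
#' @param peakDelay,undershootDelay gamma means (s).
#' @param peakDispersion,undershootDispersion gamma dispersions (s).
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param kernelLength kernel truncation (s).
#' @return named list of parameters.
#' @export
hrfParams <- function(peakDelay = 6, undershootDelay = 16,
                      peakDispersion = 1, undershootDispersion = 1,
                      ratio = 6, kernelLength = 32) {
  p <- list(peakDelay = peakDelay, undershootDelay = undershootDelay,
            peakDispersion = peakDispersion,
            undershootDispersion = undershootDispersion,
            ratio = ratio, kernelLength = kernelLength)
  if (any(unlist(p) <= 0)) stop("all HRF parameters must be positive")
  p
}

#' Canonical hemodynamic response kernel
#'
#' Difference of two gamma densities (response minus scaled undershoot),
#' sampled on the acquisition grid, truncated at `kernelLength` seconds and
#' normalized to unit peak. With the default parameters the kernel peaks at
#' ~5 s (the mode of a shape-6, scale-1 gamma) and is exactly zero at t = 0.
#'
#' @param sampleRate samples per second.
#' @param params see [hrfParams()].
#' @return numeric kernel vector.
#' @examples
#' k <- canonicalHRF(10)
#' which.max(k)  # ~5 s after onset
#' @export
canonicalHRF <- function(sampleRate, params = hrfParams()) {
  if (sampleRate <= 0) stop("sampleRate must be positive")
  tt <- seq(0, params$kernelLength, by = 1 / sampleRate)
  h <- dgamma(tt, shape = params$peakDelay / params$peakDispersion,
              scale = params$peakDispersion) -
    dgamma(tt, shape = params$undershootDelay / params$undershootDispersion,
           scale = params$undershootDispersion) / params$ratio
  h / max(h)
}

# Drift basis: intercept, linear trend, and full-period Fourier pairs
# whose period T/k exceeds cutoffPeriod. Harmonic pairs are exactly
# orthogonal (on the uniform grid) to any integer-cycle task oscillation,
# so block-frequency content is not absorbed into the drift fit; the
# linear term captures ramps exactly.
.drift_basis <- function(n, sampleRate, cutoffPeriod) {
  totalT <- n / sampleRate
  kmax <- max(0L, ceiling(totalT / cutoffPeriod) - 1L)
  i <- (seq_len(n) - 1) / n
  B <- cbind(intercept = rep(1, n), linear = i - mean(i))
  for (k in seq_len(kmax))
    B <- cbind(B, cos(2 * pi * k * i), sin(2 * pi * k * i))
  B
}

#' Remove slow drift from channel time series
#'
#' High-pass detrending by projection: the series is regressed on a drift
#' basis (intercept, linear trend, and low-frequency Fourier pairs with
#' periods longer than `cutoffPeriod`) and the fitted drift is subtracted.
#' Components slower than the cutoff are removed while task-band content at
#' typical block frequencies is attenuated by well under 5%. When `protect`
#' is supplied the drift coefficients are estimated jointly with the
#' protected regressor(s), so task-correlated signal is not absorbed into
#' the drift fit (the usual joint-design-matrix treatment of drift).
#'
#' @param x numeric vector, or samples x series matrix.
#' @param sampleRate samples per second.
#' @param cutoffPeriod high-pass cutoff (s); default 128.
#' @param protect optional regressor vector/matrix held out of the drift
#'   estimate.
#' @return detrended object of the same shape; mean approximately zero
#'   (exactly zero when `protect` is `NULL`).
#' @export
detrendSeries <- function(x, sampleRate, cutoffPeriod = 128, protect = NULL) {
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(A)
  B <- .drift_basis(n, sampleRate, cutoffPeriod)
  if (n <= ncol(B) + 5)
    stop("series too short for the drift basis at this cutoff")
  out <- .project_out(A, B, protect)
  if (vec) out[, 1] else out
}

# subtract the B-part of the joint OLS fit of A on [B, protect]
.project_out <- function(A, B, protect = NULL) {
  M <- if (is.null(protect)) B else cbind(B, protect)
  cf <- qr.coef(qr(M), A)
  cf[is.na(cf)] <- 0
  A - B %*% cf[seq_len(ncol(B)), , drop = FALSE]
}

#' Remove the shared global (systemic) component across channels
#'
#' Estimates the component common to all channels and subtracts it. The
#' first spatial principal component of the channels x samples matrix is
#' removed when its spatial loadings are near-uniform in sign (default:
#' more than 80% of loadings share a sign, the signature of a global
#' systemic source); otherwise the channel-mean time series is regressed
#' out of every channel. When `protect` is given, the global component is
#' estimated on the residuals after removing the protected (task)
#' regressor, so a genuine task response shared across channels is not
#' stripped.
#'
#' @param m channels x samples matrix (at least two channels).
#' @param protect optional task regressor(s) excluded from the global
#'   estimate.
#' @param uniformFrac sign-uniformity fraction above which the spatial-PC
#'   route is taken.
#' @return matrix of the same shape with the global component removed; the
#'   variance of its channel-mean series is a small fraction of the input's.
#' @export
removeGlobal <- function(m, protect = NULL, uniformFrac = 0.8) {
  if (!is.matrix(m) || nrow(m) < 2)
    stop("need a matrix with at least 2 channels")
  A <- t(m)                                # samples x channels
  if (all(A == A[1, 1])) {
    if (all(A == 0)) return(m)             # nothing to remove
    stop("constant input: global component is not identifiable")
  }
  qrP <- if (is.null(protect)) NULL else qr(cbind(1, protect))
  t(.remove_global_core(A, qrP, uniformFrac))
}

# core on samples x channels data with an optional prefactored protect QR
.remove_global_core <- function(A, qrP = NULL, uniformFrac = 0.8) {
  R <- if (is.null(qrP)) A else qr.resid(qrP, A)
  eg <- eigen(crossprod(R), symmetric = TRUE)
  v1 <- eg$vectors[, 1]
  signs <- sign(v1[abs(v1) > 1e-12])
  uniform <- length(signs) > 0 &&
    max(mean(signs > 0), mean(signs < 0)) > uniformFrac
  if (uniform) {
    g <- R %*% v1
    A <- A - g %*% t(v1)
  } else {
    g <- rowMeans(R)
    vg <- sum((g - mean(g))^2)
    if (vg > 0) {
      b <- crossprod(g - mean(g), R) / vg   # 1 x channels
      A <- A - (g - mean(g)) %*% b
    }
  }
  A
}

#' Combined oxy/deoxy hemodynamic signal
#'
#' The task responses of the two chromophores are anticorrelated; their
#' element-wise difference `oxy - deoxy` combines both into a single
#' BOLD-like response.
#'
#' @param oxy,deoxy equally shaped matrices (or vectors).
#' @return `oxy - deoxy`.
#' @export
hbDiff <- function(oxy, deoxy) {
  if (!identical(dim(oxy), dim(deoxy)) || length(oxy) != length(deoxy))
    stop("oxy and deoxy must have identical shapes")
  oxy - deoxy
}

#' Per-channel GLM task amplitudes
#'
#' Ordinary least squares of each channel's (processed) signal on the task
#' regressor plus an intercept; returns the regressor coefficient (beta) per
#' channel.
#'
#' @param signal channels x samples matrix (e.g. the Hbdiff signal).
#' @param design a [TaskDesign-class].
#' @return named numeric vector of betas, one per channel.
#' @export
glmBetas <- function(signal, design) {
  reg <- design@regressor
  if (ncol(signal) != length(reg))
    stop("signal sample count does not match the design regressor")
  if (anyNA(signal)) stop("signal contains missing values")
  regc <- reg - mean(reg)
  den <- sum(regc^2)
  if (den == 0) stop("constant regressor: beta is not identifiable")
  beta <- as.numeric(signal %*% regc) / den
  names(beta) <- rownames(signal)
  if (is.null(names(beta))) names(beta) <- .channel_names(nrow(signal))
  beta
}

#' Preprocess a cohort into a beta matrix
#'
#' Runs, per subject, the channel-space signal chain
#' detrend -> global-component removal -> Hbdiff -> GLM and stacks the
#' per-channel betas into a `SummarizedExperiment` (assay `"beta"`,
#' channels x subjects, cohort metadata as `colData`). Each stage can be
#' switched off. By default the task regressor is protected from the
#' detrend and global filters, so a noiseless task response passes through
#' the full chain unchanged.
#'
#' @param cohort a [Cohort-class].
#' @param detrend,globalFilter,useHbdiff stage toggles; with
#'   `useHbdiff = FALSE` only the HbO signal is fit.
#' @param cutoffPeriod detrend high-pass cutoff (s).
#' @param protectTask protect the task regressor in the filters.
#' @return `SummarizedExperiment` with one beta column per subject, in
#'   cohort order.
#' @examples
#' coh <- simulateCohort(simConfig(nTD = 3, nASD = 3, noiseSD = 0,
#'                                 globalSD = 0, driftSD = 0),
#'                       makeDesign(5, 60, 18, 12))
#' se <- preprocessCohort(coh)
#' dim(SummarizedExperiment::assay(se))
#' @export
preprocessCohort <- function(cohort, detrend = TRUE, globalFilter = TRUE,
                             useHbdiff = TRUE, cutoffPeriod = 128,
                             protectTask = TRUE) {
  subjects <- cohort@subjects
  if (length(subjects) == 0) stop("empty cohort")
  design <- cohort@design
  reg <- design@regressor
  dims <- vapply(subjects, function(s) dim(s@oxy), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("heterogeneous channel/sample dimensions across subjects")
  if (dims[2, 1] != length(reg))
    stop("subject sample count does not match the design")
  n <- dims[2, 1]
  prot <- if (protectTask) reg else NULL

  # shared projection operators (same design for every subject)
  B <- if (detrend) .drift_basis(n, design@sampleRate, cutoffPeriod) else NULL
  qrM <- if (detrend) qr(if (is.null(prot)) B else cbind(B, prot)) else NULL
  qrP <- if (globalFilter && !is.null(prot)) qr(cbind(1, prot)) else NULL
  regc <- reg - mean(reg)
  den <- sum(regc^2)
  if (den == 0) stop("constant regressor: beta is not identifiable")

  chain <- function(m) {                     # samples x channels throughout
    A <- t(m)
    if (detrend) {
      cf <- qr.coef(qrM, A)
      cf[is.na(cf)] <- 0
      A <- A - B %*% cf[seq_len(ncol(B)), , drop = FALSE]
    }
    if (globalFilter) A <- .remove_global_core(A, qrP)
    A
  }
  betas <- vapply(subjects, function(s) {
    sig <- if (useHbdiff) chain(s@oxy) - chain(s@deoxy) else chain(s@oxy)
    as.numeric(crossprod(sig, regc)) / den
  }, numeric(dims[1, 1]))
  rownames(betas) <- .channel_names(dims[1, 1])
  colnames(betas) <- cohort@meta$subject_id
  SummarizedExperiment(assays = list(beta = betas), colData = cohort@meta)
}

#' Extract the subjects x channels beta matrix
#'
#' @param se a `SummarizedExperiment` produced by [preprocessCohort()] or
#'   [readBetaMatrix()], or a plain matrix (returned unchanged).
#' @return subjects x channels numeric matrix.
#' @export
betaMatrix <- function(se) {
  if (is.matrix(se)) return(se)
  t(assay(se, "beta"))
}
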