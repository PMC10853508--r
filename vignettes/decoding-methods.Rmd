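---
title: "Decoding group membership and symptom severity from fNIRS activation maps"
author: "nirsmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding group membership and symptom severity from fNIRS activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsmvpa)
```

## The problem

Small task-based neuroimaging cohorts — here, functional near-infrared
spectroscopy (fNIRS) recordings from a few dozen adults during a live
eye-contact task — are routinely decoded with multivariate classifiers. Two
well-known statistical hazards dominate this regime:

* **Overfitting**: with more features than subjects, some classifier fits
  any labels.
* **Feature-selection leakage**: when features are ranked using *all*
  subjects (including each fold's test subject) before cross-validation,
  the reported accuracy is inflated even for labels that are pure noise —
  on random data, a tuned, pooled-selection pipeline reports around 75%
  "accuracy" where chance is 50%.

`nirsmvpa` implements the complete decoding chain for this setting —
channel-space preprocessing to GLM betas, principal-component (PC)
decomposition, t-score feature ranking, linear support-vector-machine (SVM)
classification under leave-one-out (LOO) cross-validation, permutation
inference, and severity prediction from decision scores — with the
selection step available in both a **nested** (fold-internal, leak-free)
and a **pooled** (leaky, for quantifying the bias) variant, plus a
synthetic-cohort generator with known ground truth so every stage is
testable without any external data.

## The generative model

`simulateCohort()` draws, per subject and chromophore (HbO / HbR), the
channel-space signal

$$x_c(t) = a_c\, r(t) + g(t) + d_c(t) + \varepsilon_c(t)$$

* $r(t)$ — the task regressor: an alternating block boxcar (default 18 s
  task / 12 s rest over 180 s at 30 samples/s, starting with a task block)
  convolved with the canonical double-gamma HRF (peak 6 s, undershoot 16 s,
  unit dispersions, peak:undershoot 6:1, 32-s kernel) and rescaled to unit
  maximum. A switch models the 3-s gaze sub-epochs inside each task block,
  but the default treats a block as one continuous epoch: at these
  hemodynamic time scales the regressor cannot resolve 3-s sub-structure.
* $a_c$ — the injected amplitude map. Control subjects carry the baseline
  map (default 0.5 everywhere, arbitrary concentration-like units per unit
  regressor). Affected subjects carry
  $a_c = \text{baseline} - s\,\pi_c\,u_i$: a hypoactivation pattern
  $\pi$ (default: unit weight on a contiguous 8-channel support,
  channels 20–27 of 54) scaled by the effect scale $s$ and a per-subject
  expression factor $u_i \sim \Gamma(10, 10)$ (mean 1, SD ≈ 0.32).
* $g(t)$ — one global systemic series per subject and chromophore, shared
  across channels: AR(1) with coefficient 0.95 and marginal SD 0.3. The
  cited spatial-filter literature does not prescribe a generative form; a
  slowly mixing AR(1) is the simplest process with the right "shared,
  smooth, non-task" character.
* $d_c(t)$ — integrated white noise (random-walk drift, per-step SD 0.01),
  emulating baseline wander.
* $\varepsilon_c(t)$ — white sensor noise, SD 0.5.

HbR receives the amplitude scaled by the (negative) `oxyDeoxyRatio`
(default −0.5) with independent realizations of the same noise terms —
the anticorrelated task response that motivates the combined
Hbdiff = HbO − HbR signal.

Severity scores exist only for the affected group and are affine in the
expression factor: $\text{sev}_i = 2 + 10\,u_i + N(0, 1)$, spanning
roughly 6–20 — the scale range of a typical clinical severity instrument.
This is the simplest mechanism that makes a correlation between classifier
decision scores and severity *recoverable*: subjects expressing the group
pattern more strongly are both easier to classify and more severely
affected.

**What the generator does not emulate**: between-subject variability of
the *baseline* map (control subjects differ only by noise), motion
artifacts, optode-coupling channel dropouts, heartbeat/respiration bands,
and dyadic coupling between partners. Passing recovery tests on this
generator therefore demonstrates correctness of the analysis machinery,
not performance on real recordings.

Default group sizes (19 control, 17 affected), channel count (54), sample
rate (30/s) and run length (180 s) mirror the acquisition the pipeline
targets.

## Preprocessing to beta maps

`preprocessCohort()` runs, per subject: drift removal → global-component
removal → Hbdiff → GLM, yielding one beta per channel
(`SummarizedExperiment`, channels × subjects).

* **Drift removal** (`detrendSeries`) projects out an intercept, a linear
  trend and full-period Fourier pairs with periods longer than
  `cutoffPeriod` (default 128 s). Harmonic pairs are exactly orthogonal on
  the sampling grid to integer-cycle task oscillations (a cosine-only DCT
  set is not — it absorbs odd-symmetric task content), and the linear term
  removes ramps exactly. A wavelet-based detrend would serve equally; the
  contract that matters downstream is: drift gone, mean ≈ 0, task-band
  content attenuated by well under 5% at the block frequency. Note that
  any projection high-pass reshapes *out-of-band* content — the output is
  not the input minus the ramp sample-by-sample, but its task-band
  amplitude is preserved.
* **Global filtering** (`removeGlobal`) removes the first spatial
  principal component when its channel loadings are near-uniform in sign
  (> 80% — the signature of a systemic source); otherwise it regresses
  out the channel-mean series.
* **Task protection.** Both filters accept the task regressor as a
  `protect` argument (the default in `preprocessCohort()`): drift
  coefficients are estimated jointly with the regressor, and the global
  component is estimated on task-residualized data. This is the usual
  joint-design-matrix treatment. It is also what makes the noiseless
  identity exact: without it, a noiseless cohort is a rank-1 data matrix
  whose "global component" *is* the task response, and an unprotected
  filter would remove the signal it is supposed to preserve. With
  protection, a noiseless cohort returns
  $\beta_c = (1 - \text{ratio}) \cdot a_c$ to machine precision.
* **GLM** regresses the Hbdiff signal on the task regressor plus an
  intercept only; the acquisition design has no further regressors.

## Decomposition and feature ranking

`fitPCA()` performs centered, unscaled PCA of the subjects × channels beta
matrix (channels share units, so no per-feature standardization): scores
$= (X - \bar X)V$, orthonormal component maps, explained-variance
fractions from the singular values. The default retains 32 components —
the conventional "about as many as the data support" choice for 36
subjects; it is configurable, and any value up to `nSubjects − 1` is
valid. Full-rank reconstruction
$x_i = \bar x + \sum_j \text{score}_i^j \, PC_j$ is exact.

`rankPCs()` orders components by the absolute two-sample t statistic of
their scores between the groups, computed **only on the requested subject
subset** — this subset argument is the nesting mechanism. The t flavor is
the pooled-variance statistic (Welch available). Ties break toward the
lower component index, deterministically.

One deliberate scope decision: the **PCA basis is fit once on the full
cohort** and only the *ranking* is nested. Nesting only the selection is
the leak that matters here: PCA is label-blind, so refitting it per fold
changes little, but the t-ranking uses labels and is exactly where pooled
computation leaks. Cross-validating the PCA fit as well is available by
simply calling `fitPCA()` inside a custom fold loop.

## Classification

* **Univariate** (`fitUnivariate`, `univariateLOO`): the one-dimensional
  rule $Y = wX + b$, $w \in \{\pm 1\}$, predicting the first class for
  $Y > 0$; trained by exhaustive search over orientations and thresholds
  at midpoints of consecutive sorted distinct values (± infinite
  sentinels), maximizing training accuracy with ties toward the smallest
  $|b|$, then $w = +1$. A logistic-regression scorer is available as an
  alternative fold scorer.
* **Multivariate** (`fitLinearSVM`): soft-margin linear SVM — the C-SVC
  quadratic program with hinge loss, $L_2$ penalty and regularization
  constant $C = 1$ by default ($C$ is configurable; no value is
  prescribed by the problem, and 1 is the conventional default).
  Features are z-scored **inside each training fold** (means/SDs from
  the training subjects only) for scale comparability of PC scores. The
  solver is an exact SMO (sequential minimal optimization) on the dual
  with maximal-violating-pair selection, KKT gap tolerance $10^{-6}$,
  implemented in C++ because the permutation experiments need on the
  order of $10^6$ small fits. It is verified in the test suite against
  an independent QP implementation (direction cosine on separable toys;
  primal-objective dominance on general problems).
* **Cross-validation** (`looSVM`, `tuningCurve`): leave-one-out — folds
  are deterministic, no fold-assignment randomness exists. `mode =
  "nested"` recomputes the t-ranking within each training fold;
  `mode = "pooled"` ranks once on all subjects including the held-out
  one. At `k = nPC` the two modes coincide (selection is vacuous) — a
  useful internal consistency check. Decision scores of held-out
  subjects are retained; their sign convention is "positive = second
  class level", and swapping the class labels negates every score
  exactly.

## Inference

* `permutationNull()` permutes the diagnostic labels uniformly at random
  (group sizes preserved — permutation rather than Bernoulli relabeling,
  so the null conditions on the observed 19/17 split) and reruns the full
  selection + SVM + LOO pipeline each time. The pipeline config may fix
  `k` or maximize over a `kRange` — the latter reproduces the
  "tune-then-report" optimism jointly with selection leakage.
* `pValue()` offers the literal exceedance fraction
  $\#\{\text{null} > \text{obs}\}/n$ and the add-one, ties-count-against
  rule $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n)$. The literal rule
  is the classical description; the conservative rule is the
  statistically recommended default (it is exactly valid and never zero)
  and is what `runPipeline()` reports. On accuracy distributions, which
  are heavily tied, the two can diverge sharply; both are exposed.
* `significanceThresholds()` returns nearest-rank $(1-\alpha)$ quantiles
  of the null accuracies (per configuration — thresholds are computed per
  `k` in `cvBiasExperiment()`, not pooled across `k`).
* `predictSeverity()` correlates held-out decision scores with observed
  severity on the affected subjects. Severity never enters training, so
  this correlation is an independent generalization check. The
  least-squares affine map from scores to severity units is attached for
  display only; Pearson's r is invariant to it (and flips sign under
  negative rescalings — asserted both ways in the tests). Significance
  is a two-sided severity-permutation test (default 10,000 permutations,
  add-one rule); the t-distribution formula is available as
  `method = "t"`.

## Calibration results the tests recompute

Three quantities summarize the leakage story on label-independent data
(36 subjects, 19/17, 32 iid standard-normal features); the acceptance
script recomputes them from scratch:

1. nested selection, fixed `k = 10`: mean LOO accuracy ≈ 50% — chance;
2. pooled selection with `k` tuned by maximizing the curve over 1–32:
   mean ≈ 75% — the leakage + tuning inflation;
3. the 95th percentile of a 1000-permutation null under the pooled tuned
   scheme ≈ 88% — the accuracy a pooled analysis must exceed before it
   means anything at $\alpha = 0.05$.

## Numerical and scale choices

* **Tolerances**: PCA orthonormality and reconstruction asserted at
  $10^{-8}$; SMO KKT gap $10^{-6}$; noiseless beta identity $10^{-6}$
  relative (observed: ~$10^{-15}$).
* **Tie-breaks**: feature ranking — lower index; tuning — smallest best
  `k`; univariate — smallest $|b|$, then $w = +1$. All deterministic.
* **Degenerate inputs** are errors with named messages (constant
  regressor, constant matrix, single channel, single class, empty null),
  except where a benign interpretation exists (all-zero matrix through
  the global filter; one-class univariate training, which returns a
  sentinel threshold).
* **Problem sizes in the test suite.** Monte-Carlo property studies (the
  200-cohort chance-calibration of the full signal chain; the 5-point
  effect-scale recovery grid at 50 cohorts per point) run the full chain
  on a 5-samples/s grid with the identical 18 s/12 s block structure and
  54-channel, 19+17 geometry. The tested properties are invariant to the
  sampling rate — under a null effect the accuracy distribution does not
  depend on the within-subject noise floor at all, and the recovery grid
  is calibrated against the generator's own beta-noise scale.
  Empirically that scale is ~0.15 per channel, dominated not by white
  sensor noise (whose contribution to a beta over 900+ samples is tiny)
  but by mid-band drift power and the task-correlated part of the global
  series that task-protected filtering deliberately leaves in place; the
  grid 0, 0.05, 0.1, 0.25, 1 spans chance to the pipeline's plateau by
  design. Everything user-facing defaults to the full 30 samples/s
  geometry.

## Limitations

* **Task-protected filtering cannot remove task-correlated physiology.**
  Holding the task regressor out of the drift/global estimation is what
  makes the noiseless identity exact, but its price is that the component
  of the global systemic series that happens to correlate with the task
  survives into the betas as a per-subject offset shared across channels.
  This is the classic systemic-confound dilemma of fNIRS; the offset is
  label-independent here, so it costs variance (not bias), and PCA
  isolates it into its own components.
* **Fold-standardized low-variance components dilute decision scores.**
  z-scoring PC scores inside each training fold gives every selected
  component unit scale, including near-noise components; with `k` well
  above the true signal rank, their overfitted weights add O(1) noise to
  held-out decision scores. This caps severity correlations when `k` is
  generous — which is why the recovery demonstrations use a small `k`
  matched to the (rank-1) injected pattern, and why inspecting the tuning
  curve matters in practice.
* The generator's control group has no between-subject map variability;
  real between-subject physiological variance is much larger than the
  GLM beta standard error, so absolute accuracies on synthetic cohorts
  are not predictions for real data.
* All maps live in channel space; no scalp/cortex projection or
  rendering is provided, only channel-value tables joinable to a
  channel-coordinate file.
* The univariate rule and the SVM share no calibration: decision scores
  are distances, not probabilities.
* Severity prediction is a correlation plus a display transform, not a
  trained regression model.
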