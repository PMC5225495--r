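---
title: "Phase-based static and dynamic functional connectivity with phasedyn"
author: "phasedyn maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based static and dynamic functional connectivity with phasedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasedyn)
```

## The analysis in one page

phasedyn analyzes cohorts of multivariate neural time series — one node
× time matrix per subject, sampled at a repetition time TR — through
their instantaneous phases. The canonical use case is resting-state
fMRI component time series (e.g. 26 ICA components × 202 volumes at
TR = 2.638 s), but nothing in the code is specific to fMRI beyond the
default frequency band.

The pipeline runs, in order:

1. **Narrowband filtering.** Each node series is detrended and
   band-passed to 0.04–0.07 Hz with a 4th-order Butterworth applied
   forward and backward (zero phase lag).
2. **Analytic signal.** The Hilbert transform extends each filtered
   series `x(t)` to `z(t) = x(t) + i H[x(t)]`, giving the instantaneous
   envelope `a(t) = |z(t)|` and phase `phi(t) = arg z(t)`. The first and
   last 10 samples are dropped to limit transform border effects.
3. **Whole-brain dynamics.** The Kuramoto order parameter
   `R(t) = |mean_k exp(i phi_k(t))|` measures instantaneous whole-brain
   synchrony; its temporal standard deviation is the **metastability** —
   high when the network keeps switching between coherent and incoherent
   states.
4. **Edgewise dynamics (dFC).** For each node pair the circular phase
   distance `dphi_ij(t)` in `[0, pi]` is normalized to a coupling
   `C_ij(t) = 1 - dphi_ij(t)/pi` in `[0, 1]`; the coefficient of
   variation of `C_ij(t)` over time is the per-edge dynamic-connectivity
   metric. For 26 nodes this gives 325 unique values in a canonical
   row-major upper-triangle order ((1,2), (1,3), …, (25,26)).
5. **Session-averaged coupling (sFC).** Per subject, an L1-penalized
   Gaussian likelihood estimate of the inverse covariance (graphical
   lasso) on standardized series yields partial correlations
   `p_ij = -Theta_ij / sqrt(Theta_ii Theta_jj)`, Fisher z-transformed.
6. **Surrogate tests for genuine dynamics.** Multivariate
   phase-randomized Fourier surrogates — one random phase sequence per
   subject applied to *all* nodes' spectra (preserving every amplitude
   spectrum exactly and all cross-spectra) — are pushed through the
   identical downstream pipeline; one-sample T statistics of the real
   dFC summaries are compared with their surrogate counterparts.
7. **Group inference.** Covariate-adjusted models relate the metrics to
   diagnosis: per-edge pairwise logistic regressions, a multinomial
   logit of diagnosis on metastability, and the network-based statistic
   (NBS) with permutation family-wise-error control on connected
   suprathreshold components.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| band (`lowHz`, `highHz`) | 0.04–0.07 | Hz | the narrowband in which resting-state phase coupling is conventionally defined; must lie inside (0, Nyquist ≈ 0.1895 Hz at TR 2.638 s) |
| filter order | 4 | – | standard Butterworth narrowbanding; applied forward–backward so the effective attenuation is doubled and the phase response is exactly zero |
| `trim` | 10 | samples/end | discards Hilbert border effects; 202 volumes leave 182 usable timepoints |
| `lambda` | 0.1 | – | graphical-lasso penalty on standardized (correlation-scale) data; a conventional mild penalty. The penalty used by the original FSLNets-style analyses is not published, so the value is exposed and the suite checks the estimator's properties (KKT conditions, sparsity monotonicity, λ = 0 equivalence with direct inversion) across a grid rather than at one magic value |
| `sdType` | "sample" | – | n−1 denominator for metastability and the CV numerator; the population convention is one flag away |
| `nSurrogates` | 1000 | – | desk-scale default; the full-scale analysis uses 10000. p-values live on the grid {0, 1/S, …, 1} |
| `nPerm` | 5000 | – | NBS permutation count; `primaryP` = 0.05 sets the per-edge F threshold |

## The synthetic-data generator

Real registry data of this kind are not publicly distributable, so the
package ships a generator whose cohorts have *known ground truth* and
exercise every downstream stage.

**Dynamic cohorts** integrate noisy Kuramoto phase oscillators,

  dθ_k/dt = ω_k + Σ_j K_kj sin(θ_j − θ_k) + σ dW,

by Euler–Maruyama at an internal step of TR/20 (≥ 100 steps per cycle
at 0.07 Hz; steps coarser than TR/10 are rejected), with natural
frequencies drawn uniformly so ω/2π lies in 0.04–0.07 Hz, phase noise
σ = 0.25 rad/√s, and the emitted signal sin θ_k plus Gaussian
measurement noise (SD 0.2). Global coupling K controls synchrony: at
K = 0 the order parameter shows only finite-size fluctuations, near the
critical coupling (~0.1 for these settings) metastability peaks, and at
strong coupling the network locks and metastability collapses. The test
suite verifies this non-monotone profile directly.

Group effects are encoded through K on the supercritical branch, where
metastability *decreases* with K: defaults K = 0.12 / 0.18 / 0.24 for
the SCI / MCI / AD analogue groups, plus 10% per-subject jitter. These
values were fixed once by a design simulation (before the acceptance
suite was written) so that 26 subjects per group give high power: group
means are strictly ordered SCI > MCI > AD in essentially every
replicate cohort, and the multinomial logit detects both non-reference
contrasts with negative coefficients at p < 0.05 in well over 80% of
replicates.

Covariates mirror a memory-clinic design: group-dependent age means
(71.5 / 63.5 / 63.6 years with SDs 7.9 / 11.1 / 9.6), balanced sex, a
mostly-8-channel head-coil dummy (73%), log-normal motion. The age
imbalance is deliberate: it makes covariate adjustment do real work in
the tests.

**Stationary null cohorts** are multivariate Gaussian AR(1) processes
with a chosen instantaneous cross-covariance and lag-1 autocorrelation.
Their distribution is (asymptotically) invariant to Fourier phase
randomization, so they carry matched auto- and cross-correlations but
no genuine time-varying coupling — the correct null for the surrogate
tests, which the suite uses to verify type-I error calibration.

**What the generator does not emulate:** hemodynamic convolution,
measurement drifts and physiological artifacts, spatially structured
connectomes, or amplitude dynamics. Passing tests demonstrate that the
*methods* behave as specified on data with known ground truth; they do
not certify effect sizes on real BOLD data.

## Numerical and design choices

* **Zero-phase filtering** is realized in the frequency domain: the DFT
  of each detrended series is multiplied by |H(ω)|², the squared
  magnitude response of the Butterworth band-pass. This is the
  forward–backward cascade in the circular-convolution sense; it is
  exactly reversal-symmetric, has an exact DC null, and vectorizes over
  nodes — which matters when thousands of surrogate panels are
  filtered. Border effects are circular rather than reflective and are
  absorbed by the detrend plus the 10-point end trim that the phase
  step applies anyway.
* **Circular distance** between wrapped phases uses
  `min(|Δ| mod 2π, 2π − |Δ| mod 2π)`, which keeps `C` in [0, 1] exactly
  as the normalization `1 − Δφ/π` requires.
* **Graphical lasso** is a block coordinate descent over columns, with
  every entry (including the diagonal) penalized, on the correlation
  matrix of standardized series so the penalty is scale-free. λ = 0
  falls back to direct inversion; non-convergence and singularity are
  reported, never papered over. Solutions are verified in the tests
  against the KKT conditions of the penalized likelihood.
* **Surrogate construction** draws one phase sequence per subject per
  surrogate, shared across nodes (independent rotations would destroy
  the cross-correlations the null must preserve) and independent across
  subjects (sharing them would fabricate cross-subject dependence).
  DC and Nyquist bins are untouched; conjugate symmetry keeps the
  inverse transform real. p-values count strict `T > T*` exceedances
  with no small-sample correction, so `p` is achievable on
  {0, 1/S, …, 1}. Testing a positive-valued CV against a population
  mean of zero makes every raw |T| large by construction; the
  discriminative content lies entirely in the comparison of T with its
  surrogate distribution, and the calibration tests confirm that this
  comparison is uniform under the stationary null.
* **NBS** uses ANCOVA F statistics for the group factor with
  Freedman–Lane residual permutation (covariate effects are refitted and
  their residuals permuted), component *extent* as the default statistic
  (intensity is a flag), and the (1 + b)/(1 + m) permutation p
  convention so p is never exactly zero. An exhaustive mode enumerates
  all row permutations on tiny instances (n ≤ 9) and is checked in the
  tests against an independently coded brute-force oracle.
* **Edgewise logistic p-values** are likelihood-ratio tests of the edge
  term. Wald p-values collapse toward 1 under the quasi-separation that
  large group differences induce (Hauck–Donner), which would make the
  strongest edges look least significant; coefficients and Wald SEs are
  reported alongside. No multiple-testing correction is applied at this
  stage — the NBS stage is the corrected analysis — and a Bonferroni
  threshold is a single comparison away (`0.05 / nEdges`).
* **Multinomial logit** is `nnet::multinom` with tight convergence
  settings; McFadden's pseudo-R² is reported against the intercept-only
  model. On two-class data it agrees with `glm` binomial fits to the
  optimizer's practical precision (~1e-4 relative in coefficients,
  1e-6 in likelihood-scale quantities).

## Two properties that deserve a warning

* **The CV-based dFC metric is not orthogonal to sFC.** Because
  `C_ij` distinguishes in-phase (C = 1) from anti-phase (C = 0), its
  temporal CV decreases monotonically with the signed instantaneous
  correlation of a pair. On stationary cohorts the median edgewise
  correlation between dFC and sFC is therefore intrinsically negative
  (around −0.2 to −0.45 at study dimensions), not zero. The test suite
  asserts the sign and that the shared variance stays well below half;
  treating the two metrics as complementary, not independent, is the
  right reading.
* **Genuine coupling dynamics *lower* the dFC sum.** Coupling episodes
  raise the temporal mean of C more than its SD, so dynamically coupled
  cohorts show *smaller* whole-cohort dFC sums than correlation-matched
  stationary nulls or their own phase-randomized surrogates. The
  whole-brain detection curve should accordingly be read as a
  calibration instrument (its null behavior is verified) rather than a
  one-sided "more is more dynamic" score.

## Problem sizes used by the shipped tests

The suite exercises study-scale dimensions where the property needs
them (26 nodes, 202 timepoints, 26 subjects per group for parameter
recovery; 20 replicate cohorts) and reduced dimensions elsewhere
(6–12 subjects, 8–12 nodes, 500–1000 surrogates, 500 permutations) —
sizes chosen so the full suite documents the statistical behavior,
calibration included, with Monte-Carlo envelopes wide enough to be
stable across seeds.

## Known limitations

* The Kuramoto generator is a stand-in consistent with treating
  narrowband signals as coupled oscillators; it is not a claim about
  the true generative process of BOLD data.
* Whether the upstream study detrended again before narrowband
  filtering is unreported; phasedyn always removes a linear trend
  before filtering, which is harmless for already high-passed input.
* Sliding-window dFC and amplitude-envelope coupling are out of scope;
  the envelope `a(t)` is exposed for inspection only.
* The graphical-lasso penalty of the original analyses is unknown;
  conclusions that depend on a specific λ should be checked across a
  grid (the package's properties hold across one).
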