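---
title: "Orthogonalized amplitude-envelope connectivity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonalized amplitude-envelope connectivity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaec)
library(dplyr)
```

## The problem

Resting-state EEG mixes every cortical source into every scalp electrode.
Any connectivity statistic computed directly between sensors — or between
naively reconstructed sources — is therefore contaminated by *spatial
leakage*: a single source appearing instantaneously in two signals looks
like zero-lag "connectivity" even when the underlying regions are entirely
independent. `oaec` implements a pipeline built to measure genuine
band-limited coupling between four regions implicated in depression — the
left/right subgenual anterior cingulate (sgACC) and the left/right
dorsolateral prefrontal cortex (DLPFC) — in a way that is robust to this
artifact, and to test whether that coupling separates patients from
controls, tracks clinical covariates, and carries diagnostic information.

The chain is:

1. **Minimum-norm inverse.** With a lead field $L$ and a diagonal noise
   covariance $C$ estimated from the recording itself, the whitened lead
   field is $G = C^{-1/2} L$ and the inverse operator is
   $$K = G^\top \left( G G^\top + \lambda^2 I \right)^{-1} C^{-1/2},$$
   i.e. Tikhonov-regularized minimum-norm with identity source covariance
   and no depth weighting. Source estimates are $\hat S = K X$.
2. **ROI extraction.** Sources with three unconstrained orientation
   components are collapsed to one sequence by the first principal
   component of the $3 \times T$ block (sign fixed against the
   largest-variance component); ROI members are sign-aligned to the ROI's
   first principal component and averaged. PCA (rather than the component
   norm) preserves the signal's phase, which the Hilbert step needs.
3. **Band-pass filtering.** Zero-phase (forward–backward) 4th-order
   Butterworth filters in six bands: theta 4–8, alpha 8–12, beta-1 13–17,
   beta-2 18–24, beta-3 25–30 and gamma 30–100 Hz.
4. **Symmetric orthogonalization.** The band-limited ROI signals are
   replaced by the closest (Frobenius-norm) set of mutually *orthogonal*
   signals, found by alternating the orthonormal polar factor of the
   magnitude-scaled matrix with per-row rescaling. Orthogonal rows share no
   zero-lag component, so whatever leakage the inverse left in the ROI
   signals is removed jointly and order-independently.
5. **Envelope correlation (AEC).** Each corrected signal's amplitude
   envelope is the magnitude of its analytic signal
   $|x + i\,\mathcal{H}(x)|$; AEC for a pair of ROIs is the Pearson
   correlation of their envelopes, computed per band, per subject.
6. **Statistics.** Two-tailed non-parametric permutation Welch-t tests per
   (pair, band) cell, Benjamini–Hochberg step-up FDR over the full
   $6 \times 6 = 36$-cell family; Monte-Carlo permutation Pearson
   correlations between a selected cell and clinical covariates; an
   RBF-kernel SVM over the four sgACC–DLPFC features evaluated by
   leave-one-out cross-validation.

## What the synthetic generator emulates

No public recordings accompany the design this package targets, so the
package ships a generator that plants every effect the pipeline is supposed
to find. Per subject, each ROI source is a sum over bands of
amplitude-modulated carriers
$$x_i(t) = \bigl(1 + d\, e_i(t)\bigr)\, c_i(t),$$
where the $c_i$ are independent band-limited Gaussian carriers and the
$e_i$ are slow (default 1 Hz low-passed), standardized modulators that share
correlation $\rho$ according to the coupling table. Coupling therefore
lives **only in the envelopes** — exactly the quantity AEC measures — while
carrier phases stay independent. The generator's measured ground truth
("true AEC") is the envelope correlation of each isolated band component;
it is deliberately *not* assumed equal to $\rho$, because carrier-envelope
fluctuations dilute the modulator correlation (with the default modulation
depth $d = 0.5$, a planted $\rho = 0.7$ yields a true AEC around 0.3).

Sensor data are $X = L S + N$: a smooth toy lead field (Gaussian spatial
footprints, unit-norm columns, condition number < 100) plus white noise at
a configurable power SNR (default 4). Linear mixing makes even uncoupled
sources instantaneously correlated at the sensors — the artifact stage 4
must remove.

Defaults mirror the emulated study design: 20 subjects per group,
128 channels at 512 Hz, 6-minute eyes-closed recordings, four ROIs, the six
bands above, and a single planted deficit — beta-1 coupling on the left
sgACC–right DLPFC pair of $\rho = 0.7$ in controls vs $0.2$ in patients.
The patient covariate `episodes` follows
`round(max(1, 18 - 60 * AEC + N(0, 3)))` on that cell's realized true AEC.
The slope and noise scale were fixed once from the analytic relation
$r = b\,\sigma_{AEC} / \sqrt{b^2 \sigma_{AEC}^2 + \sigma_\varepsilon^2}$
with the generator's typical between-subject spread
($\sigma_{AEC} \approx 0.05$), planting the strong negative
episodes–connectivity association (around $-0.7$) the analysis is meant to
recover.

What the generator does **not** emulate: real head geometry or atlas
parcellations (the toy lead field has no anatomy), physiological artifacts
(blinks, muscle, line noise beyond an optional synthetic tone), 1/f
background spectra, non-stationarity, or volume-conduction patterns more
complex than a fixed linear mixture. Passing tests therefore demonstrate
that the *pipeline* recovers what it is designed to recover under its own
generative assumptions — not that those assumptions exhaust real EEG.

## Numerical and design choices

* **Regularization** defaults to $\lambda^2 = 1/9$, the usual SNR = 3
  convention ($\lambda^2 = 1/\mathrm{SNR}^2$); it is a tunable argument
  everywhere it appears.
* **Filter** order 4, applied bidirectionally so the net phase response is
  zero — envelope timing must not be skewed band-by-band. The forward and
  backward passes run in compiled code and reproduce `signal::filtfilt`
  exactly (same trailing-zero padding). The generator synthesizes its
  carriers by multiplying white-noise spectra with the same Butterworth
  forward–backward magnitude response $|H(\omega)|^2$ in the frequency
  domain, which is the identical linear operation for circularly
  stationary noise at a fraction of the cost.
* **Orthogonalization** operates on unit-RMS rows: the closest-orthogonal
  objective weights rows by their magnitude, and per-ROI reconstruction
  gain carries no information, so normalizing first makes AEC exactly
  invariant to rescaling any ROI. Iterations run in the ROI-dimensional
  row-space basis (eigen-decomposition of the small Gram matrix), converge
  at a relative Frobenius change below 1e-9, and cap at 200 iterations.
  Degenerate inputs follow the optimum's own behavior: exactly duplicated
  rows make the closest orthogonal set non-unique and raise an error,
  while a row that is an exact scalar copy of another (pure leakage) is
  dominated and goes to zero — its envelope then carries no signal and its
  AEC is reported as 0 by convention.
* **Envelope** is the analytic-signal magnitude (amplitude, not squared
  power), via the FFT half-spectrum construction.
* **Edge handling**: 1 s is trimmed from each end of every envelope before
  correlating, removing filter and Hilbert edge transients.
* **Windowing**: the default correlates envelopes over the full record; an
  optional mode splits envelopes into non-overlapping windows and averages
  per-window correlations. Averaged windowed correlations and the
  full-record correlation agree for stationary signals, and the full-record
  form has the smaller variance, hence the default.
* **Permutation tests** use the Welch statistic (matching the unequal-
  variance t-tests used for cohort tables) and the add-one Monte-Carlo
  estimator $p = (1 + \#\{|t^*| \ge |t_{obs}|\})/(1 + n_{perm})$, which is
  valid (never zero) at any permutation count. The default is 10000
  permutations, seeded and reproducible; each tensor cell derives its own
  stream from the master seed.
* **FDR** is the Benjamini–Hochberg step-up rule over all 36 cells; the
  reported threshold is $k\,q/m$ at the maximal step-up rank $k$ (for a
  family of 36 with $k = 4$ at $q = 0.05$: $0.00556$). The rejection set is
  computed through `p.adjust(..., "BH")`, which is algebraically the same
  rule; an independently coded step-up loop cross-checks it in the tests.
* **SVM**: Gaussian kernel $\exp(-\|u-v\|^2 / (2 s^2))$ with kernel scale
  $s = 1$, box constraint $C = 3$, no feature standardization — the stated
  settings of the evaluation this package mirrors, with all three exposed
  as arguments. The solver is libsvm via `e1071` (tolerance 1e-6); the
  package's contribution is the leave-one-out harness and metrics, not the
  QP solver. Ties at the decision boundary resolve toward the control
  class.
* **Sign conventions**: positive group-contrast t means the control group
  has the higher AEC; dipole-orientation and ROI-member sign flips are
  fixed deterministically against first principal components.

## Problem sizes used by the shipped tests

The package's own test battery and the reproduction script run entirely on
generated data, at sizes chosen to exercise every stage meaningfully on a
single CPU: full-null calibration uses 16-subject cohorts of 16-s
recordings at 256 Hz over 200 replicates (the shortest record the
generator's invariants allow); the end-to-end power study uses the
emulated design's 20 + 20 subjects with 60-s recordings at 256 Hz and a
16-sensor array over 50 replicates; oracle-agreement checks use single
300-s records at 512 Hz. Longer recordings shrink only the sampling
variance of AEC, not the structure of any computation, so these scaled
runs exercise the identical code paths as the full-scale defaults.

## Known limitations

* The minimum-norm inverse assumes the supplied lead field; with the toy
  forward model, localization error is not a meaningful quantity and is
  not evaluated.
* Orthogonalization removes *all* zero-lag correlation, genuine or
  artifactual; truly instantaneous physiological coupling is invisible to
  this pipeline by design.
* The generator's planted effect sizes are free parameters of the
  emulation, not estimates from data: detection rates reported by the test
  battery characterize the pipeline under those settings only.
* EDF output quantizes each channel to 16 bits over its own range; for the
  synthetic cohorts this quantization is orders of magnitude below the
  effects of interest.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- run_config(
  output_dir = "oaec-demo",
  seed = 7,
  simulate = simulation_config(n_per_group = 20, fs = 256, duration = 60,
                               n_sensors = 16, seed = 7),
  n_perm = 999
)
res <- run_pipeline(cfg)

res$statmap |> arrange(p) |> head()
res$covariate_assoc
glance(res$loocv)
autoplot(res$statmap)
```

The run writes `connectivity.tsv`, `statmap.tsv`, `cohort_comparison.tsv`,
`covariate_assoc.tsv`, `classifier_metrics.json` and `run_log.json` under
`output_dir`, every file stamped with the configuration hash; re-running
with the same configuration reproduces each file byte for byte.
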