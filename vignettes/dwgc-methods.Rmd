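---
title: "Window-level Granger causality for real-time motor-imagery decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-level Granger causality for real-time motor-imagery decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwgcfmri)
```

## The problem

Real-time fMRI decoding of motor imagery must recognize, within a couple of
repetition times (TR = 2 s here), whether a subject is imagining a left- or
right-hand movement. The classical feature — the mean BOLD amplitude of a
region of interest relative to its resting level — is slow: the hemodynamic
response needs roughly 2–6 s to express a neural state change, so
amplitude-based decoding lags the task block. This package implements an
alternative feature family: *dynamic window-level Granger causality* (DWGC),
the directed predictive influence between ROI signals evaluated on short
sliding windows, together with the full pipeline around it — synthetic
ground-truth generation, spherical-ROI signal extraction, a classifier
suite, and a volume-by-volume streaming replay of the real-time loop.

## The window-level causality statistic

For an ordered node pair (source $i$, target $j$) and a window of $k$
volumes starting at $t$, two nested least-squares predictors of the target
are fitted on the `train_span` samples strictly before $t$:

* **restricted** — the target's next value regressed on its own last $p$
  (basis-expanded) values, plus an intercept;
* **full** — additionally the source's last $p$ values.

Both are then evaluated *out of sample* as one-step-ahead predictions over
the window $[t, t+k-1]$, using observed lags. With $L_1$ and $L_2$ the mean
squared errors of the restricted and full predictions,

$$F = \frac{L_1}{\max(L_2, \varepsilon)},$$

so $F \gg 1$ means the source's past improved prediction of the target
within this particular window. A detection threshold $\omega$ is calibrated
from circular-shift surrogates (below); $F$ values are kept if
$F \ge \omega$ and set to zero otherwise (boundary inclusive). The
time-indexed tensor of thresholded $F$ values over all ordered pairs is the
effective-connectivity feature stream.

Assumptions worth stating: the statistic is pairwise (no conditioning on
the remaining nodes), linear by default (a per-lag polynomial basis of
configurable degree is available for a simple nonlinear autoregression),
and treats the trailing training span as locally stationary. Because every
design contains an intercept and per-lag power terms, predictions are
invariant to affine rescaling of the series; the reported MSEs are
additionally divided by the training-span variance of the target so that
$L_1$ and $L_2$ are comparable across ROIs with different BOLD scales.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 4 | volumes | window length; short enough to track block-level state changes at TR 2 s |
| `order_p` | 1 | lags | one TR of history; higher orders dilute the few window samples |
| `train_span` | 40 | volumes | long enough for a stable coefficient estimate; a shorter span makes the fitted coupling noisier faster than it makes it more local |
| `basis` | linear (degree 2 available) | — | the nonlinear option expands each lag into powers 1..degree |
| `epsilon` | 1e-12 | — | floor on $L_2$; noise-free perfect coupling reports the capped ratio and a `saturated` flag |
| `alpha` | 0.05 | — | nominal false-positive level of the surrogate-calibrated threshold |
| `stride` | 1 | volumes | window step |

`fit_mode = "in_sample"` fits and scores both models on the span extended
through the window; it guarantees the nesting inequality $L_2 \le L_1$
window by window and is used for cross-checks against a conventional
full-series Granger test. In the default out-of-sample mode the inequality
holds only on long-run averages for genuinely coupled pairs.

### Threshold calibration

`calibrate_threshold()` circularly shifts the source series by random
offsets — destroying cross-lag structure while preserving each series'
autocorrelation — recomputes window-level $F$ on the surrogates, and sets
$\omega$ to the empirical $1-\alpha$ quantile. Per ordered pair by default
(a global pooled threshold is an option); each of the 500 default
surrogate draws contributes several window positions to the pooled
quantile, which tightens the estimate without more shifts. The
`null_calibration_study()` measures the realized false-positive fraction
on fresh null windows against the nominal level.

## The synthetic ground truth

`simulation_config()` + `simulate_latent_signals()` generate first-order
vector autoregressions whose cross-couplings switch with the experimental
condition: node $i$ follows
$x_i(t) = a_i x_i(t-1) + \sum_j c_{j\to i}(\mathrm{cond}(t))\, x_j(t-1) +
d_i(\mathrm{cond}(t)) + \epsilon_i(t)$. This is the simplest generator
whose true directed (Granger) structure is known exactly, which is the
whole point: downstream claims are scored against that truth. Every
condition's transition matrix is checked for stability (spectral radius
< 1) before simulation, and the seed fully determines all draws.

Latent signals are observed through a canonical double-gamma hemodynamic
kernel (peak 5 s, undershoot 15 s, truncated at 30 s, normalized to unit
sum so a sustained input converges to its own level), applied causally.
Coupling acts on the *latent* signals before convolution — neural-level
causality seen through hemodynamics — which is exactly why window-level
features can respond before amplitude features do. `render_volumes()`
paints ROI series onto disjoint spheres in a voxel grid (diagonal RAS+
affine, 2 mm isotropic by default) with i.i.d. observation noise, and the
NIfTI round trip through `build_sphere_mask()`/`extract_mean_series()` is
exact at zero noise.

Two generator knobs deserve emphasis:

* **amplitude vs coupling** — conditions may modulate an additive drive
  (`amplitude_schedule`), the coupling matrices, or both; real task data
  presumably modulates both, and the generator does not presume either.
* **variance matching** — coupling feeds extra variance into its target,
  so a "coupling-only" condition would still be detectable by amplitude
  variance. `variance_matched_noise()` solves a small linear (Lyapunov)
  system for per-node innovation variances that keep every node's marginal
  variance at its rest value — and, when given the sampled HRF kernel,
  matches the variance of the *convolved* signal, because hemodynamic
  filtering reweights the autocovariance and would otherwise re-leak an
  amplitude cue.

What the generator does **not** emulate: scanner drift, spikes and motion,
spatially correlated noise, subject variability, nonlinear hemodynamics,
or any geometry beyond disjoint spheres. Tests passing on this generator
show that the statistics and the pipeline behave as designed under known
ground truth; they do not certify performance on real scanner data.

## From features to decoding

`assemble_features()` turns the connectivity tensor (optionally plus
per-ROI activation values) into labeled rows, one per window, indexed at
the window's *start* volume — the moment the window's $F$ value describes.
A real-time loop can only act $k-1$ volumes later, when the window closes;
the streaming replay accounts for that latency explicitly. Two options
reflect standard decoding practice:

* `log_f` — the $F$ ratio is heavy-tailed; its log is variance-stabilized
  and what the classifiers consume in the packaged studies. Thresholded
  features remain available, but hard thresholding at the detection level
  discards class information, so detection (thresholded, for connectivity
  reporting) and decoding (raw log values) use different readouts of the
  same statistic.
* `label_lag` — labels may be taken from `label_lag` volumes before the
  window start (2 volumes ≈ 4 s at TR 2 s, the HRF rise), aligning each
  window with the neural state it actually expresses.

The classifier suite (`classifier_spec()`) covers Gaussian naive Bayes,
polynomial-kernel SVM (exponent 1, i.e. linear), RBF SVM (C = 19, gamma
set automatically from the feature variance), and two gradient-boosting
presets (depth 5 / rate 0.8 / 1000 rounds and depth 8 / rate 0.08 / 1000
rounds), both backed by xgboost. Evaluation (`kfold_evaluate()`) is
block-stratified: all samples of one task block share a fold, because
neighbouring windows overlap in data and row-level cross-validation would
leak. Reports carry the aggregated confusion matrix, accuracy, Cohen's
kappa ($\kappa = (p_o - p_e)/(1 - p_e)$) and per-fold metrics; per-TR
decoding-accuracy curves (`decoding_accuracy_curve()`) score each
within-block volume position separately — five points for a 10-s block at
TR 2 s.

## The packaged studies and their problem sizes

`R/studies.R` freezes the validation experiments as pure functions of a
seed; the test suite and `scripts/acceptance.R` both run them.

* **Direction recovery** — 50 replicates of a two-node VAR (one-way
  coupling 0.8, 600 volumes, HRF on, k = 4, p = 1): the mean window-level
  $F$ of the true direction must exceed the reverse in nearly all
  replicates.
* **Null calibration** — $\omega$ from 500 circular-shift surrogates at
  $\alpha = 0.05$, scored on 1000 fresh null windows drawn from many
  short independent series (window overlap within one long series would
  inflate the variance of the measured rate).
* **Oracle equivalence** — 10 four-node fan-in VARs (three independent
  sources driving one target at strengths 0.25/0.45/0.8, 1000 volumes):
  window-averaged log $F$ (in-sample mode) must rank the coupled pairs
  identically to `lmtest::grangertest` on the full series, with both
  methods placing every coupled pair above every null pair. The fan-in
  topology matters: in a cycle, indirect paths make "null" pairs genuinely
  causal and the property is ill-posed. Strengths are geometrically spaced
  because the property compares *realized* statistics; near-tied realized
  strengths make any two estimators disagree on ordering.
* **Coupling-modulation comparison** — 20 repeats; each simulates a
  session of 24 runs × 8 balanced blocks (10 s task / 20 s rest, TR 2 s,
  ~260 s per run), with condition-switched one-way coupling 0.7 on
  disjoint pairs and HRF-filtered-variance-matched noise, then compares
  binary left/right decoding of log-F features against activation
  features on identical block-stratified folds (paired one-sided t over
  repeats), plus averaged DA curves. Runs are balanced (even block count)
  because an odd count lets a frozen-baseline offset encode the run's
  majority class — a leakage channel that inflates the activation arm.
* **Chance floors** — three-class evaluation of label-shuffled noise
  features (600 samples, mean of 5 shuffles to tame Monte-Carlo noise in
  kappa).

These sizes were chosen so each study estimates its quantity with a
standard error comfortably inside the property band it must satisfy while
remaining a desk-scale computation; the whole acceptance script runs in
about a minute.

## Numerical choices and degenerate inputs

* Rank-deficient designs (a constant or zero source column) fall back to
  a tiny ridge penalty ($\lambda = 10^{-8}$); the zero-source case then
  reproduces the restricted model to numerical precision, preserving the
  nested-model identity $L_1 = L_2$.
* A constant target is fitted exactly by the intercept; $L_1 = 0$ and the
  ratio is 0 by the $\varepsilon$ floor convention.
* Noise-free perfect coupling drives $L_2$ below $\varepsilon$: the ratio
  is reported at the capped value and flagged `saturated`, never dropped.
* Voxel membership of a sphere is decided by voxel-centre distance
  (closed ball); ties on the boundary are included via a 1e-9 slack.
* The streaming path reuses the identical window engine on the trailing
  buffer, so stream and batch outputs are bit-identical, not merely close;
  the rest baseline freezes after the first completed rest period (a
  real-time session cannot peek ahead), and the batch path uses the same
  rule so the two stay comparable.
* Volume indexing is 1-based throughout the R API; `n_discard` (default
  10) and `n_transition` (default 4) are config-exposed.

## Known limitations

* Pairwise causality cannot distinguish direct influence from common
  drivers or chains; the oracle-equivalence study deliberately uses a
  topology where this distinction does not bite.
* With k = 4 and TR 2 s, a single window carries little information; the
  decoding advantage of connectivity features is a consistent few
  percentage points under coupling-only modulation, resolvable only with
  session-scale pooling — mirroring the modest advantage such features
  show in practice.
* The per-TR latency log of `stream_replay()` is informative only;
  wall-clock performance is hardware-dependent and not part of any
  property.
* The "resting ROI" of the activation feature is interpreted as the same
  ROI's rest-period mean (frozen after the first rest block in streaming
  mode); a dedicated reference region is not implemented.
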