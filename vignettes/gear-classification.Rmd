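---
title: "Classifying ski-skating gears from chest acceleration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ski-skating gears from chest acceleration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(skigears)
```

## The problem

In cross-country ski skating, athletes cycle through a small set of
sub-techniques — *gears* — as terrain and speed change: the asymmetric G2
(left- or right-pole dominant) on climbs, the symmetric G3 on rolling
terrain, and the asymmetric G4 (again left or right) at higher speeds.
Which gear is used where, and how often a skier switches, is valuable
training information that is tedious to extract from video.

A single triaxial accelerometer on the chest (x lateral, y vertical, z
horizontal, sampled nominally at 80 Hz) captures enough of the trunk's
periodic motion to recognize the gear automatically.  Two properties make
this harder than, say, telling walking from running: the gears differ in
movement *shape*, not amplitude or frequency — the same gear can be skied
fast or slow — and phone accelerometers deliver irregularly sampled,
noisy data.  The pipeline in this package is built around those two
constraints:

1. smooth the raw stream and divide it into movement cycles;
2. re-express every cycle as a fixed-length trajectory in acceleration
   space (100 steps × 3 axes = 300 values), independent of duration and
   sampling rate;
3. score each trajectory under five per-gear probabilistic models — a
   first-order Markov chain of multivariate Gaussians — and pick the
   maximum-likelihood gear.

## Smoothing irregularly sampled signals

All smoothing is time-domain Gaussian kernel regression
(Nadaraya–Watson): the estimate at query time $q$ is

$$\hat s(q) = \frac{\sum_i s_i\, e^{-(t_i-q)^2/2\sigma^2}}
                   {\sum_i e^{-(t_i-q)^2/2\sigma^2}},$$

with the weights computed from the actual timestamps.  Unlike an FIR
filter on a resampled grid, this is exact under irregular sampling, has
no ringing or phase distortion, reproduces constants exactly, and doubles
as the resampler: evaluating at arbitrary query times *is* the
interpolation.  The kernel is truncated at $\pm 4\sigma$ (it discards
under $10^{-4}$ of the weight mass) and evaluated blockwise so the inner
products go through BLAS.

Two bandwidths matter, and both are exposed in `preprocess_config()`:

* `sigma_segment` = **0.370 s** — wide enough that only the per-cycle
  fundamental of the vertical axis survives; this very-low-frequency
  signal defines cycle boundaries.
* `sigma_feature` = **0.090 s** (at the reference cycle duration; see
  below) — removes sensor noise while keeping the within-cycle features
  the classifier feeds on.

## Cycle segmentation

Cycle boundaries are local minima of the smoothed segmentation channel
(vertical acceleration by default; the magnitude
$\sqrt{a_x^2+a_y^2+a_z^2}$ is available for unusual mounting).  Minima
are parameter-free under the gravity offset, unlike zero crossings, which
need a reference level.  Two gates reject spurious minima: a topographic
prominence threshold (`min_prominence_frac`, default 0.1 of the smoothed
signal's interquartile range, with an absolute floor of $10^{-6}$ m/s²
so that numerically flat signals yield no cycles) and a minimum
separation of `min_cycle_duration` (default 0.5 s; of two closer minima
the deeper one is kept).  Consecutive minima 0.5–3.0 s apart delimit one
cycle; leading and trailing partial cycles are discarded, since only
whole cycles are classified.  Boundary times are refined by parabolic
interpolation through the three samples around each discrete minimum.

A wide kernel near the edge of a recording flattens boundary minima away:
with $\sigma = 0.37$ s the kernel wants $\pm 1.5$ s of context.  Plain
renormalization (truncated kernels) biases the estimate near the edges
badly enough to lose a boundary that sits within about $2\sigma$ of the
stream end.  `segment_cycles()` therefore works in two passes: the first
pass pads the signal beyond both ends by odd (point) reflection through
the endpoints — which continues the local trend instead of flattening
it — and detects minima; the second pass takes the median spacing of
those minima as the period estimate, re-pads the signal *periodically*
(copying whole periods of real data outward), and re-detects.  For a
periodic signal, periodic padding is exact whatever phase the recording
starts or ends on; on a pure 1.2-s sinusoid the detected boundaries land
within a millisecond of the analytic minima, including a minimum only
0.3 s from the stream end.

## Duration- and rate-free cycle representation

`normalize_cycle()` evaluates the kernel smoother at `n_steps = 100`
times spaced uniformly over the cycle, for all three axes — smoothing and
resampling in one pass — giving a 300-dimensional trajectory.

One design point deserves emphasis.  A smoothing constant fixed in
*time* attenuates the $k$-th harmonic of a $T$-second cycle by
$\exp(-2\pi^2\sigma^2k^2/T^2)$: the same movement executed at 0.9 s and
at 1.5 s per cycle would produce visibly different normalized
trajectories (differences of ~0.3 m/s² at realistic amplitudes),
defeating the purpose of time normalization.  The per-cycle feature
smoother therefore fixes its bandwidth in cycle *phase*:
$\sigma_\text{eff} = \texttt{sigma\_feature} \times T /
\texttt{cycle\_duration\_ref}$, with `cycle_duration_ref` = 1.4 s, the
nominal skating cycle duration.  At the reference duration the bandwidth
is exactly 90 ms, and over the observed range of cycle durations it stays
within roughly ±20% of that; in exchange the normalized representation
is invariant (to within 0.05 m/s² pointwise in the package's tests) to
both the sampling rate (80 Hz vs 50 Hz) and the execution speed of the
cycle.

## The per-gear model

Each gear $g$ gets a generative model of the normalized trajectory
$v_1,\dots,v_{100}$ ($v_t \in \mathbb R^3$):

$$v_1 \sim \mathcal N(\mu_1, S_1), \qquad
  v_t \mid v_{t-1} \sim \mathcal N(A_t v_{t-1} + b_t,\; Q_t),$$

a first-order linear-Gaussian Markov chain.  The rationale is a
parameter-count argument: a nearest-neighbour classifier ignores the
correlation structure along the trajectory entirely, while a single
Gaussian over all 300 dimensions with a full covariance has ~45k free
parameters — far too many for the ~50 cycles per gear a calibration trial
provides.  The chain keeps the sequential correlations that identify a
movement shape at about 2.1k parameters per gear, and it operates on the
continuous accelerations directly rather than discretizing them.  A
first-order chain with linear-Gaussian conditionals is the minimal model
of this family; higher orders or nonlinear conditionals would multiply
parameters without an evident gain at these data sizes.

Fitting is step-wise least squares: $\mu_1, S_1$ are the first-step
sample mean and covariance (MLE), each $(A_t, b_t)$ the least-squares map
from step $t-1$ to step $t$ across cycles, $Q_t$ the residual covariance.
The least-squares solve uses the pseudoinverse, so degenerate inputs
(e.g. identical cycles) are fitted exactly rather than erroring.  All
covariances get $\lambda I$ added; by default
$\lambda = 10^{-3}\times$ (mean per-axis variance of the training
values), floored at $10^{-8}$ — with ~50 cycles a raw 3×3 residual
covariance is occasionally near-singular, and the ridge guarantees
positive definiteness without measurably moving well-conditioned
estimates.

Classification evaluates the chain log-likelihood (computed with
Cholesky factorizations, entirely in the log domain) under all five
models and takes the argmax; exact ties resolve to the earlier gear in
the canonical order G2L, G2R, G3, G4L, G4R.  Class priors are equal, and
cycles are classified independently — no label smoothing over time — so
each prediction can be compared directly against the per-cycle video
gold standard, and errors localize to where they occur (startup,
transitions).  The chain is validated in the test suite against an
independent oracle that assembles the full joint Gaussian implied by the
chain and evaluates its density directly (agreement to $10^{-8}$), and
by parameter recovery from data simulated off a known chain.

Two training regimes exist, mirroring field practice: `collective`
(pooled data from several skiers/sessions) and `individual` (one skier's
own calibration trial).  The package treats them identically up to the
tag stored in the model file; the command-line `train` subcommand tags
one input trial as individual and several as collective.

## The synthetic reference conditions

No raw recordings ship with the package, so it carries a first-class
generator that emulates a treadmill validation protocol and serves as
the reference condition for all end-to-end claims:

* **Templates** (`make_gear_template()`): per-gear periodic 3-axis
  Fourier series (order ≤ 4) in cycle phase, hand-designed to reproduce
  the qualitative per-gear shapes (the lateral "half-moon" coupling of
  G2, the near-symmetric "butterfly" of G3) rather than fitted to any
  figure.  G2R/G4R are exact lateral mirrors of G2L/G4L; G3's lateral
  axis is half-cycle antisymmetric; templates are pairwise ≥ 1 m/s² RMS
  apart, so the classes are separable by construction.  Every gear keeps
  a strong vertical fundamental whose minimum sits at phase 0.5 of the
  constructed cycle, so segmentation lands on a consistent phase and a
  recording begins mid-movement, as real recordings do.
* **Trials**: `simulate_trial()` concatenates ~50 cycles of one gear
  (durations $\mathcal N(1.4, 0.1^2)$ s, per-cycle amplitude scale
  $\mathcal N(1, 0.05^2)$), samples at 80 Hz with 1 ms timestamp jitter
  and adds white noise of 0.3 m/s² per axis.
  `simulate_variable_protocol()` draws a block sequence calibrated to the
  reference variable trial: ≈140 cycles split ≈30/27/30/26/26 across the
  five gears with ≈23 gear transitions.  Transitions are instantaneous
  at cycle boundaries; because segmentation cuts at the vertical minima
  (phase 0.5), the cycle straddling a gear change is a genuine hybrid —
  which is exactly where the classifier should and does make its errors.
* Every stochastic draw flows from the single mandatory `seed`, so all
  fixtures are bit-reproducible.

What the generator does **not** emulate: inter-subject variability of
movement shape (only amplitude/duration vary), gradual gear morphing
across a transition, drift of sensor orientation, and non-white sensor
noise.  Perfect scores under these conditions therefore demonstrate the
pipeline's correctness and its rate/duration invariances — not
field-ready accuracy on arbitrary skiers.

## Evaluation layer

`evaluate_predictions()` aligns reference label intervals to detected
cycles by maximum temporal overlap (ties to the earlier interval; cycles
with no overlap are excluded as unlabeled), builds the 5×5 confusion
matrix in counts and row percentages, and reports overall and per-gear
accuracy (diagonal over row sum).  `error_breakdown()` classifies each
misclassified cycle as *startup* (among the first `k` cycles, default 3),
*transition* (within `w` cycles of a reference gear change, default 1;
precedence startup > transition) or *other*; the windows are
configurable because neither window has a canonical definition.  `paired_t_test()` (differences `a - b`,
delegating to `stats::t.test`, with the zero-variance cases resolved
explicitly) and `pearson_r()` cover the accompanying statistics.

## Numerical choices, in one place

* Kernel truncation ±4σ; blockwise evaluation (256 queries/block).
* Prominence gate: `0.1 × IQR`, absolute floor 1e-6 m/s².
* Minima refined by parabolic interpolation; merged under 0.5 s spacing.
* Ridge: `1e-3 ×` mean per-axis training variance, floor 1e-8.
* Likelihoods via 3×3 Cholesky factorizations; no exponentiation.
* Ties in the likelihood argmax and in label overlap go to the earlier
  canonical gear / earlier interval.
* Degenerate inputs: empty streams segment to zero cycles; constant
  streams yield no minima; a cycle count below 2 refuses to fit;
  non-positive-definite stored covariances raise a model-integrity error.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data
at the reference protocol's scale: training uses 50 cycles per gear (one fixed-gear
trial each), held-out evaluation five single-gear trials of 50 cycles,
and the variable-protocol checks average 20 independent ~140-cycle
sessions.  The transition-concentration check raises the noise to
1.0 m/s² — about three times the default sensor noise — as a realistic
worst case; the noise-monotonicity curve spans 0.3–6 m/s².  Chain-vs-
joint-Gaussian equivalence is checked at 2–4 steps, where the explicit
9–12-dimensional joint covariance is cheap to build.

## Known limitations

* The Markov-chain parameterization is the minimal reading of
  "chain of multivariate Gaussians"; richer variants (tied or structured
  covariances, higher order) may differ from other implementations of
  the same idea.
* Gear *transitions* are not modelled — a hybrid cycle is forced into
  one of five classes, and the evaluation layer only localizes the
  resulting errors.  Modelling transition cycles explicitly is the
  obvious next step.
* The pipeline assumes a chest-mounted sensor in the stated orientation;
  there is no gravity removal or orientation stabilization, which is
  adequate for classification but not for, e.g., integrating
  displacement.
* Accuracy figures on synthetic sessions bound what the code does under
  its own assumptions, not performance on snow.
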