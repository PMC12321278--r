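---
title: "Reconvolution fitting of picosecond TCSPC decays: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconvolution fitting of picosecond TCSPC decays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimrecon)
```

## The problem

Time-correlated single-photon counting (TCSPC) histograms photon
arrival delays relative to the excitation pulse.  When fluorescence
lifetimes are tens of picoseconds — as in melanin-containing pigment
organelles — they are comparable to, or shorter than, the width of the
instrument response function (IRF), and the recorded curve is
dominated by the instrument.  The decay parameters must then be
estimated by *reconvolution*: convolve a model decay with the measured
IRF and match the measurement, rather than attempting to deconvolve
the data.

The acquisition geometry this package is built around is a 2 ns
window sampled at ≈0.5 ps channels (4000 channels), a Gaussian-like
IRF of ≈20 ps FWHM, and per-recording photon budgets around 10⁶.
During prolonged laser exposure such samples photodegrade slowly, so a
session is a series of per-minute frames whose fitted parameters trace
the degradation.

## Model and estimator

The measured signal is modeled as

$$S(t_k) = \Delta \sum_{j \le k} R_{\Delta t}(t_j)\, F(t_k - t_j),
\qquad F(t) = b + \sum_{i=1}^{n} A_i e^{-t/\tau_i},$$

with $\Delta$ the channel width, $R_{\Delta t}$ the unit-sum IRF
resampled at a non-integer alignment shift $\Delta t$ (natural cubic
spline), and $n \le 3$ exponential components sorted by ascending
lifetime ($\tau_1$ fast, $\tau_2$ slow).  Because the IRF is
normalized before convolution, the amplitudes carry the counts scale.
The convolution is aperiodic with left zero-padding: at a 100 MHz
repetition rate the 10 ns excitation period dwarfs both the 2 ns
window and the sub-0.1 ns lifetimes, so wrap-around terms are below
$e^{-20}$ and a periodic ("incomplete decay") mode is deliberately out
of scope.

Fitting uses **variable projection**.  The nonlinear parameters
$(\tau_1,\dots,\tau_n,\Delta t)$ are searched globally by Differential
Evolution; at every trial point the amplitudes are solved exactly by
non-negative least squares (NNLS), so the stochastic search runs in
only $n+1$ dimensions and amplitudes are never exposed to it.  The
objective is the weighted sum of squared residuals
$\sum_k w_k (S_{\mathrm{obs}}(t_k) - S(t_k))^2$ with Poisson weights
$w_k = 1/\max(o_k^{\mathrm{raw}}, 1)$ (see below).

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `n_components` | 2 | — | a fast and a slow process; 3 available for model comparison, more invites overfitting |
| `tau_bounds` | (0.001, 1) | ns | spans the short (<0.1 ns) and long regimes with margin inside a 2 ns window |
| `shift_bounds` | (−0.05, 0.05) | ns | alignment residuals are at most a few IRF widths |
| `de_population` | 30 | — | comfortable for a ≤4-dimensional search |
| `de_max_iter` | 300 | generations | convergence is typically reached in 40–90 |
| `de_tol` | 1e-8 | relative | population objective spread; tight so "converged" means collapsed |
| `smooth_window`, `smooth_order` | 11, 3 | channels, — | 11 channels = 5.5 ps ≪ 20 ps IRF width, so the filter cannot erode the IRF peak; order 3 preserves peak curvature |
| `weighting` | poisson | — | raw-count Neyman weights with unit floor |
| `oversample` | 1 | — | refined quadrature for lifetimes below a few channel widths |

## Numerical choices

**Convolution quadrature.**  The discrete causal convolution of an
exponential with the IRF is evaluated by the exact recursion
$C_{k+1} = e^{-\Delta/\tau} C_k + \Delta R_{k+1}$ (an O(N) linear
filter), which is algebraically identical to the left-endpoint
convolution sum.  This default keeps the delta-IRF identity exact: a
unit spike IRF reproduces the bare decay shifted and scaled by the
channel width.  Left-endpoint quadrature carries a first-order
$O(\Delta/\tau)$ bias concentrated on the rising edge; with 0.5 ps
channels and lifetimes ≥ 10 ps this is irrelevant for fitting (the
same quadrature generates and fits the data, and against the analytic
exponentially-modified-Gaussian solution the fitted region agrees
closely), but `oversample ≥ 2` switches to a second-order scheme — the
IRF is spline-refined and treated as piecewise linear, and the
exponential is integrated *analytically* over each sub-channel — which
agrees with the closed-form exponentially modified Gaussian to well
under 0.5 % everywhere above 1 % of peak.

**Optimizer.**  Differential Evolution uses rand-to-best/1/bin
mutation with the factor dithered in [0.5, 1) per generation,
crossover 0.9, and uniform resampling of out-of-bounds components.
Two choices matter more than the strategy label.  First, lifetimes
are searched in **log scale**: the box (0.001, 1) ns spans three
decades, and a linearly initialized population almost never samples
the fast decade, which makes a greedy strategy collapse into
single-component local optima.  Second, out-of-bounds trials are
resampled rather than clipped, so the population cannot pile up on a
bound.  A bounded quasi-Newton polish (L-BFGS-B on the same
variable-projection objective) refines the DE optimum; it is
deterministic and can be disabled.  Given `seed`, the whole fit is
bit-reproducible.

**NNLS.**  With at most three components (plus baseline) the
constrained least-squares problem is solved exactly by enumerating
active subsets of the normal equations and taking the minimum-SSE
feasible candidate — the global optimum of this tiny convex QP, with
no iteration or tolerance.  Two lifetimes closer than 10⁻⁶ ns make
the basis numerically rank-deficient and are rejected (inside the DE
objective they receive a penalty value instead, so the search simply
moves away).

**Reduced χ².**  The package reports
$\chi^2_\nu = \frac{1}{N - (2n+1)} \sum_k
\frac{(o_k - f_k)^2}{\max(o_k^{\mathrm{raw}}, 1)}$
with $o^{\mathrm{raw}}$ the pre-smoothing counts (kept in the
histogram metadata by `savgol_smooth()`).  Two properties of this
convention deserve emphasis:

* *Smoothing pushes χ²ᵥ well below 1.*  Savitzky–Golay filtering
  shrinks the noise in the fitted data while the weights still
  reflect raw-count variance, so a correct model fitted to smoothed
  data shows χ²ᵥ ≪ 1.  This is a signature, not a defect.
* *Mostly-empty windows also push χ²ᵥ below 1.*  With sub-0.1 ns
  decays in a 2 ns window most channels hold (near) zero counts and
  contribute ≈ 0 rather than ≈ 1 to the sum.  The statistic therefore
  calibrates to 1.0 only when the decay populates the whole window;
  the package's calibration test uses such a geometry (a 0.45 ns
  decay, IRF near the window start, all channels well populated).

**Uncertainty.**  `estimate_uncertainty()` / `confint()` use a
parametric bootstrap: the fitted curve is resampled with per-channel
Poisson noise and refitted, and 16th–84th percentile intervals are
reported.  A known limitation of the percentile interval: in
sparse-count geometries the Neyman-weighted estimator carries a small
negative bias that replicates in every bootstrap refit, shifting the
interval off-center and degrading coverage.  Where channels are well
populated the interval is calibrated (the test suite checks ≈68 %
coverage there).  Interval widths scale as expected with the photon
budget in all regimes.

**Estimator conditioning across the lifetime range.**  Recovery is
hardest at the two ends of the range: below the IRF width (a 10 ps
component under a 20 ps IRF is intrinsically less determined than a
50 ps one) and as the decay tail approaches the window (scatter of
the recovered lifetime grows once the window no longer contains the
tail comfortably).  Between those regimes, relative errors at 10⁶
photons are at the few-percent level, well inside the ±10 %
single-measurement band the acceptance suite checks.

**FWHM.**  The temporal full width at half maximum interpolates
linearly between the channels bracketing each half-maximum crossing;
with noisy data showing multiple crossings, the outermost crossing on
each side of the global peak is used, which is robust to small
ripples.  Truncated peaks (half maximum not crossed on one side) are
an error naming the side.  The per-minute "width" metric is
interpreted as this temporal decay-curve width — the natural reading
for single-point (non-spectral) TCSPC recordings.

**Robust trend.**  The τ₂-versus-τ₁ relationship across a series is
fitted as a second-order polynomial under Huber loss by iteratively
reweighted least squares (relative tolerance 10⁻¹⁰).  Unless fixed,
the Huber threshold is re-estimated each iteration as 1.345 × the MAD
residual scale — the standard 95 %-efficiency convention — and an
infinite threshold reproduces ordinary least squares exactly.  The
fit stores the final threshold and the inlier fraction.

## The synthetic generator

`simulate_series()` emulates the statistical structure the analysis
assumes: a Gaussian IRF of configurable FWHM (20 ps default) on the
canonical grid; expected signal formed by the same forward model;
independent per-channel Poisson counts scaled to a photon budget; and
slow per-frame drifts — both lifetimes growing steadily (linear by
default), the A₁/A₂ ratio dropping exponentially over the first ten
frames and then holding constant, and a photon budget that rises to a
peak (frame 10 by default) and then declines.  Every series carries a
ground-truth sidecar (`truth.json` on disk) recording the per-frame
parameters, budgets and seeds, so recovery tests are self-describing.
One IRF is shared per series, matching a once-per-session IRF
measurement.

What it does **not** emulate: detector afterpulsing, dead-time and
pile-up (second order at ≤0.1 photons per excitation pulse),
background/dark counts, Brownian displacement of the specimen,
wavelength resolution, and cavitation events.  Passing recovery tests
on this generator therefore demonstrates the estimator's correctness
under Poisson shot noise and slow parameter drift — not robustness to
every instrumental artifact of real recordings.

Default ground truth is τ = (10, 50) ps at amplitude ratio 3:1 —
representative of the fast/slow decomposition in the sub-0.1 ns
regime — with drifts chosen to keep lifetimes inside (0, window/2)
over 60 frames (τ₁: +1.4×10⁻⁴ ns/frame, τ₂: +6×10⁻⁴ ns/frame; ratio
3 → 1.5 with a 3-frame time constant).

## Problem sizes and degenerate inputs

Unit and property tests run on a reduced geometry (2 ns window at 2–8
ps channels, 10⁴–5×10⁵ photons, DE population 12) chosen so the full
suite completes in minutes while preserving the physics; the
acceptance tests and `scripts/acceptance.R` use the full reference
geometry (4000 channels, 10⁶ photons, default configuration, 20
replicates).  Degenerate inputs fail loudly and early: empty or
all-zero histograms, non-uniform or mismatched grids, negative
counts, truncated IRFs, lifetime drifts leaving the physical range,
more than 50 % failed frames in a series, and bootstrap refit failure
rates above 20 % are all typed errors, not silent repairs.  The only
silent adjustments are clamping of negative post-filter counts (with
a metadata flag) and of cubic-interpolation undershoot in shifted
IRFs, both reflecting physical non-negativity.

## Known limitations

* Single-point decay curves only: no per-pixel (imaging) FLIM, no
  vendor binary formats, no photon-arrival (time-tag) mode.
* No periodic reconvolution; sessions with repetition periods
  comparable to the window need a different forward model.
* Maximum-likelihood (Poisson deviance) fitting is not offered; the
  weighted-least-squares estimator is slightly biased at very low
  counts, which also limits percentile-bootstrap coverage there.
* Frames are fitted independently; no global (shared-lifetime) fit
  across a series.
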