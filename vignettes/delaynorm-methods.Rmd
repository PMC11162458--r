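---
title: "Methods: two-component models and temporal additivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-component models and temporal additivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaynorm)
```

## The signal model

A widefield imaging trial is modelled as the sum of a fast stimulus-evoked
component and a slow stimulus-independent trend. The package offers two
forms for the evoked part:

* **linear**: `s(t) * f(t)` — a filter convolved with the binary-in-time
  stimulus vector;
* **delayed normalization (DN)**:
  `[s(t) * f_l(t)] / (σ + s(t) * f_n(t))` — the same linear drive,
  divisively normalized by a *delayed* drive through a second filter plus a
  semisaturation constant `σ`.

The slow trend `g(t)` is in both cases a per-condition weighted sum of slow
basis functions added directly (never convolved with the stimulus). Both
models are fit to the *whole* trial jointly, rather than detrending first,
to avoid biasing the evoked estimate.

Assumptions worth making explicit: responses are spatially pooled scalars
(no pixel structure); onset latency has already been removed (the
preprocessing shift), so stimulus and response are aligned at `t = 0`;
trials within a condition are exchangeable repeats; and the trend is at
least an order of magnitude slower than the evoked dynamics, which is what
makes the additive decomposition identifiable.

## Bases and filters

The fast basis is a family of raised cosines on log-warped time,
`phi(t) = log(t + t0)` with `t0` equal to one sample. Peak centers are
equally spaced in warped time; each function is
`(1 + cos(pi * clip((phi - c_i)/(2*delta), -1, 1)))/2`, rescaled to unit
sampled maximum, with the last function's support ending exactly at the
coverage (0.26 s on the 100 Hz VSDI-style grid, 0.32 s on the 20 Hz
GCaMP-style grid). The warp makes early functions narrow and late ones
wide, matching dynamics that are fastest just after onset. The exact warp
and overlap constants are not fixed by prior art, so the package commits to
the standard `log(t + dt)` warp and half-height overlap and documents them
here; the basis is checked to have full column rank so least squares is
well posed.

The slow basis uses the mirror construction on reversed time, spanning the
full trial: wide, slow functions early and narrow, fast ones late. Trials
are re-zeroed at onset, so variance accumulates toward the trial end where
the denser functions sit.

Basis counts default to `n_fast = 8`, `n_slow = 10`. These are deliberate,
modest defaults — enough to represent Gamma-like filters with a negative
lobe and smooth trends without inviting fast/slow trade-offs — and
`select_basis_counts()` provides the cross-validated sweep for users who
want to re-derive them from their own data.

The DN denominator filter is a difference of two Gamma kernels, each
normalized to unit peak *before* weighting so the two weights read directly
as lobe amplitudes. With `weight2 = 0` the filter is monophasic (low-pass);
with a delayed second lobe it is biphasic (band-pass). Shapes must exceed 1
so the kernels peak away from `t = 0`.

## Fitting

**Linear model.** One stacked least-squares solve (shared filter weights
across conditions, per-condition slow weights), or independent per-condition
solves for the linearity diagnostic. Rank-deficient designs — possible when
a 20 ms pulse barely constrains the late basis functions — are solved by
the minimum-norm SVD pseudoinverse and flagged, not silently regularized; an
optional ridge exists for the deconvolution diagnostic only.

**DN model.** Parameters split into two batches, alternated to
convergence: (A) numerator weights, denominator Gamma parameters and `σ`,
fit by Levenberg–Marquardt on log-transformed positive parameters with
per-condition slow weights frozen; (B) slow weights, closed form. The loss
is guarded to be non-increasing (a batch-A step is rejected if it would
increase it). Convergence: relative loss change below `1e-6`, at most 200
outer iterations; `σ` is floored at `1e-6` response units. Initialization
takes the numerator from the shared linear fit and a denominator prior with
a ~70 ms positive lobe and ~150 ms negative lobe; 5 seeded restarts jitter
the nonlinear parameters (SD 0.6 in log space) because the
monophasic/biphasic decision surface has a genuine local minimum in which
the second lobe vanishes. Denominator positivity is enforced by a soft
quadratic penalty during the search and rejected outright at prediction
time — clipping would silently change the model class.

The divisive form is scale-degenerate: scaling numerator, `σ` and
denominator weights jointly leaves every prediction unchanged. Raw
parameters are therefore reported together with the scale-invariant
normalization strength (peak denominator drive over `σ` for the longest
condition), and recovery tests compare *components*, not raw parameters.

**Alternative trend models.** Two simpler extractions — evoked Gamma filter
plus linear trend, or plus exponential trend with offset — are fit per
condition by simplex search over the nonlinear parameters (filter time
constant; trend decay rate) with the linearly entering parameters profiled
out in closed form. A shared-filter variant profiles one time constant
across conditions.

**Cross-validation.** Leave-one-condition-out: fit on 11 conditions,
predict the held-out evoked component, refit only slow weights on the
held-out residual (trends are condition-specific by design), and score
variance explained on the full curve. A fast-only scoring variant agrees
closely and is provided.

## The additivity metric

Each condition's evoked component is integrated (dt-weighted sum; full
trial by default, or an epoch such as the 1200 ms window starting 200 ms
before onset used for ECoG-style predictions) and the scaled power function
`a·x^c` is fit to the sums against total stimulus-on time, by Gauss–Newton
refinement from the closed-form log–log slope. ISI conditions enter as
repeated points at `x = 0.32` s; the additive reference line is anchored at
the 160 ms single pulse (any anchor gives the same line up to its own
residual; 160 ms sits mid-range of the design).

Two deliberate choices:

* **Sums use the model's evoked component**, not data minus the estimated
  trend. The two agree in expectation, but the data-driven sum is noisier
  and can go negative for the 20 ms condition (where the true sum is
  smallest), which leaves the log-domain power fit undefined. The model
  component keeps the linear-system identity (`c = 1` exactly, duration
  doubling doubles sums, ISI irrelevant) exact to numerical precision.
* **Full-tail convolution for theory checks.** Within-trial truncation
  loses a sliver of response mass for late-onset conditions; exact
  additivity identities hold only when the untruncated tail is summed, so
  `predict_*` and `summed_response` expose both conventions.

## The synthetic generator

`simulate_trials()` emulates what the analysis must survive, per trial:

* the noiseless evoked component from a known linear or DN ground truth;
* a random slow trend — low-frequency cosine series on harmonics 1–4 of
  the trial window (≲3.3 Hz on the VSDI-style grid), drawn independently
  per trial, scaled to a fixed RMS. Harmonics are kept at exact DFT bins so
  the trend's power above 4 Hz is numerically zero, enforcing the
  order-of-magnitude timescale separation; the slow *basis* itself is not
  used, because its narrow late functions would leak power into the evoked
  band;
* a deterministic artifact shared by every trial including blanks — a
  2.5 Hz heartbeat-locked oscillation plus a linear bleaching drift — which
  blank subtraction removes exactly in the noiseless limit;
* i.i.d. Gaussian sample noise.

Defaults are the study conditions: 8 repeats per condition with two ISI
conditions at 7, 16 blank trials, evoked peak normalized to 1 response
unit, noise SD 0.1 (10% of peak), slow-trend RMS 0.1, artifact amplitude
0.2. The noise magnitudes are not taken from any recording — they are
chosen once to be challenging but identifiable, and are labelled synthetic
throughout. What passing tests on this generator shows is that the
*pipeline* is correct and well conditioned; it does not certify behavior on
real data, whose trends need not be band-limited cosines and whose noise is
not white.

The canonical DN ground truth (`default_dn_truth()`) is pinned by the
filter geometry the analysis is designed to detect: numerator peak at
50 ms with a small late negative lobe, biphasic denominator peaking at
70 ms with its negative lobe near 150 ms, and normalization strong enough
to produce duration-dependent gain and contrast saturation while the
biphasic regime stays near-additive (`c ≈ 0.98`; its monophasic
counterpart drops to `c ≈ 0.75`).

## Numerical choices and degenerate inputs

* Stimulus durations that do not divide the sampling step are an error by
  default; the GCaMP-style grid renders them on a 10× finer grid and
  box-averages (conserving contrast-weighted on-time) when asked.
* `time_to_peak` breaks ties toward the earliest sample; it rejects filters
  with no positive value, and `biphasic_index` rejects the zero filter.
* The power-law fit rejects nonpositive sums by name rather than silently
  dropping them.
* Onset placement within the trial is configurable (`onset_index`),
  defaulting to 0 after latency alignment, since the analysis removes the
  conduction delay by shifting rather than modelling it.
* All randomness flows through explicit integer seeds (default 0);
  generator output is bit-reproducible.

## Problem sizes

The test-suite and example fits use the canonical sizes throughout: 121
samples × 12 conditions × ~8 repeats for VSDI-style data, 8 + 10 basis
functions, 5 restarts for the headline DN fit, 2 restarts inside
cross-validation, 50 bootstrap draws. A full DN fit takes a few seconds on
one core; leave-one-condition-out with the DN model, under a minute.

## Known limitations

* The alternative (linear/exponential) trend extractions are noticeably
  noisier than the two-component extraction, and their bias concentrates on
  the briefest condition, whose sum is smallest and hence carries the most
  leverage in the log-domain power fit. On synthetic data at the default
  noise level the exponential-trend exponent can differ from the
  two-component estimate by more than 0.1 for particular noise
  realizations, even at the extraction's global optimum — the robustness
  conclusion holds in regime (near-additive vs strongly sub-additive), not
  to arbitrary precision.
* DN parameters are reported raw despite the scale degeneracy; compare
  components or the invariant normalization strength, never raw weights,
  across fits.
* The GCaMP preset inherits the VSDI analysis wholesale; only grid, basis
  coverage and fractional rendering differ. Indicator dynamics
  (calcium-binding kinetics) are not modelled beyond the slower filters a
  fit would discover.
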