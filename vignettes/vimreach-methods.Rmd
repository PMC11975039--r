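---
title: "Methods: peri-reach modulation, tuning and encoding analysis in vimreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-reach modulation, tuning and encoding analysis in vimreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis problem

`vimreach` analyzes single- and multi-unit spiking from the
cerebellar-receiving motor thalamus (VIM) recorded during a naturalistic 3D
center-out-and-back reaching task: a central target and 8 outer targets
evenly spaced on a 178 mm circle, each displayed for 3 s with a 0.7 s
directional cue, presented in a load-balanced pseudorandom order for at
least 24 out-and-back sequences (48 reaches). Fingertip position is tracked
at 120 frames/s; spike times come from manually sorted units.

Three questions drive the pipeline: *when* around a reach a unit's firing
rate changes (peri-reach modulation), *whether* it distinguishes reach
directions (directional tuning), and *what* continuous signals it encodes
(lagged regression on kinematic and positional-error features with Shapley
attribution of R²). A synthetic-session generator with full ground truth
makes every stage testable without recorded data.

## Kinematic preprocessing

Dropped frames are linearly interpolated between the nearest valid
neighbors; leading/trailing invalid runs are never extrapolated (those
samples stay masked, as do samples within one kernel half-width of them).
Each coordinate is convolved with a normalized Gaussian kernel truncated at
±4 s.d. and renormalized at the series edges so constants are preserved
everywhere. Two kernel widths are used: **50 ms** s.d. for peri-reach
analyses (favoring stable rate estimates) and **15 ms** for regressions
(favoring temporal resolution). Velocity is obtained by central differences
on the native 120 frames/s grid, acceleration by the same operator applied
to velocity.

*Signed acceleration* is defined as ‖**a**‖·sign(**v**·**a**). The sign of a
"cross product" of two 3-vectors has no scalar meaning; the dot-product sign
is the unique scalar that separates speeding-up from braking, since
sign(**v**·**a**) = sign(d‖**v**‖/dt) wherever **v** ≠ 0.

## Reach event detection

For each go event (outer-target onset for outward reaches, its offset for
inward returns) the peak fingertip speed is located in a window from 0.5 s
before to 2.5 s after the display change, on speed that has been zero-phase
low-pass filtered at 3 Hz (4th-order Butterworth applied forward and
backward) so the 4–12 Hz tremor of this population cannot capture the peak.
The *dominant reach direction* is the mean filtered velocity in a ±0.25 s
window around the peak; the *reach-aligned velocity* is the velocity from
2 s before to 2 s after the peak projected onto that direction.

Reach Start is the last time before the peak at which the reach-aligned
velocity became positive or displayed a local minimum below 5% of its peak;
Reach End is the first such event (negative crossing or sub-5% minimum)
after the peak. Two implementation choices matter here:

- **The boundary rules run on the unfiltered projection.** A zero-phase
  low-pass filter spreads movement energy 15–45 ms across the true onset,
  biasing every crossing early by several samples. The filter is therefore
  used only where it is needed (peak picking and direction finding), while
  the crossing/minimum rules — whose robustness to residual tremor is
  provided by the 5%-minimum fallback — see the raw projected velocity.
  Verified on ground truth: boundaries within one sample (8.3 ms) on
  noiseless minimum-jerk reaches and within two samples under 2 mm, 5 Hz
  hold tremor, across 20 independent sessions.
- **Crossings are detected against a small velocity-resolution guard**
  (10⁻⁴ of the peak reach-aligned velocity, ≈ 0.04 mm/s for a typical
  reach) rather than exactly zero. An exact-zero crossing is ill-conditioned
  while the hand is at rest: residual tremor almost orthogonal to the reach
  direction leaves the projection wandering at physically meaningless
  amplitudes (< 0.1 mm/s, far below what a 120 frames/s tracker resolves)
  and can hold the crossing off for tens of milliseconds.

With realistic tracking noise (≈ 0.3 mm per frame) the raw-projection rules
jitter: median boundary errors grow to roughly 60 ms, with reach durations
biased short accordingly, because noise excursions cross zero while the true
velocity is still below the noise floor. This is an intrinsic property of
threshold-free onset rules at this signal-to-noise; downstream analyses pad
their windows (±250 ms for regressions, ±400 ms analysis window for
modulation) and are insensitive to it. Detection is most accurate on
minimally smoothed features (`kernel_detection_ms = 0`, the pipeline
default); heavier smoothing trades accuracy for fewer invalid trials on very
noisy recordings.

Curation discards durations above Q3 + 1.5·IQR (quartiles by linear
interpolation between order statistics, R type 7 — the convention matters
for which reaches are excluded and is therefore fixed and documented) and
flags sessions with fewer than 25 valid reaches. The rule is applied per
session here; pooling detected reaches across a procedure's sessions before
curation reproduces the per-hemisphere variant.

## Firing rates

The *fractional-interval* rate assigns, within each inter-spike interval of
length L, the instantaneous rate 1/L; each 1 ms bin carries the time-average
of that rate over the bin. Equivalently the rate is the derivative of the
piecewise-linear cumulative spike-count function, so bins straddling a spike
automatically carry the duration-weighted mixture of the adjacent intervals'
rates, and each interval contributes exactly 1 to the integral (the
conservation invariant the tests assert). Bins before the first / after the
last spike extend the edge intervals' rates; coincident spike times are
collapsed. Trains with fewer than two spikes yield a flagged zero rate.

Rates are smoothed with the same truncated-Gaussian kernels as the
kinematics (50 / 15 ms). For regressions they are additionally z-scored in a
sliding, centered 45 s window (truncated at the session edges, per-bin
steps) to cancel slow drifts in excitability or spike amplitude; an s.d.
floor of 10⁻⁶ spikes/s guards against zero-variance windows, which yield
flagged zeros. Z-scoring is applied after smoothing (order exposed in the
configuration). Rate functions are evaluated at arbitrary times by linear
interpolation between bin centers, with snap-to-grid so evaluation at bin
centers is exact.

## Peri-reach modulation

Each reach contributes 380 grid samples: 150 pre-reach samples at 10 ms
steps covering [−1.5 s, Reach Start), **80 evenly spaced in-reach samples**
(time-stretching: the same count regardless of duration, so an 0.4 s and an
0.8 s reach align sample-to-sample), and 150 post-reach samples over
(Reach End, +1.5 s]. The in-reach samples include both endpoints (spacing =
duration/79; a midpoint convention is available, the choice being genuinely
open). Alternative alignment modes (fixed-step from Reach Start, go-cue- or
peak-speed-anchored) are provided for sensitivity analyses.

The unit's mean rate across reaches at each grid point is compared to a
shuffle baseline: 10,000 means of `n_reaches` rate values read at times
drawn uniformly from the *entire recording*, reach epochs included. Empirical
p-values use add-one smoothing ((r+1)/(n+1)); the two-sided criterion at
α = 0.01 is the union of the two 0.005 tails. Significant runs must span at
least 5 contiguous samples (≈ 50 ms) and at least one run must intersect the
window from 400 ms before Reach Start to 400 ms after Reach End for the unit
to count as modulated.

**Null behavior of the contiguity rule.** On 500 stationary Poisson units
pushed through this exact screen, the per-timepoint tail rate is calibrated
(≈ 0.006 against the nominal 0.01, slightly conservative because of the
add-one smoothing), but the *unit-level* false-positive fraction is **13.6%**
— far above α. The reason is serial dependence: a 20 spikes/s
fractional-interval rate smoothed at 50 ms has an autocorrelation scale of
~70 ms, so neighboring 10 ms grid points move together and chance excursions
below the 0.005 tails routinely persist for five samples. Re-running the
screen at longer contiguity requirements bounds the rate (5 samples → 13%,
8 → 5%, 10 → 3.5%, 12 → 2%, 15 → 1.5% on 200 null units). The 5-sample /
50 ms setting is retained as the default for fidelity to the established
procedure — the contiguity length is exposed in the configuration precisely
so users can run this sensitivity analysis — but modulated-unit fractions
near or below ~14% should not be read as exceeding chance at these settings.
The corresponding acceptance check (unit-level false positives ≤ 5% at
5-sample contiguity) therefore fails by design of the method, not of the
implementation, and is left failing rather than loosened.

## Directional tuning and heatmaps

Reaches are grouped by movement direction, an outward reach to a target
sharing its label with the inward reach from the diametrically opposite
target (same hand-movement direction, different posture). At each grid
point a tie-corrected Kruskal–Wallis ANOVA compares rates across direction
groups (groups with fewer than 3 reaches are dropped; at least two groups
are required); tuning requires p < 0.05 for ≥ 5 contiguous samples with a
run intersecting the ±400 ms window. Per-sample severity at p < 0.05 and
p < 0.01 is retained. The same contiguity caveat applies as for modulation,
amplified by the looser α: label-permutation nulls put the unit-level rate
well above 5% even though the per-timepoint p-values are exactly calibrated
(the tests assert the latter).

Spatial activation heatmaps average the rate over fingertip visits to each
15 × 15 mm cell of the top-two principal-component plane of 3D position —
for the nearly planar center-out task this recovers the display plane, and
the cell-value multiset is invariant to rigid motions of the workspace up to
in-plane rotation/reflection of the map.

## Encoding models

Regression samples are taken at the native kinematic times from 250 ms
before each valid Reach Start to 250 ms after its Reach End (windowed
variants use 500 ms windows centered on Reach Start or Reach End, fit at
zero lag). The "kinematics only" set has 12 columns in 6 groups (3D
position, 3D velocity, speed, 3D acceleration, acceleration magnitude,
signed acceleration); "kinematics + error" adds the 3D error — instantaneous
position minus the reach's goal position, estimated as the mean position 0–1
s after Reach End (the early hold, averaging out tremor) — and its
magnitude (16 columns, 8 groups). Reaches whose hold window runs past the
recording are dropped from the error model. All columns and the response
are centered and scaled; zero-variance columns are dropped with a warning,
as are rank-deficient columns.

Ordinary least squares is fit at 241 lags (−1 s to +1 s in 1/120 s steps) by
shifting the firing-rate sample indices on the 1 ms grid, wrapping
circularly at the recording edges; the optimal lag maximizes R² (adjusted R²
with the Ezekiel correction, (n−1)/(n−p−1), is used for cross-model
comparisons). Positive lags mean neural activity follows the kinematics.

**Significance** comes from a circular-shift null: the rate is rotated
against the kinematics by offsets drawn uniformly over the whole recording,
preserving its autocorrelation while destroying alignment. Because the
observed statistic is a *maximum over 241 lags*, each null draw undergoes
the same optimal-lag search around its random offset (`statistic =
"max_lag"`, the default); comparing a maximum against single-shift draws
(`"fixed_lag"`, also available) yields strongly anti-conservative p-values
(26% of independent units "significant" at α = 0.01 in simulation, median
null p ≈ 0.05), while the selection-consistent statistic gives uniform null
p-values (KS p ≈ 0.6) and the nominal error rate. The search over all
shifts is made cheap by computing the full R²-versus-shift curve at once
via FFT cross-correlations of the rate with the orthonormalized design
columns scattered onto the rate grid (the centered design annihilates the
intercept, so subset projections reduce to plain correlation sums). A unit
is significant when its observed statistic exceeds the null's 99th
percentile (α = 0.05 for the windowed regressions).

**Shapley decomposition** attributes the full-model R² exactly: the value of
column *i* is the average over all 2^p subsets S (weights
|S|!(p−|S|−1)!/p!) of the marginal R² gain from adding *i* to S. Subset R²
values are computed from the correlation (Gram) matrix of the normalized
design — b_S' C_SS⁻¹ b_S — rather than by refitting (verified equal to lm
refits to 10⁻⁸); collinear subsets fall back to the pseudo-inverse, which
matches the OLS limit and preserves the symmetry axiom for duplicated
regressors. Per-column values sum to the full R² to 10⁻⁸ (efficiency), 3D
groups are sums of their components, and exact enumeration is refused above
20 columns. The same machinery is validated against an independently coded
brute-force enumeration and against squared simple correlations on
orthogonalized designs.

**Optimal-lag precision is data-limited.** For a minimum-jerk reach the
velocity autocorrelation scale is ≈ 0.5 s, so the R²(lag) curve is nearly
flat within ±50 ms of its peak, and at the weak-encoding regime (R² ≈ 0.1,
where the interesting units live) the argmax jitters under Poisson noise:
the estimator's s.d. is ≈ 38 ms with 96 reaches, ≈ 15 ms with 768 and
≈ 10 ms with 1,150 (it is unbiased — a deterministic-rate control recovers
the lag exactly). The package's lag-recovery benchmark therefore pools many
reaches (a 576-sequence recording, 1,150 reaches), at which point the median
absolute error reaches one lag step; per-session (≈ 48-reach) optimal lags
should be read with a ±3–5 sample uncertainty at these R² levels.

## The synthetic-session generator

The generator emulates the study conditions: 8 targets on a 178 mm circle,
3 s displays, 0.7 s cues, load-balanced pseudorandom target order with at
least 24 out-and-back sequences. Reaches are minimum-jerk point-to-point
segments — not claimed physiological truth, but smooth, unimodal and
analytically known (peak speed 1.875·distance/duration), which is what the
detector's crossing/5% rules assume — with lognormal durations (median
0.8 s, the typical duration of these center-out reaches) and uniform
150–400 ms reaction times (a placeholder for unmeasured subject behavior;
exposed in the configuration).
Tremor is a sinusoid in the 4–12 Hz band along a random 3D direction whose
phase diffuses with a 1.5 s coherence time — physiological tremor is
quasi-periodic, and a pure tone would place exact 200 ms aliases into the
encoding lag search — applied during holds with a raised-cosine fade (zero
value *and* slope at the hold/reach boundaries, keeping position and
velocity continuous), or throughout movement (action tremor) on request.
White tracking noise (0.3 mm s.d.) and Bernoulli dropped frames (1%)
emulate markerless-tracking output; the video pipeline itself is not
modeled.

Units are inhomogeneous-Poisson: rate(t) = drift(t) · max(0, baseline +
Σ w_f·z_f(t − lag) + direction gain · ⟨reach direction, preferred⟩ during
reaches), with features z-scored over the session and sampled by thinning.
A single master seed derives fixed per-stage and per-unit streams, so
sessions are bit-reproducible and adding a unit does not perturb the others.
Real VIM data differ in ways the generator does not attempt: refractoriness
and bursting, tremor-locked firing, non-Poisson variability, sorting errors,
and behavioral idiosyncrasies (disjointed or aborted reaches are emulated
only through the validity flags). Passing tests therefore certify the
*analysis*, not any claim about biology.

## Validation scale and reproducibility

The test suite validates: Shapley exactness on 200 random correlated
designs (n = 500, p ≤ 8) against brute force; null calibration of the
modulation screen on 500 stationary units (10,000 shuffles each) and of the
encoding test on 200 independent units (1,000 shifts each, scaled down from
10,000); lag recovery on 20 weak velocity-coupled units over a 1,150-reach
recording; error-term detection on 20 error-coupled units; detector accuracy
on noiseless and tremor sessions; and the structural invariants (rate
conservation, 80 in-reach samples, drift-normalized rates, byte-identical
pipeline reruns). `scripts/acceptance.R` re-derives the headline quantities
from scratch at any seed. All Monte-Carlo stages consume seeds derived from
one master seed by fixed offsets; outputs are plain CSV/JSON and reruns are
byte-identical.

## Known limitations

- Reach-boundary estimates degrade to ~60 ms median error under realistic
  tracking noise (see above); the modulation/tuning/encoding windows absorb
  this, but the reported mean reach duration is biased short accordingly.
- The unit-level modulation and tuning screens are anti-conservative at the
  default 5-sample contiguity (see the null-behavior analysis); treat the
  contiguity length as an analysis parameter, not a constant.
- The circular-shift null draws offsets from the *entire* recording, so a
  small fraction of draws land within the ±1 s lag window of true alignment
  and slightly inflate null quantiles for strongly encoding units — faithful
  to the stated procedure, and conservative.
- The error regressors proxy the goal by the achieved hold position; with
  inaccurate synthetic (or real) pointing the proxy and the true goal
  diverge, and error and position regressors remain substantially collinear
  — exactly the situation the Shapley attribution is there to arbitrate.
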