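---
title: "Pulse-waveform phenotyping: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-waveform phenotyping: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewave)
```

## What the package computes

`pulsewave` re-implements, as tested reusable code, the waveform, curve-fit
and image computations used to phenotype hypertensive mouse models from
invasive blood-pressure recordings:

* **Beat pipeline** — segmentation of a continuous arterial pressure trace
  into beats, detection of the systolic peak, end-diastole, dicrotic notch
  (DN) and anacrotic notch (AN), and gating of respiratory-artifact beats.
* **Hemodynamic metrics** — per beat: pulse pressure `PP = SBP − DBP`, mean
  arterial pressure `MAP = SBP/3 + 2·DBP/3`, augmentation pressure
  `AP = SBP − P(AN)` and augmentation index `AIx = AP/PP`; per trace: the
  diastolic decay time constant τ and heart rate.
* **Dose–response** — per-animal 4-parameter logistic (4PL) fits of pressor
  responses, reporting ED50 and Emax, with group t-tests.
* **Morphometry** — radial wall thickness and elastic-laminae counts of
  aortic-ring cross sections by the 8-line / 16-point sampling scheme.
* **Statistics** — trimmed means, two-tailed paired/unpaired Student
  t-tests, percent change, and the log-scale ratio t-test.

Because no recordings or images are distributed with such studies, the
package includes closed-form synthetic generators whose every landmark has
analytic ground truth; all tests and the acceptance script run against
those oracles.

## The synthetic beat and its oracle

One cycle of the generated pressure waveform is pieced together from
closed-form segments (`beat_shape_params()`, `generate_trace()`):

1. **Systole** (`0 ≤ t ≤ t_m`): two log-normal lobes — a forward ejection
   lobe and a delayed, scaled reflected lobe — on a cubic baseline ramp.
   The lobe overlap produces a shoulder on the upstroke (the anacrotic
   notch); the reflected lobe dominates the peak, giving the
   late-systolic-augmented shape seen in stiffened arteries. The composite
   amplitude is normalised on the sample grid so the sampled maximum equals
   `sbp` exactly at one sample.
2. **Dicrotic notch**: a raised-cosine dip of depth `dn_depth` and width
   `dn_width` at `dn_time_frac · period`.
3. **Diastole**: a zero-asymptote exponential `dbp · exp((t_end − t)/τ)`
   that reaches `dbp` exactly at the final sample. When τ is too short for
   the whole diastole to stay below SBP, the exponential occupies only its
   terminal part and a log-linear bridge connects it to the notch; the
   ground truth records the pure-exponential window either way, so the
   ln-pressure slope over that window is exactly `−1/τ`.
4. **Landing**: the final 8 ms are a cubic Hermite segment that brings the
   pressure to `dbp` with zero slope. Without it, consecutive beats join at
   a slope discontinuity whose fourth-derivative ringing corrupts the
   anacrotic-notch crossing count. The landing is excluded from the decay
   window.

Ground truth for each beat is computed from the same closed form on a 10×
oversampled grid: the foot by the intersecting-tangents rule, the AN as the
third sign change of the numerical fourth derivative before the peak, the
DN as the argmin of the dip. Detection is therefore always compared against
an oracle that is independent of the sampled-data detectors.

Default conditions are an anaesthetised-mouse-like beat: 120/80 mmHg,
period 0.15 s (400 bpm), 2,000 samples/s, τ = 0.25 s. With a ~75 ms
diastole a zero-asymptote exponential and a physiologic DN-to-DBP drop
force τ into the 0.15–0.45 s range; shorter time constants would push the
dicrotic-notch pressure above SBP. The spec-style exponential fixtures
with τ of 20–80 ms are therefore exercised on bare decay traces
(`exp_decay_trace()`), where the estimator's window assumptions hold by
construction.

What the generator does **not** emulate: baroreflex and respiratory
variability beyond the injected artifact beats, catheter damping, drift,
ectopy, and ECG morphology beyond R spikes. Passing tests show the
detectors recover the generator's landmarks under Gaussian noise — not
that they are robust to every failure mode of real catheter data.

## Detection conventions

* **Smoothing/derivatives**: Savitzky–Golay local-polynomial filters,
  order 5. Smoothing and first/second derivatives use a 21-sample window
  (10.5 ms at 2 kHz). The fourth derivative uses a 41-sample window with
  two pre-smoothing passes: at 2 kHz a fourth derivative over 21 samples
  cannot resolve the crossing structure (clean AN error ≈ 10 ms against
  the oracle; noisy detection collapses), while the wider two-stage filter
  agrees with the oracle to ~1 ms and keeps ≥ 95% of beats within 5 ms at
  0.5 mmHg noise.
* **Segmentation** (no ECG): upstrokes are maxima of dP/dt above half the
  99th-percentile slope (robust to a few outsized artifact beats), at
  least 0.55 estimated periods apart (period from the FFT autocorrelation
  of the smoothed trace); each foot is the intersection of the tangent at
  maximum dP/dt with the horizontal through the preceding diastolic
  minimum. With an ECG, boundaries are R peaks plus a configurable
  electromechanical delay (default 12 ms, matching the generator's
  R-to-foot offset).
* **AN anchor**: the third-crossing count starts 6 ms before the detected
  foot. The tangent foot sits on the upstroke just after the first
  genuine crossing, while anchoring at the preceding end-diastole admits
  smoothing-filter leakage from the previous beat's systole (the
  effective filter support is ~60 ms).
* **DN window**: first local minimum of the smoothed pressure 10–60% of
  the cycle after the peak (an augmented waveform puts the notch ~14%
  after the late systolic peak), falling back to the second-derivative
  maximum, else flagged missing.
* **Peak/trough**: indices from the smoothed trace (a raw argmax is
  upward-biased under noise), pressures read from the raw trace;
  end-diastole is refined to the raw minimum within half a smoothing
  window. Exact ties take the earliest sample and set a flag.
* **Gating**: a beat is gated when its SBP or cycle length deviates from
  the 15-beat rolling median by more than 3 normalised MADs *and* by more
  than an absolute floor (2 mmHg / 5 samples). The floor is needed because
  the MAD of a discretised near-constant series is zero; without it,
  sampling granularity alone would gate clean beats. A final segment
  truncated by the end of the trace is exempt from the cycle-length
  criterion. The rule is an explicit, deterministic surrogate for the
  proprietary beat classifiers of acquisition software.
* **Indices** are 1-based throughout, R's native convention; segments are
  half-open `[onset, end)`.

## τ and the trimmed mean

The decay slope is the least-squares slope of `ln(pressure)` from 30 ms
after the DN to 20 ms before end-diastole (avoiding valve-closure and
upstroke perturbations); for an exponential decay it equals `−1/τ`
exactly, and a raw-pressure variant is available behind `semilog = FALSE`
for comparison. τ is the reciprocal of the magnitude of the 20% per-tail
trimmed mean of the per-beat slopes — trimming is applied across beats,
not within them, and "20% trimmed" means `floor(0.2 n)` values dropped
from each tail, the convention `trimmed_mean()` implements and tests
against base R's `mean(trim =)`.

## Dose–response fitting

`fit_4pl()` fits `R(d) = bottom + (Emax − bottom)/(1 + (ED50/d)^h)` by
bounded Levenberg–Marquardt least squares (tolerance 1e-10, 500
iterations), with self-start values (min/max response, dose nearest the
mid-response, Hill slope 1) and `h, ED50 > 0` (pressors raise SBP, so
curves ascend). Zero-noise data are recovered to 1e-6 relative error;
dose-scale equivariance (doses × c ⇒ ED50 × c) is asserted numerically.
Curves are fitted per animal and ED50/Emax compared by unpaired t-tests —
pooled fitting across animals is deliberately out of scope.

## Morphometry conventions

The ring centre is the intensity-weighted centroid above the half-range
threshold. Eight lines at 22.5° through the centre give 16 rays, sampled
at 0.25 px by bilinear interpolation. Wall boundaries are half-maximum
crossings — the level is set halfway between the lumen baseline and the
*wall plateau* (median of supra-threshold intensities), so bright laminae
do not bias the boundaries — with sub-pixel interpolation of the crossing
position; thickness is measured along the ray (outer minus inner crossing
radius), matching measurement "at the point of intersection" rather than
perpendicular to the local wall. Laminae are local maxima inside the wall
(1 px in from each boundary) whose elevation above the wall plateau
(lower-decile wall intensity) exceeds 20% of the wall contrast; a uniform
wall therefore counts zero, because its only "peak" is the plateau
itself. Rays are excluded when no wall is found, when their wall extent
deviates from the ring median by more than 50% (branch points, incomplete
rings), or by a user angle mask; ring means are taken over included rays,
then averaged across sections.

The synthetic rings use radially scaled ellipses, so the per-angle radial
wall extent has a closed form that serves as the geometric oracle.

## Statistics

`group_t_test()` is the classical two-tailed Student t-test (pooled
variance; Welch behind a flag), `ratio_t_test()` a one-sample t-test of
log-ratios against zero with the geometric mean and exponentiated CI
reported (ratios are multiplicative; a linear-scale variant exists behind
a flag), and degenerate inputs (zero variance) yield flagged results
rather than errors. No multiple-testing correction is applied, matching
the source analyses.

## Problem sizes and study conditions

The test-suite and acceptance-script conditions were fixed once: 100
noise-free beats for fiducial-oracle agreement; τ recovery on decays of
20/40/80 ms, with the noisy arm at 0.5 mmHg, 60 beats and 50 seeds; the
22-beat gating fixture with artifacts at beats 8 and 16; 200 seeded
replicates at 2 mmHg noise for ED50 error; 100 seeded rings for laminae
accuracy; 2,000 null / coverage simulations for the t-test and ratio-CI
operating characteristics; and, for pipeline-end power, 200 cohorts of 10
animals per group × 20 beats (control: reflected amplitude 40 mmHg,
τ = 0.22 s; stiffened: 56 mmHg, τ = 0.30 s; 10% between-animal CV,
0.5 mmHg noise). These sizes make the full suite run in a few minutes on
one CPU while leaving every statistical band (for example the
[0.04, 0.06] type-I window) well-powered.

## Known limitations

* The AN convention (anchor, smoothing) reproduces the published
  third-zero-crossing rule only up to the unstated internals of the
  original acquisition macros; agreement is demonstrated against the
  package's own closed-form oracle, not against LabChart.
* Under noise the end-diastolic raw-minimum refinement biases DBP low by
  about one noise SD; group contrasts are unaffected (the bias is common
  to both groups).
* Morphometry assumes a single, roughly convex annulus; dissecting or
  folded rings are out of scope.
* The τ estimator presumes a mono-exponential decay over the analysis
  window; on waveforms whose window spans the log-linear bridge, the
  estimate is a smooth monotone surrogate of the true constant rather
  than the constant itself.
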