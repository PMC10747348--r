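---
title: "Quantifying equine back flexion/extension: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying equine back flexion/extension: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equiback)
```

## The measurement problem

The thoracolumbar spine of a horse flexes (arches dorsally) and extends
(hollows) cyclically during locomotion: twice per stride at walk and trot,
once per stride at gallop. The global back angle — the angle at the
eighteenth thoracic vertebra (T18) between the directions to the withers
and to the pelvis — summarises this mobility in a single trace. Optical
motion capture measures it directly from three reflective markers but
confines the horse to a camera volume; three trunk-mounted accelerometers
can measure an equivalent angle in the field. This package implements both
computations and the statistics used to establish their agreement, plus a
simulator that generates paired marker/IMU trials with analytically known
ranges so the whole chain can be validated without animal data.

## The IMU model and its assumptions

The accelerometer chain makes three assumptions:

1. **A motionless calibration window exists** (the "standing square").
   During it each sensor reads pure gravity, so the window means reveal the
   mounting tilt. The tilt model has two angles — roll about the
   terrestrial X axis (α) and pitch about the floating Y axis (β) — and
   assumes **zero yaw** about the sensor's own Z axis at standing square.
   `estimate_orientation()` solves α and β from the window means and builds
   the rotation that maps the motionless reading to (0, 0, −g); the
   estimate is exact (round-trip residual at machine precision) for tilts
   well beyond realistic mounting errors, as the ±30° sweep in the test
   suite shows. The window is validated (per-axis SD < 0.02 g, mean norm
   within 5% of 1 g) because a non-still window silently biases everything
   downstream.

2. **Vertical displacement is recoverable by band-limited double
   integration.** Gravity (and accelerometer bias) is removed by
   subtracting the static-window mean of the corrected vertical channel
   rather than a nominal 9.81 m/s², so a constant bias is absorbed exactly.
   The residual acceleration is integrated (cumulative trapezoid),
   high-pass filtered, integrated again, and high-pass filtered again.
   Filtering after *each* integration stage, rather than once at the end,
   prevents a linear velocity drift from growing quadratically into the
   displacement before any filtering happens; on a 10 s trial the
   difference is the difference between a bounded and an unbounded error.
   The cost is that all displacement content below the cutoff is discarded
   — acceptable here because only the oscillation at the cycle frequency
   (≥ 1.8 Hz for all gaits) carries information, and the cutoff sits at
   1 Hz.

3. **The angle is reconstructible from vertical displacement alone.** With
   Δz the offset of the T18 displacement below the midpoint M of the
   withers and pelvis displacements, the angle is
   arccos(Δz/X2) + arccos(Δz/X). Because the displacements are high-pass
   filtered and hence zero-mean, this trace oscillates about 180° whatever
   the horse's true standing posture: only per-cycle *ranges* are
   interpretable, never the absolute angle. This matches how the method is
   used — flexion and extension ranges, not posture.

Arccos arguments are clipped to [−1, 1]; clipping events are counted and
exposed (`clip_count` attribute) rather than silently swallowed, since
persistent clipping means the geometry configuration is wrong.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| smoothing cutoff | 5 | Hz | passes cycle frequencies (1.8–3.4 Hz) while removing impact content; applied to marker positions (MOCAP) and to the final angle (IMU) |
| drift cutoff | 1 | Hz | below every gait's cycle frequency; removes integration drift |
| filter order | 4 | — | Butterworth, applied forward–backward (zero phase) |
| common rate | 200 | Hz | both streams are spline-resampled to one rate before comparison |
| X, X2 | 0.5, 0.5 | m | tape-measured T18→pelvis and withers→T18 distances; enter the arccos denominators directly, so a 1% taping error scales the range by ≈ 1% |
| sync threshold | 2 | g | pastern strike detection above the median-norm baseline, min separation 0.5 s |
| extrema prominence | 0.5 | ° | swings smaller than this are noise, not cycles |
| extrema separation | 0.4 / f_cycle | s | same-kind extrema closer than 40% of the expected cycle period are merged |
| edge guard | 0.5 | s | cycles touching the trace edges are discarded (filter transients) |

All zero-phase filtering is done forward–backward so the two methods stay
synchronised: a causal filter would delay each trace by a different group
delay and corrupt the cycle pairing.

## Numerical choices

- **Filter edge handling.** `signal::filtfilt` applies no padding, and its
  internal zero-append lets edge transients reach ~0.7% of signal level
  several seconds into a trace. `butterworth_filter()` therefore extends
  the series by an odd reflection (long enough for the slowest filter
  transient to decay) and removes the mean before filtering, restoring it
  for low-pass filters. A constant input through a high-pass then maps to
  exactly zero.
- **Resampling** uses a cubic spline (continuous first derivative), which
  preserves amplitude to well below 0.1% at the rates involved
  (225 ↔ 200 Hz against signals ≤ 5 Hz).
- **Extremum refinement.** Peak values read off a 200 Hz grid are biased
  low by up to ~0.1% of amplitude; a three-point parabolic fit around each
  extremum removes the grid bias in both time and value.
- **Cycle pairing** between methods matches minima by time within 25% of
  the expected cycle period, which tolerates small desynchronisation
  without ever pairing different cycles.
- **Degenerate inputs** fail loudly: coincident markers, non-monotone
  timestamps, non-uniform sampling, non-still calibration windows, cutoffs
  at or above Nyquist, and sub-3-pair agreement inputs are all errors, not
  warnings.

## What the simulator emulates — and what it does not

`simulate_trial()` generates: a motionless standing-square pre-roll
(default 3 s); a raised-cosine transition into steady gait (1 s); a common
vertical trunk bounce (default 4 cm amplitude) of withers and pelvis at the
cycle frequency; a differential T18 offset whose amplitude is solved, by
inverting the trigonometric angle at the configured X and X2, so that every
steady-state cycle has *exactly* the target range (walk 2.6°, trot 3.9°,
gallop 9.5° by default — typical motion-capture means for sound horses);
per-sensor mounting tilts (drawn in ±15° unless fixed); white accelerometer
noise (default 0.01 g per axis) and marker noise (default 0.5 mm per axis);
two pastern sync impulses; and an optional systematic IMU offset (default
0.7°) emulating the field observation that the accelerometer method reads
slightly high relative to motion capture.

The marker trajectories additionally carry a static sag of T18 below the
withers–pelvis chord so that the marker-triangle angle rests at
`rest_angle_deg` (default 178° − target/2). This matters because the
3-D vector angle is unsigned: a marker triangle oscillating about exactly
180° would fold its peaks back under 180° and flexion would be
indistinguishable from extension. Real backs are never perfectly straight,
so the sag is both physically sensible and numerically necessary. The sag
is solved pointwise (Newton inversion of the triangle angle) so the marker
angle reproduces the analytic truth up to that constant offset — constants
cancel in ranges, so both methods see the same ground-truth ranges.

Deliberate simplifications, hence what passing tests do *not* show about
real data: trunk motion is purely vertical plus uniform forward translation
(no lateroflexion, axial rotation, or circle work); flexion and extension
are symmetric within a cycle, so the generator cannot represent unequal
flexion/extension targets (it requires them equal — real gait shows small
asymmetries); noise is white and Gaussian (no soft-tissue artifact, no
hoof-impact transients); stride frequencies are fixed defaults (walk
0.9 Hz, trot 1.4 Hz, gallop 1.7 Hz — plausible over-ground values, all
configurable); tilts exclude yaw, matching the method's own assumption, so
the simulator cannot probe yaw-induced error.

A further note on recovery accuracy: the prescribed 5 Hz order-4 zero-phase
low-pass has two-pass gain |H|² ≈ 0.990 at the trot cycle frequency of
2.8 Hz, so both pipelines under-read trot ranges by ≈ 1% *by construction
of the filtering protocol itself*; the end-to-end tests bound total error
accordingly (1% for MOCAP, 5% for the IMU chain, whose integration and
resampling stages add a little more).

## The agreement study model

`simulate_agreement_study()` works at the level of per-movement ranges: a
latent true range per movement drawn around the gait's typical mean, then
*both* methods measure it with independent Gaussian errors of
SD = noise/√2, so the paired-difference SD equals the nominal noise SD. The
noise is split across both axes deliberately: ordinary least products (OLP)
regression assumes comparable error on both variables, and putting all
noise on the developed axis would inflate the OLP slope by
√(1 + σ²/s_x²) and flag a spurious proportional bias. The developed method
additionally applies a slope and constant offset, which the analysis should
(and, in the test suite, does) recover.

OLP confidence intervals use the analytic geometric-mean-regression
formulas (slope b(√(B+1) ± √B) with B = t²(1−r²)/(n−2); intercept CI by
propagating the slope limits through ȳ − b x̄). Field reports of this
method sometimes compute the biases with ordinary least squares software;
the named method (OLP) is what is implemented here, and the OLS fit is what
`stats::lm` provides if a user wants the comparison. Note a statistical
fact about the proportional-bias flag: when the true slope is 1 the flag is
the complement of a 95% CI covering the truth, so it is *designed* to fire
in 5% of studies — specificity cannot exceed 95% on average.

The Bland–Altman limits use the sample SD (n−1) and the conventional 1.96
multiplier; display rounding is one decimal, half away from zero, matching
how such tables are conventionally printed.

## Problem sizes

The test suite and the acceptance script run on 8–12 s single trials
(≈ 2 700 IMU samples, ≈ 2 400 marker frames, 9–15 steady cycles per trial),
340-pair agreement studies, and 100-replicate flag-rate sweeps; these sizes
give sub-minute runtimes while leaving every statistic comfortably inside
its sampling tolerance.

## Known limitations

- Acceleration-only orientation: no gyroscope/magnetometer fusion, no
  orientation tracking during motion; a sensor that slips after
  calibration invalidates its correction.
- Absolute angles are not interpretable from the IMU pipeline (high-pass
  filtering removes the posture baseline); only ranges are.
- The cycle segmenter assumes a dominantly sinusoidal trace at the
  expected cycle frequency; severely arrhythmic gait would need manual
  review.
- Agreement statistics pool all movements; no within-horse clustering or
  repeated-measures correction is applied.
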