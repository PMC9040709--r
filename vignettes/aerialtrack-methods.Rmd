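---
title: "Methods: drone-based player tracking, kinematics and agreement validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drone-based player tracking, kinematics and agreement validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`aerialtrack` implements the processing chain of a drone-based electronic
performance and tracking system (EPTS). A single camera hovers at nadir above
a playing field; players are detected in each video frame as bounding boxes;
surveyed ground markers (control points) calibrate each frame; and the
calibrated positions feed standard athlete-monitoring metrics and
method-agreement statistics against wearable reference systems (GPS with a
Doppler speed channel, and a radio-based local positioning system, LPS).

The package covers five stages, each usable on its own:

1. **Field geometry** — per-frame planar homography estimation (DLT) and
   application, position reconstruction from bounding boxes.
2. **Scene simulation** — ground-truth motion, the camera measurement chain,
   and GPS/LPS stream emulation, so every stage can be tested end to end
   without a data collection.
3. **Tracking I/O** — CSV formats, gap handling, heatmaps.
4. **Kinematics** — resampling, zero-phase Butterworth filtering, speed,
   acceleration, cumulative distance, speed-zone distances, and
   cross-correlation synchronization.
5. **Agreement statistics** — RMSE, Bland-Altman, two-way ICCs, Pearson with
   effect classes, OLS regression, CV%, percentage absolute differences.

## The geometric model

The playing surface is treated as a plane, so the map between image pixels
$(u, v)$ and field coordinates $(x, y)$ in metres is an 8-degree-of-freedom
projective transform $H$ (a homography):

$$\lambda \begin{pmatrix} x \\ y \\ 1 \end{pmatrix}
 = H \begin{pmatrix} u \\ v \\ 1 \end{pmatrix}.$$

`estimate_homography()` solves for $H$ from $n \ge 4$ control-point
correspondences by the direct linear transform. Numerical choices:

- **Conditioning.** Both point sets are translated to their centroid and
  scaled to an RMS radius of $\sqrt 2$ before building the $2n \times 9$
  system (Hartley normalization). Pixel coordinates of order $10^3$ would
  otherwise produce condition numbers around $10^9$.
- **Overdetermined fits** use the right singular vector of the smallest
  singular value — the algebraic least-squares solution. With 4–8
  well-spread markers and sub-pixel noise this is at the noise floor, and it
  is deterministic; no iterative geometric refinement is attempted.
- **Degeneracy.** For minimal (4-point) sets every triple is checked for
  collinearity and offending points are named; for larger sets a nullspace
  of dimension larger than one (second-smallest singular value below
  $10^{-8}$ of the largest) is rejected.
- **Normalization.** Matrices are stored with $H_{33} = 1$, or unit
  Frobenius norm with a positive leading entry when $H_{33} = 0$; the
  normalization is idempotent.

Calibration is **per frame** (`calibrate_frames()`): a hovering drone is
gimbal-stabilized but still drifts slightly, and refreshing $H$ every frame
absorbs that motion instead of propagating it into player positions. No
temporal smoothing is applied across the per-frame homographies — smoothing
would trade a small variance reduction for a bias whenever real camera
motion occurs, and the static validation shows the unsmoothed chain is
already at the centimetre level. A frame with fewer than four usable markers
is an error naming the frame; an explicit `reuse_last` flag may instead
carry the previous frame's calibration forward, flagged on the result.

The field frame puts the origin at a corner with $X \in [0, L]$ along the
length and $Y \in [0, W]$ along the width. Published setups name a corner
origin but not the axis directions; `flip_axes()` converts to any of the
other corner conventions. Pixel coordinates are continuous (sub-pixel),
origin top-left, $u$ rightward, $v$ downward.

A player's position is the **centre of its bounding box** mapped through the
frame's homography. Points reconstructed far outside the field are retained
but counted in a warning: they indicate tracking faults, which are upstream
of this package.

## The scene simulator

The simulator is the package's test bed: it generates what a real collection
would have produced, plus the exact per-frame truth that a real collection
cannot provide.

**Ground truth.** Players move at a master rate of 120 Hz — chosen because
it is integer-divisible into the three sensor rates (24, 20, 15 Hz), so
sampling truth at a sensor's clock never interpolates. Per player and axis
a displacement process is drawn as white Gaussian noise low-pass filtered
(4th-order, zero-phase) at the motion profile's bandwidth (default 0.3 Hz),
normalized to the player's wall clearance around an anchor on a grid across
the field, and finally scaled so the peak instantaneous speed is 90 % of the
speed cap. The defaults encode the validation conditions: a 14 km/h cap
(amateur/training-level play rarely exceeds it) and band-limited smooth
motion. The construction guarantees in-field positions and the hard speed
cap without boundary reflections, which would inject high-frequency kinks.

What this motion model does *not* emulate: sprints against the acceleration
limit, collisions and avoidance, set-piece structure, or the long straight
runs of match play. Passing tests therefore demonstrate the correctness of
the measurement and processing chain, not the realism of any tactical
pattern.

**Camera.** A nadir pinhole at 27/50/85 m (the three preset scenarios) with
focal length 2700 px for a 3840×2160 image — the ground sampling distance
(GSD) is $h/f$ m/px, i.e. 1 cm/px at 27 m. Residual motion of a
gimbal-stabilized hover is modelled as per-frame random walks in ground XY
(default step 0.02 m) and yaw (0.002 rad); pitch/roll are absorbed by the
gimbal and omitted. No lens distortion is modelled: at nadir from ≥ 27 m the
field occupies the central part of the image where distortion is minimal,
and none was reported in comparable setups. Gaussian pixel noise (default
1 px) perturbs control-point observations and box centres; detections drop
out with a configurable probability. No quantitative jitter magnitude is
available for real flights; the defaults are stated choices, and the
per-frame calibration makes downstream results insensitive to them.

**Sensors.** GPS emits positions at 15 Hz with AR(1)-correlated noise
(default sd 0.50 m, coefficient 0.95) — GNSS error is strongly
autocorrelated, and white noise would unrealistically inflate distance — and
an independent Doppler speed channel (true speed + white noise, default sd
0.3 km/h), *not* differentiated noisy positions, mirroring how receivers
derive speed from satellite frequency shift. LPS emits positions at 20 Hz
(default sd 0.10 m) and accepts an injected clock offset for
synchronization tests. The noise presets are order-of-magnitude consistent
with the centimetre-level drone RMSEs and the decimetre/metre-level
LPS/GPS errors reported in the validation literature.

## Kinematics

The per-player chain is: fill short gaps → low-pass positions → speed →
acceleration → distance and zones.

- **Gap policy.** Runs of up to `max_gap` missing samples (default 5) are
  linearly interpolated and flagged; longer gaps split the trajectory into
  segments, and distance is never accumulated across a break, so a dropout
  cannot teleport a player and inflate distance. How real dropouts were
  handled in published pipelines is generally unstated; this explicit
  policy is the package's own.
- **Resampling** to a common 15 Hz clock uses linear interpolation of the
  original values over the overlap only (no extrapolation).
- **Filtering** is a 4th-order Butterworth low-pass applied
  forward-backward, so the net phase is zero — phase lag would bias the
  cross-correlation synchronization and shift every event in time. The
  implementation pads with odd reflection about the endpoints and uses
  offset-referenced initial conditions so constants pass exactly and edge
  transients decay inside the padding. The forward-backward pass squares
  the magnitude response; the amplitude ratio at the cutoff is 0.5. The
  default cutoff is 1 Hz: whole-body positional data in team sports is
  conventionally filtered around there, and the exact cutoff used in
  published drone validations is unstated. It is configurable everywhere.
- **Differentiation** is by central differences (exact for constant
  acceleration), one-sided at segment ends, deterministic; spline
  derivatives would smooth twice given the Butterworth stage.
- **Speed zones** default to boundaries at 4.0 and 8.0 km/h, implemented as
  half-open intervals $[0,4)$, $[4,8)$, $[8,\infty)$ so that the printed
  labels "0–3.9 / 4.0–7.9 / above 8" become exhaustive and disjoint (a
  speed of exactly 4.0 km/h is jogging). Each inter-sample distance
  increment is assigned by the mean of its two endpoint speeds — symmetric
  under trajectory reversal and conservation-friendly: zone sums plus any
  unassigned remainder equal the total distance to machine precision.
- **Synchronization** maximizes the normalized cross-correlation over
  integer-sample lags within ±`max_lag` (default 2 s), ties broken toward
  the smallest |lag|; a flat series is an error since correlation is
  undefined.
- **GPS distance** can be computed two ways: differencing (filtered)
  positions, or integrating the Doppler speed channel
  (`distance_from_speed()`). Whether published GPS totals come from
  positions or integrated Doppler speed is typically unstated; both routes
  are exposed, and the built-in workflows default to positions for
  position-only systems and to Doppler integration where a manufacturer
  speed channel exists.

## Agreement statistics

- **RMSE** is $\sqrt{\sum_i (x_i - y_i)^2 / n}$. Static validation stacks
  the X and Y residuals of every frame of a marker into a single
  evaluation (the univariate formula needs a stated 2D convention); the
  separate `reprojection_error()` quality metric is the RMSE of Euclidean
  point distances. The static report aggregates per-point RMSEs (mean,
  sample sd, max) and expresses the mean as a percentage of field length
  and width.
- **Bland-Altman**: bias = mean of paired differences $a - b$, limits of
  agreement = bias ± 1.96 × sample sd. Swapping systems negates the bias
  and mirrors the limits.
- **ICC** is computed from two-way ANOVA mean squares, single measures
  (Shrout-Fleiss): consistency $(MS_R - MS_E)/(MS_R + (k-1)MS_E)$; absolute
  agreement adds $(k/n)(MS_C - MS_E)$ to the denominator. Published
  validations report both variants without naming the model; the two-way
  single-measures pair matches the classification framework used
  (poor ≤ 0.5, moderate ≤ 0.75, good ≤ 0.9, excellent > 0.9).
- **Pearson r** is classified small < 0.3, medium < 0.5, large ≥ 0.5 on the
  magnitude.
- **Regression** is OLS of system-on-reference with $R^2$, residual RMSE
  and RMSE% (= 100 × RMSE / mean of the response).
- **CV%** is 100 × sample sd / mean.
- **Percentage absolute difference** averages $100\,|a_i - b_i|/b_i$ over
  sessions, with the reference system as denominator (documented and
  configurable by argument order).

The sample $(n-1)$ standard deviation is used throughout. Published static
tables whose sd row is only reproducible with the population formula are
treated as a presentation choice there, not adopted here; the package also
reports aggregate means at full precision rather than at table rounding.

## Problem sizes and tolerances

The test suite and the acceptance script exercise: 100 random projective
cameras (recovery to $10^{-6}$, round-trips to $10^{-9}$ m); static scenes
of 200–600 frames per noise level at pixel noise 0.5–4 px (centimetre-level
RMSE at 1 px and a linear noise response with $R^2 > 0.99$); dynamic
validation over 20 simulated sessions × 2 players; synchronization over 100
noisy trials at SNR 10 (≥ 95 % exact recovery); zone conservation on 100
random trajectories to $10^{-9}$ m; and full-chain distance recovery on
noiseless band-limited motion to 0.5 %. These sizes were chosen so each
property is measured well inside its Monte-Carlo error while the whole
suite runs in well under a minute per module.

## Known limitations

- The planar model ignores player height: a torso centre ~1 m above the
  ground projects with a small height-dependent offset that per-frame
  calibration cannot remove. At nadir directly below the camera the offset
  vanishes and grows toward the field edges; real validations absorb it
  into the dynamic comparison, and the simulator does not model it.
- The motion model is stochastic, not tactical; speed distributions are
  plausible but not sport-specific.
- Identity management is input-given: the package never re-identifies
  players after tracker identity switches.
- GPS/LPS noise models are stationary; real GNSS error drifts with
  satellite geometry and multipath over tens of minutes.
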