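---
title: "Methods: gaze data quality and end-to-end latency in gazeqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze data quality and end-to-end latency in gazeqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeqc)
```

`gazeqc` quantifies two things a clinical eye-tracking application running
in a VR headset must know about its hardware: how *spatially* trustworthy
the reported gaze is across the display, and how long the display takes to
react to an eye event (*end-to-end latency*). Both are bench measurements —
they need no human-subject data, and the package ships generators that
produce inputs with exactly known ground truth so that every stage of both
pipelines is testable.

## The fixation protocol

Spatial quality is probed with a 5 × 5 grid of fixation targets spanning
±26.6° of visual angle horizontally and vertically. Grid angles are
equally spaced (−26.6°, −13.3°, 0°, 13.3°, 26.6°) and mapped onto the
target plane at the viewing distance $d$ through the tangent,
$x = d\tan\theta$; the centre target therefore sits on the optical axis at
$(0, 0, d)$. Each of the 25 cells is shown 5 s and repeated 5 times in
seeded random order:

* **head-still** — targets are HMD-fixed (they move with the head); total
  stimulus time $25 \times 5 \times 5\,\mathrm{s} = 625$ s.
* **head-free** — targets are world-fixed and the observer moves the head;
  each presentation is followed by a 2 s central re-centering fixation,
  giving $25 \times 5 \times 7\,\mathrm{s} = 875$ s.

The grid spacing itself is a modelling choice: only the ±26.6° extent and
the row/column structure are fixed by the protocol, so equal *angular*
spacing is adopted as the natural reading and is configurable through
`grid_extent_deg`.

## Pre-processing

1. **Onset discard.** The first 500 ms after every target onset are
   dropped (`discard_s`); this window absorbs the saccade to the new
   target, so the simulator does not need to model gaze-shift dynamics.
2. **Binocular averaging.** The cyclopean direction is the renormalised
   component-wise mean of the two unit eye vectors; the origin is the mean
   eye position. A sample is valid only when *both* eyes were tracked —
   one lost eye excludes the sample for both. Samples without a detected
   eye are retained (flagged invalid) so data-loss accounting can see
   them.
3. **Re-referencing.** The target is re-referenced to the eye,
   $\mathbf{t}_e = \mathbf{T} - \mathbf{E}$, with eye positions converted
   from the tracker's millimetres to metres.
4. **Head phases (head-free).** The angular speed implied by consecutive
   HMD orientation quaternions, $\omega = 2\arccos(|\langle q_1, q_2
   \rangle|)/\Delta t$ (double-cover invariant), is smoothed with a
   5-sample moving average and thresholded at 10 °/s; runs shorter than 12
   samples (100 ms at 120 Hz) are absorbed into the surrounding phase.
   The threshold, window and minimum run are configurable — no canonical
   values exist for this split, and these defaults are conservative for
   natural head turns: deliberate re-orienting movements run well above
   10 °/s while fixational head jitter stays well below it.

## Spatial metrics

**Accuracy** is the mean angular error over the valid samples of a
segment, with the per-sample angle computed as

$$\mathrm{angle}(\mathbf{g}, \mathbf{t}_e) =
\operatorname{atan2}\!\big(\lVert \mathbf{g} \times \mathbf{t}_e \rVert,\;
\mathbf{g} \cdot \mathbf{t}_e\big),$$

which is numerically exact near 0° where the arccos-of-dot form loses
half the significant digits (the test suite checks agreement with the
arccos oracle to $10^{-9}$ degrees away from 0°).

**Precision** is the root mean square of angular distances between
*successive* gaze directions. Pairs never straddle an invalid sample, a
phase boundary, or a segment boundary; precision is computed per
presentation and averaged over repetitions of the same target. For
isotropic per-component direction noise of standard deviation $\sigma$,
consecutive differences have two independent components of variance
$2\sigma^2$ each, so RMS $\approx 2\sigma$ — the small-angle law the
validation suite checks by Monte Carlo.

**BCEA.** Gaze directions are projected to planar angles
$(h, v) = (\operatorname{atan2}(x, z), \operatorname{atan2}(y, z))$ and
the bivariate contour ellipse area covering proportion $P$ (default 0.5)
is

$$\mathrm{BCEA} = 2\pi k\, \sigma_h \sigma_v \sqrt{1 - \rho^2},
\qquad k = -\ln(1 - P),$$

the standard bivariate-normal contour formula. For
$\sigma_h = \sigma_v = 1$, $\rho = 0$, $P = 0.5$ this is
$2\pi\ln 2 \approx 4.355\ \mathrm{deg}^2$, the closed form used in the
tests together with an empirical-coverage check.

**Data loss** is
$100 \times (N_\mathrm{samples} - N_\mathrm{valid}) / N_\mathrm{expected}$,
where $N_\mathrm{expected}$ is what the nominal rate predicts for the
retained window. The formula is implemented literally; because the
numerator counts only *recorded* invalid samples, a tracker that silently
drops samples would be under-counted, so a `data_loss_convention =
"expected"` switch substitutes $N_\mathrm{expected} - N_\mathrm{valid}$.
The literal convention is the default.

**Group statistics.** Percentile summaries use linear interpolation
(type-7 quantiles) over the pooled per-target values; both the per-target
and per-subject pooling readings are supported by passing the
corresponding value vector, since either unit is defensible. Row effects
are tested with a one-way fixed-effects ANOVA (grid row as factor, the
row's per-target values as observations) and Bonferroni-corrected pooled
two-sample t-tests for all 10 row pairs.

## Latency pipeline

The latency bench trick: infrared LEDs simulate a pupil appearing (or
jumping) in front of the headset's eye camera, a high-speed camera films
the headset screen, and the delay is read off the film as the number of
frames between the LED reflection appearing and the tracker's on-screen
response dot. The pipeline is:

1. **HSV masks.** Each frame is converted to HSV and pixels are counted
   inside per-event colour boxes: a low-saturation/high-value window for
   the near-white LED reflection, a green-hue window for the pupil-on
   dot, a wrap-around red window for the pupil-shift dot. The camera's
   exact colours vary per rig, so all windows are configurable; defaults
   match the synthetic renderer.
2. **Flags.** A frame flags an event when its pixel count is *strictly*
   greater than the mask's minimum (10 px for LED and dots) and, for the
   first LED pair in the gaze-contingent scenario, strictly smaller than
   250 px; the second, larger LED pair flags above 300 px. Counts exactly
   on a bound never flag, and the 250–300 px gap cleanly separates the
   two LED pairs.
3. **Onsets and intervals.** Onsets are debounced rising edges (default
   debounce 3 frames, configurable to 1; the synthetic fixtures are
   flicker-free so 1 is exact there). Each LED onset is paired with the
   first dot onset in its cycle; LED events with no matching dot are
   tallied as dropped rather than biasing the intervals.
4. **Summary.** Latency is the *median* interval (midpoint convention for
   even counts) times the mean frame duration — from the timestamp file
   when present, else $1000/\mathrm{fps}$ ms. A one-sample
   Kolmogorov–Smirnov test against a fitted normal is attached for
   reference only: frame-quantised intervals are expected to be
   non-normal, which is exactly why the median is the headline statistic.

In the gaze-contingent scenario the green dot legitimately persists
across the LED switch (an eye is still detected); the pairing therefore
uses only the second-LED and red-dot masks, and a property test asserts
that the persisting green dot never perturbs the red intervals.

## Synthetic generators

`simulate_gaze_session()` emulates a recording: per sample the true gaze
points at the active target, is rotated by the configured per-cell offset
(radially, in a fixed direction, or in a seeded random direction),
perturbed by isotropic Gaussian noise in the tangent plane (avoiding
polar singularities and giving the RMS $\approx 2\sigma$ law), and
dropped out at a configurable per-sample rate that can differ between
head-stable and head-moving phases. Head motion is a list of
constant-rate rotation intervals that drives the HMD quaternion trace and
the ground-truth phase mask.

Two deliberate idealisations:

* **Parallel gaze.** Both simulated eyes carry the cyclopean direction
  from origins ±31.5 mm apart. Real eyes verge, and the bisector of two
  verging eye vectors deviates from the cyclopean direction by up to
  ~0.02° at 26.6° eccentricity; modelling that would make "injected
  offset = exact accuracy" only approximately true without testing any
  additional pipeline code path.
* **Instant acquisition.** No saccade dynamics; the 500 ms discard makes
  an instantaneous gaze shift indistinguishable from a realistic one to
  the pipeline.

A consequence of the noise model worth knowing when reading recovery
numbers: the mean angular error of a noisy fixation is *Rician*, sitting
above the injected offset $a$ by $\approx \sigma^2/(2a)$. At $a = 2°$,
$\sigma = 0.5°$ that is 0.02°; at $a = 0.5°$, $\sigma = 0.25°$ it is
0.06°. Accuracy-recovery tests therefore compare the pipeline against
the expected mean error under the noise model (computed by an
independent brute-force simulation), which equals the injected offset
exactly when $\sigma = 0$.

`render_frame_sequence()` emulates the camera film: flat-colour blobs
with exactly controlled pixel areas on a dark background with sparse
noise, onset frames known to the frame. Blob areas are validated against
the flag bands at construction (areas in the 250–300 px dead band are
rejected), and an optional per-frame area jitter exercises the bands'
tolerance. Realism is explicitly not the contract — mask-band compliance
and exact onset bookkeeping are.

What passing these tests shows — and does not. They establish that the
*estimators* are correct: the pipeline recovers known offsets, noise
levels, dropout rates, phases and lags from data that obeys its
assumptions. They do not establish anything about a particular headset;
real recordings add vergence, saccades, blinks, lens reflections and
asymmetric eye loss, which is precisely why the protocol exists as a
measurement to run rather than a number to assume.

## Numerical and degenerate-input choices

* `atan2`-based angles throughout; zero-magnitude vectors are a named
  error in the metric, while anti-parallel eye vectors in averaging mark
  the sample invalid instead of erroring.
* Quaternion speed clamps the inner product to 1 before `acos` and uses
  its absolute value (double cover).
* A segment with no valid samples yields `NA` metrics and is dropped from
  group statistics with a warning; fewer than two pairable samples yield
  `NA` precision; all-identical BCEA points return area 0 with a
  degeneracy flag.
* Empty LED/dot pairings raise a named error pointing at the mask
  thresholds, since a silent zero would masquerade as a perfect tracker.
* Gaze logs round-trip through CSV at 12 significant digits.

## Validation problem sizes

The shipped validation suite runs the latency worked example at full
scale (33 cycles of 1 s on / 2 s off at 8.3 ms frames, 320 × 240 px,
~12 000 frames), the lag sweep (lags 1–12) on small fast frames (96 × 72
at 30 fps — the lag in frames is independent of frame size and rate), the
offset-recovery study on one repetition of the head-still protocol (540
retained samples per target, offsets drawn in [0.5°, 8°], σ = 0.25°), and
the analytic BCEA / angle-oracle checks at $10^5$ samples.
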