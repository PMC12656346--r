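---
title: "Phase-aware swing similarity: models, parameters and design choices"
author: "dmsm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aware swing similarity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsm)
```

## The problem

Frame-wise similarity measures — cosine similarity between pose vectors at
matched frames, with or without dynamic-time-warping alignment — judge golf
swings by static postures at matched time indices. Two swings that trace the
same hand path at different tempos, or whose phases start and end at
different times, score poorly even when a coach would call them alike.

`dmsm` instead (i) segments each swing into the seven canonical phases
(address, takeaway, half, top, impact, release, finish) from kinematic cues,
and (ii) scores similarity per phase by integrating the absolute difference
between corresponding joint trajectories. The integral accumulates *path*
differences over the whole phase, so it is insensitive to frame alignment
within the phase and captures motion flow rather than isolated postures.

## Coordinate conventions

All input is 2D image coordinates from a pose estimator: origin top-left,
y increasing downward, so "the wrist is above the shoulder" means
`y_wrist <= y_shoulder`. Clips carry a handedness flag; left-handed swings
are mirrored in x (with left/right joint labels swapped) onto the
right-handed code path and all results are reported in the original frame.
The lead wrist — the left wrist for a right-handed player — is the primary
segmentation signal.

## Preprocessing

1. **Body-scale normalization.** All coordinates are divided by `s*`, the
   mean left–right shoulder distance over the address reference (the first
   10% of frames before segmentation exists, the detected address phase
   after). Skeletons of different sizes and camera distances become
   comparable; shoulder width is the unit of length everywhere below.
   Normalization deliberately leaves translation alone; address alignment
   (below) handles it.
2. **Smoothing.** A centered moving average (default window 5 frames)
   suppresses pose-estimator jitter. Edges use shrunken windows (the edge
   frame averages over the samples that exist) rather than padding: address
   and finish are static, and padding would invent data at the clip
   boundary. A consequence worth knowing: any instantaneous kinematic event
   is localized no better than about half the window, which is why the
   synthetic-recovery tests accept ±2 frames at a 5-frame window.
3. **Resampling.** Trajectory operations interpolate with a
   monotone-preserving piecewise cubic (Fritsch–Carlson Hermite spline,
   `stats::splinefun(method = "monoH.FC")`). Cubic rather than linear
   because denser, smoother samples make the phase integrals accurate in
   fast segments; monotone-preserving so no overshoot appears at the top of
   the swing. Linear interpolation remains available as a config option.
   The default working rate is 120 Hz (4× a 30 fps source); phase integrals
   use a fixed per-phase sample count instead (below).
4. **Swing-window cropping.** Long practice-range recordings are trimmed to
   2 s before and 1 s after the swing. The standalone
   `crop_swing_window()` anchors at the *onset* — the first time the
   smoothed lead-wrist speed exceeds the threshold for ≥ 3 frames. The
   automatic pipeline (`prepare_swing()`) instead anchors at the lead-wrist
   *speed peak* (mid-downswing): a window that must contain the finish
   cannot be anchored at the takeaway, since the moving phases alone span
   ~1.25 s. Clips no longer than the 3 s window are treated as already
   cropped.
5. **Address alignment.** Before comparison each clip is translated so its
   mean address-phase mid-hip sits at the origin. Together with
   normalization this makes the comparison invariant to where the player
   stood and how large they appeared in the image.

The onset speed threshold is 0.02 body-scale units per frame at 30 fps
(rescaled by 30/fps): about 2% of shoulder width per frame, which separates
setup sway from the takeaway. It is exposed in `preprocess_config()`.

## Phase segmentation

Boundaries come from an event grammar on the smoothed lead-wrist trajectory
(`y_w`, speed `v_w`) with the per-frame lead-shoulder height as reference:

| event | rule |
|---|---|
| takeaway onset | first sustained (≥ 3 frames) `v_w` above threshold |
| half onset | first backswing frame with `y_w <= y_shoulder` |
| top region | contiguous frames with `v_w` below half the onset threshold around the highest wrist point between the half onset and the downswing speed maximum |
| impact | lowest wrist point (maximum `y_w`) after the top region |
| release end | first post-impact frame with the wrist back above shoulder height |

The top is an *interval*, not a single frame, so all seven phases are
non-empty and the boundaries partition the clip exactly. Tying the top
threshold to half the onset threshold halves the free parameters. Extremum
ties are broken by the earliest frame, making segmentation deterministic.
The per-frame shoulder reference (rather than the address value) tolerates
vertical body drift during the swing. Any event missing in order raises a
segmentation error naming the first missing event; batch evaluation logs
and excludes such clips instead of failing.

## The dissimilarity measure

For one joint coordinate within one phase, with trajectories $x(t)$ and
$y(t)$ from the two clips, the phase dissimilarity is

$$DS = \int_{t_0}^{t_1} |x(t) - y(t)|\, dt,$$

approximated by the trapezoidal rule on a uniform grid — an $O(N)$ pass.
Three operational choices matter:

* **Time normalization.** Each phase's time axis is rescaled to $[0, 1]$
  (and resampled to `samples_per_phase` = 100 points) before integrating.
  Integrating over raw time would conflate tempo with path difference:
  a slower but identical backswing would accumulate spurious area. With
  normalization the integral is a pure path difference; tempo can still be
  compared via the phase durations themselves. A `time_normalize = FALSE`
  option scales the unit-interval integral back by the mean phase duration
  for users who want the raw-time reading.
* **Per-coordinate, then averaged.** The integral is defined on 1D
  trajectories; each joint's DS is the mean of its x-area and y-area. A 2D
  area between parametric curves is ill-defined for self-intersecting swing
  paths, so it is not used.
* **Joint weighting.** Per-joint DS values combine by non-negative weights
  (uniform by default). The `"biomech"` preset (wrists 2.0, hips 1.5,
  elbows and shoulders 1.0) emphasizes the hands and the hip/trunk channel;
  the exact numbers are a package choice, exposed in `similarity_config()`.
  Trunk ("spine") behaviour is deliberately *not* faked as an extra joint:
  it is measured on its own angle channel (below).

On the chosen grid the measure is the $L_1$ distance between sampled curves:
non-negative, symmetric, zero only for identical samples, and obeying the
triangle inequality — properties the test suite verifies on random
trajectories.

Because a dissimilarity in body-scale units is unbounded, reports also carry
`similarity = 1 / (1 + DS/λ)`: strictly decreasing, 1 at DS = 0, 0.5 at
DS = λ. The scale λ (default 1.0, i.e. one shoulder-width of integrated path
difference maps to 0.5) is a presentation choice; rankings are unaffected by
it.

The overall score of a clip pair is the unweighted mean of the seven phase
similarities (and the mean weighted DS on the dissimilarity scale). Each
clip is segmented by its *own* cues; no cross-clip frame alignment ever
happens.

## Baselines

Four conventional measures are implemented for benchmarking, each behind the
same configuration surface:

* **DTW + cosine** — per-frame motion vectors (concatenated per-joint
  coordinate deltas) are aligned by standard dynamic-programming DTW
  (steps (1,0), (0,1), (1,1), Euclidean local cost); the score is the mean
  cosine similarity over aligned pairs. Pairs where either vector norm is
  below 1e-9 are skipped: cosine is undefined at zero motion, and address
  frames are nearly static.
* **Euclidean** — mean per-frame RMS-per-joint distance after resampling to
  a common length, without temporal alignment or address centering;
  translation sensitivity is part of what this baseline measures.
* **Phase-wise Pearson** — mean correlation between time-normalized
  per-channel trajectories; constant channels (no motion) are excluded with
  a warning, erroring only when nothing remains.
* **Joint-angle** — mean absolute difference of elbow and shoulder interior
  angles (radians), mapped to a similarity with λ = π/6 so a 30° mean
  difference scores 0.5. Angles are similarity-invariant by construction.

## Biomechanical diagnostics

The **spine angle** is the angle between the mid-hip→mid-shoulder segment
and the image vertical, in degrees — the standard 2D surrogate for trunk
tilt. The **spine-angle delta** between two swings is the time-normalized
area between their spine-angle trajectories over takeaway..impact: the
region where trunk stability distinguishes professional from amateur
swings; including the long static finish pose would dominate the integral
with posture rather than motion. The phase range is overridable.

The **matched-frame analysis** compares the backswing and downswing hand
paths at equal heights: the frame in takeaway..half and the frame in the
top-to-impact phase whose joint height is closest to a reference (default:
the clip-mean lead-shoulder height), and the joint's *x* positions there.
Two implementation details are deliberate. First, the comparison is made in
x: the two frames are height-matched by construction, so their y values
agree up to sampling error and carry no information, while at the
shoulder-height crossing the wrist path is at its horizontal extremum,
making x robust to frame timing. Second, matching runs on the unsmoothed
sequence with 8× cubic upsampling: the moving average flattens the path
extremum asymmetrically (the downswing is several times faster than the
backswing), which would bias the x gap by far more than the effect being
measured. A gap below 0.01 body-scale units — under pose-estimator jitter —
is reported `indeterminate`; a downswing path inside the backswing path is
`downswing_lower` (the professional pattern), the converse
`backswing_lower`.

## The synthetic generator

Real swing video cannot ship with a package, so the generator produces the
cohorts every quantitative claim is tested on. One clip is: a static lower
body; a trunk whose spine angle oscillates sinusoidally (default amplitude
2°) about a 12° forward lean; and wrists on a circular arc (default radius
1.8 shoulder-widths) about the baseline-lean shoulder pivot. Within each
moving phase the arc angle progresses with cosine-eased angular velocity —
this guarantees a genuine low-speed top region and a mid-downswing speed
maximum, the two cues segmentation needs; a constant-velocity arc would
have no detectable top. The downswing hand path is shifted in x by a signed
`plane_offset` (default −0.08; negative = pro-like downswing inside the
backswing), eased in over the first third of the downswing. Ground-truth
boundaries are recorded at the parametric phase transitions, and i.i.d.
Gaussian jitter (default σ = 0.01 body units, a realistic pose-estimator
noise floor) is added under a seed, making every clip bit-reproducible.

Default phase durations are 0.9, 0.3, 0.25, 0.15, 0.25, 0.3, 0.85 s — a
3 s, 90-frame clip at 30 fps with a 2.8 backswing:downswing tempo ratio,
matching the clip geometry of consumer-camera swing datasets. The wrist-arc
pivot excludes the sway term: at the ±20° sway amplitudes used in the
trunk-stability experiments a swaying pivot would push the address-phase
wrist speed over the takeaway threshold and break segmentation; rendered
shoulders and head do sway. `top_height` is the top-of-backswing wrist y
*relative to the shoulder pivot* (default −1.6, i.e. 1.6 shoulder-widths
above the shoulders); defining it relative to the address wrist would, at
the default radius, place the top below shoulder height and make the "half"
event impossible.

`sample_player()` perturbs a base style multiplicatively (seeded Gaussian
factors, default s.d. 5%, clamped to [0.5, 1.5]) to emulate repeat swings
by one player; `benchmark_clips()` builds the standard 8-style × 4-clip
cohort spanning realistic ranges of radius, top height, plane offset, sway
and tempo.

What the generator does *not* emulate: perspective and lens distortion,
occlusion and tracking dropouts beyond short gaps, club and ball, frame-rate
jitter, or correlated (non-i.i.d.) estimator noise. Tests passing on this
cohort show the pipeline's mathematics and its noise robustness at realistic
jitter levels; they do not certify accuracy on real video.

## Statistical protocol

Cohort evaluation scores all unordered clip pairs and classifies them
same-player vs cross-player. The class difference in mean dissimilarity
("separation") is tested with Welch's two-sample t — the two classes are
not paired observations, so a paired test is not defined there. Pairing *is*
well defined across methods (identical pair lists), and
`method_comparison()` uses a paired t-test on per-pair similarities against
the reference method. Normality is checked per class with Shapiro–Wilk,
effect size is Cohen's d with pooled s.d., and the separation gets a seeded
percentile-bootstrap 95% CI (default 2000 replicates). All randomness is
seed-controlled; repeated runs are bit-identical.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 100-sample phase grids;
10001-sample grids for the analytic integral check (error ~2e-8 against
2/π); 100 noisy swings (σ = 0.01) for boundary recovery plus 25 per noise
level for the degradation sweep; the 32-clip benchmark (496 pairs) for
discrimination; 20-seed sweeps for the matched-frame direction; and
5-amplitude perturbation sweeps with σ = 0 so the response to the injected
path difference is isolated from estimator jitter. Tolerances follow the
quantity: 1e-9 for round trips and exact identities, 1e-6 for
scale/translation invariance, 1e-12 slack on floating-point metric
inequalities.

Degenerate inputs are errors, not guesses: overlapping shoulders (no body
scale), coincident hip and shoulder midpoints (no spine direction),
zero-length limb segments (no interior angle), motionless clips (no swing),
and reference heights the path never approaches (no matched frame).

## Known limitations

* Side-view 2D only; out-of-plane rotation folds into the planar angles.
* The event grammar assumes one swing per clip; multiple swings require
  cropping first.
* The similarity scale λ is a presentation constant, not calibrated against
  human ratings; only orderings and separations are interpretable across
  configurations.
* Absolute similarity values depend on the joint set and weights; compare
  values only within one configuration.
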