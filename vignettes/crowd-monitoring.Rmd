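---
title: "Pose-based social-distance estimation and crowd monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-based social-distance estimation and crowd monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

crowdwatch turns per-frame 25-joint pose detections from a fixed
surveillance camera into privacy-preserving crowd analytics: metric ground
positions, smoothed trajectories, social-distance violations, occupancy and
crowd density maps, and overcrowding segmentations. This vignette explains
the models behind each stage, the tunable parameters, and the design
decisions taken where the problem left genuine freedom.

```{r setup, message = FALSE}
library(crowdwatch)
```

## The pipeline at a glance

Each frame passes through the same stages:

1. **Localization** — each detected skeleton is reduced to one ground
   anchor `(u, v)` in image pixels, with an error-state flag.
2. **ROI filter** — anchors outside the user-drawn region of interest are
   discarded.
3. **Top-view transform** — remaining anchors are mapped to metric ground
   coordinates through the camera's ground-plane homography.
4. **Smoothing/tracking** — a flag-adaptive Kalman filter plus a global
   nearest-neighbor (GNN) tracker denoise positions and bridge occlusions.
5. **Analytics** — pairwise distances, violation counts, the binary
   anomaly label, and Gaussian-kernel density maps.

Every stage is an exported function operating on tibbles, so the stages can
also be run (and serialized) independently.

## Localization and error-state flags

The anchor is the midpoint of the feet: it lies on the ground plane (so a
homography applies), it is insensitive to the subject's height and width,
and it carries no identifying information. Joints follow the 1-based
BODY_25 layout (2 = neck, 9 = mid-hip, 10/13 = hips, 11/14 = knees,
12/15 = ankles, 20–22/23–25 = left/right toe, small-toe, heel).

The *basic* estimator requires at least 13 present joints and at least one
foot joint; `u` is the mean of the present nose/neck/mid-hip abscissae (or
the mid-range of all abscissae) and `v` the mean of the present feet
ordinates. Those requirements make it fail exactly when information becomes
scarce, which is when an estimate is most valuable.

The *proposed* estimator instead walks an ordered case list. For `u`:
both-feet average first (flag 1), then knee/hip/torso pair averages and a
single-side feet fallback (flag 2), else flag 0. For `v`: the feet mean
(flag 1); otherwise, with neck and mid-hip visible, a torso-length
extrapolation (flag 2):

$$v = v_9 + \frac{0.85}{0.6}\,(v_9 - v_2),$$

using the average human torso : lower-body ratio of 0.6 : 0.85. The cases
are evaluated strictly in order; the first match wins. The per-coordinate
flags combine into an overall flag: undefined dominates, then 0, then 1
(both coordinates feet-based), else 2.

**Sign of the extrapolation.** Written with the opposite difference,
$v_9 + (0.85/0.6)(v_2 - v_9)$, the formula places the inferred ground
*above* the hip whenever the neck is above the hip in image coordinates
(where v grows downward) — geometrically impossible for a standing person.
We therefore use the form above, which extends the torso direction past the
hip by the leg length; `localize_frames(torso_sign = -1)` reproduces the
other sign for comparison.

**Presence threshold.** Detectors attach confidences to joints but no
canonical threshold exists; `read_pose_frames()` treats confidence
strictly greater than 0 as present and exposes the threshold.

## Geometry

The simulator's camera is a standard pinhole: `[u, v, 1]ᵀ ∝ (1/αs) K [R |
T0] [x, y, z, 1]ᵀ` with the perspective division, where `αs` is the
image-to-real scale. Restricted to the ground plane (z = 0), projection
reduces to the 3 × 3 homography `H = K [r1 r2 T0] diag(αs, αs, 1)` mapping
metric top-view coordinates to pixels; the pipeline applies `H⁻¹` and
normalizes the homogeneous result before scaling to metres. The
normalization matters: a general `H` is projective, and the division by the
third homogeneous component is what makes the round trip exact (to 1e-9 in
the test suite). Points whose divisor vanishes lie on the ground-plane
horizon and raise an error rather than returning garbage. Calibration files
that store the image-to-world direction can be ingested with
`scene_config(..., inverse_convention = TRUE)`.

ROI membership is boundary-inclusive (a closed polygon), so positions on
the ROI edge are kept.

## Smoothing and tracking

Each track carries the state `x = [x, ẋ, y, ẏ]` (metres, metres/frame)
under a constant-velocity model with unit frame step. The process noise is
the discrete white-acceleration model, `q·[[1/3, 1/2], [1/2, 1]]` per axis,
with intensity `q` (default 0.05 m²/frame³) — the standard choice when only
"nearly constant velocity" is known about pedestrian motion.

The measurement is the top-view position, with isotropic variance keyed to
the localization flag: `sigma1_sq` (flag 0), `sigma2_sq` (flag 1, default
0.04 m²) and `sigma3_sq` (flag 2, default 0.25 m²). Feet-based positions
thus pull the filter harder than fallback-joint positions, and a missing
measurement performs no correction at all — the filter coasts on its
prediction. Flag-0 detections carry no coordinates; they contribute nothing
to correction and, since they cannot be associated to a specific track
without a position, they do not affect the lifecycle either. The
`sigma1_sq` slot is used only if a future partial-coordinate policy
supplies coordinates for flag-0 detections.

Association is global nearest neighbor: the cost of pairing detection and
track is `D + log det(S)`, with `D` the Mahalanobis distance of the
innovation and `S` the innovation covariance using the detection's
flag-adaptive variance; pairs with `D² > gate` are infeasible (the gate is
inclusive at equality). The optimal one-to-one assignment is found with a
Jonker–Volgenant shortest-augmenting-path solver written for this package
and cross-checked in the tests against exhaustive permutation enumeration.
Ties between equal-cost optima resolve to the stable lowest-index solution;
no randomness is involved. A switch (`literal_r_split`) reproduces the
variant in which the cost's log-determinant uses the track's previous
measurement variance while the gate uses the detection's.

**Track score.** Lifecycle decisions need a scalar track quality. We use a
cumulative log-likelihood *ratio*: an assigned measurement adds
`log N(innovation; 0, S) − log c`, with `c` a uniform clutter density
(default 0.01 m⁻²), and a missed frame adds `miss_penalty` (default −2).
The ratio form — rather than the raw log-density — is deliberate: the raw
Gaussian log-density is negative for any realistic measurement scale, so a
perfectly tracked target would drift monotonically toward deletion under a
drop-from-maximum rule. Normalizing by the clutter density makes good
associations raise the score and poor ones lower it, which is the classical
track-scoring construction, and keeps the signs of the thresholds
meaningful: tracks confirm when the score exceeds `confirm` (> 0; a
negative value confirms at birth) and die when the score falls more than
`|delete|` below its running maximum. Newborn tracks start at score 0 with
velocity 0 and covariance `diag(σ², v0², σ², v0²)` (`v0` default
2 m/frame); tentative tracks that miss more than `init_patience` frames
(default 3) are dropped.

A confirmed track whose position leaves the ROI is demoted to tentative,
keeps its id, and has its score reset to `confirm/2`, so re-entering
subjects must re-confirm. Only confirmed tracks are reported downstream,
and the report contains kinematics and flags only — no appearance or
identity features, which is the pipeline's privacy contract.

Reference per-sequence parameter presets are shipped via
`tracker_preset()` ("6p-c0" … "C7"); their scales belong to the original
tuning tool's score, so they are starting points rather than ground truth
for this implementation's score scale. `tune_tracker()` re-tunes the six
lifecycle/variance parameters on ground-truthed scenes by seeded random
search, always evaluating the starting parameters first so tuning can never
lose to the defaults.

## Crowd analytics

Violations are inclusive: a pair violates when its Euclidean top-view
distance is at most the safety distance `r` (default 2 m). The violation
count `V_t` counts *pairs*; the per-subject mask ψ marks subjects belonging
to at least one violating pair, and their count is reported separately as
`violators`. The anomaly label is simply `V_t > 0`.

Density maps place a unit-mass isotropic Gaussian kernel,

$$G(x, y) = \frac{1}{2\pi\delta^2} \exp\!\left(-\frac{x^2 + y^2}{2\delta^2}\right),$$

at each subject position, weights it by 1 (occupancy map, ODM) or ψ (crowd
map, CDM), averages over the subjects present, and then averages over
frames 1..T; frames without subjects contribute zero maps and still count
in T. The bandwidth δ (`map_resolution`, default 1 m) sets the spatial
resolution of the maps; the grid is evaluated at cell centres with 0.1 m
cells by default. The kernel's unit mass is a requirement, not a
convenience: it makes the single-subject instantaneous map integrate to 1
(checked to within 1% discretization error) and the CDM cell-wise bounded
by the ODM.

Overcrowding segmentation thresholds the averaged CDM at the value γ that
keeps 50% of the map's mass. Cells are ranked in stable descending order
and the smallest prefix whose cumulative mass reaches half the total is
retained. On tied maps this keeps the retained fraction within one cell's
share of 50% — an all-tied (uniform) map retains half its cells, not all of
them — and makes the segmentation deterministic. "Mass" is the plain sum of
cell values; the retained fraction and γ are attached to the result as
attributes.

## Evaluation metrics

With `N_t`/`N̂_t` the true/estimated per-frame person counts and
`V_t`/`V̂_t` the violation counts:

* **PDR** `= 1 − mean(|N_t − N̂_t| / (N_t + 1))`, and **VCR** the same form
  on violation counts.
* **Localization error**: per frame, estimates are associated to truth by
  the same optimal assignment used in tracking (no gate), and the frame
  term is the mean of `‖p − p̂‖ / ‖p‖` over matched pairs plus a penalty:
  `N_t` when nothing was estimated, `N̂_t` when nothing was true, else
  `|N_t − N̂_t| / N_t`. Frames empty on both sides contribute 0 (the
  formula's "otherwise" branch would divide by zero, and an empty frame
  matched by an empty estimate is perfect). Because the relative error
  normalizes by the true position's norm, a subject at the world origin
  would divide by zero; an ε of 1e-9 m guards the denominator. The
  origin-dependence is a property of the metric, which we keep for
  comparability.
* **Violation detection**: accuracy, precision, recall and F1 of the
  per-frame anomaly labels.
* **Map agreement**: Pearson correlation across the flattened averaged-CDM
  cells (NA with a warning when a map has zero variance) and the IOU of the
  two 50%-mass regions; two empty regions count as IOU 1.

`evaluate_run()` reports all of these for one safety distance or for the
guideline sweep `r = 1, 1.05, …, 2.5` m (31 values).

## The synthetic scene generator

External surveillance footage cannot ship with a package, so every stage is
exercised against simulated scenes with exact ground truth. The generator
emulates the failure modes the pipeline is designed for:

* **Motion**: near-constant-velocity walks — headings and Gaussian speeds
  (default 0.12 ± 0.03 m/frame, i.e. ~1.2 m/s at 10 fps) redrawn with
  probability `turn_rate` (default 0.02) per frame, reflected at the arena
  boundary (default 12 m × 10 m).
* **Bodies**: 25-joint stick figures with leg length 0.85 and torso 0.6 of
  the stature unit — exactly the ratio the torso fallback assumes, so the
  fallback's geometry is testable on clean data.
* **Camera**: a pinhole at (6, −8, 6) m looking at the arena centre, focal
  800 px on a 1280 × 960 image; the scene's homography is derived from the
  same camera, so simulator and pipeline share one geometry by
  construction.
* **Degradation**: i.i.d. Gaussian pixel noise on every joint, independent
  per-joint dropout, and structured occlusion rectangles in the image
  (`standard_occluders()` provides a full-height pillar plus a feet-height
  band for the default view) that swallow every joint inside them.
  Subjects losing all joints in a frame disappear from it entirely.

One deliberate geometric property: paired limb joints are placed
symmetrically along the ground direction in which camera depth is constant.
Points along that direction share the homogeneous divisor, so the mean of
the two projected feet *is* the projection of the ground point, exactly.
Noiseless scenes are therefore recovered to floating-point precision
through the entire pipeline, which turns the end-to-end recovery test into
a sharp check of the geometry rather than a tolerance negotiation. The
torso fallback, by contrast, mixes joints at different heights (different
depths) and is exact only for an affine camera — which is precisely why
fallback positions carry a worse flag and a larger measurement variance.

What the simulator does **not** emulate: pose-estimator confusion between
nearby people (swapped or merged skeletons), correlated joint noise,
non-pedestrian detections, rolling-shutter or lens distortion, and
appearance of new subjects mid-sequence. Passing the synthetic suite
therefore demonstrates the correctness of the pipeline's mathematics and
its robustness to noise, dropout and occlusion — not performance on any
particular real camera.

Scenes are deterministic functions of their integer seed: the trajectory
stage and the rendering stage draw from seeded generators (offset so they
do not replay each other's stream), and repeated simulation writes
byte-identical files.

## Numerical choices and problem sizes

* Covariances are re-symmetrized after every filter step; the tests assert
  eigenvalues ≥ −1e-9.
* Homogeneous divisions below 1e-12 raise degeneracy errors.
* The assignment solver treats infeasible (gated) pairs as a large finite
  penalty and strips them from the result, which maximizes the number of
  feasible matches before minimizing cost.
* Boundary conventions: violation at `d = r` counts; gating at `D² = gate`
  passes; ROI boundary is inside.
* The test suite runs scenes of 3–5 subjects and 20–200 frames; the
  tracking-gain comparison uses 20 seeded scenes of 150 frames with 3 px
  noise, 30% dropout and the standard occluders, and the acceptance script
  averages five such scenes. These sizes were chosen to exercise every
  code path with stable statistics while keeping the suite quick to run.

## Limitations

* The localizer assumes roughly vertical subjects; body orientation is not
  estimated, so sitting or lying poses degrade the anchor.
* Tracking bridges occlusions only as long as the score survives the
  drop-from-maximum rule; subjects occluded longer than
  `|delete| / |miss_penalty|` frames are re-initiated as new tracks (no
  re-identification, by design).
* The localization error metric is origin-dependent (it normalizes by the
  true position norm); comparisons are only meaningful within one scene
  coordinate frame.
* Table-style parameter presets transfer the original sequences' variances
  but not their score thresholds' scale; re-tune on your own footage with
  `tune_tracker()`.
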