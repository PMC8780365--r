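# crowdwatch

Privacy-preserving social-distance estimation and crowd monitoring from
pose detections, in R.

Surveillance analytics that track *people* raise obvious privacy problems:
robust trackers usually work by carrying appearance features. crowdwatch
implements the alternative: each detected person is reduced to a single
anonymous **ground anchor** — the midpoint of their feet, estimated from a
25-joint (BODY_25) skeleton — and everything downstream operates on those
anonymous points. The package is aimed at public-health and facility
analysts who have pose detections from a calibrated fixed camera and want
per-frame distance violations, occupancy patterns and overcrowding regions
without storing anything person-specific.

## What it computes

Given per-frame poses `J_m = {(u_mj, v_mj)}` (possibly with many missing
joints), a scene ROI polygon, and a ground-plane homography `H` with scale
`α_s`:

1. **Localization with error-state flags.** An ordered fallback cascade
   estimates the anchor from feet, knees, hips or torso joints. Each
   coordinate carries a flag: 1 = feet-based, 2 = inferred (e.g.
   `v = v₉ + (0.85/0.6)(v₉ − v₂)` from the torso length), 0 = unresolvable,
   undefined = not detected.
2. **Top-view transform.** `[x, y]ᵀ = α_s · norm(H⁻¹ [u, v, 1]ᵀ)` maps
   anchors to metres on the ground plane.
3. **Flag-adaptive tracking.** A constant-velocity Kalman filter whose
   measurement variance σ² is keyed to the flag, plus a global
   nearest-neighbor tracker (gated Mahalanobis cost `D + log det S`,
   optimal Munkres-style assignment) with an explicit track lifecycle
   (tentative → confirmed → demoted/deleted).
4. **Crowd analytics.** Pairwise distances `d_ij`; violations `d_ij ≤ r`;
   anomaly label `S_t = 1[V_t > 0]`; occupancy and crowd density maps as
   time-averaged unit-mass Gaussian mixtures
   `G(x,y) = (2πδ²)⁻¹ exp(−(x²+y²)/2δ²)`; overcrowded regions as the
   cells holding the top 50% of crowd-map mass.
5. **Evaluation.** Person detection rate `PDR = 1 − mean |N−N̂|/(N+1)`,
   Munkres-matched relative localization error, violation
   accuracy/precision/recall/F1, violations count rate (VCR), crowd-map
   Pearson correlation and region IOU — per safety distance or swept over
   r = 1–2.5 m.

A seeded synthetic scene generator (constant-velocity pedestrians,
articulated stick figures, pinhole projection, pixel noise, joint dropout,
structured occluders) provides ground-truthed data for every stage, so the
whole pipeline is testable without video.

## Worked example

```r
library(crowdwatch)

# a noisy, occluded synthetic scene: 5 pedestrians, 150 frames,
# 3 px joint noise, 30% joint dropout, a pillar and a feet-height band
sim <- simulate_scene(sim_config(n_subjects = 5, n_frames = 150,
                                 px_noise = 3, p_drop = 0.3,
                                 occluders = standard_occluders(),
                                 seed = 42))

run <- run_pipeline(sim$poses, sim$scene)
run
#> <crowd_run> 150 frames, 6 subjects/tracks, method 'proposed', tracking TRUE
#>   anomaly frames: 76 of 150 (r = 2 m)

evaluate_run(run, sim$truth, r = 2)
#>   r   pdr loc_error accuracy precision recall    f1   vcr  corr   iou
#> 1 2 0.887     0.211    0.733     0.987  0.658 0.789 0.744 0.941 0.605
```

Reading the numbers: the tracker reports the right number of people 88.7%
of the time (`pdr`), matched positions are off by 21% of their distance
from the scene origin on average (`loc_error`, inflated here by coasting
through the pillar), violation frames are detected with high precision
(0.987) but reduced recall (0.658) because fully occluded subjects cannot
contribute to pair distances, and the predicted crowd density map
correlates 0.941 with the ground-truth map. `autoplot(run)` draws the
tracked trajectories over the crowd map; `tidy(run)` and `glance(run)`
give the per-frame table and a one-row summary.

A thin CLI wraps the same functions
(`exec/crowdwatch simulate|run|evaluate|tune`).

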