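---
title: "Tracking two microsurgical instruments by detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking two microsurgical instruments by detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duotrack)
```

## The problem

In robot-assisted microsurgery (for example vessel anastomosis performed
with a dedicated two-arm robotic platform), a camera observes at most two
elongated instruments. An object detector proposes axis-aligned bounding
boxes with confidence scores on every video frame, but a detector alone has
no notion of identity: it cannot say which box is the left arm and which is
the right arm, it occasionally misses an instrument (motion blur, specular
reflections, occlusion), and it occasionally hallucinates a box. `duotrack`
implements the *data-association* stage that turns such per-frame detections
into two identity-consistent, temporally smooth tracks, plus the evaluation
metrics and a synthetic scene generator so the whole pipeline is testable
without video or a trained network.

The scene model makes two assumptions that the scheme relies on: the two
instruments are **not crossed in the first frame** (so left/right identity
is well defined at the start), and instruments **never enter the field of
view from the top border** (they approach from the sides or from below, as
the surgeon's manipulators do).

## The pipeline

Each frame passes through two stages.

### Filtering

1. Detections with confidence below `confidence_threshold` (default 0.5)
   are discarded.
2. The candidate list is clipped to at most `max_instances` (default 2)
   boxes using a position rule, a size rule, and a confidence tie-break:
   a box contacting only the top border is discarded (an instrument cannot
   hang from the top); a box larger than `max_area_fraction` (default 0.5)
   of the frame is discarded (an instrument tip never fills half the
   frame); if more than two candidates remain, the most confident ones are
   kept. The position and size rules are stated qualitatively by the design
   this package follows; the concrete operationalization (top-only contact,
   the 0.5 area fraction, confidence tie-break with left-edge distance as
   the secondary key) is this package's choice and every constant is
   exposed in `filter_config()`.

### Association

* **Initial identity.** ID 1 is the left arm and ID 2 the right arm. With
  one detection, ID 1 is assigned; with two, ID 1 goes to the box with the
  smaller distance from the frame's left edge. An exact tie (possible
  because the distance is measured to the box's left extent) is broken by
  the leftmost centre, making the rule total.
* **Matching.** When the numbers of live tracks and detections agree, the
  assignment maximizing total IoU is taken (with at most two objects the
  two candidate pairings are compared directly; no assignment solver is
  needed, and greedy equals optimal in the mismatched case too). An exact
  tie preserves the existing left/right ordering.
* **Smoothing.** A matched track's box becomes the convex combination
  `box <- alpha * box_prev + (1 - alpha) * detection` with
  `alpha = IoU(box_prev, detection)`. Large overlap (slow motion) therefore
  damps detector jitter strongly, while low overlap (fast motion) lets the
  new detection dominate; disjoint boxes give `alpha = 0`, i.e. the
  detection is adopted unchanged. "Proportional to the IoU" is implemented
  as equality; the weight and the whole mechanism are configurable
  (`alpha_mode`, `smoothing_enabled`) for ablation.
* **Missed detections.** Every track carries a Kalman filter. When a track
  has no matching detection, its predicted box is emitted instead, so short
  detector dropouts do not interrupt the track.
* **Edge exit.** A coasting track is deleted when its predicted box touches
  an image border, its estimated velocity points outward through that
  border, and the contact has lasted more than `max_edge_frames = 2`
  consecutive frames, i.e. deletion occurs exactly on the third consecutive
  outward-contact frame. Contact with inward motion never deletes: an
  instrument resting against a border while moving back into the scene is
  kept indefinitely. On deletion, the last *real* detection (never a Kalman
  extrapolation) is stored together with the ID.
* **Re-tracking.** An unmatched detection is first tested against the
  stored deleted tracks: if its IoU with a stored box is positive, or it
  lies in the same vertical half of the frame, the old identity is
  reclaimed. Candidates are ranked by overlap, then by distance, which also
  fixes the behaviour when both arms have left the scene and one returns
  (nearest stored box wins — a package decision; the underlying scheme does
  not address simultaneous double exits). Otherwise a new track is created
  with the lowest free ID, and if the creation leaves ID 1 to the right of
  ID 2 the labels are swapped so ID 1 is always the leftmost instrument.
  This correction applies at creation time only and never rewrites frames
  already emitted.

### The Kalman filter

The motion model is a constant-velocity filter on the 8-dimensional state
`(x, y, w, h, vx, vy, vw, vh)`; the observation selects `(x, y, w, h)`.
The description this package implements calls the transition matrix 4x4
*and* constant-velocity, which is internally inconsistent — a 4-state
filter cannot carry velocity. The constant-velocity reading is the default
because the edge-exit rule needs a velocity estimate ("motion converging
toward the edge"); a literal 4-state random-walk filter is available as
`kalman_config(mode = "random_walk")`, with the caveat that its zero
velocity estimate disables the outward-motion test. Process and measurement
noise are both interpreted as a standard deviation of 2 px (variances 4 px²
on every state), reflecting few-pixel localization error and small
deviation from linear motion. At initialization the velocity prior variance
is inflated 10x over the position variance so the first corrections
dominate the unobserved velocities; covariance updates use the Joseph form.
The filter is corrected with the **raw** detection, not the smoothed box,
so smoothing cannot feed back into the motion model (double filtering).
`dt` is fixed at 1 frame.

## Evaluation metrics

Ground truth and hypotheses are matched per frame by maximum total IoU
among pairs with IoU at least 0.5 (the community default; the threshold is
an argument). Then:

* `MOTA = 1 - (sum FN + FP + IDSW) / sum GT`. Identity switches are counted
  per object per change of matched hypothesis ID (the CLEAR convention); a
  detection gap alone is a false negative, not a switch.
* **MOTP** is implemented in two explicitly separate forms, because the
  printed definition this package follows normalizes the accumulated
  true-positive IoU by the number of *frames* — under which a perfect
  two-instrument video scores 2.0 — while the values reported alongside it
  (about 0.74) are only consistent with the usual per-*match* normalization.
  `motp()` is the frame-normalized form exactly as printed; `motp_per_match()`
  is the CLEAR form. Neither is silently substituted for the other.
* **MSCAV** (mean of the sum of consecutive area variation): for each frame
  transition, every identity present in both frames contributes its
  relative area change `(A_t - A_{t-1}) / A_{t-1}` with `A = w * h`;
  contributions are summed per transition and averaged over the
  `n_frames - 1` transitions (the sum range is read as running over
  transitions). The metric is signed; distance from zero measures box-area
  oscillation, which is what the IoU-weighted smoothing is designed to
  suppress.

## The synthetic world

`scenario_config()` states the simulated conditions once; tests never tune
them toward a result. Defaults: 250 frames (an 8 s video at ~30 fps),
640x480 px frame, two 40x120 px boxes (aspect ratio 3: elongated
instruments), speed 2 px/frame, detector jitter std 2 px on each of
x, y, w, h, dropout probability 0.05, 0.1 spurious detections per frame
(half biased toward the borders to exercise the positional discard), and
confidence scores from a clipped Gaussian N(0.9, 0.05). Frame size, speed,
dropout and false-positive rates are this package's choice of realistic
detector behaviour for this setting; the video length matches the stated
test conditions and the jitter matches the filter's few-pixel noise
assumption.

Instrument 1 starts at 30% of the frame width, instrument 2 at 70%, both at
60% height — never crossed, never touching the top. Motion is linear (with
reflection), sinusoidal, or piecewise-linear per instrument; interior
trajectories keep a 10 px buffer from every border so that edge contact
happens only during scripted exit events. An exit/re-entry event steers the
instrument to the nearest of the left/right/bottom borders over the 10
frames before the exit (the detector still sees it, partially, while it
leaves), removes it for the gap, and re-inserts it touching the border of
the requested half moving inward. All randomness flows from one seed
through four independent sub-generators (jitter, dropout, false positives,
confidences), so an ablation that toggles smoothing sees the identical
detection stream.

What the generator does **not** emulate: appearance (no pixels are
rendered), occlusion between the instruments, correlated or non-Gaussian
detector noise, aspect-ratio changes as the tool articulates, and detector
confidence that degrades near the image border. A green test on this world
therefore establishes the logic of filtering/association/metrics, not
detector-grade performance on surgical video; the headline numbers of the
original setting (MOTA ~0.99, per-match MOTP ~0.74 on ten private surgical
videos with trained CNN detectors) are not reproducible here and are not
asserted anywhere.

## Numerical and degenerate-input choices

* Boxes are real-valued; widths/heights must be strictly positive, and the
  Kalman box estimate floors w and h at 1 px.
* `frame_half` assigns the exact midline to the left half; `touches_edge`
  uses a configurable contact tolerance (`edge_margin`, default 1 px) since
  exact contact is meaningless for real-valued boxes.
* Equal-confidence clipping ties prefer the smaller left-edge distance,
  mirroring the ID-1 preference; all matching ties preserve left/right
  order.
* Deleted tracks are retained for the remainder of the video by default
  (`deleted_max_age = Inf`); an interior track that stops being detected
  coasts indefinitely, since only edge exit deletes — the scheme assumes
  instruments leave through borders.
* MOTA is undefined (error) without ground truth; frame-normalized MOTP is
  undefined without frames; MSCAV requires two frames and positive areas.

## Verifying the headline behaviour

The acceptance suite (`tests/testthat/test-acceptance.R`) checks, among
others: perfect input gives MOTA exactly 1 with zero switches; matching
agrees with brute-force assignment enumeration on 1,000 random IoU
matrices; the Kalman one-step prediction error drops below 0.5 px within 5
cycles on a noiseless constant-velocity target and a 3-frame dropout does
not break identity; the smoothed box always lies in the componentwise
envelope of its inputs and reproduces the worked example
`prev = (0,0,4,4), curr = (2,0,4,4) -> (4/3, 0, 4, 4)`; across 20 seeds at
jitter 2 px/dropout 0.05 the MSCAV magnitude with IoU-weighted smoothing is
below the unsmoothed value on every seed and its across-seed variance is
smaller (the direction of the smoothing ablation); exit/re-entry scenarios
reclaim the original identity in 20/20 seeds (the scripted scenarios set
the false-positive rate to zero — a spurious border box during the absence
could legitimately reclaim the stored ID first, which is detector
robustness, not the re-tracking rule under test); and the edge-exit rule
deletes exactly on the third outward-contact frame while inward contact is
retained.

```{r example}
cfg <- scenario_config(n_frames = 100, seed = 7)
sim <- simulate_scene(cfg)
run <- track_stream(sim$detections, cfg$geometry)
evaluate_tracking(sim$gt, run$records)
```

## Known limitations

* At most two instruments; a third simultaneous object is rejected
  upstream by clipping (and an over-capacity condition is an error, not a
  silent drop).
* No appearance model: re-tracking relies on geometry (overlap/half), so
  two instruments that swap sides entirely while both are out of view can
  re-acquire swapped identities.
* The random-walk Kalman mode cannot drive the outward-motion edge test.
* Equal-count matching assigns all pairs even at zero overlap (by
  definition of the scheme), so a simultaneous dropout-plus-false-positive
  can momentarily teleport a track; it recovers on the next frame with a
  real detection.
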