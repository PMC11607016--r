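# duotrack

Tracking-by-detection for **two robotic microsurgical instruments**. A
neural detector proposes per-frame bounding boxes with confidence scores;
`duotrack` supplies everything downstream of it: filtering the raw
detections, assigning the persistent identities *ID 1 = left arm,
ID 2 = right arm*, matching detections to tracks by IoU, smoothing matched
boxes, carrying missed detections with a constant-velocity Kalman filter,
deleting tracks that leave through an image border, re-acquiring
instruments that re-enter the scene, and scoring the result with
CLEAR-MOT-style metrics. A synthetic scene generator makes the whole
pipeline testable with no video, no trained network, and no downloads.

## The method in brief

Per frame, detections below confidence 0.5 are dropped and the list is
clipped to at most two candidates (no instrument may hang from the top
border; none may fill more than half the frame). Matched track boxes are
smoothed by

```
box_i = alpha * box_{i-1} + (1 - alpha) * box_i,   alpha = IoU(box_{i-1}, box_i)
```

so slow motion (high overlap) is heavily damped while fast motion passes
through. A per-track Kalman filter on the state `(x, y, w, h, vx, vy, vw, vh)`
with process and measurement noise of 2 px fills detection gaps; a coasting
track touching a border with outward velocity for more than two consecutive
frames is deleted, and its last real box is stored. A detection that cannot
be matched reclaims a stored identity if it overlaps the stored box or lies
in the same vertical half of the frame; otherwise it becomes a new track
with the lowest free ID, relabelled if needed so ID 1 stays leftmost.

Evaluation: `MOTA = 1 - (FN + FP + IDSW) / GT`; MOTP in two explicit
normalizations (per frame, as the definition this package follows prints
it, and per match, the usual CLEAR form — see the vignette for why both
exist); and MSCAV, the mean over frame transitions of the summed relative
box-area change, a signed stability measure that the IoU-weighted smoothing
is designed to pull toward zero.

## Worked example

```r
library(duotrack)

cfg <- scenario_config(n_frames = 250, seed = 1)   # 640x480, jitter 2 px,
sim <- simulate_scene(cfg)                         # 5% dropout, 0.1 FP/frame
run <- track_stream(sim$detections, cfg$geometry)
evaluate_tracking(sim$gt, run$records)
```

```
Tracking evaluation
  MOTA            : 0.9960
  MOTP (per frame): 1.6781
  MOTP (per match): 0.8407
  MSCAV           : +0.00274
  FN 1 | FP 1 | IDSW 0 | GT 500 | frames 250
```

Of 500 ground-truth instrument instances, one was missed and one spurious
box survived (MOTA 0.996), with no identity switch. Per-frame MOTP near 2
means both instruments were matched in almost every frame at high IoU
(0.84 per match: the smoothed box trails a moving instrument slightly).
MSCAV of +0.003 says box areas fluctuate by ~0.3% per frame on average;
rerunning with `config = tracker_config(smoothing_enabled = FALSE)` gives
+0.008 on the same detections — the smoothing ablation direction.

## Command line

```sh
Rscript inst/cli/duotrack.R simulate --seed 2 --out-dir sim/
Rscript inst/cli/duotrack.R track --dets sim/det.csv --width 640 --height 480 \
        --out sim/trk.csv --summary sim/run.json
Rscript inst/cli/duotrack.R evaluate --gt sim/gt.csv --hyp sim/trk.csv --out sim/report.json
```

Streams are CSV with header `frame,id,x,y,w,h,conf`, centre-based xywh
coordinates, frames 1-based, id −1 for raw detections;
`to_motchallenge()` / `from_motchallenge()` convert to the corner-based
MOTChallenge layout. `--no-smoothing`, `--alpha-mode`, `--kalman-mode
{cv,random-walk}` expose the ablation switches.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
simulate a default scenario at the given seed, track it, evaluate against
the simulated ground truth, and report the smoothing ablation — and writes
its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

See the methods vignette (`vignettes/instrument-tracking.Rmd`) for the
model, its assumptions, every tunable parameter with units and defaults,
what the synthetic world does and does not emulate, and known limitations.
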