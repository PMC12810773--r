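---
title: "Multi-view cattle behavior recognition: association, fusion and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view cattle behavior recognition: association, fusion and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowfuse)
```

## Scope and model

`cowfuse` implements the post-detector half of a two-camera cattle
monitoring system aimed at estrus detection. The upstream half — the
object detectors that produce per-frame cow-identity boxes and behavior
boxes for each view — is deliberately out of scope; the package consumes
their output as detection streams and is agnostic to how they were
produced. Six behaviors are scored: `stand`, `lie`, `eat`, `drink`,
`chin_rest` and `ride`, the last two being the estrus-related positive
class of the binary evaluation.

The pipeline has three stages.

**Association.** Within one view and one frame, each cow's identity box
is compared by Intersection-over-Union against every behavior box. The
max-IoU behavior box is assigned to the cow provided its IoU *strictly*
exceeds the threshold τ. Two fallback branches keep the per-cow timeline
total: if the cow's identity box exists but no behavior box clears τ,
the behavior is uncertain and the previous frame's behavior is carried
forward (`fallback_low_iou`); if the identity detector missed the cow
entirely, likewise (`fallback_missing`). Before a cow's first match the
timeline holds an explicit `unknown` sentinel (excluded from
evaluation) rather than an invented behavior; users who prefer a
concrete prior can select the `fixed_label` initial policy. Association
is causal by construction: an entry depends only on the current frame's
detections and the threaded previous state, a property the test suite
checks directly by editing frames and asserting the past is untouched.

**Fusion.** The ensemble is decision-level: it operates on the two
views' *association outputs*, not on boxes or scores, and
fallback-sourced labels are fused exactly like matched ones. The front
view's label wins by default; for the (top, front) pairs in the override
table — by default `(stand, drink)` and `(stand, chin_rest)` — the top
view's label wins. These two pairs target the front view's documented
failure modes: cows merely standing near the water trough read as
drinking, and standing cows occluded by rear-to-front alignment read as
chin-resting. Alignment occlusion can also produce a spurious `ride`,
but the fusion rule is kept to the two-pair form; `(stand, ride)` is not
in the default table, and the table is a configuration object so users
can add it without code changes. Frames where only one view has
information use the informative view (`single_view`); where neither
does, the result stays `unknown` (`both_unknown`). Both cases are our
addition — a fusion rule must be total over sentinels — and are flagged
in `rule_applied` for auditability.

**Evaluation.** Predictions are scored per (cow, frame) against ground
truth, binarized into estrus (`ride`, `chin_rest`) versus non-estrus,
with estrus as the positive class. `precision = tp/(tp+fp)`,
`recall = tp/(tp+fn)`, `f1 = 2tp/(2tp+fp+fn)`; any metric with a zero
denominator is reported as 0 and named in an `undefined` attribute so
the convention is never silent. A `sampling_interval` stride evaluates
every k-th frame, because frame-level scoring at camera rate is only one
of several defensible evaluation units for long recordings; the default
is 1 (every frame). One-vs-rest per-behavior F1 uses the same
conventions, flagging behaviors absent from both sides as
`unsupported`.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `iou_threshold` | 0.5 | IoU | the standard detection-overlap convention; the match requires strict `>` |
| `identity/behavior_confidence_floor` | 0 | probability | no pre-filtering; detectors' own thresholds are treated as upstream policy |
| `initial_behavior_policy` | `unknown_sentinel` | — | never invent a behavior before the first match |
| override table | `(stand, drink)`, `(stand, chin_rest)` | — | the two documented front-view error modes |
| `sampling_interval` | 1 | frames | frame-level scoring; stride expressible for coarser units |
| `exclude_unknown` | `TRUE` | — | sentinels carry no information and cannot be binarized |

Tie-breaks are deterministic and documented rather than meaningful:
among several identity boxes for one cow, highest confidence, then
larger area, then lowest `(x_min, y_min)`; among equal-IoU behavior
boxes, higher confidence, then lexicographic label. One behavior box may
match several cows — riding intrinsically involves two animals — so no
one-to-one constraint is imposed.

## Geometry conventions

Boxes are absolute pixels, origin top-left, half-open
`[x_min, x_max) × [y_min, y_max)`. Half-open intervals make area and
intersection arithmetic exact; the IoU implementation is verified
against a brute-force integer-pixel-counting oracle to 1e-9 on 1,000
random box pairs. YOLO-normalized center/size coordinates are converted
to corners at the parsing boundary (and back on write, an exact
involution up to 1e-9); corners falling outside the image are clipped.
The default frame is 960 × 570 px at 10 fps — a landscape CCTV frame —
but size, rate and view are manifest fields, never hard-coded. The two
views are aligned by integer frame index at equal fps; resampling
unequal rates is out of scope.

## What the simulator emulates

The simulator generates the latent state a barn camera pair would
observe, then corrupts it at the detection level. Defaults describe the
reference setup: three cows (A, B, C) in a 4 × 8 m pen, two synchronized
960 × 570 px views at 10 fps.

*Behavior* is a per-cow semi-Markov process: bout lengths are geometric
(the simplest memoryless choice, with a closed-form occupancy oracle
used by the tests), means per behavior in frames
(`stand` 300, `lie` 600, `eat` 200, `drink` 100, `chin_rest` 50,
`ride` 30 at 10 fps — minutes-long maintenance bouts, seconds-long
estrus events); the next behavior is drawn from the stationary
probabilities excluding the current one
(`stand` .45, `lie` .25, `eat` .15, `drink` .08, `chin_rest` .04,
`ride` .03). The resulting strong class imbalance — estrus behaviors
around 1% of frames — is deliberate: rarity of the positive class is the
defining difficulty of the task. Long-run occupancy is checked against
an independent embedded-chain eigen-oracle.

*Positions* follow a bounded random walk (step sd 0.08 m/frame);
drinking cows are pulled into the trough zone, and riding/chin-resting
cows are placed directly behind their nearest neighbour, which is what
later triggers front-view alignment occlusion.

*Projection* maps pen coordinates to per-view boxes: linearly for the
top view with a fixed per-behavior footprint, and with depth-dependent
scale and row for the front view (nearer cows lower and larger). Two
geometric contexts are flagged: `near_trough_standing` (standing inside
the trough zone) and, front view only, `aligned_behind` (within a
0.5 m × 2 m cone directly behind another cow). When both apply the
trough context wins, on the grounds that the trough is the stronger
local cue; this is a documented choice, not a claim about real
detectors.

*Corruption* is a per-view error model: a 6 × 6 row-stochastic confusion
matrix from true behavior to emitted behavior-box label, optional
context-gated replacement rows, independent identity/behavior box
dropout, Gaussian corner jitter (clipped and re-validated), and uniform
confidences. Errors are injected at the label/box level rather than by
rendering pixels: detector failures are characterized behaviorally
(which confusions, in which geometric contexts), which is exactly what a
detection-level simulator can reproduce; pixel simulation would add cost
without testable fidelity.

The shipped `default_error_models()` are the calibration constants of
the simulated study: the top view's `stand` row leaks 0.17 + 0.17 into
`ride`/`chin_rest` unconditionally (top-down loss of posture), while the
front view is near-diagonal with context-gated leaks
(`P(drink | stand, near trough) = 0.6`;
`P(chin_rest | stand, aligned) = 0.45`, plus 0.10 to `ride`), with 5%
dropout and 3 px jitter on both views. These magnitudes are properties
of the fixture, chosen once so the two simulated detectors exhibit the
documented qualitative error modes with the top view strictly worse on
estrus false positives; they are not measurements of any real detector.
Consequently, passing tests show that the *pipeline logic* behaves as
specified under realistic error structure — they do not certify
performance numbers on real barn video, where detector errors are
correlated in time, cows occlude each other in both views, and lighting
varies.

## Numerical and degenerate-input choices

- Strict inequality at the threshold: τ = 1 can never match; raising τ
  never increases the number of matched entries (tested over a grid).
- Confusion rows must sum to 1 within 1e-9; stationary probabilities
  likewise.
- An empty frame is data (the detectors saw nothing), a missing frame
  file in a YOLO directory is read as empty, but a duplicate frame index
  is an error.
- Timelines are validated as total functions over roster × frames, with
  `matched_iou` present iff matched and `unknown` iff pre-first-match.
- All randomness passes through a single seed; group-wise label sampling
  iterates groups in sorted order, so equal seeds give byte-identical
  streams, timelines and metrics JSON (asserted with checksums).

## Problem sizes

The test suite exercises the oracle comparisons at 1,000 random box
pairs, occupancy convergence at 50,000 frames (with dwells scaled down
tenfold, which leaves occupancy invariant while packing in enough
renewal cycles for a ±0.03 bound), context-rate checks at 10,000+
flagged frames, the noise-free end-to-end identity at 5,000 frames × 3
cows, and the replicated noisy study at 20 replicates × 5,000 frames
(seeds 0–19 relative to the base seed). The same study is what
`scripts/acceptance.R` recomputes.

## Known limitations

- No multi-frame tracking, global assignment, or re-identification: the
  association is per-frame greedy with temporal fallback, as specified.
- No temporal smoothing or confidence-weighted fusion; the ensemble is
  the stated two-pair rule table.
- Event/bout-level evaluation and estrus-alarm logic (onset/duration
  thresholds) are out of scope; scoring is frame-level with a stride.
- The simulator's error processes are independent across frames;
  real detector errors persist across consecutive frames, which the
  fallback mechanism would propagate differently.
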