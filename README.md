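# cowfuse

Multi-view cattle behavior recognition by bounding-box association and
decision-level ensemble fusion.

## The problem

Estrus detection on dairy farms depends on spotting two brief, rare
behaviors — **riding** (mounting) and **chin-resting** — amid the ordinary
repertoire of standing, lying, eating and drinking. Camera-based systems
run two object detectors per view on synchronized CCTV footage: one that
finds and identifies each cow (identity boxes) and one that localizes and
classifies behaviors (behavior boxes). Two post-processing problems
remain, and `cowfuse` solves exactly those:

1. **Association** — which cow is performing which detected behavior?
   Each cow's identity box is linked to the behavior box with the highest
   Intersection-over-Union (IoU), provided it strictly exceeds a
   threshold τ (default 0.5):

   `IoU(A, B) = |A ∩ B| / |A ∪ B|`

   If no behavior box clears τ for a cow, or the cow is missed entirely
   by the identity detector, the cow keeps its behavior from the previous
   frame — two fallback branches that keep the per-cow timeline
   continuous through detector dropouts.

2. **Fusion** — the two views fail in different, systematic ways. A
   top-down camera loses postural cues (standing cows get called riding
   or chin-resting); a front camera misreads cows standing near the water
   trough as drinking and rear-to-front aligned cows as chin-resting. The
   decision-level ensemble uses the front view's label by default but
   prefers the top view when it says `stand` while the front view says
   `drink` or `chin_rest`.

Timelines are scored against ground truth by binarizing behaviors into
estrus (`ride`, `chin_rest`) vs non-estrus and computing the confusion
matrix, precision, recall and F1, plus one-vs-rest F1 per behavior.

The package is detector-agnostic: it consumes per-frame detection
streams (YOLO-format text files with a manifest, or JSON-lines) from any
source. A built-in simulator generates ground-truth behavior schedules
(semi-Markov bouts, pen-geometry trajectories) and corrupts them with
configurable, view-specific error models, so the entire pipeline is
testable without video or detector weights.

## Worked example

Simulate a two-view dataset with the shipped error models and run the
full pipeline:

```r
library(cowfuse)
sc <- scenario_config(n_frames = 2000, seed = 42)
em <- default_error_models()
ds <- generate_dataset(sc, em$top, em$front)
fit <- run_pipeline(ds$top, ds$front, ds$truth)
fit
```

```
Two-view behavior recognition pipeline
  cows: A, B, C; frames fused: 2000
  top associations: 5443 matched, 258 low-IoU fallback, 298 missing-cow fallback
  front associations: 5388 matched, 277 low-IoU fallback, 335 missing-cow fallback
  fusion: 47 top overrides, 5952 front defaults

Estrus-vs-non-estrus performance by camera configuration

     configuration  tp  fp   tn fn n_evaluated precision recall    f1
          top only 101 355 5537  6        5999     0.221  0.944 0.359
        front only 101 220 5673  6        6000     0.315  0.944 0.472
 two-view ensemble  99 182 5711  8        6000     0.352  0.925 0.510
```

Reading the output: of 6,000 (cow, frame) decisions the top view alone
produces 355 estrus false positives (standing misread as riding or
chin-resting from above), the front view 220, and the ensemble 182 — the
47 top-override fusions removed front-view false positives at almost no
recall cost, so the ensemble's estrus F1 (0.510) beats front-only
(0.472), which beats top-only (0.359). Per-behavior F1s (printed below
the table) show the same pattern concentrated in `chin_rest` and
`drink`.

Individual stages are exposed as ordinary functions: `read_stream()` /
`write_stream()`, `associate_stream()`, `fuse_timelines()`,
`confusion()` / `precision_recall_f1()` / `compare_views()`, and
`simulate_truth()` / `project_views()` / `corrupt_detections()`. A thin
CLI with `simulate | associate | fuse | evaluate | run` subcommands is
in `inst/cli/cowfuse.R`.

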