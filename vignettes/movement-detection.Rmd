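---
title: "Detecting hand movements from pose keypoints: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hand movements from pose keypoints: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmotion)
```

## The problem

Research on co-speech gesture and other manual behaviour relies on frame-level
annotation of when hands move: onset and offset of every movement, entered by
trained coders in tools such as ELAN or ANVIL. That is slow, and for corpus
work prohibitively so. handmotion automates the *detection* step —
segmenting movement from non-movement in the 2-D keypoint trajectories a pose
estimator extracts from video — so that the human coder's job reduces to
removing non-gesture movements (fidgeting, self-grooming) and touching up
boundaries. It deliberately does not attempt *recognition*: telling gestures
from non-gesture movements, or classifying gesture types, is out of scope.

The input is the standard single-person pose layout: per frame, 25 body
keypoints plus 21 keypoints per hand, each an $(x, y, c)$ triplet of pixel
coordinates and a confidence score in $[0,1]$. Undetected keypoints arrive as
$(0, 0, 0)$ and are preserved verbatim; frames whose document lists no person
are represented the same way. The package reads the estimator's per-frame
JSON dialect or three intermediate keypoint CSVs (body / left hand / right
hand), which it can also write.

## The classifier

Detection runs independently per keypoint on a default set of eight manual
keypoints: both wrists, a mid-forearm point per arm (synthesized as the
coordinate midpoint of elbow and wrist, with confidence the per-frame minimum
of the two — the midpoint of two estimated landmarks is no more reliable than
its worse parent), and each hand's index fingertip and thumb tip. Wrist and
forearm capture gross arm movement; the fingertips capture small-amplitude
finger movement that wrist coordinates miss.

Every frame $k$ of a keypoint track passes through a cascade:

1. **Reliability gate.** If confidence $c_k$ is below `reliability_threshold`
   (default 0.3), frame $k$ is labelled no-movement outright. Low-confidence
   coordinates are too noisy to interpret, and a false "movement" there would
   be pure estimator jitter.
2. **Rest test.** Over the window $k-7, \dots, k+7$ (15 frames, 600 ms at
   25 fps), count the frames whose distance to frame $k$ is strictly below
   `rest_pixel_tolerance` (10 px). If at least `rest_certainty` (0.7) of the
   window is within tolerance, frame $k$ is at rest. The window is clamped at
   the sequence edges and the proportion uses the available frames, so
   boundary frames remain classifiable. Frame $k$ itself is counted (its
   distance is 0); with a full window the test is thus "at least 11 of 15
   frames near frame $k$".
3. **Onset test.** Frame $k$ starts a movement if its distance to frame
   $k-1$ exceeds `movement_pixel_threshold` (5 px) *and* at least
   `lookahead_min_count` (3) of the up-to-`lookahead_frames` (5) existing
   frames after $k$ also lie more than 5 px from frame $k$. The lookahead
   requires displacement to persist: an isolated one-frame coordinate spike
   can still pass the raw test at the spike frame itself, but the movement it
   opens collapses to a single frame (the next frame is already at rest) and
   is removed by post-processing, which is the intended false-positive
   protection.
4. **Extension.** A detected movement runs from its onset up to, but not
   including, the next frame classified as rest, searched within
   `rest_search_limit` (300) upcoming frames; if no rest frame is found the
   range is multiplied by `search_growth_factor` (1.5) and retried, capped at
   the final frame. A movement never followed by rest runs to the end of the
   recording. Scanning resumes at the terminating rest frame; frames inside
   an active movement are not re-tested for onset.

Per-keypoint masks are merged by frame-wise OR: a movement visible at any of
the eight keypoints is kept, so low confidence at some keypoints does not
create false negatives.

Distances are Euclidean by default. The alternative `per-axis-max` metric
($\max(|\Delta x|, |\Delta y|)$) is provided because threshold comparisons on
"pixel difference" admit either reading; Euclidean matches the intuitive
magnitude of 2-D motion and is the default. Detection is invariant under
coordinate translation, so the image origin convention is irrelevant.

### Post-processing and export

The merged mask is run-length encoded into segments (maximal runs of
movement frames). Two rules then apply, in this order: segments shorter than
`min_segment_frames` (4) are removed, and segments separated by a gap of at
most `max_merge_gap_frames` (4 frames strictly between them) are merged,
transitively left to right. Removal-before-merging is the default; the
reverse order is available (`rule_order = "merge_first"`) for sensitivity
checks — the two differ exactly when a short segment sits within merging
range of its neighbours. "Shorter than four frames" is read as duration
$< 4$ (3-frame segments die, 4-frame segments survive) and "within four
frames" as gap $\le 4$; both readings are configurable because the boundary
semantics admit either convention.

Segments convert to annotations on an exclusive-end convention: a segment of
frames $s..e$ (1-based) begins at boundary $s-1$ and ends at boundary $e$,
so its duration is exactly its frame count times $1000/\mathrm{fps}$ ms
(40 ms per frame at 25 fps). Boundaries are rendered as zero-padded
`hh:mm:ss.ms` with milliseconds rounded to nearest, ties away from zero. The
annotation CSV (`tier, begin, end, duration, value`, comma- or tab-separated,
byte-deterministic) follows the delimited-text import expectations of ELAN
and ANVIL; a minimal native `.eaf` XML writer is included as a convenience.

## The synthetic generator

`scenario_spec()` + `generate_recording()` simulate what the detector needs
to be tested against, with exact ground truth:

* **Rest** is a fixed pixel anchor plus i.i.d. Gaussian jitter per frame and
  axis (`rest_jitter_sd`, default 1 px) — the simplest noise model whose
  spread can be positioned against the 10 px / 5 px thresholds.
* **Ramp episodes** displace the keypoint by `amplitude` pixels over
  `duration` frames in a per-keypoint random direction, ending at a new
  anchor (as a gesture stroke that ends in a different rest position).
* **Out–hold–return episodes** move out, freeze exactly (no jitter) for
  `hold` frames, and return — the gesture-hold case that coordinate-change
  detection provably misclassifies (see limitations).
* **Confidence** is a constant baseline (default 0.9) with optional i.i.d.
  dropouts to $(0, 0, 0)$, mimicking the estimator's undetected-keypoint
  convention.

All eight default keypoints execute every episode (wrists *and* elbows are
driven, so the synthesized mid-forearm moves too); the remaining keypoints
sit at static anchors. Everything is a pure function of the spec including
its seed; the generator restores the caller's RNG state.

What the generator does *not* emulate: realistic limb kinematics (velocity
profiles, anatomical coupling between keypoints), estimator noise that is
correlated in time or across keypoints, partial occlusion (confidence decay
rather than dropout), and multi-person scenes. Tests passing on this
generator therefore certify the decision logic against its own definitions —
thresholds, windows, post-processing, timing — not detection performance on
real video, which depends on upstream pose-estimation quality.

### Scenario sizes used in the shipped tests

The property suites run 100-seed batches of 400-frame (16 s) scenarios with
one to three ramp episodes of 12–30 frames (0.5–1.2 s, the scale of real
gesture strokes) and amplitudes of at least 60 px with per-frame steps above
the 5 px onset threshold, plus 100 movement-free scenarios at 1 px jitter.
Under those conditions recall at the 60 % overlap criterion is 1.0 and the
false-alarm count is 0. Episode durations matter for the overlap arithmetic:
the detector, by design, extends each movement a few frames past motion
offset (a rest window needs ~11 of 15 stable frames to re-establish, so
detection typically ends 2–5 frames late, and jitter can very occasionally
fire an onset up to ~3 frames early). A $d$-frame episode detected as up to
$d+7$ frames has intersection-over-union $d/(d+7)$, which clears 0.6 only
for $d \ge 11$ — sub-half-second episodes cannot meet a 60 % Jaccard
criterion under this detector even when they are found, which is why the
recovery suites use gesture-scale durations. Episodes are also separated by
at least 30 rest frames, since movements not separated by a re-established
rest state are, by construction, one movement to this detector.

## Evaluation

`temporal_overlap()` is intersection over union in frames (symmetric, 1 iff
identical); an intersection-over-longer-duration variant is available
(`method = "max"`) since event-agreement tools differ in the denominator.
`match_segments()` does greedy one-to-one matching in timeline order at an
overlap criterion (default 0.6): because both lists are sorted and
non-overlapping, qualifying pairs cannot cross, and in-order greedy matching
attains the optimum — the test suite verifies this against brute-force
maximum matching. Recall is matched/reference (vacuously 1 with no reference
events), precision matched/detected. `raw_agreement()` is the proportion of
frames with identical movement/no-movement labels. Chance-corrected
event-level agreement (kappa-style) is intentionally not implemented; raw
agreement plus precision/recall at the overlap criterion are the package's
native metrics.

## Parameters at a glance

| parameter | default | unit | role |
|---|---|---|---|
| `reliability_threshold` | 0.3 | — | confidence gate |
| `rest_halfwidth` | 7 | frames | rest window = 15 frames (600 ms at 25 fps) |
| `rest_pixel_tolerance` | 10 | px | "near frame k" for the rest test |
| `rest_certainty` | 0.7 | proportion | window fraction required at rest |
| `movement_pixel_threshold` | 5 | px | onset step and lookahead threshold |
| `lookahead_frames` / `lookahead_min_count` | 5 / 3 | frames | onset persistence check |
| `rest_search_limit` | 300 | frames | movement-end search (~12 s at 25 fps) |
| `search_growth_factor` | 1.5 | — | search-range growth when no rest found |
| `min_segment_frames` | 4 | frames | short-segment removal |
| `max_merge_gap_frames` | 4 | frames | gap merging |

The pixel thresholds are resolution-dependent: they were calibrated for
conversational video at typical recording resolutions and should be rescaled
for very high-resolution or very distant framing. The frame-count parameters
are rate-dependent: at fps other than 25, the same wall-clock behaviour
requires scaling `rest_halfwidth`, `lookahead_frames`, `rest_search_limit`,
`min_segment_frames` and `max_merge_gap_frames` proportionally.

## Numerical and degenerate-input choices

* Strictness mirrors the rule wording: rest uses strictly-less-than
  tolerance, onset strictly-greater-than threshold.
* The first frame is never an onset (no predecessor); the last frame can
  never be confirmed as one (no lookahead frames, and 3 confirmations are
  required).
* Low-confidence frames inside *another* frame's rest window still
  contribute their coordinates — the gate applies only to the frame being
  classified. A $(0,0,0)$ dropout therefore pushes its window neighbours
  away from rest, but the onset lookahead prevents isolated dropouts from
  opening movements; dense dropout runs can open short spurious movements,
  which post-processing mostly removes. This is the faithful behaviour of
  the cascade, not a bug.
* Millisecond rounding is nearest-integer, ties away from zero;
  annotation-to-frame round-trips are exact whenever $1000/\mathrm{fps}$ is
  integral (e.g. 25, 40, 50 fps).
* Empty inputs: an all-rest recording produces zero segments and a
  header-only annotation file; evaluation against an empty reference defines
  recall as 1 (vacuous truth).

## Known limitations

* **Holds.** A hand held motionless mid-gesture longer than the rest window
  is, by definition, at rest to this detector: the hold interior is
  classified no-movement and the episode splits into its transport phases
  (`generate_hold_scenario()` reproduces this deterministically). Holds
  shorter than the window survive inside one movement, and splits with gaps
  of at most 4 frames are re-merged.
* **Small movements.** Displacements that never exceed 5 px between frames
  and 10 px within a window are invisible by construction.
* **Boundary bias.** Detected offsets run a few frames late (rest-window
  re-establishment); onset timing is accurate to ~1 frame for supra-threshold
  steps.
* **2-D pixels.** Thresholds are in image pixels, not millimetres; no depth,
  no camera calibration, no multi-person tracking.
* **Detection only.** Gesture/non-gesture classification, gesture-phase
  segmentation (stroke/hold/retraction) and velocity profiling are out of
  scope.
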