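---
title: "Detecting and evaluating visual attention to dynamic AOIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and evaluating visual attention to dynamic AOIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeaoi)
```

## The problem

Mobile eye trackers record an egocentric video plus a gaze signal. Analysts
want to know *when the wearer attended which object* — contiguous attention
events to areas of interest (AOIs). Annotating AOIs by hand is slow, and in
mobile settings every participant has a different video, so keyframed
annotations cannot be reused across recordings. `gazeaoi` implements two
automatic detectors built on pre-trained vision models (exposed here as
pluggable backends), the extraction of ground-truth events from manual
annotations, and a fine-grained, segment-based evaluation framework from
activity recognition.

## The IC detector

The IC method classifies small image patches around the gaze point and
aggregates the label stream with a working-memory event machine:

1. the gaze signal is resampled to a low rate (default 5 Hz, i.e. one tick
   every 200 ms), keeping the sample nearest each tick;
2. a `patch_size` × `patch_size` crop (default 200 px, clamped inside the
   frame) around each remaining sample is classified by the backend, which
   returns up to five `(label, probability)` candidates;
3. similar labels are merged through a lookup table by summing their
   probabilities (e.g. several car-like labels collapsing onto one
   canonical car label), and the top-1 result feeds the event machine;
4. the machine keeps a duration counter `Cdur` and a noise counter
   `Cnoise` per label. A prediction whose probability strictly exceeds
   `t_prob` adds the elapsed stream time to its label's `Cdur` and to the
   `Cnoise` of every *other* label already accumulating; once
   `Cdur > t_dur` an *attention started* event fires (ending a different
   active label first), and once `Cnoise > t_noise` a label is reset
   (ending it if active). Emitted timestamps are corrected by `-t_dur` to
   compensate detection latency.

Tunable parameters, all in `ic_config()`:

| parameter | default | meaning |
|---|---|---|
| `t_dur` | 300 ms | evidence needed before an event starts |
| `t_noise` | 300 ms | off-label time tolerated before a label resets |
| `t_prob` | 0.40 | minimum probability for a tick to count |
| `sample_rate` | 5 Hz | gaze resampling rate |
| `patch_size` | 200 px | crop side length |

The default setting is named `IC-152-300-40`
(`ic_method_name(ic_config())`). Raising `t_dur`/`t_noise` trades recall
for precision: fewer, longer, more reliable events (the acceptance suite
checks that the number of returned events never increases with the
thresholds on a fixed stream).

Two unstated corner cases needed decisions. First, a tick at or below
`t_prob` supports no label, so it counts as noise for *every* label with a
non-zero duration counter — the natural extension of the "all other
classes" rule. Second, when a new label displaces the active one, the
*ended* signal is emitted before the *started* signal and both carry the
same corrected timestamp, which keeps per-label intervals disjoint. The
first prediction of a stream contributes no elapsed time (its `delta` is
zero); unterminated events are closed at the last prediction timestamp so
evaluation always sees finite intervals.

## The OD detector

The OD method works per fixation: the frame nearest the fixation start is
fetched (equidistant ties to the earlier frame), the detector backend
returns object instances — label, confidence, bounding box, optional
segmentation mask — and the fixation centroid is hit-tested against the
instance areas. `object_mask = "bbox"` (setting `OD-bbox`, the default)
tests boxes, `"mask"` (`OD-mask`) tests masks; since a mask lies inside its
box, mask-mode hits are always a subset of bbox-mode hits. Among multiple
hits the highest-probability instance wins, exact ties going to input
order for determinism. Each hit emits one event spanning the fixation.

Instances whose labels do not occur in the scenario's label→AOI map are
excluded before the hit test: an unmapped detection can never become an
AOI event. The detection confidence threshold is not prescribed anywhere,
so the common default of 0.5 is used and exposed as
`od_config(score_threshold=)`.

## Ground truth and scenario maps

`extract_ground_truth()` replays what a manual annotation campaign
encodes: for every frame spanned by a fixation (frame midpoints against
the half-open fixation interval), the fixation centroid is tested against
every AOI's keyframe-interpolated region; contiguous hit frames become
frame-aligned events. If a frame hits two AOIs (e.g. nested boxes), it is
assigned to the AOI whose contiguous candidate run is longer, ties going
to track order. Frame-wise testing is an interpretation — the source
material defines the rule only by one sentence about selecting "the longer
event" — and is documented as such. AOI tracks are absent outside their
keyframe span; no extrapolation is performed because annotation tools
leave that behaviour undefined.

The label→AOI maps for the eleven benchmark scenarios ship as a CSV table
(`load_scenario_config()`), one map per scenario and method; AOIs without
any usable class label are listed as unmapped and are expected to fail
(`is_failing()` flags a frame-level deletion rate ≥ 90 %).

## The evaluation framework

Evaluation is one-vs-rest per AOI on binary frame signals. Events shorter
than one frame time are dropped, then same-AOI events with sub-frame gaps
are merged (in that order, following the order the rules are stated in).
The paired signals are cut into segments wherever either changes; each
segment is TP/TN/FP/FN.

Event level — every ground-truth event is exactly one of: deletion `D` (no
overlapping prediction), fragmented `F` (≥ 2 overlapping predictions),
merged `M` (an overlapping prediction also covers another ground-truth
event), both `FM`, or correct `C` (exclusive one-to-one overlap);
symmetrically each prediction is an insertion `I'`, fragmenting `F'`,
merging `M'`, both `FM'`, or correct. `C` is counted once and is equal
from both sides. Overlap means at least one shared frame; with half-open
intervals, events touching at a boundary do not overlap. The compound
`FM`/`FM'` assignment (both conditions holding simultaneously) is the
implemented reading of the deferred compound cases.

Frame level — FP segments become merge frames `Mf` when they lie between
two TP stretches of one (necessarily merging) prediction, overfill
`Of^α`/`Of^ω` at the edges of a partly correct prediction, and insertions
`If` otherwise; FN segments become fragmentation `Ff`, underfill
`Uf^α`/`Uf^ω`, or deletion `Df` symmetrically. This ordering (merge >
overfill > insertion; fragmentation > underfill > deletion) is structural:
the interior cases are determined by the run's TP layout, the edge cases
require a TP neighbour.

Metrics: conservative `Pr = C/|R|`, `Re = C/|E|`; progressive
`Pr* = (|R|−I')/|R|`, `Re* = (|E|−D)/|E|`; the event-based f1 is their
harmonic mean. Frame rates divide each count by the positive (`P`) or
negative (`N`) ground-truth frames, so `fpr = ir+mr+oα+oω` and
`1−tpr = dr+fr+uα+uω` hold exactly. Ratios with zero denominators are
reported as `NA` rather than 0 or 100, so aggregated tables are not
biased. Aggregation over participants or AOIs sums the raw counts (which
equals concatenating the recordings) and recomputes ratios afterwards.
`render_ead()`/`plot_ead()` produce the event-analysis-diagram breakdown
against `|E|` and `|R|`.

## The synthetic world

The generator exists so every claim above is testable offline, and its
defaults are fixed once:

* `gen_gt_events()`: disjoint, frame-aligned events, durations 800–2000 ms
  and gaps 600–1600 ms by default — the range of typical dwell times on a
  moving object and wide enough that a 300 ms threshold machine can
  operate; 25 fps frame grid (40 ms).
* `perturb_events()` applies *non-interacting* edits — deletions,
  insertions, fragmentations with two-frame internal gaps, merges of
  consecutive events, boundary jitter on correct events — and returns the
  exact error ledger those edits must score as. Interacting or infeasible
  edits are rejected with an error instead of silently mislabelling the
  ledger; this is the module's central guarantee.
* `mock_classifier()` emits the true label inside events (probability 0.9)
  and cycling confuser labels outside (0.6, above the probability
  threshold so the event machine can terminate events promptly via a
  confuser takeover).
* `gen_gaze()` models limited spatial *accuracy*, the dominant eye-tracker
  failure mode: one Gaussian offset per event, of scale `sigma` px, shared
  by the event's samples and its fixation centroid. Precision jitter
  within a fixation is deliberately not modelled — averaging would cancel
  it and it does not drive the deletion-inflation mechanism under study.

What a green test establishes: the scoring machinery is exact (checked
against a brute-force oracle and against constructed ledgers), the IC
machine recovers clean streams within `t_dur` + one tick, OD-bbox
dominates OD-mask on identical detections, and deletion rates rise
monotonically with accuracy noise. What it does not establish: performance
on real recordings — real vision backends confuse visually similar
instances, AOIs may have no matching class label at all, and smooth
pursuit degrades fixation detection; none of these are in the synthetic
world.

## Numerical choices and degenerate inputs

* Time is real-valued ms; every interval is half-open `[start, end)`, so
  boundaries are never double-counted.
* A frame is covered by an event iff its *midpoint* lies inside the
  interval; frame-aligned events therefore binarise exactly.
* Polygon containment uses the even-odd rule with an inclusive boundary
  (tolerance 1e-9, scale-relative) — any consistent rule would do, this
  one is oracle-testable.
* Resampling anchors ticks at the first sample timestamp; ticks farther
  than half a tick from every sample are dropped.
* Probability ties in the OD hit test and AOI ties in ground-truth
  conflict resolution break deterministically (input/track order).
* Zero-length events cannot be constructed; readers reject `end <= start`
  with the offending line.

## Limitations

The package scores detections; it does not ship CNN weights, so real-image
backends must be provided by the user behind the two one-function backend
interfaces. Multi-object tracking (distinguishing identical-looking
instances), appearance change over time, and error-aware gaze-to-object
mapping under calibration drift are out of scope. The exhaustive oracle
sweep in the acceptance suite runs on a reduced enumeration space (all
signal pairs with ≤ 2 events on 10 frames, plus samples from the larger
space); the full stated space is combinatorially out of reach on any
hardware.
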