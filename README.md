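# gazeaoi

Automatic detection of visual attention to areas of interest (AOIs) in
mobile / egocentric eye tracking, and a fine-grained evaluation framework
for such detectors.

## Who this is for

Eye-tracking researchers who want dwell-level AOI annotation without
annotating every recording by hand, and method developers who need a
rigorous, event-aware way to score a gaze-to-AOI mapper against ground
truth. Everything runs offline: the vision models are pluggable backends
(one plain function each), and a synthetic-data module generates gaze,
fixations, AOI tracks, scripted backends and error-injected prediction
streams with exactly known error ledgers.

## What is inside

**Two detectors.**

* **IC** — gaze-guided image classification: the gaze stream is resampled
  to 5 Hz, a 200×200 px patch around each sample is classified (top-5
  labels with probabilities), similar labels are merged by summing
  probabilities, and a working-memory event machine with a duration
  counter `Cdur`, a noise counter `Cnoise` and thresholds
  `T_dur = T_noise = 300` ms, `T_p = 40 %` turns the top-1 label stream
  into *attention started / confirmed / ended* signals (default setting
  `IC-152-300-40`).
* **OD** — per-fixation object detection matching: for each fixation the
  frame nearest its start is hit-tested at the fixation centroid against
  detected object instances, using bounding boxes (`OD-bbox`, default) or
  segmentation masks (`OD-mask`); the higher-probability instance wins a
  double hit.

**Ground truth.** `extract_ground_truth()` turns fixations plus
keyframe-interpolated AOI tracks into frame-aligned attention events,
resolving frames claimed by two AOIs in favour of the longer candidate
event.

**Evaluation.** One-vs-rest per AOI, following the segment-based
activity-recognition taxonomy: event error classes

```
|E| = D + F + FM + M + C          (ground-truth events)
|R| = M' + FM' + F' + I' + C      (returned events)
```

frame error classes (`Df`, `Ff`, underfill `Uf^α/Uf^ω`, `TP`; `If`, `Mf`,
overfill `Of^α/Of^ω`, `TN`), conservative precision/recall
`Pr = C/|R|`, `Re = C/|E|`, progressive `Pr* = (|R|−I′)/|R|`,
`Re* = (|E|−D)/|E|`, the event-based `f1 = 2·Pr*·Re*/(Pr*+Re*)`, rate
identities `fpr = ir+mr+oα+oω`, `1−tpr = dr+fr+uα+uω`, count aggregation
across recordings/AOIs, the `dr ≥ 90 %` failing-AOI rule, and EAD (event
analysis diagram) tables/plots.

**Scenario maps.** The label→AOI lookup tables for the eleven benchmark
scenarios (ImageNet-style labels for IC, MS-COCO-style labels for OD) are
packaged: `load_scenario_config("07-kite", "OD")`.

## Worked example

Inject a known error mix into a synthetic ground-truth stream and score
it:

```r
library(gazeaoi)

gt <- gen_gt_events(8, seed = 42, aoi = "red car")
spec <- perturbation_spec(n_delete = 1, n_insert = 2,
                          fragmentations = list(c(1, 2)),
                          merges = list(c(4, 2)))
per <- perturb_events(gt, spec, seed = 43)
meta <- video_meta(duration_ms = max(gt$end) + 200)
res <- evaluate_attention(gt, per$pred, meta)
metrics_table(res)[1, c("D","F","M","C","I_prime","F_prime","M_prime",
                        "Pr","Re","Pr_star","Re_star","f1")]
#>   D F M C I_prime F_prime M_prime    Pr Re Pr_star Re_star    f1
#> 1 1 1 2 4       2       2       1 44.44 50   77.78    87.5 82.35
render_ead(res$total$event)
#>   class count pct_E pct_R
#> 1     D     1  12.5    NA
#> 2     F     1  12.5    NA
#> 3    FM     0   0.0    NA
#> 4     M     2  25.0    NA
#> 5     C     4  50.0  44.4
#> 6   FM'     0    NA   0.0
#> 7    M'     1    NA  11.1
#> 8    F'     2    NA  22.2
#> 9    I'     2    NA  22.2
```

Reading it: of 8 ground-truth events, 1 was deleted, 1 fragmented (by 2
fragmenting predictions), 2 were merged by 1 merging prediction and 4 were
matched exactly; 2 predictions were pure insertions. Only exclusive
matches count for the conservative scores (`Re = 4/8 = 50 %`), while the
progressive scores forgive fragmentation/merging (`Re* = 7/8 = 87.5 %`).
These counts equal the ledger `perturb_events()` returned — that
round-trip is the backbone of the test suite.

Running a detector end to end looks like:

```r
stream <- mock_classifier(gt, hit_prob = 1, seed = 7)        # scripted backend
pred <- run_ic(gaze, meta, scripted_classifier_backend(stream),
               aoi_map = c("passenger car" = "red car"))
```

and a command-line front-end composes the whole pipeline
(`simulate → detect-ic/detect-od → ground-truth → evaluate`):

```sh
Rscript inst/cli/gazeaoi simulate --out-dir fixtures --seed 4
Rscript inst/cli/gazeaoi evaluate --gt fixtures/gt.jsonl \
    --pred fixtures/pred.jsonl --n-frames 500 --out metrics.csv
```

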