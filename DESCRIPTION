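Package: gazeaoi
Title: Automatic Visual Attention Detection and Event-Based Evaluation for
    Mobile Eye Tracking
Version: 0.1.0
Authors@R:
    person("gazeaoi", "developers", email = "gazeaoi@example.org",
           role = c("aut", "cre"))
Description: Detects visual attention to areas of interest (AOIs) in
    egocentric eye-tracking recordings and evaluates the detections against
    annotated ground truth. Two detection strategies are provided behind
    pluggable vision backends: aggregation of gaze-centred image-patch
    classifications through a working-memory, threshold-based event machine
    (IC), and per-fixation hit testing against detected object instances via
    bounding boxes or segmentation masks (OD). Ground-truth attention events
    are extracted from fixations and keyframe-interpolated AOI tracks. The
    evaluation follows the segment-based activity-recognition taxonomy of
    Ward and colleagues: insertion, deletion, fragmentation and merge errors
    at the event level, underfill/overfill at the frame level, conservative
    and progressive precision/recall, and event analysis diagram (EAD)
    output. A synthetic-data module generates ground-truth scenarios, noisy
    gaze traces, scripted classifier/detector backends and error-injected
    prediction streams with exact expected error ledgers, so the whole
    pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
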