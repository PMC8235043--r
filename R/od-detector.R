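# Attention detection by per-fixation object-detection matching (OD).
#
# For each fixation the frame closest to the fixation start is fetched, all
# detected object instances on that frame are obtained from a pluggable
# detector backend, and the fixation centroid is hit-tested against the
# instance areas (bounding box or segmentation mask). A hit emits one
# attention event spanning the fixation.

#' OD method configuration
#'
#' @param object_mask Which object area to hit-test: `"bbox"` (default,
#'   setting `OD-bbox`) or `"mask"` (`OD-mask`). Instances without a mask
#'   fall back to their bounding box in mask mode.
#' @param score_threshold Minimum detection confidence; instances below it
#'   are discarded before the hit test.
#' @return An object of class `od_config`.
#' @export
od_config <- function(object_mask = c("bbox", "mask"), score_threshold = 0.5) {
  object_mask <- match.arg(object_mask)
  stopifnot(score_threshold >= 0, score_threshold <= 1)
  structure(list(object_mask = object_mask,
                 score_threshold = score_threshold),
            class = "od_config")
}

#' Parameterised method name, e.g. "OD-bbox"
#'
#' @param config An [od_config()].
#' @return Character scalar.
#' @export
od_method_name <- function(config) paste0("OD-", config$object_mask)

#' Detected object instance
#'
#' @param label Class label of the detection.
#' @param probability Detection confidence in `[0, 1]`.
#' @param bbox Rectangle [region()] bounding the object.
#' @param mask Optional polygon [region()] with the object outline; must lie
#'   within `bbox`.
#' @return An object of class `detected_instance`.
#' @export
detected_instance <- function(label, probability, bbox, mask = NULL) {
  stopifnot(inherits(bbox, "region"), bbox$kind == "rectangle",
            probability >= 0, probability <= 1)
  if (!is.null(mask)) stopifnot(inherits(mask, "region"))
  structure(list(label = label, probability = probability,
                 bbox = bbox, mask = mask),
            class = "detected_instance")
}

#' Frame index closest to a fixation start
#'
#' @param start Fixation start in ms (must lie within the video).
#' @param meta A [video_meta()].
#' @return 0-based frame index whose timestamp is nearest `start`;
#'   equidistant ties go to the earlier frame.
#' @export
frame_for_fixation <- function(start, meta) {
  duration <- meta$n_frames * meta$frame_ms
  if (start < 0 || start >= duration) {
    stop("fixation start lies outside the video duration")
  }
  lo <- floor(start / meta$frame_ms)
  d_lo <- start - lo * meta$frame_ms
  d_hi <- (lo + 1) * meta$frame_ms - start
  f <- if (d_hi < d_lo) lo + 1 else lo   # tie -> earlier frame
  as.integer(min(f, meta$n_frames - 1L))
}

#' Hit-test a point against detected instances
#'
#' Returns the instance whose area (bounding box or mask, per
#' `config$object_mask`) contains the point. When several areas are hit the
#' instance with the highest probability wins; exact probability ties go to
#' the first instance in input order.
#'
#' @param x,y Point in pixels (typically a fixation centroid).
#' @param instances List of [detected_instance()] objects (assumed already
#'   filtered to the score threshold).
#' @param config An [od_config()].
#' @return A `detected_instance` or `NULL` when nothing is hit.
#' @export
hit_test <- function(x, y, instances, config = od_config()) {
  hit <- vapply(instances, function(inst) {
    area <- if (config$object_mask == "mask" && !is.null(inst$mask)) {
      inst$mask
    } else {
      inst$bbox
    }
    point_in_region(x, y, area)
  }, logical(1))
  if (!any(hit)) return(NULL)
  hits <- instances[hit]
  probs <- vapply(hits, function(inst) inst$probability, numeric(1))
  hits[[which.max(probs)]]
}

#' Run the full OD detection pipeline
#'
#' Per fixation: fetch the frame closest to the fixation start, obtain the
#' detections from the backend, keep instances whose label appears in
#' `aoi_map` and whose probability reaches the score threshold, and hit-test
#' the fixation centroid. A hit emits one event `[start, end)` carrying the
#' mapped AOI name and the instance probability; at most one event per
#' fixation. Backend failures skip the fixation with a warning.
#'
#' @param fixations A [fixation_events()] data frame, time-ordered.
#' @param meta A [video_meta()].
#' @param backend `function(frame)` returning a list of
#'   [detected_instance()] objects for a 0-based frame index, e.g.
#'   [scripted_detector_backend()].
#' @param aoi_map Named character vector, detector label -> AOI name.
#' @param config An [od_config()].
#' @return An [attention_events()] data frame with `source = "OD"`.
#' @export
run_od <- function(fixations, meta, backend, aoi_map = character(),
                   config = od_config()) {
  rows <- vector("list", nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    frame <- frame_for_fixation(fixations$start[i], meta)
    instances <- tryCatch(backend(frame),
                          error = function(e) {
                            warning(sprintf("backend failed at frame %d: %s",
                                            frame, conditionMessage(e)))
                            NULL
                          })
    if (is.null(instances) || length(instances) == 0L) next
    keep <- vapply(instances, function(inst) {
      inst$probability >= config$score_threshold && inst$label %in% names(aoi_map)
    }, logical(1))
    instances <- instances[keep]
    if (length(instances) == 0L) next
    inst <- hit_test(fixations$x[i], fixations$y[i], instances, config)
    if (is.null(inst)) next
    rows[[i]] <- attention_events(
      start = fixations$start[i], end = fixations$end[i],
      label = inst$label, aoi = unname(aoi_map[[inst$label]]),
      probability = inst$probability, source = "OD")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_events() else out
}

#' Scripted detector backend
#'
#' Wraps a per-frame table of detected instances as an OD backend. Frames
#' without an entry yield no detections.
#'
#' @param frames Named list; names are 0-based frame indices as character,
#'   values are lists of [detected_instance()] objects.
#' @return A `function(frame)` suitable for [run_od()].
#' @export
scripted_detector_backend <- function(frames) {
  force(frames)
  function(frame) {
    key <- as.character(frame)
    if (key %in% names(frames)) frames[[key]] else list()
  }
}
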