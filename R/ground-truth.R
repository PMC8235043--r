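# Ground-truth attention events from fixations and annotated AOI tracks.

#' Extract ground-truth attention events
#'
#' For every frame a fixation spans (a frame is spanned when its midpoint
#' timestamp lies in the fixation interval), the fixation centroid is tested
#' against each AOI's interpolated region. Contiguous hit frames per AOI
#' become one frame-aligned attention event. When two or more AOIs contain
#' the centroid on the same frame, the frame is assigned to the AOI whose
#' contiguous candidate event (measured before conflict resolution) is
#' longer; ties go to the first AOI in track order. The result is
#' conflict-free: no frame is counted for two AOIs.
#'
#' @param fixations A [fixation_events()] data frame.
#' @param tracks List of [aoi_track()] objects sharing the video timeline.
#' @param meta A [video_meta()].
#' @return An [attention_events()] data frame with `source =
#'   "ground_truth"`, events aligned to frame boundaries and disjoint per
#'   AOI.
#' @export
extract_ground_truth <- function(fixations, tracks, meta) {
  n <- meta$n_frames
  a <- length(tracks)
  if (n == 0L || a == 0L || nrow(fixations) == 0L) return(empty_events())
  mids <- (seq_len(n) - 0.5) * meta$frame_ms
  hit <- matrix(FALSE, nrow = n, ncol = a)
  for (i in seq_len(nrow(fixations))) {
    frames <- which(mids >= fixations$start[i] & mids < fixations$end[i])
    for (f in frames) {
      for (j in seq_len(a)) {
        if (hit[f, j]) next
        reg <- interpolate_track(tracks[[j]], f - 1L)   # 0-based frame index
        if (!is.null(reg) &&
            point_in_region(fixations$x[i], fixations$y[i], reg)) {
          hit[f, j] <- TRUE
        }
      }
    }
  }

  # candidate run length per frame and AOI, before conflict resolution
  run_len <- matrix(0L, nrow = n, ncol = a)
  for (j in seq_len(a)) {
    r <- rle(hit[, j])
    run_len[, j] <- rep(r$lengths, r$lengths) * hit[, j]
  }

  conflict <- which(rowSums(hit) > 1L)
  for (f in conflict) {
    winner <- which.max(run_len[f, ])    # ties -> first AOI in track order
    drop <- setdiff(which(hit[f, ]), winner)
    hit[f, drop] <- FALSE
  }

  out <- vector("list", a)
  for (j in seq_len(a)) {
    r <- rle(hit[, j])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) next
    out[[j]] <- attention_events(
      start = (starts[keep] - 1L) * meta$frame_ms,
      end = ends[keep] * meta$frame_ms,
      label = tracks[[j]]$aoi, aoi = tracks[[j]]$aoi,
      probability = 1, source = "ground_truth")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty_events())
  res[order(res$start, res$aoi), , drop = FALSE]
}
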