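# Shared domain types and geometry/time conventions.
#
# Conventions used throughout the package:
#   * time is real-valued milliseconds from recording start; all event
#     intervals are half-open [start, end)
#   * pixel coordinates have the origin at the top-left corner, x grows
#     rightward, y grows downward; frame indices are 0-based
#   * a frame's timestamp is frame * 1000/fps; its midpoint is
#     (frame + 0.5) * 1000/fps

#' Video metadata
#'
#' Describes the timeline and frame geometry of an egocentric video feed.
#' The default resolution and frame rate match a typical scene camera
#' (1920x1080 at 25 fps).
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in frames per second (must be positive).
#' @param n_frames Number of frames; may be omitted when `duration_ms` is
#'   given, in which case the smallest frame count covering that duration is
#'   used.
#' @param duration_ms Optional recording duration in milliseconds.
#' @return An object of class `video_meta` with fields `width`, `height`,
#'   `fps`, `n_frames` and the derived frame duration `frame_ms = 1000/fps`.
#' @export
video_meta <- function(width = 1920, height = 1080, fps = 25,
                       n_frames = NULL, duration_ms = NULL) {
  if (is.null(n_frames)) {
    if (is.null(duration_ms)) {
      stop("either `n_frames` or `duration_ms` must be given")
    }
    n_frames <- ceiling(duration_ms * fps / 1000)
  }
  stopifnot(width > 0, height > 0, fps > 0, n_frames >= 0)
  structure(
    list(width = width, height = height, fps = fps,
         n_frames = as.integer(n_frames), frame_ms = 1000 / fps),
    class = "video_meta"
  )
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("<video_meta> %dx%d px, %g fps, %d frames (%.1f s)\n",
              x$width, x$height, x$fps, x$n_frames,
              x$n_frames * x$frame_ms / 1000))
  invisible(x)
}

#' Timestamp of a frame
#'
#' @param frame 0-based frame index (vectorised).
#' @param meta A [video_meta()] object.
#' @return Frame timestamp(s) in milliseconds, `frame * 1000/fps`.
#' @export
frame_timestamp <- function(frame, meta) {
  if (any(frame < 0) || any(frame >= meta$n_frames)) {
    stop("frame index out of range [0, n_frames)")
  }
  frame * meta$frame_ms
}

#' Spatial region (axis-aligned rectangle or polygon)
#'
#' Rectangles are stored as two corner vertices `(x1, y1)`, `(x2, y2)` with
#' `x1 < x2`, `y1 < y2` and are treated as half-open pixel sets
#' (`x1 <= x < x2`). Polygons need at least three vertices; containment uses
#' the even-odd rule with the boundary counting as inside.
#'
#' @param kind `"rectangle"` or `"polygon"`.
#' @param vertices An n x 2 numeric matrix of `(x, y)` vertices.
#' @return An object of class `region`.
#' @export
region <- function(kind = c("rectangle", "polygon"), vertices) {
  kind <- match.arg(kind)
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must be an n x 2 matrix of (x, y)")
  if (kind == "rectangle") {
    if (nrow(v) != 2L || v[1, 1] >= v[2, 1] || v[1, 2] >= v[2, 2]) {
      stop("a rectangle needs two corners with x1 < x2 and y1 < y2")
    }
  } else if (nrow(v) < 3L) {
    stop("a polygon needs at least 3 vertices")
  }
  structure(list(kind = kind, vertices = v), class = "region")
}

#' @rdname region
#' @param x1,y1,x2,y2 Rectangle corners, `x1 < x2`, `y1 < y2`.
#' @export
rect_region <- function(x1, y1, x2, y2) {
  region("rectangle", rbind(c(x1, y1), c(x2, y2)))
}

#' @rdname region
#' @param x Either a vector of x coordinates or an n x 2 vertex matrix.
#' @param y Vector of y coordinates when `x` is a vector.
#' @export
polygon_region <- function(x, y = NULL) {
  v <- if (is.null(y)) x else cbind(x, y)
  region("polygon", v)
}

# point on segment check, used so that polygon boundaries count as inside
.point_on_segment <- function(px, py, x1, y1, x2, y2, eps = 1e-9) {
  scale <- max(1, abs(x2 - x1) + abs(y2 - y1))
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  if (abs(cross) > eps * scale) return(FALSE)
  px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
    py >= min(y1, y2) - eps && py <= max(y1, y2) + eps
}

# even-odd rule via ray casting; boundary inclusive
.point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (.point_on_segment(px, py, v[j, 1], v[j, 2], v[i, 1], v[i, 2])) {
      return(TRUE)
    }
    if ((v[i, 2] > py) != (v[j, 2] > py)) {
      xint <- v[j, 1] + (py - v[j, 2]) * (v[i, 1] - v[j, 1]) / (v[i, 2] - v[j, 2])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Point-in-region test
#'
#' Rectangles are half-open (`x1 <= x < x2`, `y1 <= y < y2`) so adjacent
#' regions never double-count a pixel. Polygons use the even-odd rule with
#' an inclusive boundary.
#'
#' @param x,y Point coordinates in pixels.
#' @param region A [region()] object.
#' @return `TRUE` if the point lies inside the region.
#' @export
point_in_region <- function(x, y, region) {
  v <- region$vertices
  if (region$kind == "rectangle") {
    x >= v[1, 1] && x < v[2, 1] && y >= v[1, 2] && y < v[2, 2]
  } else {
    .point_in_polygon(x, y, v)
  }
}

#' Region centroid and bounding box
#'
#' The centroid of a rectangle is its centre; for polygons the vertex mean
#' is used (adequate for the roughly convex object outlines handled here).
#'
#' @param region A [region()] object.
#' @return `region_centroid`: numeric `c(x, y)`. `region_bbox`: the
#'   axis-aligned bounding rectangle as a [region()].
#' @export
region_centroid <- function(region) {
  v <- region$vertices
  if (region$kind == "rectangle") {
    c((v[1, 1] + v[2, 1]) / 2, (v[1, 2] + v[2, 2]) / 2)
  } else {
    colMeans(v)
  }
}

#' @rdname region_centroid
#' @export
region_bbox <- function(region) {
  v <- region$vertices
  if (region$kind == "rectangle") return(region)
  rect_region(min(v[, 1]), min(v[, 2]), max(v[, 1]), max(v[, 2]))
}

#' Keyframed AOI annotation track
#'
#' An AOI (area of interest) track holds the region of one annotated object
#' at a strictly increasing sequence of keyframes; regions for intermediate
#' frames are obtained by vertex-wise linear interpolation
#' ([interpolate_track()]). Outside the keyframe span the AOI is considered
#' absent (off screen) -- no extrapolation is performed.
#'
#' @param aoi AOI name.
#' @param frames Integer vector of 0-based keyframe indices, strictly
#'   increasing.
#' @param regions List of [region()] objects, one per keyframe, all of the
#'   same kind.
#' @return An object of class `aoi_track`.
#' @export
aoi_track <- function(aoi, frames, regions) {
  stopifnot(is.character(aoi), length(aoi) == 1L,
            length(frames) == length(regions), length(frames) >= 1L)
  if (any(diff(frames) <= 0)) stop("keyframe indices must be strictly increasing")
  kinds <- vapply(regions, function(r) r$kind, character(1))
  if (length(unique(kinds)) > 1L) {
    stop("all keyframes of a track must share one region kind")
  }
  structure(list(aoi = aoi, frames = as.integer(frames), regions = regions),
            class = "aoi_track")
}

#' Interpolate an AOI track at a frame
#'
#' Returns the keyframe region exactly at a keyframe, the vertex-wise linear
#' interpolation between the two bracketing keyframes in between, and `NULL`
#' outside the keyframe span (AOI not on screen).
#'
#' @param track An [aoi_track()].
#' @param frame 0-based frame index.
#' @return A [region()] or `NULL`.
#' @export
interpolate_track <- function(track, frame) {
  f <- track$frames
  if (frame < f[1L] || frame > f[length(f)]) return(NULL)
  i <- findInterval(frame, f)
  if (f[i] == frame) return(track$regions[[i]])
  r1 <- track$regions[[i]]
  r2 <- track$regions[[i + 1L]]
  if (nrow(r1$vertices) != nrow(r2$vertices)) {
    stop(sprintf(
      "track '%s': cannot interpolate between keyframes %d and %d with %d vs %d vertices",
      track$aoi, f[i], f[i + 1L], nrow(r1$vertices), nrow(r2$vertices)))
  }
  w <- (frame - f[i]) / (f[i + 1L] - f[i])
  region(r1$kind, (1 - w) * r1$vertices + w * r2$vertices)
}

#' Gaze sample stream
#'
#' @param timestamp Milliseconds from recording start, non-decreasing.
#' @param x,y Gaze position in pixels.
#' @param valid Logical validity flag (tracking loss etc.).
#' @return A data frame with columns `timestamp`, `x`, `y`, `valid`.
#' @export
gaze_samples <- function(timestamp = numeric(), x = numeric(),
                         y = numeric(), valid = TRUE) {
  n <- length(timestamp)
  valid <- rep_len(valid, n)
  if (n && any(timestamp < 0)) stop("gaze timestamps must be >= 0")
  if (n && any(diff(timestamp) < 0)) {
    stop("gaze timestamps must be non-decreasing")
  }
  data.frame(timestamp = as.numeric(timestamp), x = as.numeric(x),
             y = as.numeric(y), valid = valid)
}

#' Fixation event stream
#'
#' @param start,end Fixation interval in milliseconds, `end > start`,
#'   half-open.
#' @param x,y Fixation centroid in pixels.
#' @return A data frame with columns `start`, `end`, `x`, `y`.
#' @export
fixation_events <- function(start = numeric(), end = numeric(),
                            x = numeric(), y = numeric()) {
  if (length(start) && any(end <= start)) {
    stop("fixations must satisfy end > start")
  }
  data.frame(start = as.numeric(start), end = as.numeric(end),
             x = as.numeric(x), y = as.numeric(y))
}

#' Attention events
#'
#' A detected or ground-truth attention interval for one AOI. Intervals are
#' half-open `[start, end)` in milliseconds. `aoi` may be `NA` for detected
#' events whose raw label has no AOI mapping (kept so insertions can be
#' audited).
#'
#' @param start,end Event interval in milliseconds, `end > start`.
#' @param label Raw label (e.g. the vision model's class label).
#' @param aoi Mapped AOI name, or `NA` when unmapped.
#' @param probability Model probability in `[0, 1]`.
#' @param source One of `"IC"`, `"OD"`, `"ground_truth"`, `"synthetic"`.
#' @return A data frame with columns `aoi`, `label`, `start`, `end`,
#'   `probability`, `source`.
#' @export
attention_events <- function(start = numeric(), end = numeric(),
                             label = "target", aoi = label,
                             probability = 1, source = "ground_truth") {
  n <- length(start)
  stopifnot(length(end) == n)
  if (n && any(end <= start)) stop("attention events must satisfy end > start")
  df <- data.frame(aoi = rep_len(as.character(aoi), n),
                   label = rep_len(as.character(label), n),
                   start = as.numeric(start), end = as.numeric(end),
                   probability = rep_len(as.numeric(probability), n),
                   source = rep_len(as.character(source), n))
  df
}

# canonical empty event table
empty_events <- function() attention_events(numeric(0), numeric(0))
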