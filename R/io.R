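# File formats: gaze/fixation CSV, attention events JSON Lines, AOI tracks
# JSON, detection fixtures JSON, metrics/EAD CSV, and the packaged
# scenario label->AOI maps.

#' Read and write gaze sample streams
#'
#' CSV with header `timestamp_ms,x_px,y_px,valid`; the round trip is
#' lossless to the written precision. Malformed rows are rejected with the
#' offending line number.
#'
#' @param path File path.
#' @return `read_gaze`: a [gaze_samples()] data frame.
#' @export
read_gaze <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(df))) {
    stop("gaze CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(df$timestamp_ms) | is.na(df$x_px) | is.na(df$y_px))
  if (length(bad)) {
    stop("malformed gaze row at line ", bad[1L] + 1L)
  }
  gaze_samples(timestamp = df$timestamp_ms, x = df$x_px, y = df$y_px,
               valid = as.logical(df$valid))
}

#' @rdname read_gaze
#' @param gaze A [gaze_samples()] data frame.
#' @export
write_gaze <- function(gaze, path) {
  out <- data.frame(timestamp_ms = gaze$timestamp, x_px = gaze$x,
                    y_px = gaze$y, valid = gaze$valid)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write fixation event streams
#'
#' CSV with header `start_ms,end_ms,x_px,y_px`.
#'
#' @param path File path.
#' @return `read_fixations`: a [fixation_events()] data frame.
#' @export
read_fixations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_ms", "end_ms", "x_px", "y_px")
  if (!all(need %in% names(df))) {
    stop("fixation CSV must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(df$start_ms) | is.na(df$end_ms))
  if (length(bad)) stop("malformed fixation row at line ", bad[1L] + 1L)
  fixation_events(start = df$start_ms, end = df$end_ms,
                  x = df$x_px, y = df$y_px)
}

#' @rdname read_fixations
#' @param fixations A [fixation_events()] data frame.
#' @export
write_fixations <- function(fixations, path) {
  out <- data.frame(start_ms = fixations$start, end_ms = fixations$end,
                    x_px = fixations$x, y_px = fixations$y)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read and write attention events as JSON Lines
#'
#' One JSON object per line with fields `aoi`, `label`, `start_ms`,
#' `end_ms`, `probability`, `source`; events are sorted by start time on
#' write. Events with `end <= start` are rejected.
#'
#' @param path File path.
#' @return `read_events`: an [attention_events()] data frame.
#' @export
read_events <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_events())
  rows <- lapply(seq_along(lines), function(i) {
    x <- jsonlite::fromJSON(lines[i])
    if (is.null(x$start_ms) || is.null(x$end_ms) || x$end_ms <= x$start_ms) {
      stop("line ", i, ": event must have end_ms > start_ms")
    }
    data.frame(aoi = if (is.null(x$aoi)) NA_character_ else x$aoi,
               label = if (is.null(x$label)) NA_character_ else x$label,
               start = x$start_ms, end = x$end_ms,
               probability = if (is.null(x$probability)) NA_real_ else x$probability,
               source = if (is.null(x$source)) NA_character_ else x$source)
  })
  do.call(rbind, rows)
}

#' @rdname read_events
#' @param events An [attention_events()] data frame.
#' @export
write_events <- function(events, path) {
  events <- events[order(events$start, events$aoi), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    rec <- list(aoi = events$aoi[i], label = events$label[i],
                start_ms = events$start[i], end_ms = events$end[i],
                probability = events$probability[i],
                source = events$source[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                digits = NA), con)
  }
  invisible(path)
}

#' Read and write AOI annotation tracks as JSON
#'
#' Format: `{"video": {"width", "height", "fps", "n_frames"}, "tracks":
#' [{"aoi", "kind", "keyframes": [{"frame", "vertices": [[x, y], ...]},
#' ...]}]}`. Keyframed polygon exports from annotation tools (e.g.
#' CVAT-style tracks) map onto this structure directly.
#'
#' @param path File path.
#' @return `read_tracks`: `list(meta = <video_meta>, tracks = <list of
#'   aoi_track>)`.
#' @export
read_tracks <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  meta <- video_meta(width = x$video$width, height = x$video$height,
                     fps = x$video$fps, n_frames = x$video$n_frames)
  tracks <- lapply(x$tracks, function(tr) {
    frames <- vapply(tr$keyframes, function(k) as.integer(k$frame), integer(1))
    regions <- lapply(tr$keyframes, function(k) {
      v <- do.call(rbind, lapply(k$vertices, unlist))
      region(tr$kind, v)
    })
    aoi_track(tr$aoi, frames, regions)
  })
  list(meta = meta, tracks = tracks)
}

#' @rdname read_tracks
#' @param meta A [video_meta()].
#' @param tracks List of [aoi_track()] objects.
#' @export
write_tracks <- function(meta, tracks, path) {
  x <- list(
    video = list(width = meta$width, height = meta$height, fps = meta$fps,
                 n_frames = meta$n_frames),
    tracks = lapply(tracks, function(tr) {
      list(aoi = tr$aoi, kind = tr$regions[[1L]]$kind,
           keyframes = lapply(seq_along(tr$frames), function(i) {
             v <- tr$regions[[i]]$vertices
             list(frame = tr$frames[i],
                  vertices = lapply(seq_len(nrow(v)),
                                    function(r) c(v[r, 1], v[r, 2])))
           }))
    }))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read a scripted detection fixture as an OD backend
#'
#' JSON format: `{"<frame>": [{"label", "probability", "bbox": [x1, y1, x2,
#' y2], "mask": [[x, y], ...]}, ...], ...}`; `mask` is optional.
#'
#' @param path File path.
#' @return A `function(frame)` suitable for [run_od()].
#' @export
read_detections <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  frames <- lapply(x, function(insts) {
    lapply(insts, function(d) {
      bb <- unlist(d$bbox)
      mask <- if (is.null(d$mask)) {
        NULL
      } else {
        polygon_region(do.call(rbind, lapply(d$mask, unlist)))
      }
      detected_instance(d$label, d$probability,
                        rect_region(bb[1], bb[2], bb[3], bb[4]), mask)
    })
  })
  scripted_detector_backend(frames)
}

#' List the packaged evaluation scenarios
#'
#' @return Character vector of scenario names shipped with the package.
#' @export
list_scenarios <- function() {
  unique(.scenario_table()$scenario)
}

.scenario_table <- function() {
  path <- system.file("extdata", "scenario_label_maps.csv",
                      package = "gazeaoi", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Load a scenario's label-to-AOI mapping
#'
#' The package ships the label->AOI maps for the eleven benchmark scenarios
#' for both detection methods (ImageNet-style labels for IC, MS-COCO-style
#' labels for OD). AOIs without any usable class label are listed as
#' unmapped: no method can detect attention to them and they are expected
#' to fail.
#'
#' @param scenario Scenario name (see [list_scenarios()]).
#' @param method `"IC"` or `"OD"`.
#' @param path Optional path to a custom CSV with columns `scenario`,
#'   `method`, `aoi`, `label` (empty label = unmapped AOI); defaults to the
#'   packaged table.
#' @return An object of class `scenario_config`: a list with `scenario`,
#'   `method`, `mapping` (named character, label -> AOI), `aois` and
#'   `unmapped_aois`.
#' @export
load_scenario_config <- function(scenario, method = c("IC", "OD"),
                                 path = NULL) {
  method <- match.arg(method)
  tab <- if (is.null(path)) {
    .scenario_table()
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  }
  if (!scenario %in% tab$scenario) {
    stop("unknown scenario '", scenario, "'; available: ",
         paste(unique(tab$scenario), collapse = ", "))
  }
  rows <- tab[tab$scenario == scenario & tab$method == method, , drop = FALSE]
  mapped <- rows[!is.na(rows$label), , drop = FALSE]
  if (anyDuplicated(mapped$label)) {
    stop("scenario '", scenario, "': a label maps to more than one AOI")
  }
  mapping <- stats::setNames(mapped$aoi, mapped$label)
  structure(list(scenario = scenario, method = method, mapping = mapping,
                 aois = unique(rows$aoi),
                 unmapped_aois = setdiff(unique(rows$aoi),
                                         unique(mapped$aoi))),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s [%s]: %d labels -> %d AOIs (%d unmapped)\n",
              x$scenario, x$method, length(x$mapping),
              length(x$aois), length(x$unmapped_aois)))
  invisible(x)
}
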