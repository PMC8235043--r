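# Attention detection by gaze-guided image classification (IC).
#
# Pipeline: resample gaze to a low rate -> crop a patch around each gaze
# sample -> classify the patch (pluggable backend, top-5 labels with
# probabilities) -> merge similar labels -> feed the top-1 prediction into a
# working-memory, threshold-based event machine that emits attention
# started/confirmed/ended signals.

#' IC method configuration
#'
#' Defaults follow the reference setting `IC-152-300-40`: duration and noise
#' thresholds of 300 ms, probability threshold 40%, a ResNet-152 style
#' backend, gaze resampled to 5 Hz and 200x200 px patches.
#'
#' @param t_dur Duration threshold in ms; a label must accumulate more than
#'   this before an attention event starts.
#' @param t_noise Noise threshold in ms; accumulated off-label time beyond
#'   this resets a label (and ends its event if active).
#' @param t_prob Minimum probability; the top-1 prediction must *exceed*
#'   this to count towards its duration counter.
#' @param model Backend model name, used only for method naming/logging.
#' @param sample_rate Gaze resampling rate in Hz.
#' @param patch_size Side length of the square crop in pixels.
#' @return An object of class `ic_config`.
#' @export
ic_config <- function(t_dur = 300, t_noise = 300, t_prob = 0.40,
                      model = "resnet152", sample_rate = 5,
                      patch_size = 200L) {
  stopifnot(t_dur > 0, t_noise > 0, t_prob >= 0, t_prob <= 1,
            sample_rate > 0, patch_size > 0)
  structure(list(t_dur = t_dur, t_noise = t_noise, t_prob = t_prob,
                 model = model, sample_rate = sample_rate,
                 patch_size = as.integer(patch_size)),
            class = "ic_config")
}

#' Parameterised method name, e.g. "IC-152-300-40"
#'
#' @param config An [ic_config()].
#' @return Character scalar `IC-<model>-<Tdur/noise>-<Tp>`.
#' @export
ic_method_name <- function(config) {
  digits <- gsub("[^0-9]", "", config$model)
  if (!nzchar(digits)) digits <- config$model
  sprintf("IC-%s-%d-%d", digits, as.integer(config$t_dur),
          as.integer(round(100 * config$t_prob)))
}

#' @export
print.ic_config <- function(x, ...) {
  cat(sprintf("<ic_config> %s (Tnoise=%g ms, %g Hz, %d px patch)\n",
              ic_method_name(x), x$t_noise, x$sample_rate, x$patch_size))
  invisible(x)
}

#' Resample a gaze stream to a fixed rate
#'
#' Ticks are placed every `1000/rate` ms starting at the first sample's
#' timestamp. Each tick keeps the input sample nearest in time (ties go to
#' the earlier sample); ticks with no sample within half a tick are dropped,
#' and a sample is never emitted twice.
#'
#' @param gaze A [gaze_samples()] data frame.
#' @param rate Target rate in Hz (default 5).
#' @return A subset of `gaze` rows, ordered in time.
#' @export
resample_gaze <- function(gaze, rate = 5) {
  if (nrow(gaze) == 0L) return(gaze)
  tick <- 1000 / rate
  ts <- gaze$timestamp
  ticks <- seq(ts[1L], ts[length(ts)], by = tick)
  lo <- findInterval(ticks, ts)         # last sample at or before each tick
  lo[lo < 1L] <- 1L
  hi <- pmin(lo + 1L, length(ts))
  d_lo <- abs(ticks - ts[lo])
  d_hi <- abs(ts[hi] - ticks)
  pick <- ifelse(d_hi < d_lo, hi, lo)   # tie -> earlier sample
  dist <- pmin(d_lo, d_hi)
  pick <- pick[dist <= tick / 2]
  pick <- pick[!duplicated(pick)]
  gaze[pick, , drop = FALSE]
}

#' Gaze-centred crop geometry
#'
#' Computes the `patch` x `patch` pixel rectangle centred at the gaze point,
#' shifted where necessary so it lies fully inside the frame. Gaze points
#' outside the frame are clamped to the frame first.
#'
#' @param x,y Gaze position in pixels.
#' @param patch Patch side length in pixels; must not exceed the frame.
#' @param meta A [video_meta()].
#' @return A rectangle [region()] of size `patch` x `patch`.
#' @export
crop_geometry <- function(x, y, patch, meta) {
  stopifnot(patch <= min(meta$width, meta$height))
  x <- min(max(x, 0), meta$width)
  y <- min(max(y, 0), meta$height)
  x1 <- min(max(x - patch / 2, 0), meta$width - patch)
  y1 <- min(max(y - patch / 2, 0), meta$height - patch)
  rect_region(x1, y1, x1 + patch, y1 + patch)
}

#' Merge similar class labels
#'
#' Labels that map to the same canonical label under `merge_map` are
#' replaced by a single entry whose probability is the sum of the merged
#' probabilities; the result is sorted by probability, descending (stable in
#' input order on ties). Labels absent from the map are their own canonical
#' label.
#'
#' @param preds Data frame with columns `label` and `probability` (the top-k
#'   output of a classification backend).
#' @param merge_map Named character vector mapping label -> canonical label.
#' @return A data frame with columns `label`, `probability`.
#' @export
merge_labels <- function(preds, merge_map = character()) {
  if (nrow(preds) == 0L) return(preds[, c("label", "probability")])
  canon <- preds$label
  hit <- canon %in% names(merge_map)
  canon[hit] <- unname(merge_map[canon[hit]])
  first_pos <- match(unique(canon), canon)
  prob <- vapply(unique(canon),
                 function(l) sum(preds$probability[canon == l]),
                 numeric(1))
  out <- data.frame(label = unique(canon), probability = unname(prob))
  out[order(-out$probability, first_pos), , drop = FALSE]
}

#' Fresh IC event-machine state
#'
#' Holds the per-label duration counter `Cdur`, the per-label noise counter
#' `Cnoise`, the currently attended label and the timestamp of the last
#' update. The first update of a stream contributes no time (`last_update`
#' is initialised at the first prediction's timestamp).
#'
#' @return An object of class `ic_state`.
#' @export
new_ic_state <- function() {
  structure(list(c_dur = numeric(), c_noise = numeric(),
                 last_prob = numeric(), active = NA_character_,
                 last_update = NA_real_),
            class = "ic_state")
}

#' One step of the IC attention event machine
#'
#' With `delta` the stream time since the previous update:
#' 1. if `p > Tp`, `Cdur[c] += delta` and every other label with a non-zero
#'    duration counter gets `Cnoise += delta`; if `p <= Tp` the tick counts
#'    as noise for *all* labels with non-zero duration (a low-confidence
#'    tick supports no label);
#' 2. if `Cdur[c] > Tdur`: an `ended` signal for a different active label is
#'    emitted first, then `started` for `c` (`confirmed` when `c` is already
#'    active); `c` becomes active and both its counters reset;
#' 3. any label whose noise counter exceeds `Tnoise` has both counters
#'    reset; if it was active an `ended` signal is emitted and the active
#'    label cleared.
#'
#' All emitted timestamps are `timestamp - Tdur`, compensating the detection
#' latency of the duration threshold.
#'
#' @param state An `ic_state` (see [new_ic_state()]).
#' @param label,probability The incoming top-1 prediction `(c, p(c))`.
#' @param timestamp Prediction timestamp in ms; must not precede the
#'   previous update.
#' @param config An [ic_config()].
#' @return `list(state = <updated state>, signals = <data frame>)`; signals
#'   have columns `kind` (`started`/`confirmed`/`ended`), `label`,
#'   `probability`, `timestamp`.
#' @export
update_attention <- function(state, label, probability, timestamp, config) {
  if (!is.na(state$last_update) && timestamp < state$last_update) {
    stop("prediction timestamps must be non-decreasing")
  }
  delta <- if (is.na(state$last_update)) 0 else timestamp - state$last_update
  cd <- state$c_dur
  cn <- state$c_noise
  if (!label %in% names(cd)) {
    cd[label] <- 0
    cn[label] <- 0
  }
  state$last_prob[label] <- probability

  sig_kind <- character()
  sig_label <- character()
  sig_prob <- numeric()
  emit <- function(kind, lab, prob) {
    sig_kind[length(sig_kind) + 1L] <<- kind
    sig_label[length(sig_label) + 1L] <<- lab
    sig_prob[length(sig_prob) + 1L] <<- prob
  }

  if (probability > config$t_prob) {
    cd[label] <- cd[label] + delta
    grow <- setdiff(names(cd)[cd > 0], label)
    cn[grow] <- cn[grow] + delta
  } else {
    grow <- names(cd)[cd > 0]
    cn[grow] <- cn[grow] + delta
  }

  if (cd[label] > config$t_dur) {
    if (!is.na(state$active) && state$active != label) {
      emit("ended", state$active, state$last_prob[[state$active]])
    }
    kind <- if (!is.na(state$active) && state$active == label) "confirmed" else "started"
    emit(kind, label, probability)
    state$active <- label
    cd[label] <- 0
    cn[label] <- 0
  }

  for (k in names(cn)[cn > config$t_noise]) {
    cd[k] <- 0
    cn[k] <- 0
    if (!is.na(state$active) && state$active == k) {
      emit("ended", k, state$last_prob[[k]])
      state$active <- NA_character_
    }
  }

  state$c_dur <- cd
  state$c_noise <- cn
  state$last_update <- timestamp
  signals <- data.frame(kind = sig_kind, label = sig_label,
                        probability = sig_prob,
                        timestamp = rep(timestamp - config$t_dur,
                                        length(sig_kind)))
  list(state = state, signals = signals)
}

#' Run the IC event machine over a prediction stream
#'
#' @param stream Data frame with columns `timestamp`, `label`,
#'   `probability` (time-ordered top-1 predictions).
#' @param config An [ic_config()].
#' @return Data frame of attention signals (see [update_attention()]).
#' @export
detect_attention <- function(stream, config = ic_config()) {
  state <- new_ic_state()
  out <- vector("list", nrow(stream))
  for (i in seq_len(nrow(stream))) {
    step <- update_attention(state, stream$label[i], stream$probability[i],
                             stream$timestamp[i], config)
    state <- step$state
    out[[i]] <- step$signals
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(kind = character(), label = character(),
                      probability = numeric(), timestamp = numeric())
  }
  res
}

#' Pair attention signals into events
#'
#' Each `started` ... `ended` pair of the same label becomes one
#' [attention_events()] row; `confirmed` signals do not alter intervals. A
#' `started` without a matching `ended` is closed at `end_time` (evaluation
#' needs finite intervals); an `ended` without a `started` is dropped with a
#' warning. Zero-duration pairs are discarded.
#'
#' @param signals Time-ordered signal data frame.
#' @param end_time Closing timestamp for unterminated events; defaults to
#'   the last signal timestamp.
#' @param source Source tag for the produced events.
#' @return An [attention_events()] data frame.
#' @export
signals_to_events <- function(signals, end_time = NULL, source = "IC") {
  if (nrow(signals) == 0L) return(empty_events())
  if (is.null(end_time)) end_time <- max(signals$timestamp)
  open_start <- numeric()
  open_prob <- numeric()
  starts <- ends <- probs <- numeric()
  labels <- character()
  close_event <- function(lab, at) {
    if (at > open_start[[lab]]) {
      starts[length(starts) + 1L] <<- open_start[[lab]]
      ends[length(ends) + 1L] <<- at
      probs[length(probs) + 1L] <<- open_prob[[lab]]
      labels[length(labels) + 1L] <<- lab
    }
    open_start[[lab]] <<- NA_real_
  }
  for (i in seq_len(nrow(signals))) {
    lab <- signals$label[i]
    kind <- signals$kind[i]
    is_open <- lab %in% names(open_start) && !is.na(open_start[[lab]])
    if (kind == "started") {
      if (is_open) {
        warning(sprintf("label '%s': started while already open; closing", lab))
        close_event(lab, signals$timestamp[i])
      }
      open_start[[lab]] <- signals$timestamp[i]
      open_prob[[lab]] <- signals$probability[i]
    } else if (kind == "ended") {
      if (!is_open) {
        warning(sprintf("label '%s': ended without started; dropped", lab))
      } else {
        close_event(lab, signals$timestamp[i])
      }
    }
  }
  for (lab in names(open_start)) {
    if (!is.na(open_start[[lab]])) close_event(lab, end_time)
  }
  ev <- attention_events(start = starts, end = ends, label = labels,
                         aoi = labels, probability = probs, source = source)
  ev[order(ev$start, ev$label), , drop = FALSE]
}

#' Run the full IC detection pipeline
#'
#' Composition of [resample_gaze()], [crop_geometry()], the classification
#' backend, [merge_labels()], [update_attention()] and
#' [signals_to_events()]. Event labels are translated to AOI names through
#' `aoi_map`; events with unmapped labels are kept with `aoi = NA` so
#' insertion errors remain auditable. A backend failure on a patch skips
#' that tick with a warning.
#'
#' @param gaze A [gaze_samples()] data frame.
#' @param meta A [video_meta()].
#' @param backend `function(x, y, timestamp)` returning a data frame with
#'   columns `label`, `probability` (up to five rows), e.g.
#'   [scripted_classifier_backend()].
#' @param merge_map Named character vector, label -> canonical label.
#' @param aoi_map Named character vector, canonical label -> AOI name
#'   (e.g. `load_scenario_config(...)$mapping`).
#' @param config An [ic_config()].
#' @return An [attention_events()] data frame with `source = "IC"`.
#' @export
run_ic <- function(gaze, meta, backend, merge_map = character(),
                   aoi_map = character(), config = ic_config()) {
  rs <- resample_gaze(gaze, config$sample_rate)
  rs <- rs[rs$valid, , drop = FALSE]
  state <- new_ic_state()
  sigs <- vector("list", nrow(rs))
  last_t <- NA_real_
  for (i in seq_len(nrow(rs))) {
    crop_geometry(rs$x[i], rs$y[i], config$patch_size, meta)  # validates geometry
    preds <- tryCatch(backend(rs$x[i], rs$y[i], rs$timestamp[i]),
                      error = function(e) {
                        warning(sprintf("backend failed at t=%g ms: %s",
                                        rs$timestamp[i], conditionMessage(e)))
                        NULL
                      })
    if (is.null(preds) || nrow(preds) == 0L) next
    merged <- merge_labels(preds, merge_map)
    step <- update_attention(state, merged$label[1L], merged$probability[1L],
                             rs$timestamp[i], config)
    state <- step$state
    sigs[[i]] <- step$signals
    last_t <- rs$timestamp[i]
  }
  signals <- do.call(rbind, sigs)
  if (is.null(signals) || nrow(signals) == 0L) return(empty_events())
  events <- signals_to_events(signals, end_time = last_t, source = "IC")
  events$aoi <- unname(aoi_map[events$label])
  events
}

#' Scripted classifier backend
#'
#' Wraps a pre-computed classification stream (e.g. from
#' [mock_classifier()]) as an IC backend: each call returns the stream row
#' nearest in time to the requested timestamp.
#'
#' @param stream Data frame with columns `timestamp`, `label`,
#'   `probability`.
#' @return A `function(x, y, timestamp)` suitable for [run_ic()].
#' @export
scripted_classifier_backend <- function(stream) {
  force(stream)
  function(x, y, timestamp) {
    i <- which.min(abs(stream$timestamp - timestamp))
    stream[i, c("label", "probability"), drop = FALSE]
  }
}
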