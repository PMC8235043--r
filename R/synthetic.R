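# Synthetic fixture generation: ground-truth event scenarios, controlled
# error-injected prediction streams with exact expected error ledgers,
# noisy gaze traces, and scripted classifier/detector backends. Everything
# is deterministic under an explicit seed (withr::with_seed; no global RNG
# state leaks).

#' Generate disjoint ground-truth attention events
#'
#' Draws `n` ordered, non-overlapping events whose durations and inter-event
#' gaps are sampled uniformly from the given ranges and snapped to the frame
#' grid, so downstream frame-level scoring is exact. The first event starts
#' after one gap.
#'
#' @param n Number of events.
#' @param duration_range,gap_range Ranges in ms (`c(min, max)`); the minimum
#'   gap must exceed two frame times so neighbouring events stay separable.
#' @param seed Integer seed; identical seeds give identical output.
#' @param frame_ms Frame duration used for grid alignment (default 40 ms,
#'   i.e. 25 fps).
#' @param aoi,label AOI name and raw label for all events.
#' @return An [attention_events()] data frame with
#'   `source = "ground_truth"`.
#' @export
gen_gt_events <- function(n, duration_range = c(800, 2000),
                          gap_range = c(600, 1600), seed = 1,
                          frame_ms = 40, aoi = "target", label = aoi) {
  stopifnot(n >= 0, gap_range[1] > 2 * frame_ms)
  if (n == 0L) return(empty_events())
  grid_range <- function(rng) {
    k <- seq(ceiling(rng[1] / frame_ms), floor(rng[2] / frame_ms))
    if (length(k) == 0L) stop("range infeasible on the frame grid")
    k
  }
  kd <- grid_range(duration_range)
  kg <- grid_range(gap_range)
  withr::with_seed(seed, {
    durs <- frame_ms * kd[sample.int(length(kd), n, replace = TRUE)]
    gaps <- frame_ms * kg[sample.int(length(kg), n, replace = TRUE)]
  })
  starts <- cumsum(gaps) + c(0, cumsum(durs))[seq_len(n)]
  attention_events(start = starts, end = starts + durs, label = label,
                   aoi = aoi, probability = 1, source = "ground_truth")
}

#' Perturbation specification
#'
#' Describes a set of non-interacting edits applied to a ground-truth event
#' stream by [perturb_events()]: whole-event deletions, insertions into
#' gaps, fragmentations of single events, merges of consecutive events, and
#' boundary jitter (overfill) on untouched events. Because the edits target
#' distinct, well-separated events, the implied [event_counts()] ledger is
#' exact.
#'
#' @param n_delete Number of ground-truth events to drop.
#' @param n_insert Number of spurious events to insert into gaps.
#' @param fragmentations List of `c(index, parts)`: split event `index`
#'   (1-based) into `parts` pieces separated by two-frame gaps.
#' @param merges List of `c(first, span)`: replace events
#'   `first ... first+span-1` by one bridging event.
#' @param jitter_start,jitter_end Boundary extension in ms applied to
#'   untouched (correct) events: start moves earlier by `jitter_start`, end
#'   moves later by `jitter_end` (overfill; must stay clear of neighbours).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(n_delete = 0, n_insert = 0,
                              fragmentations = list(), merges = list(),
                              jitter_start = 0, jitter_end = 0) {
  stopifnot(n_delete >= 0, n_insert >= 0,
            jitter_start >= 0, jitter_end >= 0)
  for (fr in fragmentations) stopifnot(length(fr) == 2, fr[2] >= 2)
  for (m in merges) stopifnot(length(m) == 2, m[2] >= 2)
  structure(list(n_delete = n_delete, n_insert = n_insert,
                 fragmentations = fragmentations, merges = merges,
                 jitter_start = jitter_start, jitter_end = jitter_end),
            class = "perturbation_spec")
}

#' Apply a perturbation spec to ground-truth events
#'
#' Produces a prediction stream together with the exact [event_counts()]
#' ledger it must score as: each deletion contributes `D`, each insertion
#' `I'`, a fragmentation into `k` parts contributes `F = 1` and `F' = k`, a
#' merge over `g` events contributes `M = g` and `M' = 1`, and every
#' untouched event contributes `C` (boundary jitter leaves it correct).
#' Interacting or infeasible edits are rejected with an error rather than
#' silently mislabelled.
#'
#' @param gt Frame-aligned ground-truth events (one AOI), e.g. from
#'   [gen_gt_events()].
#' @param spec A [perturbation_spec()].
#' @param seed Integer seed controlling which events are deleted and which
#'   gaps receive insertions.
#' @param frame_ms Frame duration in ms.
#' @return `list(pred = <attention_events>, ledger = <event_counts>)`.
#' @export
perturb_events <- function(gt, spec, seed = 1, frame_ms = 40) {
  n <- nrow(gt)
  gt <- gt[order(gt$start), , drop = FALSE]
  frag_idx <- vapply(spec$fragmentations, function(f) as.integer(f[1]), integer(1))
  merge_cov <- unlist(lapply(spec$merges, function(m) m[1]:(m[1] + m[2] - 1L)))
  touched <- c(frag_idx, merge_cov)
  if (any(touched < 1L) || any(touched > n)) {
    stop("perturbation targets an event index outside the stream")
  }
  if (anyDuplicated(touched)) stop("conflicting perturbation targets")
  avail <- setdiff(seq_len(n), touched)
  if (spec$n_delete > length(avail)) stop("not enough events left to delete")
  # a gap lying inside a merge span is bridged by the merging prediction and
  # cannot receive an insertion
  gap_ok <- rep(TRUE, max(n - 1L, 0L))
  for (m in spec$merges) {
    span <- m[1]:(m[1] + m[2] - 1L)
    gap_ok[span[-length(span)]] <- FALSE
  }
  free_gaps <- which(gap_ok)
  if (spec$n_insert > length(free_gaps)) {
    stop("not enough gaps for the insertions")
  }
  withr::with_seed(seed, {
    del_idx <- avail[sample.int(length(avail), spec$n_delete)]
    ins_gaps <- if (spec$n_insert > 0) {
      free_gaps[sample.int(length(free_gaps), spec$n_insert)]
    } else {
      integer()
    }
  })
  correct_idx <- setdiff(avail, del_idx)

  # jitter feasibility: extensions must not reach a neighbouring event
  if (spec$jitter_start > 0 || spec$jitter_end > 0) {
    for (i in correct_idx) {
      prev_end <- if (i > 1L) gt$end[i - 1L] else -Inf
      next_start <- if (i < n) gt$start[i + 1L] else Inf
      if (gt$start[i] - spec$jitter_start < max(0, prev_end + frame_ms) ||
          gt$end[i] + spec$jitter_end > next_start - frame_ms) {
        stop("jitter too large for the gaps around event ", i)
      }
    }
  }

  pieces <- list()
  add <- function(start, end, prob = 0.9) {
    pieces[[length(pieces) + 1L]] <<- data.frame(start = start, end = end,
                                                 probability = prob)
  }
  for (i in correct_idx) {
    add(max(0, gt$start[i] - spec$jitter_start),
        gt$end[i] + spec$jitter_end)
  }
  for (fr in spec$fragmentations) {
    i <- as.integer(fr[1])
    k <- as.integer(fr[2])
    nf <- round((gt$end[i] - gt$start[i]) / frame_ms)
    if (nf < k + 2L * (k - 1L)) {
      stop("event ", i, " too short to fragment into ", k, " parts")
    }
    part_frames <- rep((nf - 2L * (k - 1L)) %/% k, k)
    part_frames[k] <- part_frames[k] + (nf - 2L * (k - 1L)) %% k
    at <- gt$start[i]
    for (j in seq_len(k)) {
      add(at, at + part_frames[j] * frame_ms)
      at <- at + (part_frames[j] + 2L) * frame_ms
    }
  }
  for (m in spec$merges) {
    i <- as.integer(m[1])
    j <- i + as.integer(m[2]) - 1L
    add(gt$start[i], gt$end[j])
  }
  for (gi in ins_gaps) {
    lo <- gt$end[gi] + 2 * frame_ms + spec$jitter_end
    hi <- gt$start[gi + 1L] - 2 * frame_ms - spec$jitter_start
    lo <- ceiling(lo / frame_ms) * frame_ms
    if (hi - lo < 2 * frame_ms) stop("gap ", gi, " too small for an insertion")
    mid <- lo + floor((hi - lo - 2 * frame_ms) / (2 * frame_ms)) * frame_ms
    add(mid, mid + 2 * frame_ms, prob = 0.6)
  }

  pred <- do.call(rbind, pieces)
  if (is.null(pred)) {
    pred_events <- empty_events()
  } else {
    pred <- pred[order(pred$start), , drop = FALSE]
    pred_events <- attention_events(start = pred$start, end = pred$end,
                                    label = gt$label[1], aoi = gt$aoi[1],
                                    probability = pred$probability,
                                    source = "synthetic")
  }
  ledger <- event_counts(
    D = spec$n_delete,
    F = length(spec$fragmentations),
    FM = 0,
    M = sum(vapply(spec$merges, function(m) as.integer(m[2]), integer(1))),
    C = length(correct_idx),
    I_prime = spec$n_insert,
    F_prime = sum(vapply(spec$fragmentations,
                         function(f) as.integer(f[2]), integer(1))),
    FM_prime = 0,
    M_prime = length(spec$merges))
  list(pred = pred_events, ledger = ledger)
}

#' Draw a random feasible perturbation spec
#'
#' Samples a small spec (deletions, insertions, at most one fragmentation
#' and one two-event merge, optional one-frame jitter) guaranteed feasible
#' for `gt` under the default generator settings.
#'
#' @param gt Ground-truth events from [gen_gt_events()].
#' @param seed Integer seed.
#' @param frame_ms Frame duration in ms.
#' @return A [perturbation_spec()].
#' @export
random_perturbation_spec <- function(gt, seed = 1, frame_ms = 40) {
  n <- nrow(gt)
  withr::with_seed(seed, {
    merges <- list()
    frags <- list()
    used <- integer()
    if (n >= 3L && stats::runif(1) < 0.7) {
      first <- sample.int(n - 1L, 1L)
      merges <- list(c(first, 2L))
      used <- first:(first + 1L)
    }
    rest <- setdiff(seq_len(n), used)
    long_enough <- rest[(gt$end[rest] - gt$start[rest]) / frame_ms >= 8]
    if (length(long_enough) && stats::runif(1) < 0.7) {
      i <- long_enough[sample.int(length(long_enough), 1L)]
      frags <- list(c(i, sample(2:3, 1L)))
      used <- c(used, i)
    }
    free <- n - length(used)
    n_delete <- if (free > 0) sample(0:min(2L, free), 1L) else 0L
    n_insert <- if (n > 2L) sample(0:min(3L, n - 2L), 1L) else 0L
    jit <- sample(c(0, frame_ms), 1L)
  })
  perturbation_spec(n_delete = n_delete, n_insert = n_insert,
                    fragmentations = frags, merges = merges,
                    jitter_start = jit, jitter_end = jit)
}

#' Scripted classification stream over ground-truth events
#'
#' Emits one top-1 prediction per tick. Inside a ground-truth event the
#' event's label is emitted with probability `p_hit` with chance `hit_prob`,
#' otherwise a confuser label (with probability `p_conf`). Outside events a
#' confuser is always emitted; confusers cycle deterministically per gap so
#' the event machine can terminate an attention event cleanly. The stream
#' extends a few ticks past the last event.
#'
#' @param gt Ground-truth events (one AOI).
#' @param tick_rate Tick rate in Hz (default 5, matching the IC resampling
#'   rate).
#' @param hit_prob Chance that an in-event tick carries the true label.
#' @param confusers Character vector of confuser labels.
#' @param p_hit,p_conf Probability values attached to true/confuser labels.
#' @param seed Integer seed.
#' @param t_end Optional stream end in ms.
#' @return Data frame with columns `timestamp`, `label`, `probability`.
#' @export
mock_classifier <- function(gt, tick_rate = 5, hit_prob = 1,
                            confusers = c("background_a", "background_b"),
                            p_hit = 0.9, p_conf = 0.6, seed = 1,
                            t_end = NULL) {
  stopifnot(hit_prob >= 0, hit_prob <= 1, p_hit >= 0, p_hit <= 1,
            p_conf >= 0, p_conf <= 1, length(confusers) >= 1)
  tick <- 1000 / tick_rate
  if (is.null(t_end)) {
    t_end <- (if (nrow(gt)) max(gt$end) else 0) + 4 * tick
  }
  ts <- seq(0, t_end, by = tick)
  lab <- character(length(ts))
  prob <- numeric(length(ts))
  withr::with_seed(seed, {
    for (i in seq_along(ts)) {
      t <- ts[i]
      inside <- which(gt$start <= t & t < gt$end)
      if (length(inside) && stats::runif(1) < hit_prob) {
        lab[i] <- gt$label[inside[1L]]
        prob[i] <- p_hit
      } else {
        gap_id <- findInterval(t, gt$start)
        lab[i] <- confusers[1L + (gap_id %% length(confusers))]
        prob[i] <- p_conf
      }
    }
  })
  data.frame(timestamp = ts, label = lab, probability = prob)
}

#' Generate noisy gaze samples and fixations for ground-truth events
#'
#' Emulates the dominant eye-tracker failure mode, limited spatial
#' *accuracy*: each attention event receives one isotropic Gaussian offset
#' of scale `sigma` (px) applied to the AOI centroid, shared by all of the
#' event's samples and by its fixation centroid. With `sigma = 0` gaze sits
#' exactly on the centroids. Outside events gaze rests near the bottom-right
#' frame corner (away from any AOI in the bundled scenarios). One fixation
#' spans each event.
#'
#' @param gt Ground-truth events whose `aoi` names match the `tracks`.
#' @param tracks List of [aoi_track()] objects.
#' @param meta A [video_meta()].
#' @param sigma Accuracy-noise scale in pixels (`>= 0`).
#' @param rate Gaze sampling rate in Hz (default 60).
#' @param seed Integer seed.
#' @return `list(gaze = <gaze_samples>, fixations = <fixation_events>)`.
#' @export
gen_gaze <- function(gt, tracks, meta, sigma = 0, rate = 60, seed = 1) {
  stopifnot(sigma >= 0)
  step <- 1000 / rate
  duration <- meta$n_frames * meta$frame_ms
  ts <- seq(0, duration - step / 2, by = step)
  track_names <- vapply(tracks, function(tr) tr$aoi, character(1))
  bg <- c(meta$width - 2, meta$height - 2)
  offsets <- withr::with_seed(seed, {
    matrix(stats::rnorm(2L * nrow(gt), 0, sigma), ncol = 2)
  })
  centroid_at <- function(aoi, t_ms) {
    j <- match(aoi, track_names)
    if (is.na(j)) return(NULL)
    frame <- min(max(floor(t_ms / meta$frame_ms), 0), meta$n_frames - 1L)
    reg <- interpolate_track(tracks[[j]], frame)
    if (is.null(reg)) NULL else region_centroid(reg)
  }
  gx <- rep(bg[1], length(ts))
  gy <- rep(bg[2], length(ts))
  for (i in seq_len(nrow(gt))) {
    in_ev <- which(ts >= gt$start[i] & ts < gt$end[i])
    for (k in in_ev) {
      cen <- centroid_at(gt$aoi[i], ts[k])
      if (!is.null(cen)) {
        gx[k] <- cen[1] + offsets[i, 1]
        gy[k] <- cen[2] + offsets[i, 2]
      }
    }
  }
  fx <- fy <- numeric(nrow(gt))
  for (i in seq_len(nrow(gt))) {
    cen <- centroid_at(gt$aoi[i], (gt$start[i] + gt$end[i]) / 2)
    if (is.null(cen)) cen <- bg
    fx[i] <- cen[1] + offsets[i, 1]
    fy[i] <- cen[2] + offsets[i, 2]
  }
  list(gaze = gaze_samples(timestamp = ts, x = gx, y = gy, valid = TRUE),
       fixations = fixation_events(start = gt$start, end = gt$end,
                                   x = fx, y = fy))
}

#' Detector backend that follows the AOI tracks
#'
#' Returns, for every frame, one detected instance per on-screen AOI track:
#' the bounding box of the interpolated region, and a rectangular polygon
#' mask inset by `mask_inset` px on each side (so masks are strictly
#' contained in their boxes, as with a real instance-segmentation model).
#'
#' @param tracks List of [aoi_track()] objects.
#' @param label_for Optional named character vector AOI -> detector label;
#'   defaults to the AOI name itself.
#' @param probability Detection confidence reported for every instance.
#' @param mask_inset Inset of the polygon mask relative to the box, in px.
#' @return A `function(frame)` suitable for [run_od()].
#' @export
mock_detector_backend <- function(tracks, label_for = NULL,
                                  probability = 0.9, mask_inset = 0) {
  force(tracks)
  function(frame) {
    out <- list()
    for (tr in tracks) {
      reg <- interpolate_track(tr, frame)
      if (is.null(reg)) next
      bb <- region_bbox(reg)
      v <- bb$vertices
      d <- min(mask_inset, (v[2, 1] - v[1, 1]) / 2 - 1,
               (v[2, 2] - v[1, 2]) / 2 - 1)
      d <- max(d, 0)
      mask <- polygon_region(
        x = c(v[1, 1] + d, v[2, 1] - d, v[2, 1] - d, v[1, 1] + d),
        y = c(v[1, 2] + d, v[1, 2] + d, v[2, 2] - d, v[2, 2] - d))
      lab <- if (!is.null(label_for) && tr$aoi %in% names(label_for)) {
        unname(label_for[[tr$aoi]])
      } else {
        tr$aoi
      }
      out[[length(out) + 1L]] <- detected_instance(lab, probability, bb, mask)
    }
    out
  }
}
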