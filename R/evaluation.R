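# Segment-based frame and event error taxonomy for event detection
# (insertion/deletion/fragmentation/merge plus underfill/overfill),
# conservative and progressive precision/recall, aggregation and EAD output.
#
# All scoring is one-vs-rest per AOI on binary frame signals. A segment is a
# maximal run of frames on which both the ground-truth and the prediction
# signal are constant.

#' Event error counts
#'
#' Ground-truth side: deletions `D`, fragmented `F`, fragmented-and-merged
#' `FM`, merged `M`, correct `C`. Prediction side: insertions `I_prime`,
#' fragmenting `F_prime`, fragmenting-and-merging `FM_prime`, merging
#' `M_prime`, and the same `C`. The identities
#' `|E| = D + F + FM + M + C` and `|R| = M' + FM' + F' + I' + C` hold by
#' construction (`E_total`, `R_total`).
#'
#' @param D,F,FM,M,C,I_prime,F_prime,FM_prime,M_prime Non-negative integer
#'   counts.
#' @return An object of class `event_counts`.
#' @export
event_counts <- function(D = 0, F = 0, FM = 0, M = 0, C = 0,
                         I_prime = 0, F_prime = 0, FM_prime = 0,
                         M_prime = 0) {
  x <- list(D = D, F = F, FM = FM, M = M, C = C,
            I_prime = I_prime, F_prime = F_prime,
            FM_prime = FM_prime, M_prime = M_prime)
  stopifnot(all(unlist(x) >= 0))
  x$E_total <- D + F + FM + M + C
  x$R_total <- M_prime + FM_prime + F_prime + I_prime + C
  structure(x, class = "event_counts")
}

#' Frame error counts
#'
#' Positive-side (ground truth on) frames: deletion `Df`, fragmentation
#' `Ff`, underfill at event start/end `Uf_alpha`/`Uf_omega`, and `TP`.
#' Negative-side frames: insertion `If`, merge `Mf`, overfill
#' `Of_alpha`/`Of_omega`, and `TN`. `P` and `N` are the respective totals.
#'
#' @param Df,Ff,Uf_alpha,Uf_omega,TP,If,Mf,Of_alpha,Of_omega,TN Non-negative
#'   frame counts.
#' @return An object of class `frame_counts`.
#' @export
frame_counts <- function(Df = 0, Ff = 0, Uf_alpha = 0, Uf_omega = 0,
                         TP = 0, If = 0, Mf = 0, Of_alpha = 0,
                         Of_omega = 0, TN = 0) {
  x <- list(Df = Df, Ff = Ff, Uf_alpha = Uf_alpha, Uf_omega = Uf_omega,
            TP = TP, If = If, Mf = Mf, Of_alpha = Of_alpha,
            Of_omega = Of_omega, TN = TN)
  stopifnot(all(unlist(x) >= 0))
  x$P <- Df + Ff + Uf_alpha + Uf_omega + TP
  x$N <- If + Mf + Of_alpha + Of_omega + TN
  structure(x, class = "frame_counts")
}

#' Pre-process an event stream for evaluation
#'
#' First removes events shorter than one frame time, then merges same-AOI
#' events separated by a gap smaller than one frame time (in that order).
#' The merged event keeps the first event's label/source and the maximum
#' probability.
#'
#' @param events An [attention_events()] data frame.
#' @param frame_ms Frame duration in ms.
#' @return The cleaned event data frame, ordered by start time.
#' @export
preprocess_events <- function(events, frame_ms) {
  if (nrow(events) == 0L) return(events)
  events <- events[events$end - events$start >= frame_ms, , drop = FALSE]
  if (nrow(events) == 0L) return(events)
  key <- ifelse(is.na(events$aoi), "\r<NA>", events$aoi)
  parts <- lapply(split(seq_len(nrow(events)), key), function(idx) {
    e <- events[idx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    keep <- 1L
    for (i in seq_len(nrow(e))[-1L]) {
      if (e$start[i] - e$end[keep] < frame_ms) {
        e$end[keep] <- max(e$end[keep], e$end[i])
        e$probability[keep] <- max(e$probability[keep], e$probability[i])
      } else {
        keep <- keep + 1L
        e[keep, ] <- e[i, ]
      }
    }
    e[seq_len(keep), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$start, out$aoi), , drop = FALSE]
}

#' Project events onto a binary frame signal
#'
#' A frame is positive iff its midpoint timestamp lies inside some event
#' interval `[start, end)`.
#'
#' @param events An [attention_events()] data frame (typically one AOI).
#' @param meta A [video_meta()].
#' @return Logical vector of length `meta$n_frames`.
#' @export
binarize_events <- function(events, meta) {
  mids <- (seq_len(meta$n_frames) - 0.5) * meta$frame_ms
  sig <- rep(FALSE, meta$n_frames)
  for (i in seq_len(nrow(events))) {
    sig <- sig | (mids >= events$start[i] & mids < events$end[i])
  }
  sig
}

# maximal runs of TRUE as a 2-column matrix of 1-based inclusive frame
# indices
.runs <- function(sig) {
  r <- rle(as.logical(sig))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

# per-frame run id (0 where the signal is off)
.run_ids <- function(sig, runs) {
  ids <- integer(length(sig))
  for (i in seq_len(nrow(runs))) ids[runs[i, 1]:runs[i, 2]] <- i
  ids
}

#' Segment a ground-truth/prediction signal pair
#'
#' A segment ends whenever the ground truth or the prediction changes, so
#' both signals are constant within each segment. Each segment is rated
#' TP/TN/FP/FN from its `(gt, pred)` pair.
#'
#' @param gt,pred Logical frame signals of equal length.
#' @return Data frame with 0-based half-open `start_frame`/`end_frame`,
#'   logical `gt`, `pred` and the `rating`.
#' @export
segment_signals <- function(gt, pred) {
  if (length(gt) != length(pred)) stop("signals must have equal length")
  if (length(gt) == 0L) {
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      gt = logical(), pred = logical(),
                      rating = character()))
  }
  key <- paste0(as.integer(gt), as.integer(pred))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  g <- gt[starts]
  p <- pred[starts]
  rating <- ifelse(g & p, "TP", ifelse(!g & !p, "TN", ifelse(p, "FP", "FN")))
  data.frame(start_frame = starts - 1L, end_frame = ends,
             gt = g, pred = p, rating = rating)
}

#' Score event error classes
#'
#' Classifies every ground-truth and predicted event (maximal positive run)
#' by its overlap structure. A ground-truth event with no overlapping
#' prediction is a deletion `D`; overlapped by two or more predictions it is
#' fragmented; if any of its overlapping predictions also overlaps another
#' ground-truth event it is merged; both conditions give `FM`; an exclusive
#' one-to-one overlap is correct `C`. Symmetrically on the prediction side:
#' no overlap is an insertion `I'`, overlapping two or more ground-truth
#' events is merging (`M'`, or `FM'` if it also fragments), sharing a
#' ground-truth event with other predictions is fragmenting `F'`, and an
#' exclusive one-to-one overlap is `C`. Overlap means at least one shared
#' frame; with half-open intervals, events touching only at a boundary do
#' not overlap. `C` is counted once and is identical from both sides.
#'
#' @param gt,pred Either logical frame signals of equal length, or
#'   [attention_events()] data frames for one AOI (then `meta` is required
#'   and the streams must be preprocessed, i.e. free of within-stream
#'   overlap).
#' @param meta A [video_meta()], only used for data-frame input.
#' @return An [event_counts()] object.
#' @export
score_events <- function(gt, pred, meta = NULL) {
  if (is.data.frame(gt)) {
    stopifnot(!is.null(meta))
    .check_disjoint(gt)
    .check_disjoint(pred)
    gt <- binarize_events(gt, meta)
    pred <- binarize_events(pred, meta)
  }
  stopifnot(length(gt) == length(pred))
  g <- .runs(gt)
  p <- .runs(pred)
  ng <- nrow(g)
  np <- nrow(p)
  if (ng && np) {
    ov <- outer(seq_len(ng), seq_len(np), function(i, j) {
      pmax(g[i, 1], p[j, 1]) <= pmin(g[i, 2], p[j, 2])
    })
  } else {
    ov <- matrix(FALSE, ng, np)
  }
  g_n <- rowSums(ov)
  p_n <- colSums(ov)
  g_frag <- g_n >= 2                     # gt overlapped by >= 2 predictions
  p_merg <- p_n >= 2                     # prediction overlapping >= 2 gts
  g_merged <- as.vector(ov %*% p_merg) > 0
  p_fragging <- as.vector(g_frag %*% ov) > 0
  c_gt <- sum(g_n == 1 & !g_merged)
  c_pred <- sum(p_n == 1 & !p_fragging)
  stopifnot(c_gt == c_pred)
  event_counts(
    D = sum(g_n == 0),
    F = sum(g_frag & !g_merged),
    FM = sum(g_frag & g_merged),
    M = sum(!g_frag & g_merged),
    C = c_gt,
    I_prime = sum(p_n == 0),
    F_prime = sum(p_fragging & !p_merg),
    FM_prime = sum(p_fragging & p_merg),
    M_prime = sum(p_merg & !p_fragging))
}

.check_disjoint <- function(events) {
  if (nrow(events) < 2L) return(invisible(TRUE))
  e <- events[order(events$start), , drop = FALSE]
  if (any(e$start[-1L] < e$end[-nrow(e)])) {
    stop("events within one stream overlap; preprocess them first")
  }
  invisible(TRUE)
}

#' Score frame error classes
#'
#' Projects the segment ratings to frames. False-positive segments inside a
#' prediction run that has true-positive frames on both sides are merge
#' frames `Mf` (the prediction bridges two ground-truth events); before the
#' run's first TP they are overfill `Of_alpha`, after its last TP overfill
#' `Of_omega`; FP segments of a prediction with no TP at all are insertions
#' `If`. Symmetrically, false-negative segments between TP stretches of one
#' ground-truth event are fragmentation frames `Ff`; at the start/end of a
#' partly covered event they are underfill `Uf_alpha`/`Uf_omega`; frames of
#' entirely uncovered events are deletions `Df`. TP/TN frames are counted
#' directly.
#'
#' @inheritParams score_events
#' @return A [frame_counts()] object.
#' @export
score_frames <- function(gt, pred, meta = NULL) {
  if (is.data.frame(gt)) {
    stopifnot(!is.null(meta))
    gt <- binarize_events(gt, meta)
    pred <- binarize_events(pred, meta)
  }
  stopifnot(length(gt) == length(pred))
  segs <- segment_signals(gt, pred)
  tp <- gt & pred
  g_runs <- .runs(gt)
  p_runs <- .runs(pred)
  gid <- .run_ids(gt, g_runs)
  pid <- .run_ids(pred, p_runs)
  tp_range <- function(runs) {
    lapply(seq_len(nrow(runs)), function(i) {
      w <- which(tp[runs[i, 1]:runs[i, 2]])
      if (length(w) == 0L) NULL else runs[i, 1] + c(w[1L], w[length(w)]) - 1L
    })
  }
  g_tp <- tp_range(g_runs)
  p_tp <- tp_range(p_runs)
  cnt <- c(Df = 0, Ff = 0, Uf_alpha = 0, Uf_omega = 0, TP = 0,
           If = 0, Mf = 0, Of_alpha = 0, Of_omega = 0, TN = 0)
  for (s in seq_len(nrow(segs))) {
    a <- segs$start_frame[s] + 1L
    b <- segs$end_frame[s]
    len <- b - a + 1L
    cls <- switch(segs$rating[s],
      TP = "TP",
      TN = "TN",
      FP = {
        rng <- p_tp[[pid[a]]]
        if (is.null(rng)) "If"
        else if (b < rng[1L]) "Of_alpha"
        else if (a > rng[2L]) "Of_omega"
        else "Mf"
      },
      FN = {
        rng <- g_tp[[gid[a]]]
        if (is.null(rng)) "Df"
        else if (b < rng[1L]) "Uf_alpha"
        else if (a > rng[2L]) "Uf_omega"
        else "Ff"
      })
    cnt[cls] <- cnt[cls] + len
  }
  do.call(frame_counts, as.list(cnt))
}

#' Compute performance metrics from error counts
#'
#' Event level: conservative precision `Pr = C/|R|` and recall
#' `Re = C/|E|`; progressive precision `Pr* = (|R|-I')/|R|` and recall
#' `Re* = (|E|-D)/|E|` (fragmenting/merging matches count as correct); the
#' event-based f1 is the harmonic mean of `Pr*` and `Re*`. Frame level:
#' each error count divided by `P` (positive frames) or `N` (negative
#' frames), so that `fpr = ir + mr + o_alpha + o_omega` and
#' `100 - tpr = dr + fr + u_alpha + u_omega`. All values are percentages.
#' Ratios with a zero denominator are `NA` (absent), never 0 or 100.
#'
#' @param ev An [event_counts()] object.
#' @param fr A [frame_counts()] object.
#' @return An object of class `metric_record` (a named list of
#'   percentages).
#' @export
compute_metrics <- function(ev, fr) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  Pr <- pct(ev$C, ev$R_total)
  Re <- pct(ev$C, ev$E_total)
  Pr_star <- pct(ev$R_total - ev$I_prime, ev$R_total)
  Re_star <- pct(ev$E_total - ev$D, ev$E_total)
  f1 <- if (!is.na(Pr_star) && !is.na(Re_star) && Pr_star + Re_star > 0) {
    2 * Pr_star * Re_star / (Pr_star + Re_star)
  } else {
    NA_real_
  }
  dr <- pct(fr$Df, fr$P)
  frr <- pct(fr$Ff, fr$P)
  u_alpha <- pct(fr$Uf_alpha, fr$P)
  u_omega <- pct(fr$Uf_omega, fr$P)
  tpr <- pct(fr$TP, fr$P)
  ir <- pct(fr$If, fr$N)
  mr <- pct(fr$Mf, fr$N)
  o_alpha <- pct(fr$Of_alpha, fr$N)
  o_omega <- pct(fr$Of_omega, fr$N)
  fpr <- if (fr$N > 0) ir + mr + o_alpha + o_omega else NA_real_
  structure(list(Pr = Pr, Re = Re, Pr_star = Pr_star, Re_star = Re_star,
                 f1 = f1, dr = dr, fr = frr, u_alpha = u_alpha,
                 u_omega = u_omega, ir = ir, mr = mr, o_alpha = o_alpha,
                 o_omega = o_omega, fpr = fpr, tpr = tpr),
            class = "metric_record")
}

#' Aggregate error counts over recordings or AOIs
#'
#' Field-wise sums; summing the absolute counts corresponds to
#' concatenating the underlying recordings, and ratio metrics are
#' recomputed afterwards from the summed counts.
#'
#' @param x List of [event_counts()] (or [frame_counts()]) objects; an
#'   empty list yields all-zero counts.
#' @return A single counts object of the same class.
#' @export
aggregate_event_counts <- function(x) {
  fields <- c("D", "F", "FM", "M", "C", "I_prime", "F_prime",
              "FM_prime", "M_prime")
  sums <- lapply(fields, function(f) sum(vapply(x, `[[`, numeric(1), f)))
  names(sums) <- fields
  do.call(event_counts, sums)
}

#' @rdname aggregate_event_counts
#' @export
aggregate_frame_counts <- function(x) {
  fields <- c("Df", "Ff", "Uf_alpha", "Uf_omega", "TP", "If", "Mf",
              "Of_alpha", "Of_omega", "TN")
  sums <- lapply(fields, function(f) sum(vapply(x, `[[`, numeric(1), f)))
  names(sums) <- fields
  do.call(frame_counts, sums)
}

#' @rdname aggregate_event_counts
#' @param pairs List of `list(event = <event_counts>, frame =
#'   <frame_counts>)` pairs from disjoint recordings/AOIs.
#' @export
aggregate_counts <- function(pairs) {
  list(event = aggregate_event_counts(lapply(pairs, `[[`, "event")),
       frame = aggregate_frame_counts(lapply(pairs, `[[`, "frame")))
}

#' Failing-AOI rule
#'
#' An AOI counts as failing when the method essentially never detects it: a
#' frame-level deletion rate `dr >= 90%` (a recall of exactly zero is
#' `dr = 100%`).
#'
#' @param fr A [frame_counts()] object.
#' @return `TRUE`/`FALSE`, or `NA` when `P = 0` (undefined).
#' @export
is_failing <- function(fr) {
  if (fr$P == 0) return(NA)
  100 * fr$Df / fr$P >= 90
}

#' Event analysis diagram (EAD) table
#'
#' Tabulates the event error classes with their counts and their
#' percentages of the ground-truth events `|E|` (for D, F, FM, M, C) and of
#' the returned events `|R|` (for C, FM', M', F', I'). `C` is shown against
#' both denominators.
#'
#' @param ev An [event_counts()] object.
#' @return A data frame with columns `class`, `count`, `pct_E`, `pct_R`.
#' @export
render_ead <- function(ev) {
  classes <- c("D", "F", "FM", "M", "C", "FM'", "M'", "F'", "I'")
  counts <- c(ev$D, ev$F, ev$FM, ev$M, ev$C, ev$FM_prime, ev$M_prime,
              ev$F_prime, ev$I_prime)
  pe <- function(k) if (ev$E_total > 0) 100 * k / ev$E_total else NA_real_
  pr <- function(k) if (ev$R_total > 0) 100 * k / ev$R_total else NA_real_
  data.frame(
    class = classes,
    count = counts,
    pct_E = c(vapply(counts[1:5], pe, numeric(1)), rep(NA_real_, 4)),
    pct_R = c(rep(NA_real_, 4), vapply(counts[5:9], pr, numeric(1))))
}

#' Plot an EAD as two stacked horizontal bars
#'
#' One bar decomposes the ground-truth events `|E|`, the other the returned
#' events `|R|`.
#'
#' @param ev An [event_counts()] object.
#' @param main Plot title.
#' @return Invisibly, the [render_ead()] table.
#' @export
plot_ead <- function(ev, main = "Event analysis diagram") {
  tab <- render_ead(ev)
  e_row <- c(D = ev$D, F = ev$F, FM = ev$FM, M = ev$M, C = ev$C)
  r_row <- c(C = ev$C, "FM'" = ev$FM_prime, "M'" = ev$M_prime,
             "F'" = ev$F_prime, "I'" = ev$I_prime)
  m <- matrix(0, nrow = 9, ncol = 2,
              dimnames = list(c(names(e_row), names(r_row)[-1]),
                              c("|E|", "|R|")))
  m[1:5, 1] <- e_row
  m[c(5:9), 2] <- r_row
  graphics::barplot(m, horiz = TRUE, main = main,
                    col = grDevices::hcl.colors(9, "Spectral"),
                    legend.text = rownames(m),
                    args.legend = list(x = "topright", cex = 0.7))
  invisible(tab)
}

#' Evaluate predicted attention events against ground truth
#'
#' Runs the full one-vs-rest evaluation: optional pre-processing, per-AOI
#' binarisation, event and frame scoring, metric computation and the
#' failing-AOI flag, plus count aggregation over AOIs with recomputed
#' metrics.
#'
#' @param gt,pred [attention_events()] data frames (any mix of AOIs;
#'   predicted events with `aoi = NA` are ignored for per-AOI scoring).
#' @param meta A [video_meta()].
#' @param aois AOIs to evaluate; defaults to all AOIs present in either
#'   stream.
#' @param preprocess Apply [preprocess_events()] first (default `TRUE`).
#' @return A list with `per_aoi` (named list of `event`, `frame`,
#'   `metrics`, `failing` per AOI) and `total` (aggregated counts and
#'   metrics).
#' @export
evaluate_attention <- function(gt, pred, meta, aois = NULL,
                               preprocess = TRUE) {
  if (preprocess) {
    gt <- preprocess_events(gt, meta$frame_ms)
    pred <- preprocess_events(pred, meta$frame_ms)
  }
  if (is.null(aois)) {
    aois <- sort(unique(stats::na.omit(c(gt$aoi, pred$aoi))))
  }
  per_aoi <- lapply(aois, function(a) {
    gs <- binarize_events(gt[!is.na(gt$aoi) & gt$aoi == a, , drop = FALSE], meta)
    ps <- binarize_events(pred[!is.na(pred$aoi) & pred$aoi == a, , drop = FALSE], meta)
    ev <- score_events(gs, ps)
    fr <- score_frames(gs, ps)
    list(event = ev, frame = fr, metrics = compute_metrics(ev, fr),
         failing = is_failing(fr))
  })
  names(per_aoi) <- aois
  total <- aggregate_counts(per_aoi)
  total$metrics <- compute_metrics(total$event, total$frame)
  list(per_aoi = per_aoi, total = total)
}

#' Flatten evaluation results to a metrics table
#'
#' @param result Output of [evaluate_attention()].
#' @return A data frame with one row per AOI plus a `"(total)"` row,
#'   containing the raw counts and all metric percentages.
#' @export
metrics_table <- function(result) {
  row_of <- function(name, x) {
    ev <- x$event
    fr <- x$frame
    m <- if (is.null(x$metrics)) compute_metrics(ev, fr) else x$metrics
    cbind(data.frame(aoi = name),
          as.data.frame(unclass(ev)), as.data.frame(unclass(fr)),
          as.data.frame(lapply(unclass(m), function(v) v)))
  }
  rows <- c(lapply(names(result$per_aoi),
                   function(a) row_of(a, result$per_aoi[[a]])),
            list(row_of("(total)", result$total)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
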