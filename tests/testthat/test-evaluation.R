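sig <- function(x) as.logical(as.integer(strsplit(x, "")[[1]]))

test_that("pre-processing removes sub-frame events, then merges near-adjacent ones", {
  e <- attention_events(start = c(0, 120, 500), end = c(30, 200, 600),
                        label = "a")
  out <- preprocess_events(e, frame_ms = 40)
  expect_equal(out$start, c(120, 500))   # [0,30) dropped: 30 < 40

  e2 <- attention_events(start = c(0, 120), end = c(100, 200), label = "a")
  out2 <- preprocess_events(e2, frame_ms = 40)
  expect_equal(nrow(out2), 1L)
  expect_equal(c(out2$start, out2$end), c(0, 200))   # gap 20 < 40

  # events of different AOIs never merge
  e3 <- attention_events(start = c(0, 120), end = c(100, 200),
                         label = c("a", "b"))
  expect_equal(nrow(preprocess_events(e3, 40)), 2L)

  expect_equal(nrow(preprocess_events(empty_events(), 40)), 0L)
})

test_that("binarisation uses frame midpoints against half-open intervals", {
  meta <- video_meta(fps = 25, n_frames = 5)
  ev <- attention_events(start = 0, end = 80, label = "a")
  expect_equal(binarize_events(ev, meta), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(binarize_events(empty_events(), meta), rep(FALSE, 5))
  whole <- attention_events(start = 0, end = 200, label = "a")
  expect_equal(binarize_events(whole, meta), rep(TRUE, 5))
})

test_that("segmentation cuts at every signal change and rates segments", {
  segs <- segment_signals(sig("000111"), sig("001110"))
  expect_equal(segs$rating, c("TN", "FP", "TP", "FN"))
  expect_equal(segs$start_frame, c(0L, 2L, 3L, 5L))
  expect_equal(segs$end_frame, c(2L, 3L, 5L, 6L))

  expect_equal(nrow(segment_signals(rep(TRUE, 7), rep(TRUE, 7))), 1L)
  expect_equal(segment_signals(sig("0101"), sig("0101"))$rating,
               c("TN", "TP", "TN", "TP"))
  expect_error(segment_signals(sig("01"), sig("010")), "equal length")
})

test_that("event scoring reproduces the canonical overlap cases", {
  ident <- score_events(sig("0110011001100"), sig("0110011001100"))
  expect_counts_equal(ident, list(D = 0, F = 0, FM = 0, M = 0, C = 3,
                                  I_prime = 0, F_prime = 0, FM_prime = 0,
                                  M_prime = 0))

  # one prediction bridging two ground-truth events
  merge <- score_events(sig("111111111100000000001111111111"),
                        sig("111111111111111111111111111111"))
  expect_counts_equal(merge, list(D = 0, M = 2, M_prime = 1, C = 0))

  # one ground-truth event fragmented by two predictions
  frag <- score_events(sig("111111111111111111111111111111"),
                       sig("111111111100000000001111111111"))
  expect_counts_equal(frag, list(F = 1, F_prime = 2, C = 0))

  # fragmenting + merging in one stream: gt event 1 split by two
  # predictions, the second of which bridges into gt event 2
  fm <- score_events(sig("11111111110011111"), sig("11001111111111111"))
  expect_equal(fm$FM, 1)
  expect_equal(fm$FM_prime, 1)
  expect_equal(fm$F_prime, 1)
  expect_equal(fm$M, 1)
})

test_that("touching events do not overlap (half-open boundary)", {
  counts <- score_events(sig("110000"), sig("001100"))
  expect_equal(counts$D, 1)
  expect_equal(counts$I_prime, 1)
  expect_equal(counts$C, 0)
})

test_that("event scoring matches the brute-force oracle on random streams", {
  set.seed(23)
  for (rep in 1:200) {
    g <- random_signal(20, 4)
    p <- random_signal(20, 4)
    expect_counts_equal(score_events(g, p), oracle_score_events(g, p))
  }
})

test_that("frame scoring projects segments to error frames", {
  # gt [10,50), pred [20,60) on a unit frame grid
  g <- rep(FALSE, 70); g[11:50] <- TRUE
  p <- rep(FALSE, 70); p[21:60] <- TRUE
  fr <- score_frames(g, p)
  expect_equal(fr$Uf_alpha, 10)
  expect_equal(fr$TP, 30)
  expect_equal(fr$Of_omega, 10)
  expect_equal(fr$Df, 0)

  # prediction with no ground truth: all frames insertions
  fr2 <- score_frames(rep(FALSE, 20), sig("00011110000111000000"))
  expect_equal(fr2$If, 7)
  expect_equal(fr2$TN, 13)

  # merging prediction: the bridged gap frames are merge frames
  g3 <- rep(FALSE, 30); g3[1:10] <- TRUE; g3[21:30] <- TRUE
  fr3 <- score_frames(g3, rep(TRUE, 30))
  expect_equal(fr3$Mf, 10)
  expect_equal(fr3$TP, 20)

  # fragmented ground truth: the uncovered middle frames are fragmentation
  fr4 <- score_frames(rep(TRUE, 30), g3)
  expect_equal(fr4$Ff, 10)
  expect_equal(fr4$Uf_alpha, 0)

  # fully deleted event
  fr5 <- score_frames(sig("0011100"), rep(FALSE, 7))
  expect_equal(fr5$Df, 3)
  expect_equal(fr5$TN, 4)
})

test_that("metrics reproduce the published worked example", {
  # |E| = 2438 with C = 371 and D = 1619; |R| = 801 with I' = 48, F' = 206
  ev <- event_counts(D = 1619, F = 60, FM = 0, M = 388, C = 371,
                     I_prime = 48, F_prime = 206, FM_prime = 0,
                     M_prime = 176)
  expect_equal(ev$E_total, 2438)
  expect_equal(ev$R_total, 801)
  m <- compute_metrics(ev, frame_counts(TP = 1, TN = 1))
  expect_equal(round(m$Re, 2), 15.22)
  expect_equal(round(m$Pr, 2), 46.32)
  expect_equal(round(m$Re_star, 2), 33.59)
  expect_equal(round(m$Pr_star, 2), 94.01)
  ead <- render_ead(ev)
  expect_equal(round(ead$pct_E[ead$class == "D"], 2), 66.41)
  expect_equal(round(ead$pct_E[ead$class == "F"], 2), 2.46)
  expect_equal(round(ead$pct_R[ead$class == "F'"], 2), 25.72)

  # f1 is the harmonic mean of the progressive scores
  ev5 <- event_counts(D = 1, C = 1, I_prime = 1, M_prime = 0,
                      F_prime = 0, FM_prime = 0)
  m5 <- compute_metrics(ev5, frame_counts(TP = 1, TN = 1))
  expect_equal(m5$Pr_star, 50)
  expect_equal(m5$Re_star, 50)
  expect_equal(m5$f1, 50)
})

test_that("undefined ratios are absent, not zero", {
  m <- compute_metrics(event_counts(), frame_counts())
  expect_true(is.na(m$Pr))
  expect_true(is.na(m$Re))
  expect_true(is.na(m$f1))
  expect_true(is.na(m$tpr))
  expect_true(is.na(m$fpr))
  only_gt <- compute_metrics(event_counts(D = 2), frame_counts(Df = 10))
  expect_true(is.na(only_gt$Pr))
  expect_equal(only_gt$Re, 0)
})

test_that("aggregation sums counts; ratios are recomputed afterwards", {
  a <- event_counts(C = 1, D = 1)
  b <- event_counts(C = 3, D = 1)
  tot <- aggregate_event_counts(list(a, b))
  expect_equal(tot$C, 4)
  expect_equal(tot$E_total, 6)
  m <- compute_metrics(tot, frame_counts(TP = 1, TN = 1))
  expect_equal(round(m$Re, 2), 66.67)

  expect_equal(aggregate_event_counts(list(a)), a)
  zero <- aggregate_event_counts(list())
  expect_equal(zero$E_total, 0)
  zf <- aggregate_frame_counts(list())
  expect_equal(zf$P + zf$N, 0)
})

test_that("scoring concatenated recordings equals summing per-recording counts", {
  set.seed(31)
  for (rep in 1:20) {
    g1 <- random_signal(40, 3); p1 <- random_signal(40, 3)
    g2 <- random_signal(40, 3); p2 <- random_signal(40, 3)
    # separate recordings with an all-negative guard frame
    gc <- c(g1, FALSE, g2); pc <- c(p1, FALSE, p2)
    ev_sum <- aggregate_event_counts(list(score_events(g1, p1),
                                          score_events(g2, p2)))
    fr_sum <- aggregate_frame_counts(list(score_frames(g1, p1),
                                          score_frames(g2, p2)))
    ev_cat <- score_events(gc, pc)
    fr_cat <- score_frames(gc, pc)
    expect_counts_equal(ev_cat, unclass(ev_sum))
    got <- unlist(unclass(fr_cat)); want <- unlist(unclass(fr_sum))
    want["TN"] <- want["TN"] + 1; want["N"] <- want["N"] + 1  # guard frame
    expect_equal(as.numeric(got[names(want)]), as.numeric(want))
  }
})

test_that("the failing-AOI rule is dr >= 90%", {
  expect_true(is_failing(frame_counts(Df = 10)))                   # dr = 100
  expect_true(is_failing(frame_counts(Df = 90, TP = 10)))          # dr = 90
  expect_false(is_failing(frame_counts(Df = 899, TP = 101)))       # dr = 89.9
  expect_true(is.na(is_failing(frame_counts(TN = 5))))             # P = 0
})

test_that("EAD handles degenerate inputs", {
  all_c <- render_ead(event_counts(C = 4))
  expect_equal(all_c$pct_E[all_c$class == "C"], 100)
  expect_equal(all_c$pct_R[all_c$class == "C"], 100)
  zero <- render_ead(event_counts())
  expect_equal(zero$count, rep(0, 9))
  expect_true(all(is.na(zero$pct_E)))
})

test_that("score_events on event frames rejects overlapping streams", {
  meta <- video_meta(fps = 25, n_frames = 100)
  ok <- attention_events(start = c(0, 500), end = c(400, 900), label = "a")
  bad <- attention_events(start = c(0, 300), end = c(400, 900), label = "a")
  expect_error(score_events(bad, ok, meta), "overlap")
  counts <- score_events(ok, ok, meta)
  expect_equal(counts$C, 2)
})

test_that("evaluate_attention runs one-vs-rest per AOI and aggregates", {
  meta <- video_meta(fps = 25, n_frames = 250)
  gt <- attention_events(start = c(0, 2000, 5000), end = c(1000, 3000, 6000),
                         label = c("A", "B", "A"), aoi = c("A", "B", "A"))
  pred <- attention_events(start = c(0, 2000, 8000), end = c(1000, 3000, 8500),
                           label = c("A", "B", "A"), aoi = c("A", "B", "A"))
  res <- evaluate_attention(gt, pred, meta)
  expect_named(res$per_aoi, c("A", "B"))
  expect_equal(res$per_aoi$B$event$C, 1)
  expect_equal(res$per_aoi$A$event$D, 1)
  expect_equal(res$per_aoi$A$event$I_prime, 1)
  expect_equal(res$total$event$C, 2)
  tab <- metrics_table(res)
  expect_equal(nrow(tab), 3L)
  expect_true("(total)" %in% tab$aoi)
})
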