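test_that("gaze resampling keeps one nearest sample per tick", {
  full <- gaze_samples(timestamp = seq(0, 983, by = 1000 / 60),
                       x = 1, y = 1)
  rs <- resample_gaze(full, rate = 5)
  expect_true(nrow(rs) %in% 5:6)
  expect_true(all(abs(diff(rs$timestamp) - 200) < 20))

  one <- gaze_samples(timestamp = 0, x = 3, y = 4)
  expect_equal(resample_gaze(one, 5), one)
  empty <- gaze_samples()
  expect_equal(nrow(resample_gaze(empty, 5)), 0L)
})

test_that("resampling drops ticks with no sample within half a tick", {
  sparse <- gaze_samples(timestamp = c(0, 1000), x = 1, y = 1)
  rs <- resample_gaze(sparse, rate = 5)  # ticks at 0,200,...,1000
  expect_equal(rs$timestamp, c(0, 1000))
})

test_that("crop geometry centres and clamps", {
  meta <- video_meta(n_frames = 100)
  expect_equal(crop_geometry(960, 540, 200, meta)$vertices,
               rbind(c(860, 440), c(1060, 640)), ignore_attr = TRUE)
  expect_equal(crop_geometry(0, 0, 200, meta)$vertices,
               rbind(c(0, 0), c(200, 200)), ignore_attr = TRUE)
  expect_equal(crop_geometry(1920, 540, 200, meta)$vertices,
               rbind(c(1720, 440), c(1920, 640)), ignore_attr = TRUE)
  # gaze outside the frame is clamped first
  expect_equal(crop_geometry(-500, 2000, 200, meta)$vertices,
               rbind(c(0, 880), c(200, 1080)), ignore_attr = TRUE)
})

test_that("label merging sums probabilities per canonical label", {
  map <- c("streetcar" = "passenger car", "limousine" = "passenger car",
           "passenger car" = "passenger car")
  preds <- data.frame(label = c("passenger car", "streetcar", "limousine"),
                      probability = c(0.30, 0.20, 0.10))
  out <- merge_labels(preds, map)
  expect_equal(out$label, "passenger car")
  expect_equal(out$probability, 0.60)

  expect_equal(merge_labels(preds, character()), preds)

  five <- data.frame(label = letters[1:5], probability = rep(0.2, 5))
  allmap <- setNames(rep("a", 5), letters[1:5])
  out5 <- merge_labels(five, allmap)
  expect_equal(out5$label, "a")
  expect_equal(out5$probability, 1.0)
})

test_that("the event machine follows the counter rules (hand simulation)", {
  cfg <- ic_config()  # Tdur = Tnoise = 300 ms, Tp = 0.40

  # strict threshold: p = Tp contributes nothing
  step <- update_attention(new_ic_state(), "car", 0.39, 0, cfg)
  expect_equal(nrow(step$signals), 0L)
  expect_equal(unname(step$state$c_dur["car"]), 0)
  step <- update_attention(new_ic_state(), "car", 0.40, 0, cfg)
  expect_equal(unname(step$state$c_dur["car"]), 0)

  # ticks at 200/400/600 ms: Cdur[car] = 0, 200, 400 > 300 -> started,
  # timestamp corrected to 600 - 300 = 300
  st <- data.frame(timestamp = c(200, 400, 600), label = "car",
                   probability = 0.9)
  sig <- detect_attention(st, cfg)
  expect_equal(sig$kind, "started")
  expect_equal(sig$label, "car")
  expect_equal(sig$timestamp, 300)

  # continuing with kite at 800/1000: Cdur[kite] reaches 400 at t = 1000
  # (car's counters were reset at the start, so no noise path fires first);
  # ended(car) precedes started(kite), both at 1000 - 300 = 700
  st2 <- rbind(st, data.frame(timestamp = c(800, 1000), label = "kite",
                              probability = 0.9))
  sig2 <- detect_attention(st2, cfg)
  expect_equal(sig2$kind, c("started", "ended", "started"))
  expect_equal(sig2$label, c("car", "car", "kite"))
  expect_equal(sig2$timestamp, c(300, 700, 700))

  # a re-confirmed label emits confirmed, not started
  st3 <- data.frame(timestamp = seq(200, 1400, by = 200), label = "car",
                    probability = 0.9)
  sig3 <- detect_attention(st3, cfg)
  expect_equal(sig3$kind[1], "started")
  expect_true(all(sig3$kind[-1] == "confirmed"))

  # noise-triggered end: car active, then low-confidence ticks accumulate
  # noise for labels with non-zero duration
  st4 <- rbind(st3[1:4, ],
               data.frame(timestamp = seq(1000, 1800, by = 200),
                          label = "other", probability = 0.9))
  sig4 <- detect_attention(st4, cfg)
  expect_true("ended" %in% sig4$kind[sig4$label == "car"])

  expect_error(update_attention(step$state, "car", 0.9, -100, cfg),
               "non-decreasing")
})

test_that("counters never go negative and only reset via the two branches", {
  cfg <- ic_config()
  set.seed(5)
  state <- new_ic_state()
  t <- 0
  for (i in 1:300) {
    t <- t + sample(c(100, 200, 300), 1)
    lab <- sample(c("a", "b", "c"), 1)
    p <- runif(1)
    state <- update_attention(state, lab, p, t, cfg)$state
    expect_true(all(state$c_dur >= 0))
    expect_true(all(state$c_noise >= 0))
    # a counter above its threshold must have been reset this very step
    expect_true(all(state$c_dur <= cfg$t_dur + 300))
    expect_true(all(state$c_noise <= cfg$t_noise + 300))
  }
})

test_that("signals pair into half-open events", {
  sig <- data.frame(kind = c("started", "confirmed", "ended"),
                    label = "car", probability = 0.9,
                    timestamp = c(100, 500, 900))
  ev <- signals_to_events(sig)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(100, 900))

  open_sig <- data.frame(kind = "started", label = "car",
                         probability = 0.9, timestamp = 100)
  ev2 <- signals_to_events(open_sig, end_time = 700)
  expect_equal(c(ev2$start, ev2$end), c(100, 700))

  orphan <- data.frame(kind = "ended", label = "car", probability = 0.9,
                       timestamp = 50)
  expect_warning(ev3 <- signals_to_events(orphan), "without started")
  expect_equal(nrow(ev3), 0L)
})

test_that("per-label events from one signal stream never overlap", {
  cfg <- ic_config()
  set.seed(17)
  for (rep in 1:5) {
    stream <- data.frame(
      timestamp = seq(0, 20000, by = 200),
      label = sample(c("a", "b", "c"), 101, replace = TRUE),
      probability = runif(101))
    ev <- signals_to_events(detect_attention(stream, cfg))
    for (lab in unique(ev$label)) {
      e <- ev[ev$label == lab, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    }
  }
})

test_that("run_ic composes the pipeline and maps labels to AOIs", {
  meta <- video_meta(duration_ms = 2200)
  gaze <- gaze_samples(timestamp = seq(0, 2190, by = 1000 / 60),
                       x = 960, y = 540)
  always_car <- function(x, y, t) {
    data.frame(label = "passenger car", probability = 0.9)
  }
  ev <- run_ic(gaze, meta, always_car,
               aoi_map = c("passenger car" = "red car"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$label, "passenger car")
  expect_equal(ev$aoi, "red car")
  expect_equal(ev$source, "IC")

  below <- function(x, y, t) data.frame(label = "x", probability = 0.1)
  expect_equal(nrow(run_ic(gaze, meta, below)), 0L)

  # unmapped labels are retained with aoi = NA
  ev_na <- run_ic(gaze, meta, always_car)
  expect_equal(nrow(ev_na), 1L)
  expect_true(is.na(ev_na$aoi))
})

test_that("default configuration is named IC-152-300-40", {
  expect_equal(ic_method_name(ic_config()), "IC-152-300-40")
  expect_equal(ic_method_name(ic_config(t_dur = 100, t_prob = 0.2,
                                        model = "resnet50")),
               "IC-50-100-20")
  expect_equal(od_method_name(od_config()), "OD-bbox")
  expect_equal(od_method_name(od_config("mask")), "OD-mask")
})
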