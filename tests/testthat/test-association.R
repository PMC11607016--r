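g <- frame_geometry(640, 480)

test_that("initial IDs go left-to-right by left-edge distance", {
  # d1 = 40, d2 = 300
  dets <- det_df(list(bbox(50, 200, 20, 60), bbox(310, 200, 20, 60)),
                 conf = c(0.9, 0.9))
  tr <- assign_initial_ids(dets, g)
  expect_equal(sapply(tr, `[[`, "id"), c(1L, 2L))
  expect_equal(tr[[1]]$box[["x"]], 50)
  # order of the input does not matter
  tr2 <- assign_initial_ids(dets[2:1, ], g)
  expect_equal(sapply(tr2, `[[`, "id"), c(1L, 2L))
  expect_equal(tr2[[1]]$box[["x"]], 50)
  # a single instrument always becomes ID 1
  one <- assign_initial_ids(det_df(list(bbox(500, 200, 20, 60)), 0.9), g)
  expect_equal(one[[1]]$id, 1L)
  # equal distances: the leftmost centre wins (wider box has centre right)
  tie <- det_df(list(bbox(60, 100, 40, 40), bbox(90, 300, 100, 40)),
                conf = c(0.9, 0.9))
  trt <- assign_initial_ids(tie, g)
  expect_equal(trt[[1]]$box[["x"]], 60)
  expect_equal(trt[[1]]$id, 1L)
})

test_that("box smoothing is the IoU-weighted convex combination", {
  cfg <- tracker_config()
  b <- bbox(10, 10, 4, 4)
  expect_equal(smooth_box(b, b, cfg), b)
  # disjoint boxes: alpha = 0, the current detection dominates entirely
  expect_equal(smooth_box(bbox(0, 0, 4, 4), bbox(100, 100, 4, 4), cfg),
               bbox(100, 100, 4, 4))
  # worked example: alpha = IoU = 1/3
  expect_equal(smooth_box(bbox(0, 0, 4, 4), bbox(2, 0, 4, 4), cfg),
               bbox(4 / 3, 0, 4, 4))
  # constant mode and disabled smoothing
  ccfg <- tracker_config(alpha_mode = "constant", alpha_constant = 0.25)
  expect_equal(smooth_box(bbox(0, 0, 4, 4), bbox(4, 0, 4, 4), ccfg),
               bbox(3, 0, 4, 4))
  off <- tracker_config(smoothing_enabled = FALSE)
  expect_equal(smooth_box(bbox(0, 0, 4, 4), bbox(2, 0, 4, 4), off),
               bbox(2, 0, 4, 4))
})

test_that("smoothed boxes stay in the componentwise envelope of their inputs", {
  set.seed(21)
  inside <- logical(0)
  for (k in 1:500) {
    prev <- random_box()
    curr <- random_box()
    for (cfg in list(tracker_config(),
                     tracker_config(alpha_mode = "constant",
                                    alpha_constant = runif(1)))) {
      s <- smooth_box(prev, curr, cfg)
      inside <- c(inside, all(s >= pmin(prev, curr) - 1e-12 &
                                s <= pmax(prev, curr) + 1e-12))
    }
  }
  expect_true(all(inside))
})

test_that("equal-count matching maximizes total IoU and preserves order on ties", {
  cfg <- tracker_config()
  t1 <- duotrack:::new_track(1L, bbox(100, 100, 30, 60))
  t2 <- duotrack:::new_track(2L, bbox(300, 100, 30, 60))
  # single pair
  p <- match_equal_counts(list(t1), det_df(list(bbox(102, 100, 30, 60)), 1), cfg)
  expect_equal(p$det, 1L)
  # identity assignment clearly better
  dets <- det_df(list(bbox(104, 100, 30, 60), bbox(296, 100, 30, 60)), c(1, 1))
  p <- match_equal_counts(list(t1, t2), dets, cfg)
  expect_equal(p$det[p$track == 1], 1L)
  expect_equal(p$det[p$track == 2], 2L)
  # crossed detections: assignment follows the overlap, not the order
  p <- match_equal_counts(list(t1, t2), dets[2:1, ], cfg)
  expect_equal(p$det[p$track == 1], 2L)
  # all-zero IoU tie: left/right ordering is preserved
  far <- det_df(list(bbox(600, 400, 10, 10), bbox(500, 400, 10, 10)), c(1, 1))
  p <- match_equal_counts(list(t1, t2), far, cfg)
  expect_equal(p$det[p$track == 1], 2L) # t1 is leftmost, det 2 is leftmost
  expect_equal(p$det[p$track == 2], 1L)
})

test_that("equal-count matching agrees with enumerating both pairings", {
  cfg <- tracker_config()
  set.seed(22)
  got <- numeric(300)
  want <- numeric(300)
  for (k in 1:300) {
    tboxes <- list(random_box(), random_box())
    dboxes <- list(random_box(), random_box())
    tracks <- list(duotrack:::new_track(1L, tboxes[[1]]),
                   duotrack:::new_track(2L, tboxes[[2]]))
    p <- match_equal_counts(tracks, det_df(dboxes, c(1, 1)), cfg)
    got[k] <- sum(p$iou)
    want[k] <- max(iou(tboxes[[1]], dboxes[[1]]) + iou(tboxes[[2]], dboxes[[2]]),
                   iou(tboxes[[1]], dboxes[[2]]) + iou(tboxes[[2]], dboxes[[1]]))
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("an interior track coasts on the Kalman prediction when undetected", {
  tr <- duotrack:::new_track(1L, bbox(300, 200, 40, 120))
  tr$kf$mean[5:6] <- c(3, -2)
  res <- handle_missing(list(tr), matched_ids = integer(0), g,
                        tracker_config(), kalman_config(), frame = 10L)
  expect_length(res$kept, 1)
  expect_length(res$deleted, 0)
  kept <- res$kept[[1]]
  expect_equal(unname(kept$box[1:2]), c(303, 198))
  expect_equal(kept$frames_since_detection, 1L)
  # matched tracks pass through untouched
  res2 <- handle_missing(list(tr), matched_ids = 1L, g,
                         tracker_config(), kalman_config(), frame = 10L)
  expect_identical(res2$kept[[1]], tr)
})

test_that("re-tracking reclaims by overlap, then by vertical half, else creates", {
  cfg <- tracker_config()
  kcfg <- kalman_config()
  # overlap with the last real box: old ID reclaimed
  deleted <- list(list(id = 2L, last_box = bbox(600, 200, 40, 120),
                       frame_deleted = 50L))
  live <- list(duotrack:::new_track(1L, bbox(150, 200, 40, 120)))
  det <- det_df(list(bbox(590, 210, 40, 120)), 0.9)
  rc <- retrack_or_create(det, deleted, live, g, cfg, kcfg)
  expect_setequal(sapply(rc$tracks, `[[`, "id"), c(1L, 2L))
  expect_length(rc$deleted, 0)
  # zero overlap but same vertical half: still reclaimed
  det_far <- det_df(list(bbox(420, 420, 40, 60)), 0.9)
  rc <- retrack_or_create(det_far, deleted, live, g, cfg, kcfg)
  expect_setequal(sapply(rc$tracks, `[[`, "id"), c(1L, 2L))
  # opposite half, zero overlap: a NEW track with the lowest free ID
  det_opp <- det_df(list(bbox(250, 420, 40, 60)), 0.9)
  rc <- retrack_or_create(det_opp, deleted, live, g, cfg, kcfg)
  expect_setequal(sapply(rc$tracks, `[[`, "id"), c(1L, 2L))
  expect_length(rc$deleted, 1) # the stored instance was not consumed
  # creation-time consistency: ID 1 must end up leftmost
  det_left <- det_df(list(bbox(25, 200, 40, 60)), 0.9)
  rc <- retrack_or_create(det_left, list(), live, g, cfg, kcfg)
  ids <- sapply(rc$tracks, `[[`, "id")
  xs <- sapply(rc$tracks, function(t) t$box[["x"]])
  expect_equal(xs[ids == 1L], 25)
  expect_equal(xs[ids == 2L], 150)
  # over-capacity is an error
  two_live <- list(duotrack:::new_track(1L, bbox(150, 200, 40, 120)),
                   duotrack:::new_track(2L, bbox(500, 200, 40, 120)))
  expect_error(retrack_or_create(det_opp, list(), two_live, g, cfg, kcfg),
               "over-capacity")
})

test_that("perfect separated detections keep constant IDs forever", {
  cfg <- scenario_config(n_frames = 120, jitter_std = 0, dropout_prob = 0,
                         false_positive_rate = 0, seed = 9)
  sim <- simulate_scene(cfg)
  run <- track_stream(sim$detections, cfg$geometry)
  per_frame <- split(run$records$id, run$records$frame)
  expect_true(all(vapply(per_frame, function(ids)
    identical(sort(ids), c(1L, 2L)), logical(1))))
  expect_equal(count_id_switches(sim$gt, run$records), 0L)
})

test_that("tracker invariants hold on noisy streams: <= 2 live tracks, unique IDs in {1,2}", {
  for (seed in c(31, 32, 33)) {
    cfg <- scenario_config(n_frames = 150, seed = seed)
    sim <- simulate_scene(cfg)
    run <- track_stream(sim$detections, cfg$geometry)
    per_frame <- split(run$records$id, run$records$frame)
    expect_true(all(vapply(per_frame, function(ids)
      length(ids) <= 2 && anyDuplicated(ids) == 0 && all(ids %in% 1:2),
      logical(1))))
  }
})
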