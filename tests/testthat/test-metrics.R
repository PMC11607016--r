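test_that("frame matching is the maximum-total-IoU assignment", {
  gt <- frame_df(1, c(1, 2), list(bbox(100, 100, 20, 40), bbox(300, 100, 20, 40)))
  # identical records: everything matches
  m <- match_frame(gt, gt)
  expect_equal(nrow(m$matches), 2)
  expect_equal(m$fn, 0)
  expect_equal(m$fp, 0)
  expect_equal(sum(m$matches$iou), 2)
  # missing hypothesis: one FN
  m <- match_frame(gt, gt[1, ])
  expect_equal(m$fn, 1)
  expect_equal(m$fp, 0)
  # a greedy matcher would take the 0.6 pair; the optimum is anti-diagonal
  mat <- rbind(c(0.6, 0.55), c(0.55, 0))
  a <- duotrack:::optimal_assignment(mat, 0.5)
  expect_equal(a, c(2L, 1L))
})

test_that("optimal assignment agrees with brute-force enumeration", {
  set.seed(77)
  got <- numeric(200)
  want <- numeric(200)
  for (k in 1:200) {
    nG <- sample(1:3, 1)
    nH <- sample(1:3, 1)
    m <- matrix(runif(nG * nH), nG, nH)
    thr <- sample(c(0, 0.3, 0.5), 1)
    a <- duotrack:::optimal_assignment(m, thr)
    got[k] <- sum(m[cbind(which(!is.na(a)), a[!is.na(a)])])
    want[k] <- brute_assignment_score(m, thr)
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("MOTA combines FN, FP and identity switches over ground truth", {
  expect_equal(mota(mot_counts(gt = 20L)), 1)
  # 10 frames, 2 objects, one dropped hypothesis box
  gt <- do.call(rbind, lapply(1:10, function(f)
    frame_df(f, c(1, 2), list(bbox(100, 100, 20, 40), bbox(300, 100, 20, 40)))))
  hyp <- gt[!(gt$frame == 5 & gt$id == 2), ]
  ev <- evaluate_tracking(gt, hyp)
  expect_equal(ev$counts$fn, 1L)
  expect_equal(ev$mota, 0.95)
  # no floor: more errors than ground truth goes negative
  expect_equal(mota(mot_counts(fn = 15L, fp = 10L, gt = 20L)), -0.25)
  expect_error(mota(mot_counts(gt = 0L)), "undefined-metric")
})

test_that("MOTP normalizes by frames; the per-match variant by matches", {
  gt <- do.call(rbind, lapply(1:10, function(f)
    frame_df(f, c(1, 2), list(bbox(100, 100, 20, 40), bbox(300, 100, 20, 40)))))
  ev <- evaluate_tracking(gt, gt)
  expect_equal(ev$motp, 2) # two perfect matches per frame
  expect_equal(ev$motp_per_match, 1)
  expect_equal(motp(mot_counts(iou_sum = 7.4, n_matches = 10L, n_frames = 10L)),
               0.74)
  # 2 px x-shift of 20x40 boxes: IoU = 18*40 / (2*800 - 720) = 9/11
  hyp <- gt
  hyp$x <- hyp$x + 2
  ev <- evaluate_tracking(gt, hyp)
  expect_equal(ev$mota, 1)
  expect_equal(ev$motp_per_match, 9 / 11, tolerance = 1e-12)
  expect_equal(ev$motp, 18 / 11, tolerance = 1e-12)
  # no matches at all: frame-normalized MOTP is 0
  far <- gt
  far$x <- far$x + 500
  expect_equal(evaluate_tracking(gt, far)$motp, 0)
  expect_error(motp(mot_counts(n_frames = 0L)), "undefined-metric")
})

test_that("MSCAV measures relative area change per transition", {
  # constant boxes
  const <- do.call(rbind, lapply(1:20, function(f)
    frame_df(f, 1, list(bbox(100, 100, 20, 40)))))
  expect_equal(mscav(const), 0)
  # 10% area growth per transition, any horizon
  grow <- do.call(rbind, lapply(1:15, function(f)
    frame_df(f, 1, list(bbox(100, 100, 10, 10 * 1.1^(f - 1))))))
  expect_equal(mscav(grow), 0.1, tolerance = 1e-12)
  # shrinking areas: signed and negative
  shrink <- do.call(rbind, lapply(1:15, function(f)
    frame_df(f, 1, list(bbox(100, 100, 10, 10 * 0.9^(f - 1))))))
  expect_equal(mscav(shrink), -0.1, tolerance = 1e-12)
  # an identity present in only one of two consecutive frames contributes 0
  sparse <- rbind(frame_df(1, 1, list(bbox(100, 100, 20, 40))),
                  frame_df(2, 2, list(bbox(300, 100, 20, 80))),
                  frame_df(3, 2, list(bbox(300, 100, 20, 80))))
  expect_equal(mscav(sparse), 0)
  expect_error(mscav(const[const$frame == 1, ]), "at least two frames")
  bad <- frame_df(1, 1, list(bbox(1, 1, 1, 1)))
  bad$w <- 0
  expect_error(mscav(rbind(bad, frame_df(2, 1, list(bbox(1, 1, 1, 1)))), 2),
               "invalid-record")
})

test_that("a stream smoothed with alpha = 1 has exactly zero MSCAV", {
  # no dropout: every frame is matched, so every emitted box is the frozen
  # smoothed box (a coasting frame would emit the moving Kalman prediction)
  cfg <- scenario_config(n_frames = 60, jitter_std = 2, dropout_prob = 0,
                         false_positive_rate = 0, seed = 44)
  sim <- simulate_scene(cfg)
  frozen <- track_stream(sim$detections, cfg$geometry,
                         config = tracker_config(alpha_mode = "constant",
                                                 alpha_constant = 1))
  # boxes are frozen to their first value, so every area transition is 0
  expect_equal(mscav(frozen$records, cfg$n_frames), 0)
})

test_that("identity switches count per-object changes of matched hypothesis ID", {
  boxes <- list(bbox(100, 100, 20, 40), bbox(300, 100, 20, 40))
  gt <- do.call(rbind, lapply(1:10, function(f) frame_df(f, c(1, 2), boxes)))
  # consistent labels: zero switches
  expect_equal(count_id_switches(gt, gt), 0L)
  # labels swap once mid-video: each object switches -> 2
  hyp <- gt
  swap <- hyp$frame >= 6
  hyp$id[swap] <- 3 - hyp$id[swap]
  expect_equal(count_id_switches(gt, hyp), 2L)
  # an unmatched gap with the same ID afterwards is not a switch
  gap <- gt[!(gt$frame %in% 4:6 & gt$id == 2), ]
  expect_equal(count_id_switches(gt, gap), 0L)
  expect_equal(evaluate_tracking(gt, gap)$counts$fn, 3L)
})

test_that("accumulation is invariant to frame-order permutation of the input", {
  cfg <- scenario_config(n_frames = 40, jitter_std = 1, dropout_prob = 0,
                         false_positive_rate = 0, seed = 13)
  sim <- simulate_scene(cfg)
  run <- track_stream(sim$detections, cfg$geometry)
  ev1 <- evaluate_tracking(sim$gt, run$records)
  set.seed(1)
  shuffle <- function(df) df[sample(nrow(df)), ]
  ev2 <- evaluate_tracking(shuffle(sim$gt), shuffle(run$records))
  expect_equal(ev1$mota, ev2$mota)
  expect_equal(ev1$motp, ev2$motp)
  expect_equal(ev1$counts$idsw, ev2$counts$idsw)
})
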