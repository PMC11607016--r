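#' Initialize a tracker
#'
#' Creates an empty tracker state holding the frame geometry and the three
#' configuration objects. Feed it one frame of (filtered) detections at a
#' time with [tracker_step()], or use [track_stream()] to run a whole
#' detection stream.
#'
#' @param g A [frame_geometry()].
#' @param filter A [filter_config()] (kept for [track_stream()]).
#' @param config A [tracker_config()].
#' @param kalman A [kalman_config()].
#' @return A list of class `duotrack_tracker`.
#' @export
tracker_init <- function(g, filter = filter_config(),
                         config = tracker_config(),
                         kalman = kalman_config()) {
  structure(list(geometry = g, filter = filter, config = config,
                 kalman = kalman, tracks = list(), deleted = list(),
                 frame = 0L, last_record = NULL),
            class = "duotrack_tracker")
}

#' Advance the tracker by one frame
#'
#' Orchestrates the per-frame association logic on detections that have
#' already been filtered and clipped: equal track/detection counts are
#' matched by maximum total IoU; on a count mismatch the best-overlapping
#' pairs are matched greedily, unmatched tracks coast on Kalman predictions
#' subject to the edge-exit rules, and unmatched detections are re-tracked
#' against deleted instruments or become new tracks. Matched tracks adopt
#' the IoU-weighted smoothed box while their Kalman filter is corrected with
#' the raw detection, so smoothing never feeds back into the motion model.
#'
#' @param state A `duotrack_tracker`.
#' @param dets Data frame of filtered detections for this frame
#'   (`x, y, w, h, conf`), at most 2 rows; may have zero rows.
#' @return The updated state; `state$last_record` holds this frame's output
#'   as a data frame `frame, id, x, y, w, h`.
#' @export
tracker_step <- function(state, dets) {
  stopifnot(inherits(state, "duotrack_tracker"))
  state$frame <- state$frame + 1L
  g <- state$geometry
  cfg <- state$config
  kcfg <- state$kalman
  tracks <- state$tracks
  nT <- length(tracks)
  nD <- if (is.null(dets)) 0L else nrow(dets)

  preds <- lapply(tracks, function(tr) kf_predict(tr$kf, kcfg))

  pairs <- NULL
  if (nT > 0 && nD > 0) {
    pairs <- if (nT == nD) match_equal_counts(tracks, dets, cfg)
    else match_greedy(tracks, dets, cfg)
  }
  matched_t <- if (is.null(pairs)) integer(0) else pairs$track
  matched_d <- if (is.null(pairs)) integer(0) else pairs$det

  kept <- list()
  for (k in seq_along(matched_t)) {
    i <- matched_t[k]
    tr <- tracks[[i]]
    raw <- det_box(dets[matched_d[k], ])
    tr$kf <- kf_correct(preds[[i]], raw, kcfg)
    tr$box <- smooth_box(tr$box, raw, cfg)
    tr$last_real_box <- raw
    tr$frames_since_detection <- 0L
    tr$edge_contact_frames <-
      if (length(touches_edge(tr$box, g)) > 0) tr$edge_contact_frames + 1L
      else 0L
    kept[[length(kept) + 1L]] <- tr
  }

  for (i in setdiff(seq_len(nT), matched_t)) {
    res <- handle_missing_track(tracks[[i]], preds[[i]], g, cfg, state$frame)
    if (res$deleted) state$deleted[[length(state$deleted) + 1L]] <- res$record
    else kept[[length(kept) + 1L]] <- res$track
  }

  # age out stale deletion records, if a finite retention is configured
  if (is.finite(cfg$deleted_max_age) && length(state$deleted) > 0) {
    age_ok <- vapply(state$deleted, function(d)
      state$frame - d$frame_deleted <= cfg$deleted_max_age, logical(1))
    state$deleted <- state$deleted[age_ok]
  }

  ud <- setdiff(seq_len(nD), matched_d)
  if (length(ud) > 0) {
    if (nT == 0 && length(state$deleted) == 0) {
      kept <- c(kept, assign_initial_ids(dets[ud, , drop = FALSE], g, kcfg))
    } else {
      rc <- retrack_or_create(dets[ud, , drop = FALSE], state$deleted, kept,
                              g, cfg, kcfg)
      kept <- rc$tracks
      state$deleted <- rc$deleted
    }
  }

  kept <- kept[order(track_ids(kept))]
  state$tracks <- kept
  state$last_record <- if (length(kept) == 0) {
    data.frame(frame = integer(0), id = integer(0), x = numeric(0),
               y = numeric(0), w = numeric(0), h = numeric(0))
  } else {
    data.frame(frame = state$frame,
               id = track_ids(kept),
               x = vapply(kept, function(t) t$box[[1]], numeric(1)),
               y = vapply(kept, function(t) t$box[[2]], numeric(1)),
               w = vapply(kept, function(t) t$box[[3]], numeric(1)),
               h = vapply(kept, function(t) t$box[[4]], numeric(1)))
  }
  state
}

#' Track a whole detection stream
#'
#' Runs the full filtering + association pipeline over a per-frame detection
#' stream and returns the tracked records. Wall-clock time is split into
#' detection ingest/filtering and association, as bookkeeping of the
#' two-stage inference time t = t_d + t_a.
#'
#' @param detections Data frame with columns `frame, x, y, w, h, conf`
#'   (an `id` column, conventionally -1 for raw detections, is ignored).
#'   Frames are 1-based; frames with no rows are processed as empty.
#' @param g A [frame_geometry()].
#' @param n_frames Horizon; defaults to `max(detections$frame)`.
#' @param filter A [filter_config()].
#' @param config A [tracker_config()].
#' @param kalman A [kalman_config()].
#' @return A list of class `duotrack_run` with elements `records` (data
#'   frame `frame, id, x, y, w, h, conf` with conf = 1), `n_frames`, and
#'   `timing` (seconds: `t_detection`, `t_association`, `t_total`,
#'   `ms_per_frame`).
#' @examples
#' cfg <- scenario_config(n_frames = 40, jitter_std = 0, dropout_prob = 0,
#'                        false_positive_rate = 0, seed = 7)
#' dets <- degrade(generate_ground_truth(cfg), cfg)
#' run <- track_stream(dets, cfg$geometry)
#' head(run$records)
#' @export
track_stream <- function(detections, g, n_frames = NULL,
                         filter = filter_config(),
                         config = tracker_config(),
                         kalman = kalman_config()) {
  if (is.null(n_frames))
    n_frames <- if (nrow(detections) > 0) max(detections$frame) else 0L
  state <- tracker_init(g, filter, config, kalman)
  records <- vector("list", n_frames)
  t_det <- 0
  t_assoc <- 0
  for (f in seq_len(n_frames)) {
    t0 <- proc.time()[["elapsed"]]
    dets <- detections[detections$frame == f, , drop = FALSE]
    dets <- filter_detections(dets, g, filter)
    t1 <- proc.time()[["elapsed"]]
    state <- tracker_step(state, dets)
    t2 <- proc.time()[["elapsed"]]
    t_det <- t_det + (t1 - t0)
    t_assoc <- t_assoc + (t2 - t1)
    records[[f]] <- state$last_record
  }
  out <- do.call(rbind, records)
  if (is.null(out))
    out <- data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0))
  out$conf <- rep(1, nrow(out))
  structure(list(records = out, n_frames = n_frames,
                 timing = list(t_detection = t_det, t_association = t_assoc,
                               t_total = t_det + t_assoc,
                               ms_per_frame = if (n_frames > 0)
                                 1000 * (t_det + t_assoc) / n_frames else NA_real_)),
            class = "duotrack_run")
}

#' @export
print.duotrack_run <- function(x, ...) {
  cat(sprintf("duotrack run: %d frames, %d records, %.1f ms/frame (t_d + t_a)\n",
              x$n_frames, nrow(x$records), x$timing$ms_per_frame))
  invisible(x)
}
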