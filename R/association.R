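#' Tracker configuration
#'
#' @param alpha_mode Weight of the previous box in the smoothing update:
#'   `"iou"` (default; the weight equals the IoU between the previous box
#'   and the current detection, so large overlap means a smooth transition
#'   and low overlap lets the new detection dominate) or `"constant"`.
#' @param alpha_constant Weight used when `alpha_mode = "constant"`.
#' @param smoothing_enabled Apply the weighted-sum smoothing at all
#'   (default `TRUE`); when `FALSE` matched tracks adopt the raw detection.
#' @param max_edge_frames A coasting (undetected) track whose predicted box
#'   touches an image border with outward velocity for more than this many
#'   consecutive frames is deleted (default 2, i.e., deletion on the third
#'   consecutive contact frame).
#' @param iou_match_threshold Minimum IoU (strict) for a track-detection
#'   match when track and detection counts differ (default 0: any positive
#'   overlap matches).
#' @param deleted_max_age Frames a deleted track remains eligible for
#'   re-tracking (default `Inf`: for the remainder of the video).
#'
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(alpha_mode = c("iou", "constant"),
                           alpha_constant = 0.5,
                           smoothing_enabled = TRUE,
                           max_edge_frames = 2L,
                           iou_match_threshold = 0,
                           deleted_max_age = Inf) {
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(alpha_constant >= 0, alpha_constant <= 1,
            max_edge_frames >= 0, iou_match_threshold >= 0)
  structure(list(alpha_mode = alpha_mode,
                 alpha_constant = alpha_constant,
                 smoothing_enabled = isTRUE(smoothing_enabled),
                 max_edge_frames = as.integer(max_edge_frames),
                 iou_match_threshold = iou_match_threshold,
                 deleted_max_age = deleted_max_age),
            class = "tracker_config")
}

# a live track: persistent id 1/2, current (smoothed) box, Kalman state,
# consecutive edge-contact counter, frames since last real detection, and
# the last REAL detection (stored for re-tracking, never an extrapolation)
new_track <- function(id, box, kalman = kalman_config()) {
  validate_bbox(box)
  list(id = as.integer(id), box = box, kf = kf_init(box, kalman),
       edge_contact_frames = 0L, frames_since_detection = 0L,
       last_real_box = box)
}

track_ids <- function(tracks) vapply(tracks, function(t) t$id, integer(1))

#' Initial left/right identity assignment
#'
#' With a single detection, ID 1 is assigned. With two, ID 1 goes to the
#' detection with the smaller distance from the frame's left edge and ID 2
#' to the other, under the scene assumption that the two arms are not
#' crossed in the first frame. An exact distance tie is broken by the
#' leftmost box centre.
#'
#' @param dets Data frame of at most 2 detections (`x, y, w, h, conf`).
#' @param g A [frame_geometry()].
#' @param kalman A [kalman_config()] for the fresh track states.
#' @return A list of tracks.
#' @export
assign_initial_ids <- function(dets, g, kalman = kalman_config()) {
  n <- nrow(dets)
  if (n > 2) stop("at most two detections can receive initial IDs")
  if (n == 0) return(list())
  boxes <- lapply(seq_len(n), function(i) det_box(dets[i, ]))
  if (n == 1) return(list(new_track(1L, boxes[[1]], kalman)))
  d <- vapply(boxes, left_edge_distance, numeric(1), g = g)
  first <- if (d[1] == d[2]) {
    if (boxes[[1]][[1]] <= boxes[[2]][[1]]) 1L else 2L
  } else if (d[1] < d[2]) 1L else 2L
  other <- 3L - first
  list(new_track(1L, boxes[[first]], kalman),
       new_track(2L, boxes[[other]], kalman))
}

#' Weighted smoothing of consecutive matched boxes
#'
#' Componentwise convex combination `alpha * prev + (1 - alpha) * curr`.
#' With `alpha_mode = "iou"` the weight is the IoU of the two boxes: a
#' large overlap yields a smooth transition, while a low overlap indicates
#' non-negligible motion and lets the current detection dominate.
#'
#' @param prev Previous (track) box.
#' @param curr Current (detection) box.
#' @param config A [tracker_config()].
#' @return The smoothed box; `curr` when smoothing is disabled.
#' @export
smooth_box <- function(prev, curr, config = tracker_config()) {
  validate_bbox(prev)
  validate_bbox(curr)
  if (!config$smoothing_enabled) return(curr)
  alpha <- switch(config$alpha_mode,
                  iou = iou(prev, curr),
                  constant = config$alpha_constant)
  alpha <- min(max(alpha, 0), 1)
  out <- alpha * unname(prev[1:4]) + (1 - alpha) * unname(curr[1:4])
  names(out) <- c("x", "y", "w", "h")
  out
}

#' Optimal track-detection pairing when counts are equal
#'
#' With at most two objects the assignment maximizing total IoU is found by
#' comparing the two possible pairings directly (no assignment solver is
#' needed). An exact tie preserves the existing left/right ordering: the
#' track with the smaller centre x is paired to the detection with the
#' smaller centre x.
#'
#' @param tracks List of live tracks (length 1 or 2).
#' @param dets Data frame of detections, `nrow(dets) == length(tracks)`.
#' @param config A [tracker_config()].
#' @return Data frame with columns `track`, `det` (indices) and `iou`.
#' @export
match_equal_counts <- function(tracks, dets, config = tracker_config()) {
  n <- length(tracks)
  stopifnot(n == nrow(dets), n >= 1, n <= 2)
  dboxes <- lapply(seq_len(n), function(j) det_box(dets[j, ]))
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- iou(tracks[[i]]$box, dboxes[[j]])
  if (n == 1)
    return(data.frame(track = 1L, det = 1L, iou = m[1, 1]))
  straight <- m[1, 1] + m[2, 2]
  crossed <- m[1, 2] + m[2, 1]
  pairing <- if (straight > crossed) {
    c(1L, 2L)
  } else if (crossed > straight) {
    c(2L, 1L)
  } else {
    # tie: pair by left/right order of centres
    tx <- c(tracks[[1]]$box[[1]], tracks[[2]]$box[[1]])
    dx <- c(dboxes[[1]][[1]], dboxes[[2]][[1]])
    det_order <- order(dx)[order(order(tx))]
    det_order
  }
  data.frame(track = c(1L, 2L), det = pairing,
             iou = c(m[1, pairing[1]], m[2, pairing[2]]))
}

# greedy best-IoU matching for unequal counts; with <= 2 objects greedy is
# optimal. Pairs require iou strictly above the threshold.
match_greedy <- function(tracks, dets, config = tracker_config()) {
  nT <- length(tracks)
  nD <- nrow(dets)
  dboxes <- lapply(seq_len(nD), function(j) det_box(dets[j, ]))
  m <- matrix(0, nT, nD)
  for (i in seq_len(nT)) for (j in seq_len(nD))
    m[i, j] <- iou(tracks[[i]]$box, dboxes[[j]])
  pairs <- data.frame(track = integer(0), det = integer(0), iou = numeric(0))
  repeat {
    mx <- max(m)
    if (mx <= config$iou_match_threshold) break
    ij <- which(m == mx, arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(track = unname(ij[1]),
                                     det = unname(ij[2]), iou = mx))
    m[ij[1], ] <- -1
    m[, ij[2]] <- -1
    if (nrow(pairs) == min(nT, nD)) break
  }
  pairs
}

# decide the fate of one unmatched track: coast on the Kalman prediction,
# unless the prediction has been touching a border while moving outward
# through it for more than max_edge_frames consecutive frames, in which case
# the instrument is assumed to have left the field of view and the track is
# deleted (storing its last real detection for re-tracking).
handle_missing_track <- function(track, pred, g, config, frame) {
  pbox <- kf_box(pred)
  touching <- touches_edge(pbox, g)
  contact <- length(touching) > 0
  cnt <- if (contact) track$edge_contact_frames + 1L else 0L
  vel <- kf_velocity(pred)
  outward <- ("left" %in% touching && vel[1] < 0) ||
    ("right" %in% touching && vel[1] > 0) ||
    ("top" %in% touching && vel[2] < 0) ||
    ("bottom" %in% touching && vel[2] > 0)
  if (contact && outward && cnt > config$max_edge_frames) {
    return(list(deleted = TRUE,
                record = list(id = track$id,
                              last_box = track$last_real_box,
                              frame_deleted = frame)))
  }
  track$kf <- pred
  track$box <- pbox
  track$edge_contact_frames <- cnt
  track$frames_since_detection <- track$frames_since_detection + 1L
  list(deleted = FALSE, track = track)
}

#' Handle tracks with no matching detection
#'
#' Each unmatched track is advanced with the Kalman prediction. The
#' prediction is accepted unless the instrument appears to be leaving the
#' scene: the predicted box touches an image border, the estimated velocity
#' points outward through that border, and the contact has persisted for
#' more than `max_edge_frames` consecutive frames. A rejected track becomes
#' a deleted-track record carrying the last real detection (not a Kalman
#' extrapolation) for later re-tracking. Contact without outward motion is
#' always retained.
#'
#' @param tracks List of live tracks.
#' @param matched_ids Integer IDs of the tracks that were matched this frame.
#' @param g A [frame_geometry()].
#' @param config A [tracker_config()].
#' @param kalman A [kalman_config()].
#' @param frame Current frame index (stored on deletion records).
#' @return List with elements `kept` (tracks, predictions applied) and
#'   `deleted` (deleted-track records).
#' @export
handle_missing <- function(tracks, matched_ids, g,
                           config = tracker_config(),
                           kalman = kalman_config(), frame = 0L) {
  kept <- list()
  deleted <- list()
  for (tr in tracks) {
    if (tr$id %in% matched_ids) {
      kept[[length(kept) + 1L]] <- tr
      next
    }
    res <- handle_missing_track(tr, kf_predict(tr$kf, kalman), g, config, frame)
    if (res$deleted) deleted[[length(deleted) + 1L]] <- res$record
    else kept[[length(kept) + 1L]] <- res$track
  }
  list(kept = kept, deleted = deleted)
}

#' Re-track returning instruments or create new tracks
#'
#' Each unmatched detection is first tested against the deleted-track list:
#' if its IoU with a deleted track's last real box is positive, or it lies
#' in the same vertical half of the frame, the old identity is reclaimed
#' (preferring the largest overlap, then the nearest last box). Otherwise a
#' new track is created with the lowest free ID in {1, 2}. When a creation
#' leaves ID 1 to the right of ID 2, the IDs are swapped so that ID 1 is
#' always the leftmost instrument; the correction applies at creation time
#' only, never retroactively to emitted records.
#'
#' @param dets Data frame of unmatched detections.
#' @param deleted List of deleted-track records.
#' @param tracks List of currently live tracks.
#' @param g A [frame_geometry()].
#' @param config A [tracker_config()].
#' @param kalman A [kalman_config()].
#' @return List with elements `tracks` (live tracks including the new ones)
#'   and `deleted` (remaining deleted records).
#' @export
retrack_or_create <- function(dets, deleted, tracks, g,
                              config = tracker_config(),
                              kalman = kalman_config()) {
  created <- FALSE
  # leftmost detection first, for determinism
  for (j in order(dets$x)) {
    box <- det_box(dets[j, ])
    live <- track_ids(tracks)
    cand_idx <- which(!vapply(deleted, function(d) d$id %in% live, logical(1)))
    reclaimed <- FALSE
    if (length(cand_idx) > 0) {
      ious <- vapply(cand_idx, function(k) iou(deleted[[k]]$last_box, box),
                     numeric(1))
      halves <- vapply(cand_idx, function(k)
        frame_half(deleted[[k]]$last_box, g) == frame_half(box, g), logical(1))
      ok <- ious > 0 | halves
      if (any(ok)) {
        sel <- cand_idx[ok]
        sel_iou <- ious[ok]
        if (any(sel_iou > 0)) {
          pick <- sel[which.max(sel_iou)]
        } else {
          dist <- vapply(sel, function(k)
            sum((deleted[[k]]$last_box[1:2] - box[1:2])^2), numeric(1))
          pick <- sel[which.min(dist)]
        }
        tracks[[length(tracks) + 1L]] <-
          new_track(deleted[[pick]]$id, box, kalman)
        deleted <- deleted[-pick]
        reclaimed <- TRUE
      }
    }
    if (!reclaimed) {
      free <- setdiff(1:2, live)
      if (length(free) == 0)
        stop("over-capacity: more unmatched detections than free track IDs")
      tracks[[length(tracks) + 1L]] <- new_track(min(free), box, kalman)
      created <- TRUE
    }
  }
  # creation-time consistency: ID 1 must be the leftmost instrument
  if (created && length(tracks) == 2) {
    ids <- track_ids(tracks)
    i1 <- which(ids == 1L)
    i2 <- which(ids == 2L)
    if (length(i1) == 1 && length(i2) == 1 &&
        tracks[[i1]]$box[[1]] > tracks[[i2]]$box[[1]]) {
      tracks[[i1]]$id <- 2L
      tracks[[i2]]$id <- 1L
    }
  }
  list(tracks = tracks, deleted = deleted)
}
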