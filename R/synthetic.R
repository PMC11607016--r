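#' Synthetic dual-instrument scenario configuration
#'
#' Describes a simulated microsurgical scene: two elongated instruments
#' moving inside the frame, optionally leaving and re-entering through the
#' side or bottom borders (never the top, and never crossed in the first
#' frame), observed by an imperfect detector that jitters, drops, and
#' hallucinates boxes.
#'
#' Defaults emulate the conditions the tracker is designed for: an 8 s video
#' of about 250 frames at 640x480, slow tool motion of 2 px/frame, box
#' localization error of about 2 px, occasional missed detections (5%), and
#' a spurious detection every ~10 frames.
#'
#' @param n_frames Video length in frames (default 250).
#' @param geometry A [frame_geometry()] (default 640x480, margin 1).
#' @param motion Length-2 character vector, per-instrument motion model:
#'   `"linear"` (straight lines with reflection at an interior safety
#'   margin), `"sinusoidal"`, or `"piecewise"` (direction re-sampled every
#'   40 frames).
#' @param speed Nominal speed, pixels/frame (default 2).
#' @param box_w,box_h Instrument box size, pixels (default 40x120; aspect
#'   ratio 3, emulating elongated instruments).
#' @param jitter_std Detector localization noise std, pixels, applied
#'   independently to x, y, w, h (default 2).
#' @param dropout_prob Probability a true instrument is missed in a frame
#'   (default 0.05).
#' @param false_positive_rate Expected spurious detections per frame,
#'   Poisson (default 0.1); half of the spurious boxes are biased toward the
#'   frame borders to exercise the positional discard.
#' @param exit_reentry Optional data frame with columns
#'   `id, exit_frame, reentry_frame, reentry_half` scripting instruments
#'   that leave the field of view and come back (`reentry_half` is
#'   `"left"` or `"right"`).
#' @param confidence_mean,confidence_sd Detection score model; scores are
#'   Gaussian clipped to `[0, 1]` (default mean 0.9, sd 0.05).
#' @param seed Integer seed; one seed drives all randomness through
#'   independent sub-generators.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_frames = 250L,
                            geometry = frame_geometry(640, 480),
                            motion = c("linear", "linear"),
                            speed = 2,
                            box_w = 40, box_h = 120,
                            jitter_std = 2,
                            dropout_prob = 0.05,
                            false_positive_rate = 0.1,
                            exit_reentry = NULL,
                            confidence_mean = 0.9,
                            confidence_sd = 0.05,
                            seed = 1L) {
  stopifnot(n_frames >= 1, speed >= 0, box_w > 0, box_h > 0,
            jitter_std >= 0, dropout_prob >= 0, dropout_prob <= 1,
            false_positive_rate >= 0, confidence_sd >= 0)
  motion <- rep_len(motion, 2)
  if (!all(motion %in% c("linear", "sinusoidal", "piecewise")))
    stop("invalid-scenario: unknown motion model")
  if (!is.null(exit_reentry)) {
    req <- c("id", "exit_frame", "reentry_frame", "reentry_half")
    if (!all(req %in% names(exit_reentry)))
      stop("invalid-scenario: exit_reentry needs columns ",
           paste(req, collapse = ", "))
    if (any(exit_reentry$reentry_frame <= exit_reentry$exit_frame))
      stop("invalid-scenario: reentry_frame must be after exit_frame")
    if (any(exit_reentry$exit_frame < 2) ||
        any(exit_reentry$reentry_frame > n_frames))
      stop("invalid-scenario: exit/reentry frames outside the horizon")
    if (!all(exit_reentry$id %in% 1:2) ||
        !all(exit_reentry$reentry_half %in% c("left", "right")))
      stop("invalid-scenario: id must be 1/2 and reentry_half left/right")
  }
  structure(list(n_frames = as.integer(n_frames), geometry = geometry,
                 motion = motion, speed = speed, box_w = box_w,
                 box_h = box_h, jitter_std = jitter_std,
                 dropout_prob = dropout_prob,
                 false_positive_rate = false_positive_rate,
                 exit_reentry = exit_reentry,
                 confidence_mean = confidence_mean,
                 confidence_sd = confidence_sd,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# interior safety bounds for a box centre: instruments keep a 10 px buffer
# from every border (5 px extra below the top) except during scripted exits,
# so detector jitter never produces incidental edge contact.
centre_bounds <- function(cfg) {
  g <- cfg$geometry
  list(xmin = cfg$box_w / 2 + 10, xmax = g$width - cfg$box_w / 2 - 10,
       ymin = cfg$box_h / 2 + 15, ymax = g$height - cfg$box_h / 2 - 10)
}

# advance a position one frame under a velocity, reflecting at the bounds
reflect_step <- function(pos, vel, b) {
  p <- pos + vel
  if (p[1] < b$xmin) { p[1] <- 2 * b$xmin - p[1]; vel[1] <- -vel[1] }
  if (p[1] > b$xmax) { p[1] <- 2 * b$xmax - p[1]; vel[1] <- -vel[1] }
  if (p[2] < b$ymin) { p[2] <- 2 * b$ymin - p[2]; vel[2] <- -vel[2] }
  if (p[2] > b$ymax) { p[2] <- 2 * b$ymax - p[2]; vel[2] <- -vel[2] }
  list(pos = p, vel = vel)
}

#' Generate ground-truth instrument trajectories
#'
#' Deterministic given the scenario seed. Instrument 1 starts strictly left
#' of instrument 2 and the two boxes never overlap in the first frame;
#' neither instrument ever enters through the top border. Scripted
#' exit/re-entry events are realized physically: the instrument steers
#' toward the nearest side/bottom border over the 10 frames before its exit,
#' is absent during the gap, and re-enters touching the border of the
#' requested half moving inward.
#'
#' @param cfg A [scenario_config()].
#' @return Data frame `frame, id, x, y, w, h, conf` (conf = 1).
#' @export
generate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  g <- cfg$geometry
  b <- centre_bounds(cfg)
  set.seed(cfg$seed)
  angles <- stats::runif(2, 0, 2 * pi)
  phases <- stats::runif(2, 0, 2 * pi)
  piecewise_seed <- sample.int(2^31 - 1, 2)

  rows <- list()
  for (inst in 1:2) {
    pos <- c(if (inst == 1) 0.30 * g$width else 0.70 * g$width,
             0.60 * g$height)
    pos[1] <- min(max(pos[1], b$xmin), b$xmax)
    pos[2] <- min(max(pos[2], b$ymin), b$ymax)
    vel <- cfg$speed * c(cos(angles[inst]), sin(angles[inst]))
    base <- pos # anchor for sinusoidal motion
    events <- if (is.null(cfg$exit_reentry)) NULL
    else cfg$exit_reentry[cfg$exit_reentry$id == inst, , drop = FALSE]
    ev_i <- 1L
    absent_until <- 0L
    lead_target <- NULL
    lead_start <- NULL
    set.seed(piecewise_seed[inst])
    t_anchor <- 0L
    f <- 1L
    while (f <= cfg$n_frames) {
      ev <- if (!is.null(events) && ev_i <= nrow(events))
        events[ev_i, , drop = FALSE] else NULL
      if (!is.null(ev) && f >= ev$exit_frame && f < ev$reentry_frame) {
        # absent
        if (f == ev$reentry_frame - 1L || ev$reentry_frame == f + 1L) {
          # handled below at reentry
        }
        f <- f + 1L
        next
      }
      if (!is.null(ev) && f == ev$reentry_frame) {
        # re-enter touching the border of the requested half, moving inward
        pos <- c(if (ev$reentry_half == "left") cfg$box_w / 2 + 1
                 else g$width - cfg$box_w / 2 - 1,
                 0.60 * g$height)
        vel <- c(if (ev$reentry_half == "left") cfg$speed else -cfg$speed, 0)
        base <- c(min(max(pos[1], b$xmin), b$xmax), pos[2])
        t_anchor <- f
        ev_i <- ev_i + 1L
        rows[[length(rows) + 1L]] <- c(f, inst, pos, cfg$box_w, cfg$box_h)
        f <- f + 1L
        next
      }
      lead <- !is.null(ev) && f >= ev$exit_frame - 10L && f < ev$exit_frame
      if (lead) {
        if (is.null(lead_target) || !identical(lead_start, ev$exit_frame)) {
          # steer toward the nearest of left/right/bottom so that the centre
          # reaches the border on the last visible frame
          dists <- c(left = pos[1], right = g$width - pos[1],
                     bottom = g$height - pos[2])
          edge <- names(which.min(dists))
          lead_target <- switch(edge,
                                left = c(cfg$box_w / 2 - 2, pos[2]),
                                right = c(g$width - cfg$box_w / 2 + 2, pos[2]),
                                bottom = c(pos[1], g$height - cfg$box_h / 2 + 2))
          lead_from <- pos
          lead_n <- ev$exit_frame - f
          lead_step <- (lead_target - lead_from) / lead_n
          lead_start <- ev$exit_frame
          vel <- lead_step
        }
        pos <- pos + vel
      } else {
        mtype <- cfg$motion[inst]
        if (mtype == "linear") {
          st <- reflect_step(pos, vel, b)
          pos <- st$pos
          vel <- st$vel
        } else if (mtype == "sinusoidal") {
          Tper <- 120
          A <- cfg$speed * Tper / (2 * pi)
          tt <- f - t_anchor
          pos <- c(base[1] + A * sin(2 * pi * tt / Tper + phases[inst]),
                   base[2] + 0.5 * A * sin(2 * pi * tt / (1.7 * Tper)))
          pos[1] <- min(max(pos[1], b$xmin), b$xmax)
          pos[2] <- min(max(pos[2], b$ymin), b$ymax)
        } else { # piecewise
          if ((f - t_anchor) %% 40L == 0L) {
            a <- stats::runif(1, 0, 2 * pi)
            vel <- cfg$speed * c(cos(a), sin(a))
          }
          st <- reflect_step(pos, vel, b)
          pos <- st$pos
          vel <- st$vel
        }
      }
      rows[[length(rows) + 1L]] <- c(f, inst, pos, cfg$box_w, cfg$box_h)
      f <- f + 1L
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("frame", "id", "x", "y", "w", "h")
  out <- out[order(out$frame, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  out$conf <- 1
  # first-frame scene assumptions, by construction; verified defensively
  f1 <- out[out$frame == 1L, , drop = FALSE]
  if (nrow(f1) == 2) {
    b1 <- det_box(f1[f1$id == 1L, ])
    b2 <- det_box(f1[f1$id == 2L, ])
    if (iou(b1, b2) > 0 || b1[[1]] >= b2[[1]])
      stop("invalid-scenario: instruments crossed in the first frame")
  }
  out
}

#' Degrade ground truth into a detector-like stream
#'
#' Emulates detector failure modes on top of the true boxes: independent
#' Gaussian jitter on (x, y, w, h), Bernoulli dropout, Poisson spurious
#' detections (half biased toward the borders), and Gaussian confidence
#' scores clipped to `[0, 1]`. All randomness derives from the scenario seed
#' through four independent sub-generators (jitter, dropout, false
#' positives, confidence), so ablations differ only in the component under
#' test.
#'
#' @param gt Ground truth from [generate_ground_truth()].
#' @param cfg The same [scenario_config()].
#' @return Data frame `frame, id, x, y, w, h, conf` with id = -1.
#' @export
degrade <- function(gt, cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  g <- cfg$geometry
  n <- nrow(gt)
  set.seed(cfg$seed + 1L)
  sub <- sample.int(2^31 - 1, 4)

  set.seed(sub[1])
  jit <- matrix(stats::rnorm(4 * n, 0, cfg$jitter_std), ncol = 4)
  set.seed(sub[2])
  dropped <- stats::runif(n) < cfg$dropout_prob
  set.seed(sub[3])
  conf <- pmin(pmax(stats::rnorm(n, cfg$confidence_mean, cfg$confidence_sd),
                    0), 1)

  keep <- !dropped
  det <- data.frame(frame = gt$frame[keep], id = rep(-1L, sum(keep)),
                    x = gt$x[keep] + jit[keep, 1],
                    y = gt$y[keep] + jit[keep, 2],
                    w = pmax(1, gt$w[keep] + jit[keep, 3]),
                    h = pmax(1, gt$h[keep] + jit[keep, 4]),
                    conf = conf[keep])

  set.seed(sub[4])
  n_fp <- stats::rpois(cfg$n_frames, cfg$false_positive_rate)
  fp_rows <- list()
  for (f in seq_len(cfg$n_frames)) {
    for (k in seq_len(n_fp[f])) {
      w <- stats::runif(1, 20, 80)
      h <- stats::runif(1, 40, 160)
      if (stats::runif(1) < 0.5) { # border-biased spurious detection
        edge <- sample(c("left", "right", "top", "bottom"), 1)
        p <- switch(edge,
                    left = c(w / 2 - stats::runif(1, 0, w / 4),
                             stats::runif(1, h / 2, g$height - h / 2)),
                    right = c(g$width - w / 2 + stats::runif(1, 0, w / 4),
                              stats::runif(1, h / 2, g$height - h / 2)),
                    top = c(stats::runif(1, w / 2, g$width - w / 2),
                            h / 2 - stats::runif(1, 0, h / 4)),
                    bottom = c(stats::runif(1, w / 2, g$width - w / 2),
                               g$height - h / 2 + stats::runif(1, 0, h / 4)))
      } else {
        p <- c(stats::runif(1, w / 2, g$width - w / 2),
               stats::runif(1, h / 2, g$height - h / 2))
      }
      fp_rows[[length(fp_rows) + 1L]] <-
        data.frame(frame = f, id = -1L, x = p[1], y = p[2], w = w, h = h,
                   conf = stats::runif(1, 0.2, 0.95))
    }
  }
  if (length(fp_rows) > 0) det <- rbind(det, do.call(rbind, fp_rows))
  det <- det[order(det$frame), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Simulate a full scenario
#'
#' Convenience wrapper returning both the ground truth and the degraded
#' detection stream for a scenario.
#'
#' @param cfg A [scenario_config()].
#' @return List with elements `gt` and `detections`.
#' @export
simulate_scene <- function(cfg) {
  gt <- generate_ground_truth(cfg)
  list(gt = gt, detections = degrade(gt, cfg))
}
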