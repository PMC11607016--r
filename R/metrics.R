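#' @section Metric conventions:
#' MOTA combines false negatives, false positives and identity switches:
#' `MOTA = 1 - (sum FN + FP + IDSW) / sum GT`. MOTP accumulates the IoU of
#' true-positive matches; the primary form here normalizes by the number of
#' FRAMES, so a perfect two-instrument video scores 2.0, and a per-match
#' normalization (the usual CLEAR convention, bounded by 1) is provided
#' separately as [motp_per_match()]. MSCAV is the mean over frame
#' transitions of the summed relative area change of instances present in
#' both frames; values near zero indicate stable box areas.
#' @name duotrack-metrics
#' @keywords internal
NULL

# optimal assignment of rows (ground truth) to columns (hypotheses) of an
# IoU matrix: maximize total IoU over pairs with iou >= threshold; rows may
# stay unmatched. Exhaustive recursion -- frames hold at most a few objects.
optimal_assignment <- function(m, threshold) {
  nG <- nrow(m)
  nH <- ncol(m)
  best_score <- -Inf
  best_n <- -1L
  best <- rep(NA_integer_, nG)
  assign <- rep(NA_integer_, nG)
  used <- rep(FALSE, max(nH, 1L))
  consider <- function(score) {
    n_match <- sum(!is.na(assign))
    if (score > best_score + 1e-12 ||
        (abs(score - best_score) <= 1e-12 && n_match > best_n)) {
      best_score <<- score
      best_n <<- n_match
      best <<- assign
    }
  }
  rec <- function(i, score) {
    if (i > nG) {
      consider(score)
      return(invisible(NULL))
    }
    rec(i + 1L, score) # row i unmatched
    for (j in seq_len(nH)) {
      if (!used[j] && m[i, j] >= threshold) {
        used[j] <<- TRUE
        assign[i] <<- j
        rec(i + 1L, score + m[i, j])
        used[j] <<- FALSE
        assign[i] <<- NA_integer_
      }
    }
  }
  rec(1L, 0)
  best
}

#' Match ground truth to hypotheses within one frame
#'
#' Maximum-total-IoU assignment among ground-truth/hypothesis pairs whose
#' IoU reaches the threshold; unmatched ground truth counts as a false
#' negative, unmatched hypotheses as false positives.
#'
#' @param gt,hyp Data frames for one frame with columns `id, x, y, w, h`.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return List with `matches` (data frame `gt_id, hyp_id, iou`), `fn`, `fp`.
#' @export
match_frame <- function(gt, hyp, iou_threshold = 0.5) {
  nG <- nrow(gt)
  nH <- nrow(hyp)
  if (nG == 0 || nH == 0) {
    return(list(matches = data.frame(gt_id = integer(0), hyp_id = integer(0),
                                     iou = numeric(0)),
                fn = nG, fp = nH))
  }
  m <- matrix(0, nG, nH)
  for (i in seq_len(nG)) for (j in seq_len(nH))
    m[i, j] <- iou(det_box(gt[i, ]), det_box(hyp[j, ]))
  a <- optimal_assignment(m, iou_threshold)
  matched <- which(!is.na(a))
  list(matches = data.frame(gt_id = gt$id[matched],
                            hyp_id = hyp$id[a[matched]],
                            iou = m[cbind(matched, a[matched])]),
       fn = nG - length(matched),
       fp = nH - length(matched))
}

#' Accumulated tracking error counts
#'
#' Container for the per-video sums entering MOTA/MOTP.
#'
#' @param fn,fp,idsw,gt Summed false negatives, false positives, identity
#'   switches and ground-truth instances.
#' @param iou_sum Accumulated IoU over all true-positive matches.
#' @param n_matches Number of true-positive matches.
#' @param n_frames Number of frames evaluated.
#' @return A list of class `mot_counts`.
#' @export
mot_counts <- function(fn = 0L, fp = 0L, idsw = 0L, gt = 0L,
                       iou_sum = 0, n_matches = 0L, n_frames = 0L) {
  stopifnot(fn >= 0, fp >= 0, idsw >= 0, gt >= 0, iou_sum >= 0)
  structure(list(fn = fn, fp = fp, idsw = idsw, gt = gt, iou_sum = iou_sum,
                 n_matches = n_matches, n_frames = n_frames),
            class = "mot_counts")
}

#' Multiple object tracking accuracy
#'
#' `1 - (fn + fp + idsw) / gt`; at most 1, with no lower floor (heavy
#' failure modes give negative values, returned as-is).
#'
#' @param counts A [mot_counts()].
#' @return A number `<= 1`.
#' @export
mota <- function(counts) {
  if (counts$gt <= 0) stop("undefined-metric: MOTA needs at least one ground-truth instance")
  1 - (counts$fn + counts$fp + counts$idsw) / counts$gt
}

#' Frame-normalized multiple object tracking precision
#'
#' Accumulated true-positive IoU divided by the number of FRAMES. With two
#' perfectly tracked instruments per frame this equals 2.0; see
#' [motp_per_match()] for the per-match normalization bounded by 1.
#'
#' @param counts A [mot_counts()].
#' @return A nonnegative number.
#' @export
motp <- function(counts) {
  if (counts$n_frames <= 0) stop("undefined-metric: MOTP needs at least one frame")
  counts$iou_sum / counts$n_frames
}

#' Per-match multiple object tracking precision
#'
#' Accumulated true-positive IoU divided by the number of matches (the
#' common CLEAR-MOT convention, bounded by 1). Provided as a cross-check
#' alongside the frame-normalized [motp()].
#'
#' @param counts A [mot_counts()].
#' @return A number in `[0, 1]`, or `NaN` when there are no matches.
#' @export
motp_per_match <- function(counts) {
  if (counts$n_matches <= 0) return(NaN)
  counts$iou_sum / counts$n_matches
}

#' Mean of the sum of consecutive area variation (MSCAV)
#'
#' For every frame transition t-1 -> t, each identity present in both frames
#' contributes its relative area change `(Area_t - Area_{t-1}) / Area_{t-1}`
#' (area = width x height); contributions are summed within the transition
#' and averaged over all transitions of the horizon. The metric is signed;
#' a substantial distance from zero indicates strong frame-to-frame box
#' oscillation. Identities appearing in only one of the two frames
#' contribute nothing.
#'
#' @param records Data frame `frame, id, x, y, w, h` of tracked boxes.
#' @param n_frames Horizon; defaults to `max(records$frame)`. The number of
#'   transitions averaged over is `n_frames - 1`.
#' @return A signed number.
#' @export
mscav <- function(records, n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(records) > 0) max(records$frame) else 0L
  if (n_frames < 2) stop("MSCAV needs at least two frames")
  area <- records$w * records$h
  if (any(area <= 0)) stop("invalid-record: box areas must be positive")
  total <- 0
  prev <- records[records$frame == 1L, , drop = FALSE]
  for (t in 2:n_frames) {
    cur <- records[records$frame == t, , drop = FALSE]
    common <- intersect(prev$id, cur$id)
    for (id in common) {
      a0 <- prev$w[prev$id == id] * prev$h[prev$id == id]
      a1 <- cur$w[cur$id == id] * cur$h[cur$id == id]
      total <- total + (a1 - a0) / a0
    }
    prev <- cur
  }
  total / (n_frames - 1)
}

#' Count identity switches against ground truth
#'
#' A switch is counted whenever the hypothesis identity matched to a
#' ground-truth object differs from the hypothesis identity it was most
#' recently matched to; an unmatched gap alone is a false negative, not a
#' switch.
#'
#' @param gt,hyp Data frames `frame, id, x, y, w, h` over the same horizon.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @return Nonnegative integer.
#' @export
count_id_switches <- function(gt, hyp, iou_threshold = 0.5) {
  evaluate_tracking(gt, hyp, iou_threshold = iou_threshold)$counts$idsw
}

#' Evaluate a tracking hypothesis against ground truth
#'
#' Per-frame maximum-IoU matching (see [match_frame()]) accumulated over the
#' horizon, yielding MOTA, the frame-normalized MOTP, the per-match MOTP,
#' MSCAV of the hypothesis stream, and the raw error counts.
#'
#' @param gt,hyp Data frames `frame, id, x, y, w, h` (a `conf` column is
#'   ignored). Frames are 1-based.
#' @param iou_threshold Minimum IoU for a true positive (default 0.5).
#' @param n_frames Horizon; defaults to the larger of the two streams' maxima.
#' @return A list of class `duotrack_eval` with elements `mota`, `motp`
#'   (frame-normalized), `motp_per_match`, `mscav`, and `counts`
#'   (a [mot_counts()]).
#' @export
evaluate_tracking <- function(gt, hyp, iou_threshold = 0.5, n_frames = NULL) {
  if (is.null(n_frames)) {
    n_frames <- max(c(gt$frame, hyp$frame, 0L))
  }
  if (n_frames < 1) stop("undefined-metric: empty evaluation horizon")
  fn <- 0L; fp <- 0L; idsw <- 0L; gt_total <- 0L
  iou_sum <- 0; n_matches <- 0L
  last_hyp <- list() # most recent hypothesis id matched to each gt id
  for (f in seq_len(n_frames)) {
    gtf <- gt[gt$frame == f, , drop = FALSE]
    hyf <- hyp[hyp$frame == f, , drop = FALSE]
    m <- match_frame(gtf, hyf, iou_threshold)
    fn <- fn + m$fn
    fp <- fp + m$fp
    gt_total <- gt_total + nrow(gtf)
    iou_sum <- iou_sum + sum(m$matches$iou)
    n_matches <- n_matches + nrow(m$matches)
    for (k in seq_len(nrow(m$matches))) {
      gid <- as.character(m$matches$gt_id[k])
      hid <- m$matches$hyp_id[k]
      if (!is.null(last_hyp[[gid]]) && last_hyp[[gid]] != hid)
        idsw <- idsw + 1L
      last_hyp[[gid]] <- hid
    }
  }
  counts <- mot_counts(fn = fn, fp = fp, idsw = idsw, gt = gt_total,
                       iou_sum = iou_sum, n_matches = n_matches,
                       n_frames = n_frames)
  structure(list(mota = mota(counts),
                 motp = motp(counts),
                 motp_per_match = motp_per_match(counts),
                 mscav = if (n_frames >= 2 && nrow(hyp) > 0)
                   mscav(hyp, n_frames) else NA_real_,
                 counts = counts),
            class = "duotrack_eval")
}

#' @export
print.duotrack_eval <- function(x, ...) {
  c_ <- x$counts
  cat("Tracking evaluation\n")
  cat(sprintf("  MOTA            : %.4f\n", x$mota))
  cat(sprintf("  MOTP (per frame): %.4f\n", x$motp))
  cat(sprintf("  MOTP (per match): %.4f\n", x$motp_per_match))
  cat(sprintf("  MSCAV           : %+.5f\n", x$mscav))
  cat(sprintf("  FN %d | FP %d | IDSW %d | GT %d | frames %d\n",
              c_$fn, c_$fp, c_$idsw, c_$gt, c_$n_frames))
  invisible(x)
}
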