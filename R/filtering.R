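#' Detection filter configuration
#'
#' Defaults reproduce the intended tracker behaviour: detections scoring
#' below 0.5 are discarded, and the candidate list is clipped to the two
#' robotic arms using position (no instrument may hang from the top border,
#' mirroring the scene assumption that instruments never enter from above)
#' and size (an instrument tip never fills half the frame) rules, with a
#' final confidence tie-break.
#'
#' @param confidence_threshold Minimum detector score kept (default 0.5).
#' @param max_instances Maximum detections per frame after clipping
#'   (default 2, the number of robotic arms).
#' @param max_area_fraction Maximum box area as a fraction of the frame area
#'   (default 0.5).
#' @param reject_top_entry Discard boxes contacting only the top border
#'   (default `TRUE`).
#' @param position_rule_every_frame Apply the top-entry positional discard on
#'   every frame (default `TRUE`) rather than only when over budget.
#'
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(confidence_threshold = 0.5,
                          max_instances = 2L,
                          max_area_fraction = 0.5,
                          reject_top_entry = TRUE,
                          position_rule_every_frame = TRUE) {
  stopifnot(confidence_threshold >= 0, confidence_threshold <= 1,
            max_instances >= 1, max_area_fraction > 0, max_area_fraction <= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 max_instances = as.integer(max_instances),
                 max_area_fraction = max_area_fraction,
                 reject_top_entry = isTRUE(reject_top_entry),
                 position_rule_every_frame = isTRUE(position_rule_every_frame)),
            class = "filter_config")
}

# extract the (x, y, w, h) box from one detection/record row
det_box <- function(row) {
  c(x = row$x[[1]], y = row$y[[1]], w = row$w[[1]], h = row$h[[1]])
}

#' Discard weak detections
#'
#' Keeps exactly the detections whose confidence is at least the threshold,
#' preserving input order.
#'
#' @param dets Data frame of detections with columns `x, y, w, h, conf`.
#' @param config A [filter_config()].
#' @return The surviving rows of `dets`.
#' @export
filter_by_confidence <- function(dets, config = filter_config()) {
  dets[dets$conf >= config$confidence_threshold, , drop = FALSE]
}

#' Clip candidate detections to the allowed number of instruments
#'
#' Applies, in order: (i) top-entry rejection — a box contacting the top
#' border while not contacting left/right/bottom cannot be an instrument,
#' since instruments never enter from above; (ii) a size rule discarding
#' boxes larger than `max_area_fraction` of the frame; (iii) if more than
#' `max_instances` remain, the highest-confidence ones are kept (ties broken
#' by smaller left-edge distance, mirroring the ID-1 preference).
#'
#' @param dets Data frame of confidence-filtered detections.
#' @param g A [frame_geometry()].
#' @param config A [filter_config()].
#' @return At most `config$max_instances` rows of `dets`, input order
#'   preserved.
#' @export
clip_candidates <- function(dets, g, config = filter_config()) {
  n <- nrow(dets)
  if (n == 0) return(dets)
  keep <- rep(TRUE, n)
  over_budget <- n > config$max_instances
  for (i in seq_len(n)) {
    b <- det_box(dets[i, ])
    if (config$reject_top_entry &&
        (config$position_rule_every_frame || over_budget)) {
      touching <- touches_edge(b, g)
      if ("top" %in% touching &&
          !any(c("left", "right", "bottom") %in% touching))
        keep[i] <- FALSE
    }
    if (box_area(b) > config$max_area_fraction * g$width * g$height)
      keep[i] <- FALSE
  }
  dets <- dets[keep, , drop = FALSE]
  if (nrow(dets) > config$max_instances) {
    d_left <- vapply(seq_len(nrow(dets)),
                     function(i) left_edge_distance(det_box(dets[i, ]), g),
                     numeric(1))
    ord <- order(-dets$conf, d_left)
    dets <- dets[sort(ord[seq_len(config$max_instances)]), , drop = FALSE]
  }
  dets
}

#' Full per-frame detection filter
#'
#' Convenience wrapper: [filter_by_confidence()] followed by
#' [clip_candidates()]. Idempotent.
#'
#' @inheritParams clip_candidates
#' @return At most `config$max_instances` detections.
#' @export
filter_detections <- function(dets, g, config = filter_config()) {
  clip_candidates(filter_by_confidence(dets, config), g, config)
}
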