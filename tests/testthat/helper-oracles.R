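# Independent oracles used to freeze expected values. These deliberately use
# different mechanisms than the package implementation.

# IoU by rasterization: count unit pixel cells (centres at k + 0.5) covered
# by each box. Exact for boxes with integer extents.
iou_raster <- function(a, b) {
  ext <- function(bx) c(bx[1] - bx[3] / 2, bx[1] + bx[3] / 2,
                        bx[2] - bx[4] / 2, bx[2] + bx[4] / 2)
  ea <- ext(a)
  eb <- ext(b)
  xs <- seq(floor(min(ea[1], eb[1])), ceiling(max(ea[2], eb[2])) - 1) + 0.5
  ys <- seq(floor(min(ea[3], eb[3])), ceiling(max(ea[4], eb[4])) - 1) + 0.5
  grid <- expand.grid(x = xs, y = ys)
  in_box <- function(e) grid$x > e[1] & grid$x < e[2] & grid$y > e[3] & grid$y < e[4]
  ia <- in_box(ea)
  ib <- in_box(eb)
  sum(ia & ib) / sum(ia | ib)
}

# Brute-force maximum-total-IoU assignment score: enumerate every assignment
# vector (each row matched to a column or NA) via expand.grid, keep the
# injective ones whose pairs all reach the threshold.
brute_assignment_score <- function(m, threshold) {
  nG <- nrow(m)
  nH <- ncol(m)
  choices <- rep(list(c(NA_integer_, seq_len(nH))), nG)
  all_assign <- do.call(expand.grid, choices)
  best <- 0
  for (r in seq_len(nrow(all_assign))) {
    a <- as.integer(all_assign[r, ])
    picked <- a[!is.na(a)]
    if (anyDuplicated(picked)) next
    ok <- TRUE
    s <- 0
    for (i in seq_len(nG)) {
      if (!is.na(a[i])) {
        if (m[i, a[i]] < threshold) { ok <- FALSE; break }
        s <- s + m[i, a[i]]
      }
    }
    if (ok && s > best) best <- s
  }
  best
}

# random valid box within a WxH frame
random_box <- function(width = 200, height = 200) {
  w <- runif(1, 2, 60)
  h <- runif(1, 2, 60)
  c(x = runif(1, w / 2, width - w / 2), y = runif(1, h / 2, height - h / 2),
    w = w, h = h)
}

# single-frame record/detection data frame from a list of (id, box)
frame_df <- function(frame, ids, boxes) {
  do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(frame = frame, id = ids[i], x = boxes[[i]][1],
               y = boxes[[i]][2], w = boxes[[i]][3], h = boxes[[i]][4],
               conf = 1)))
}

# detections data frame (id = -1) from boxes + confidences
det_df <- function(boxes, conf) {
  do.call(rbind, lapply(seq_along(boxes), function(i)
    data.frame(x = boxes[[i]][1], y = boxes[[i]][2], w = boxes[[i]][3],
               h = boxes[[i]][4], conf = conf[i])))
}
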