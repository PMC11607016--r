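#' Axis-aligned bounding box in centre-based xywh convention
#'
#' Boxes use the centre-based convention of the YOLO detector family:
#' `x`, `y` are the pixel coordinates of the box centre, with the origin at
#' the top-left corner of the image and y increasing downward; `w`, `h` are
#' the full width and height in pixels. Sub-pixel coordinates are allowed
#' (smoothing and Kalman estimation produce real-valued boxes).
#'
#' @param x,y Box centre, pixels.
#' @param w,h Full box width and height, pixels; must be strictly positive.
#'
#' @return A named numeric vector `c(x, y, w, h)`.
#' @examples
#' b <- bbox(50, 50, 20, 20)
#' box_area(b)
#' @export
bbox <- function(x, y, w, h) {
  b <- c(x = as.numeric(x)[1], y = as.numeric(y)[1],
         w = as.numeric(w)[1], h = as.numeric(h)[1])
  validate_bbox(b)
  b
}

#' Validate a bounding box
#'
#' Checks the box invariants: four finite coordinates, strictly positive
#' width and height. Signals an `invalid geometry` error otherwise.
#'
#' @param b Numeric vector `(x, y, w, h)`.
#' @return The box, invisibly.
#' @export
validate_bbox <- function(b) {
  if (length(b) < 4 || !all(is.finite(b[1:4])))
    stop("invalid geometry: box must have four finite coordinates (x, y, w, h)")
  if (b[[3]] <= 0 || b[[4]] <= 0)
    stop("invalid geometry: box width and height must be positive")
  invisible(b)
}

#' Frame geometry
#'
#' Image dimensions plus the tolerance within which a box extent counts as
#' "touching" a border. The tolerance is configurable because contact is
#' otherwise ill-defined for the real-valued boxes produced by smoothing.
#'
#' @param width,height Image dimensions, pixels (> 0).
#' @param edge_margin Contact tolerance, pixels (>= 0, default 1).
#'
#' @return A list of class `frame_geometry`.
#' @export
frame_geometry <- function(width, height, edge_margin = 1) {
  if (width <= 0 || height <= 0 || edge_margin < 0)
    stop("invalid geometry: width and height must be positive, edge_margin nonnegative")
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 edge_margin = as.numeric(edge_margin)),
            class = "frame_geometry")
}

# box extents as (left, right, top, bottom)
box_extents <- function(b) {
  c(left = b[[1]] - b[[3]] / 2, right = b[[1]] + b[[3]] / 2,
    top = b[[2]] - b[[4]] / 2, bottom = b[[2]] + b[[4]] / 2)
}

#' Box area
#'
#' @param b Box `(x, y, w, h)`.
#' @return `w * h`, square pixels.
#' @export
box_area <- function(b) b[[3]] * b[[4]]

#' Intersection over Union of two boxes
#'
#' Area of intersection divided by area of union; 0 for disjoint boxes,
#' 1 iff the boxes are identical. Symmetric in its arguments.
#'
#' @param a,b Boxes `(x, y, w, h)`.
#' @return A number in `[0, 1]`.
#' @examples
#' iou(bbox(0, 0, 4, 4), bbox(2, 0, 4, 4)) # 1/3
#' @export
iou <- function(a, b) {
  validate_bbox(a)
  validate_bbox(b)
  ea <- box_extents(a)
  eb <- box_extents(b)
  iw <- max(0, min(ea[["right"]], eb[["right"]]) - max(ea[["left"]], eb[["left"]]))
  ih <- max(0, min(ea[["bottom"]], eb[["bottom"]]) - max(ea[["top"]], eb[["top"]]))
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Distance of a box from the frame's left edge
#'
#' Distance in pixels from the left image border to the box's left extent
#' `x - w/2`, clamped at zero. This is the quantity that drives the initial
#' left/right identity assignment (ID 1 goes to the smaller distance).
#'
#' @param b Box `(x, y, w, h)`.
#' @param g A [frame_geometry()].
#' @return Nonnegative number, pixels.
#' @export
left_edge_distance <- function(b, g) {
  validate_bbox(b)
  max(0, b[[1]] - b[[3]] / 2)
}

#' Single-frame edge contact
#'
#' Reports which image borders lie within `g$edge_margin` of the
#' corresponding box extent (a box already past a border also counts as
#' touching it). The consecutive-contact counter that drives track deletion
#' lives in the track state; this reports one frame only.
#'
#' @param b Box `(x, y, w, h)`.
#' @param g A [frame_geometry()].
#' @return Character vector, subset of `c("left", "right", "top", "bottom")`.
#' @export
touches_edge <- function(b, g) {
  validate_bbox(b)
  e <- box_extents(b)
  m <- g$edge_margin
  out <- character(0)
  if (e[["left"]] <= m) out <- c(out, "left")
  if (e[["right"]] >= g$width - m) out <- c(out, "right")
  if (e[["top"]] <= m) out <- c(out, "top")
  if (e[["bottom"]] >= g$height - m) out <- c(out, "bottom")
  out
}

#' Vertical half of the frame containing a box centre
#'
#' Used by the re-tracking rule: an instrument re-entering in the same
#' vertical half as a previously deleted one reclaims its identity. A centre
#' exactly on the midline is assigned to the left half so the rule is total
#' and deterministic.
#'
#' @param b Box `(x, y, w, h)`.
#' @param g A [frame_geometry()].
#' @return `"left"` or `"right"`.
#' @export
frame_half <- function(b, g) {
  validate_bbox(b)
  if (b[[1]] <= g$width / 2) "left" else "right"
}
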