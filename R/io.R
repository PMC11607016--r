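#' Write a detection or track stream as MOT-style CSV
#'
#' Comma-separated with a header line `frame,id,x,y,w,h,conf`; coordinates
#' are centre-based (see [bbox()]), frames 1-based, rows sorted by
#' `(frame, id)`. Raw detections conventionally carry id = -1. Use
#' [to_motchallenge()] for the corner-based layout public MOT tooling
#' expects.
#'
#' @param records Data frame with columns `frame, id, x, y, w, h` and
#'   optionally `conf` (filled with 1 when absent).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mot_csv <- function(records, path) {
  if (is.null(records$conf)) records$conf <- 1
  if (is.null(records$id)) records$id <- -1L
  records <- records[order(records$frame, records$id),
                     c("frame", "id", "x", "y", "w", "h", "conf"),
                     drop = FALSE]
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a MOT-style CSV stream
#'
#' Inverse of [write_mot_csv()]. An empty file yields a zero-row stream;
#' frames absent from the file are simply empty. Malformed rows (non-numeric
#' fields, frame index below 1) are reported with their line numbers.
#'
#' @param path Input file path.
#' @return Data frame `frame, id, x, y, w, h, conf`.
#' @export
read_mot_csv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  empty <- data.frame(frame = integer(0), id = integer(0), x = numeric(0),
                      y = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0))
  if (file.size(path) == 0) return(empty)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  req <- c("frame", "id", "x", "y", "w", "h", "conf")
  if (!all(req %in% names(df)))
    stop("malformed stream ", path, ": expected columns ",
         paste(req, collapse = ","))
  num <- lapply(df[req], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)) | num$frame < 1)
  if (length(bad) > 0)
    stop("malformed rows in ", path, " at line(s) ",
         paste(bad + 1L, collapse = ", "),
         " (non-numeric field or frame < 1)")
  out <- as.data.frame(num)
  out$frame <- as.integer(out$frame)
  out$id <- as.integer(out$id)
  out
}

#' Convert a centre-based stream to the MOTChallenge corner layout
#'
#' Public MOT tooling uses `(bb_left, bb_top)` corner coordinates; this
#' package uses box centres internally.
#'
#' @param records Data frame `frame, id, x, y, w, h[, conf]`.
#' @return Data frame `frame, id, bb_left, bb_top, w, h, conf, x, y, z`
#'   (the trailing world coordinates fixed at -1 per convention).
#' @export
to_motchallenge <- function(records) {
  if (is.null(records$conf)) records$conf <- 1
  data.frame(frame = records$frame, id = records$id,
             bb_left = records$x - records$w / 2,
             bb_top = records$y - records$h / 2,
             w = records$w, h = records$h, conf = records$conf,
             x = -1, y = -1, z = -1)
}

#' Convert a MOTChallenge corner-layout stream to the centre convention
#'
#' @param df Data frame with columns `frame, id, bb_left, bb_top, w, h` and
#'   optionally `conf`.
#' @return Data frame `frame, id, x, y, w, h, conf`.
#' @export
from_motchallenge <- function(df) {
  data.frame(frame = df$frame, id = df$id,
             x = df$bb_left + df$w / 2, y = df$bb_top + df$h / 2,
             w = df$w, h = df$h,
             conf = if (is.null(df$conf)) 1 else df$conf)
}
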