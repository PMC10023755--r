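#' Bounding boxes
#'
#' Boxes are rows of a data frame with columns `x_min`, `y_min`, `x_max`,
#' `y_max` (0-based pixel coordinates, half-open: the box covers pixel
#' columns `x_min .. x_max - 1` and rows `y_min .. y_max - 1`) and a `label`
#' column (default `"PWML"`). The half-open convention makes widths and
#' areas simple differences and composes cleanly with the continuous
#' coordinate frame used for geometric transforms, where pixel `i` spans
#' `[i, i + 1)`.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box corners.
#' @param label Character label(s), recycled.
#' @return A `data.frame` with one row per box.
#' @export
bbox <- function(x_min, y_min, x_max, y_max, label = "PWML") {
  b <- data.frame(
    x_min = as.numeric(x_min), y_min = as.numeric(y_min),
    x_max = as.numeric(x_max), y_max = as.numeric(y_max),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  bad <- b$x_min >= b$x_max | b$y_min >= b$y_max
  if (any(bad)) stop("degenerate box: need x_min < x_max and y_min < y_max", call. = FALSE)
  b
}

#' @rdname bbox
#' @export
empty_boxes <- function() {
  data.frame(
    x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    label = character(0), stringsAsFactors = FALSE
  )
}

#' Areas and pairwise intersection-over-union of boxes
#'
#' @param a,b Box data frames as produced by [bbox()].
#' @return `box_area`: numeric vector. `box_iou`: an `nrow(a) x nrow(b)`
#'   matrix of IoU values.
#' @export
box_area <- function(a) (a$x_max - a$x_min) * (a$y_max - a$y_min)

#' @rdname box_area
#' @export
box_iou <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  if (na == 0L || nb == 0L) return(out)
  for (j in seq_len(nb)) {
    ix <- pmax(0, pmin(a$x_max, b$x_max[j]) - pmax(a$x_min, b$x_min[j]))
    iy <- pmax(0, pmin(a$y_max, b$y_max[j]) - pmax(a$y_min, b$y_min[j]))
    inter <- ix * iy
    out[, j] <- inter / (box_area(a) + box_area(b)[j] - inter)
  }
  out
}

#' Tight bounding box of a binary mask
#'
#' @param mask Logical (or 0/1) matrix in `[row = y, col = x]` orientation.
#' @param label Label for the returned box.
#' @return A one-row box data frame (half-open, 0-based), or [empty_boxes()]
#'   if the mask has no true pixel.
#' @export
mask_bbox <- function(mask, label = "PWML") {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_boxes())
  bbox(
    x_min = min(idx[, 2L]) - 1L, y_min = min(idx[, 1L]) - 1L,
    x_max = max(idx[, 2L]), y_max = max(idx[, 1L]),
    label = label
  )
}

#' Clip boxes to an image canvas
#'
#' Boxes that collapse below one pixel in either dimension after clipping
#' are removed (with a warning when `warn = TRUE`).
#'
#' @param boxes Box data frame.
#' @param size Canvas size `c(width, height)` in pixels.
#' @param warn Warn when a box is dropped.
#' @return The clipped box data frame.
#' @export
clip_boxes <- function(boxes, size, warn = TRUE) {
  if (nrow(boxes) == 0L) return(boxes)
  w <- size[1L]; h <- size[2L]
  boxes$x_min <- pmax(boxes$x_min, 0); boxes$y_min <- pmax(boxes$y_min, 0)
  boxes$x_max <- pmin(boxes$x_max, w); boxes$y_max <- pmin(boxes$y_max, h)
  keep <- boxes$x_max - boxes$x_min >= 1 & boxes$y_max - boxes$y_min >= 1
  if (warn && any(!keep)) {
    warning(sprintf("%d box(es) dropped: smaller than 1 px after clipping", sum(!keep)),
      call. = FALSE)
  }
  boxes[keep, , drop = FALSE]
}
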