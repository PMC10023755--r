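#' Reference blob-detector parameters
#'
#' A deterministic classical detector for punctate hyperintense foci:
#' scale-normalized Laplacian-of-Gaussian (centre-surround) filtering at a
#' small range of blob radii, local maxima across space and scale, greedy
#' non-maximum suppression, and a probability-like score. It exists so the
#' full compose / annotate / detect / evaluate loop can be exercised
#' end-to-end without a trained network; the evaluation stack consumes
#' detection JSON from any source, so a real detector's output can be
#' scored identically. Scores are the per-image-normalized filter response
#' mapped to percent, monotone in response but not calibrated
#' probabilities.
#'
#' @param scales_px Ascending blob radii in pixels (default 1:4).
#' @param response_floor Minimum normalized response kept, as a fraction of
#'   the image's maximum response (default 0.05).
#' @param nms_iou Overlap above which the weaker of two detections is
#'   suppressed (default 0.3; must lie in `[0, 1)`).
#' @return A `detector_params` list.
#' @export
detector_params <- function(scales_px = 1:4, response_floor = 0.05, nms_iou = 0.3) {
  if (is.unsorted(scales_px, strictly = TRUE)) {
    stop("scales_px must be strictly ascending", call. = FALSE)
  }
  if (nms_iou < 0 || nms_iou >= 1) stop("nms_iou must lie in [0, 1)", call. = FALSE)
  structure(list(scales_px = scales_px, response_floor = response_floor,
                 nms_iou = nms_iou), class = "detector_params")
}

# scale-normalized LoG kernel (sign-flipped so bright blobs respond
# positively); radius r corresponds to sigma = r / sqrt(2)
log_kernel <- function(radius) {
  sigma <- radius / sqrt(2)
  half <- max(2L, ceiling(3 * sigma))
  g <- seq(-half, half)
  d2 <- outer(g^2, g^2, `+`)
  # -sigma^2 * LoG of a unit Gaussian: positive centre for bright blobs,
  # scale-normalized so the best-matching radius wins across scales
  k <- exp(-d2 / (2 * sigma^2)) * (2 * sigma^2 - d2) / (2 * pi * sigma^4)
  k - mean(k) # zero-DC so constant regions give zero response
}

# TRUE where x is a strict-or-equal local max within its 3x3 neighbourhood
# and strictly positive
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- x
  ok <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ok <- ok & (x >= pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx])
  }
  ok & (x > 0)
}

# greedy NMS: keep detections in descending score order, drop any that
# overlap a kept one above `iou`
nms_greedy <- function(boxes, scores, iou) {
  ord <- order(scores, decreasing = TRUE)
  keep <- logical(length(ord))
  for (i in ord) {
    cand <- boxes[i, , drop = FALSE]
    if (any(keep)) {
      ious <- box_iou(boxes[keep, , drop = FALSE], cand)
      if (any(ious > iou)) next
    }
    keep[i] <- TRUE
  }
  keep
}

#' Detect punctate blobs in a slice
#'
#' Candidate maxima are restricted to the head: an Otsu threshold on the
#' intensity histogram separates tissue from the dark air background, and
#' maxima whose centre falls outside it are discarded (matching how any
#' practical detector is applied to brain slices).
#'
#' @param image An [image_slice()] or matrix.
#' @param params A [detector_params()].
#' @param image_id Identifier recorded on each detection row.
#' @return Detection data frame (see [write_detections()] for the schema),
#'   sorted by descending probability. Constant images yield no detections.
#' @export
detect_lesions <- function(image, params = detector_params(), image_id = "image") {
  x <- unclass(image)
  brain <- x > EBImage::otsu(EBImage::Image(x / 255), range = c(0, 1)) * 255
  responses <- lapply(params$scales_px, function(r) {
    EBImage::filter2(x, log_kernel(r), boundary = "replicate")
  })
  rmax <- max(vapply(responses, max, numeric(1)))
  if (!is.finite(rmax) || rmax <= 1e-6) return(empty_detections())
  cand <- NULL
  for (si in seq_along(params$scales_px)) {
    r <- params$scales_px[si]
    resp <- responses[[si]]
    mx <- local_maxima(resp)
    # keep spatial maxima that also dominate the neighbouring scales
    if (si > 1L) mx <- mx & (resp >= responses[[si - 1L]])
    if (si < length(responses)) mx <- mx & (resp >= responses[[si + 1L]])
    idx <- which(mx & brain & (resp / rmax >= params$response_floor), arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    cand <- rbind(cand, data.frame(
      cy = idx[, 1L], cx = idx[, 2L], radius = r,
      response = resp[idx], stringsAsFactors = FALSE
    ))
  }
  if (is.null(cand) || nrow(cand) == 0L) return(empty_detections())
  size <- image_size(x)
  boxes <- bbox(
    x_min = pmax(cand$cx - 1L - cand$radius, 0),
    y_min = pmax(cand$cy - 1L - cand$radius, 0),
    x_max = pmin(cand$cx + cand$radius, size[1L]),
    y_max = pmin(cand$cy + cand$radius, size[2L])
  )
  keep <- nms_greedy(boxes, cand$response, params$nms_iou)
  boxes <- boxes[keep, , drop = FALSE]
  resp <- cand$response[keep]
  out <- data.frame(
    image_id = image_id,
    x_min = boxes$x_min, y_min = boxes$y_min,
    x_max = boxes$x_max, y_max = boxes$y_max,
    probability_percent = pmin(100, 100 * resp / rmax),
    stringsAsFactors = FALSE
  )
  out[order(out$probability_percent, decreasing = TRUE), , drop = FALSE]
}
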