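#' The augmentation set
#'
#' The fixed six-fold augmentation used to multiply a composite corpus:
#' the original image, a left-right flip, scaling by 0.95 and 1.05 about
#' the image centre, and rotation by +15 and -15 degrees about the centre.
#' Scaling and rotation keep the original canvas (crop/pad), fill exposed
#' pixels with `fill_value` and interpolate bilinearly.
#'
#' @param fill_value Intensity for pixels mapped from outside the source
#'   canvas (default 0).
#' @return An `augmentation_spec` with the fixed, ordered list of six ops.
#' @export
augmentation_spec <- function(fill_value = 0) {
  ops <- list(
    list(name = "identity"),
    list(name = "hflip"),
    list(name = "scale", factor = 0.95),
    list(name = "scale", factor = 1.05),
    list(name = "rotate", angle = 15),
    list(name = "rotate", angle = -15)
  )
  structure(list(ops = ops, interpolation = "bilinear", fill_value = fill_value),
            class = "augmentation_spec")
}

op_tag <- function(op) {
  switch(op$name,
    identity = "orig",
    hflip = "hflip",
    scale = sprintf("scale%0.2f", op$factor),
    rotate = sprintf("rot%+d", as.integer(op$angle))
  )
}

# forward affine map p' = A p + b in continuous image coordinates
# (x right, y down, pixel i spanning [i, i+1)); rotation/scaling about the
# canvas centre
op_affine <- function(op, size) {
  w <- size[1L]; h <- size[2L]
  c0 <- c(w / 2, h / 2)
  switch(op$name,
    identity = list(A = diag(2), b = c(0, 0)),
    hflip = list(A = matrix(c(-1, 0, 0, 1), 2, 2), b = c(w, 0)),
    scale = {
      s <- op$factor
      list(A = diag(2) * s, b = c0 - s * c0)
    },
    rotate = {
      th <- op$angle * pi / 180
      A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      list(A = A, b = as.vector(c0 - A %*% c0))
    },
    stop("unknown augmentation op: ", op$name, call. = FALSE)
  )
}

#' Apply one augmentation op to an image
#'
#' Identity and horizontal flip are exact index operations; scaling and
#' rotation are bilinear resamplings about the image centre onto the
#' original canvas, with out-of-canvas pixels set to `fill_value`.
#'
#' @param image An [image_slice()] or matrix.
#' @param op One element of `augmentation_spec()$ops`.
#' @param fill_value Fill intensity (default 0).
#' @return The transformed [image_slice()], same dimensions as the input.
#' @export
transform_image <- function(image, op, fill_value = 0) {
  px <- attr(image, "pixel_size_mm") %||% 0.83
  x <- unclass(image)
  out <- switch(op$name,
    identity = x,
    hflip = x[, ncol(x):1, drop = FALSE],
    {
      af <- op_affine(op, image_size(x))
      # EBImage::affine forward-maps continuous coords with dim1 as its x;
      # our matrices are [y, x], so the map is expressed in swapped axes
      m <- rbind(
        c(af$A[2, 2], af$A[1, 2]),
        c(af$A[2, 1], af$A[1, 1]),
        c(af$b[2], af$b[1])
      )
      y <- EBImage::affine(x, m, filter = "bilinear",
                           output.dim = dim(x), bg.col = fill_value,
                           antialias = FALSE)
      quantize8(matrix(y, nrow(x), ncol(x)))
    }
  )
  image_slice(out, pixel_size_mm = px)
}

#' Transform a bounding box consistently with its image
#'
#' Maps the box corners through the same continuous affine map as
#' [transform_image()] and takes the axis-aligned hull (for rotations this
#' is the hull of the four rotated corners), then clips to the canvas.
#' Boxes that fall below one pixel after clipping are dropped.
#'
#' @param boxes Box data frame (may be several rows).
#' @param op One element of `augmentation_spec()$ops`.
#' @param size Canvas `c(width, height)` in pixels.
#' @return The transformed, clipped box data frame.
#' @export
transform_boxes <- function(boxes, op, size) {
  if (nrow(boxes) == 0L) return(boxes)
  if (op$name == "identity") return(boxes)
  af <- op_affine(op, size)
  out <- boxes
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    corners <- rbind(
      c(b$x_min, b$y_min), c(b$x_max, b$y_min),
      c(b$x_min, b$y_max), c(b$x_max, b$y_max)
    )
    mapped <- t(af$A %*% t(corners) + af$b)
    out$x_min[i] <- min(mapped[, 1]); out$x_max[i] <- max(mapped[, 1])
    out$y_min[i] <- min(mapped[, 2]); out$y_max[i] <- max(mapped[, 2])
  }
  clip_boxes(out, size)
}

#' Augment a set of composite records six-fold
#'
#' Every record yields six: the original plus its five transforms, with
#' boxes transformed consistently and `transform_tag` recording the op.
#'
#' @param records List of [composite_record()]s with images (unless
#'   `keep_images = FALSE`).
#' @param spec An [augmentation_spec()].
#' @param keep_images Transform and retain images (default `TRUE`). With
#'   `FALSE` only box geometry and provenance are produced, which is enough
#'   for corpus arithmetic at scale.
#' @param size Canvas `c(width, height)`; required only for records that do
#'   not carry an image.
#' @return List of [composite_record()]s of length `6 * length(records)`.
#' @export
augment_set <- function(records, spec = augmentation_spec(), keep_images = TRUE,
                        size = NULL) {
  stopifnot(length(records) >= 1L)
  out <- vector("list", 6L * length(records))
  k <- 0L
  for (rec in records) {
    rsize <- if (!is.null(rec$image)) image_size(rec$image) else size
    if (is.null(rsize)) {
      stop("records without images need an explicit canvas `size`", call. = FALSE)
    }
    for (op in spec$ops) {
      k <- k + 1L
      img <- if (keep_images && !is.null(rec$image)) {
        transform_image(rec$image, op, spec$fill_value)
      }
      out[[k]] <- composite_record(
        image = img,
        boxes = transform_boxes(rec$boxes, op, rsize),
        background_id = rec$background_id,
        lesion_slice_id = rec$lesion_slice_id,
        transform_tag = op_tag(op),
        id = paste(rec$id, op_tag(op), sep = "__")
      )
    }
  }
  out
}
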