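#' Tissue label codes
#'
#' Integer codes used in tissue label maps: background 0, cortex 1,
#' white matter 2, ventricle 3. Label maps are plain integer matrices in
#' `[row = y, col = x]` orientation, like the image matrices they annotate.
#'
#' @format Named integer vector of length 4.
#' @export
TISSUE_LABELS <- c(
  background   = 0L,
  cortex       = 1L,
  white_matter = 2L,
  ventricle    = 3L
)

#' Create an image slice
#'
#' An image slice is a numeric matrix of 8-bit intensities in `[0, 255]`,
#' stored `[row = y, col = x]` with the origin at the top-left, plus a
#' `pixel_size_mm` attribute. All pixel coordinates used by this package are
#' 0-based; bounding boxes are half-open (see [bbox()]).
#'
#' @param data Numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size_mm In-plane pixel size in millimetres (default 0.83,
#'   a typical thin-slice T1 acquisition for infants).
#' @return An `image_slice` object (a classed matrix).
#' @export
image_slice <- function(data, pixel_size_mm = 0.83) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("image contains non-finite values", call. = FALSE)
  if (min(data) < 0 || max(data) > 255) {
    stop("intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(data,
    pixel_size_mm = pixel_size_mm,
    class = c("image_slice", "matrix", "array")
  )
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf(
    "<image_slice> %d x %d px, %.2f mm/px, intensity [%d, %d]\n",
    ncol(x), nrow(x), attr(x, "pixel_size_mm") %||% NA_real_,
    round(min(x)), round(max(x))
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Width and height of an image in pixels
#' @param image Matrix-like image.
#' @return Integer `c(width, height)`.
#' @export
image_size <- function(image) c(ncol(image), nrow(image))

#' Quantize intensities to 8-bit levels
#'
#' Rounds half away from zero (so 0.5 -> 1, 127.5 -> 128) and clamps to
#' `[0, 255]`. This is the quantization applied after every intensity
#' operation so that written PNGs and in-memory values agree.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape, integer-valued doubles in `[0, 255]`.
#' @export
quantize8 <- function(x) {
  y <- sign(x) * floor(abs(x) + 0.5)
  y[y < 0] <- 0
  y[y > 255] <- 255
  y
}

#' Read / write 8-bit grayscale PNG slices
#'
#' Images are written as single-channel 8-bit PNG; tissue label maps are
#' written with the raw label code as the stored byte (so they are nearly
#' black when viewed, but lossless).
#'
#' @param path File path.
#' @param image An [image_slice()] or plain matrix in `[0, 255]`.
#' @param pixel_size_mm Pixel size recorded on the returned slice.
#' @return `read_slice_png` returns an [image_slice()]; writers return the
#'   path invisibly.
#' @export
write_slice_png <- function(image, path) {
  png::writePNG(quantize8(unclass(image)) / 255, target = path)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_slice_png <- function(path, pixel_size_mm = 0.83) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L] # tolerate gray written as RGB
  image_slice(round(a * 255), pixel_size_mm = pixel_size_mm)
}

#' @rdname write_slice_png
#' @param mask Integer label matrix (values 0..255).
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(unclass(mask) / 255, target = path)
  invisible(path)
}

#' @rdname write_slice_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}
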