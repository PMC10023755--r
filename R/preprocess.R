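#' Intensity normalization parameters
#'
#' A percentile-clipped linear contrast stretch, the single-channel
#' equivalent of the interactive auto-contrast/auto-tone adjustments
#' typically applied to exported MR slices before compositing. On a
#' grayscale image both adjustments reduce to the same operation: clip a
#' small fraction of pixels at each tail of the histogram and map the
#' remaining range linearly onto the output range. The default 0.1% per
#' tail matches the conventional default clipping of such tools; the exact
#' fractions used by any given operator are unknowable, so they are
#' exposed here.
#'
#' @param clip_low,clip_high Fraction of pixels clipped at the dark / bright
#'   tail (defaults 0.001 each; their sum must be < 1).
#' @param out_min,out_max Output intensity range (defaults 0, 255).
#' @return A `normalize_params` list.
#' @export
normalize_params <- function(clip_low = 0.001, clip_high = 0.001,
                             out_min = 0, out_max = 255) {
  if (clip_low < 0 || clip_high < 0 || clip_low + clip_high >= 1) {
    stop("need 0 <= clip_low + clip_high < 1", call. = FALSE)
  }
  if (out_min >= out_max) stop("out_min must be < out_max", call. = FALSE)
  structure(list(clip_low = clip_low, clip_high = clip_high,
                 out_min = out_min, out_max = out_max),
            class = "normalize_params")
}

#' Percentile-clipped linear contrast stretch
#'
#' Finds the clip endpoints by order statistics -- the dark endpoint is the
#' `floor(clip_low * n) + 1`-th smallest pixel, the bright endpoint the
#' `floor(clip_high * n)`-th largest -- maps them linearly to
#' `[out_min, out_max]`, clamps, and re-quantizes to 8-bit levels by
#' rounding half away from zero. The mapping is monotone non-decreasing;
#' constant images are returned unchanged (there is no contrast to
#' stretch and no defensible endpoint pair).
#'
#' @param image An [image_slice()] or numeric matrix.
#' @param params A [normalize_params()].
#' @return The normalized [image_slice()].
#' @export
auto_contrast <- function(image, params = normalize_params()) {
  stopifnot(inherits(params, "normalize_params"))
  px <- attr(image, "pixel_size_mm") %||% 0.83
  x <- unclass(image)
  n <- length(x)
  if (n == 0L) stop("empty image", call. = FALSE)
  s <- sort(as.vector(x))
  lo <- s[floor(params$clip_low * n) + 1L]
  hi <- s[n - floor(params$clip_high * n)]
  if (hi <= lo) {
    return(image_slice(x, pixel_size_mm = px)) # constant (or fully clipped) image
  }
  y <- (x - lo) / (hi - lo) * (params$out_max - params$out_min) + params$out_min
  y[y < params$out_min] <- params$out_min
  y[y > params$out_max] <- params$out_max
  image_slice(quantize8(y), pixel_size_mm = px)
}
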