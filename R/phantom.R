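#' Phantom slice parameters
#'
#' Parameters of the synthetic infant-brain slice phantom. The phantom is a
#' deliberately simple geometric stand-in for an axial T1-weighted slice at
#' term-equivalent age: a brain ellipse with a bright cortical ribbon, a
#' darker (unmyelinated) white-matter interior and a pair of dark
#' ventricles. It exists so that every stage of the compositing and
#' evaluation pipeline can run on images with exactly known tissue maps and
#' lesion ground truth.
#'
#' Default intensities follow the T1 appearance of the neonatal brain, where
#' cortex is brighter than the largely unmyelinated white matter and CSF is
#' dark. Punctate lesions are modelled as hyperintense foci relative to the
#' surrounding white matter.
#'
#' @param image_size Square canvas side in pixels (>= 64; default 256).
#' @param cortex_thickness Cortical ribbon thickness in pixels.
#' @param ventricle_scale Ventricle size as a fraction of the brain radius.
#' @param wm_mean,cortex_mean,ventricle_mean,background_mean Mean tissue
#'   intensities in `[0, 255]`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param pixel_size_mm In-plane resolution in mm (default 0.83).
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(image_size = 256L,
                           cortex_thickness = 6L,
                           ventricle_scale = 0.18,
                           wm_mean = 110,
                           cortex_mean = 150,
                           ventricle_mean = 45,
                           background_mean = 8,
                           noise_sd = 5,
                           pixel_size_mm = 0.83) {
  if (image_size < 64L) stop("image_size must be >= 64", call. = FALSE)
  means <- c(wm_mean, cortex_mean, ventricle_mean, background_mean)
  if (any(means < 0) || any(means > 255)) stop("tissue means must lie in [0, 255]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (ventricle_scale <= 0 || ventricle_scale >= 0.5) {
    stop("ventricle_scale must lie in (0, 0.5)", call. = FALSE)
  }
  p <- list(
    image_size = as.integer(image_size),
    cortex_thickness = as.integer(cortex_thickness),
    ventricle_scale = ventricle_scale,
    wm_mean = wm_mean, cortex_mean = cortex_mean,
    ventricle_mean = ventricle_mean, background_mean = background_mean,
    noise_sd = noise_sd, pixel_size_mm = pixel_size_mm
  )
  # the inner (sub-cortical) ellipse must retain room for ventricles + WM
  if (min(0.40, 0.46) * image_size - cortex_thickness <= ventricle_scale * 0.46 * image_size + 4) {
    stop("image_size too small to fit ventricles inside the cortex ribbon", call. = FALSE)
  }
  class(p) <- "phantom_params"
  p
}

# squared normalized ellipse radius on the pixel-center grid
ellipse_r2 <- function(size, cx, cy, a, b) {
  x <- (seq_len(size) - 0.5) # continuous pixel-center coordinates
  dx2 <- ((x - cx) / a)^2
  dy2 <- ((x - cy) / b)^2
  outer(dy2, dx2, `+`) # [row = y, col = x]
}

#' Generate one synthetic brain slice
#'
#' Builds the tissue label map (background / cortex / white matter /
#' ventricle; the labels partition every pixel) and renders intensities as
#' per-tissue means plus Gaussian noise, quantized to 8 bit. Slice-to-slice
#' anatomical variability is emulated by a small seeded jitter of the brain
#' axes, centre, and ventricle size. Fully deterministic for a fixed
#' `(params, seed)`.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed for this slice.
#' @return A list with elements `image` ([image_slice()]) and `mask`
#'   (integer label matrix, see [TISSUE_LABELS]).
#' @export
generate_slice <- function(params = phantom_params(), seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  n <- params$image_size
  with_substream(derive_seed(seed, "phantom-geom"), {
    jit <- stats::runif(5, -1, 1)
  })
  cx <- n / 2 + jit[1] * 0.02 * n
  cy <- n / 2 + jit[2] * 0.02 * n
  a <- 0.40 * n * (1 + 0.03 * jit[3]) # left-right semi-axis
  b <- 0.46 * n * (1 + 0.03 * jit[4]) # anterior-posterior semi-axis
  vscale <- params$ventricle_scale * (1 + 0.05 * jit[5])

  brain <- ellipse_r2(n, cx, cy, a, b) <= 1
  inner <- ellipse_r2(n, cx, cy, a - params$cortex_thickness, b - params$cortex_thickness) <= 1
  # two lateral ventricles, slightly overlapping at the midline so CSF is
  # one connected structure and WM remains a single connected region
  va <- vscale * a * 0.55
  vb <- vscale * b * 1.25
  off <- va * 0.85
  vent <- (ellipse_r2(n, cx - off, cy, va, vb) <= 1) |
    (ellipse_r2(n, cx + off, cy, va, vb) <= 1)
  vent <- vent & inner

  lab <- matrix(TISSUE_LABELS[["background"]], n, n)
  lab[brain] <- TISSUE_LABELS[["cortex"]]
  lab[inner] <- TISSUE_LABELS[["white_matter"]]
  lab[vent] <- TISSUE_LABELS[["ventricle"]]
  storage.mode(lab) <- "integer"

  means <- c(params$background_mean, params$cortex_mean,
             params$wm_mean, params$ventricle_mean)[lab + 1L]
  with_substream(derive_seed(seed, "phantom-noise"), {
    noise <- stats::rnorm(n * n, 0, params$noise_sd)
  })
  img <- quantize8(matrix(means + noise, n, n))
  list(image = image_slice(img, params$pixel_size_mm), mask = lab)
}

#' Lesion injection specification
#'
#' Punctate lesions are rendered as isotropic Gaussian intensity bumps of
#' amplitude `contrast` above the local white matter, truncated at two
#' standard deviations; the lesion's binary mask is the level set above a
#' quarter of the peak, so `diameter_px` is the mask diameter. At 0.83 mm
#' per pixel the default 2--6 px range corresponds to roughly 1.7--5 mm
#' foci, the scale at which these lesions present.
#'
#' @param count Number of lesions to inject (>= 0).
#' @param diameter_px Length-2 range of mask diameters in pixels (within
#'   `[1, 15]`).
#' @param contrast Peak intensity above the local white matter (> 0).
#' @param count_distribution Per-case lesion-count model used by
#'   [sample_lesion_counts()]: a list with `min`, `max`, `mean`, `sd`.
#'   Defaults to counts between 1 and 19 with mean 6.0 and SD 5.4, the
#'   per-infant distribution this generator emulates.
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(count,
                        diameter_px = c(2, 6),
                        contrast = 40,
                        count_distribution = list(min = 1, max = 19, mean = 6.0, sd = 5.4)) {
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  if (length(diameter_px) == 1L) diameter_px <- rep(diameter_px, 2L)
  if (diameter_px[1] < 1 || diameter_px[2] > 15 || diameter_px[1] > diameter_px[2]) {
    stop("diameter_px must be an increasing range within [1, 15]", call. = FALSE)
  }
  if (contrast <= 0) stop("contrast must be > 0", call. = FALSE)
  structure(
    list(count = as.integer(count), diameter_px = diameter_px,
         contrast = contrast, count_distribution = count_distribution),
    class = "lesion_spec"
  )
}

#' Sample per-case lesion counts
#'
#' Draws integer lesion counts from a rounded normal with the
#' `count_distribution` mean and SD, rejection-sampled into
#' `[min, max]`.
#'
#' @param n Number of cases.
#' @param dist Count distribution list (see [lesion_spec()]).
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_lesion_counts <- function(n, dist = lesion_spec(1)$count_distribution, seed = 1L) {
  with_substream(derive_seed(seed, "lesion-counts"), {
    out <- integer(0)
    while (length(out) < n) {
      k <- round(stats::rnorm(n, dist$mean, dist$sd))
      out <- c(out, k[k >= dist$min & k <= dist$max])
    }
    out[seq_len(n)]
  })
}

# Gaussian bump truncated at 2*sigma; mask = level set above peak/4.
# sigma chosen so the mask diameter equals `diameter`.
lesion_profile <- function(diameter, contrast) {
  sigma <- diameter / (2 * sqrt(2 * log(4)))
  r_cut <- 2 * sigma
  half <- ceiling(r_cut)
  g <- seq(-half, half)
  d2 <- outer(g^2, g^2, `+`)
  bump <- contrast * exp(-d2 / (2 * sigma^2))
  bump[d2 > r_cut^2] <- 0
  list(bump = bump, mask = bump > 0.25 * contrast, half = half, sigma = sigma)
}

#' Inject punctate lesions into a phantom slice
#'
#' Places `spec$count` non-overlapping Gaussian lesions at rejection-sampled
#' positions whose masks lie entirely inside the white matter. Pixels
#' outside the (truncated) lesion footprints are left bit-identical to the
#' input. Ground-truth boxes are the tight bounding boxes of the lesion
#' masks (0-based, half-open).
#'
#' @param image Phantom [image_slice()].
#' @param mask Tissue label matrix from [generate_slice()].
#' @param spec A [lesion_spec()].
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap per lesion.
#' @return A list with `image` (lesioned slice) and `boxes` (ground-truth
#'   box data frame). The boxes carry an `injections` attribute: a list of
#'   per-lesion records (centre, diameter, sigma, contrast, mask pixel
#'   indices) for use as an oracle in downstream checks.
#' @export
inject_lesions <- function(image, mask, spec, seed = 1L, max_attempts = 1000L) {
  stopifnot(inherits(spec, "lesion_spec"))
  if (spec$count == 0L) {
    b <- empty_boxes(); attr(b, "injections") <- list()
    return(list(image = image, boxes = b))
  }
  wm <- mask == TISSUE_LABELS[["white_matter"]]
  dist_wm <- EBImage::distmap(wm) # distance to nearest non-WM pixel
  img <- unclass(image)
  n <- nrow(img)
  occupied <- matrix(FALSE, n, n) # union of lesion footprints (2 sigma disks)
  boxes <- NULL
  records <- vector("list", spec$count)

  with_substream(derive_seed(seed, "inject"), {
    for (i in seq_len(spec$count)) {
      d <- stats::runif(1, spec$diameter_px[1], spec$diameter_px[2])
      prof <- lesion_profile(d, spec$contrast)
      half <- prof$half
      # candidate centres: WM pixels far enough from non-WM for the whole
      # truncated footprint to stay inside the white matter
      ok <- which(dist_wm > half + 1)
      if (length(ok) == 0L) stop("white matter too small for lesion footprint", call. = FALSE)
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        ci <- ok[sample.int(length(ok), 1L)]
        cy <- ((ci - 1L) %% n) + 1L
        cx <- ((ci - 1L) %/% n) + 1L
        ys <- (cy - half):(cy + half)
        xs <- (cx - half):(cx + half)
        if (any(occupied[ys, xs])) next
        sub <- img[ys, xs]
        img[ys, xs] <- ifelse(prof$bump > 0, quantize8(sub + prof$bump), sub)
        occupied[ys, xs] <- occupied[ys, xs] | (prof$bump > 0)
        # tight mask bbox in global 0-based coordinates
        mb <- mask_bbox(prof$mask)
        mb$x_min <- mb$x_min + xs[1L] - 1L; mb$x_max <- mb$x_max + xs[1L] - 1L
        mb$y_min <- mb$y_min + ys[1L] - 1L; mb$y_max <- mb$y_max + ys[1L] - 1L
        boxes <- rbind(boxes, mb)
        lesion_px <- which(prof$mask, arr.ind = TRUE)
        records[[i]] <- list(
          center = c(x = cx - 0.5, y = cy - 0.5), diameter = d,
          sigma = prof$sigma, contrast = spec$contrast,
          mask_rows = lesion_px[, 1L] + ys[1L] - 1L,
          mask_cols = lesion_px[, 2L] + xs[1L] - 1L
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("could not place lesion %d after %d attempts", i, max_attempts),
          call. = FALSE)
      }
    }
  })
  attr(boxes, "injections") <- records
  list(image = image_slice(img, attr(image, "pixel_size_mm") %||% 0.83), boxes = boxes)
}
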