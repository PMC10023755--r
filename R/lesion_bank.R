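#' Lesion extraction parameters
#'
#' Controls the automatic selection of punctate lesions from a normalized
#' slice. A candidate focus must stand out from its local background
#' (`k_sigma` local standard deviations, estimated in a sliding window),
#' contain a strong seed pixel (`seed_k_sigma`, the analogue of clicking a
#' magic-wand tool on an unambiguous bright spot; candidates whose peak
#' does not reach it are treated as noise), and then pass the
#' inclusion/exclusion rules for punctate lesions: not too small or too
#' widespread (`min_area`/`max_area`), not linear (`max_elongation`), and
#' not faint (`min_contrast` above the local background). When a tissue
#' map is available the candidate's centroid must lie in white matter.
#'
#' @param k_sigma Region threshold in local-SD units (default 3).
#' @param min_area,max_area Component area window in pixels (defaults 2, 40).
#' @param max_elongation Maximum principal-axis ratio (default 3); the
#'   ratio of the square roots of the mask's principal second central
#'   moments (with the 1/12 single-pixel term), so a 3 x 15 streak scores 5.
#' @param min_contrast Minimum peak height above the local mean (default 10).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param local_window Sliding-window halfwidth basis for local background
#'   statistics, in pixels (default 15; the window is `local_window` square).
#' @param seed_k_sigma Seed threshold in local-SD units (default `k_sigma + 1.5`).
#' @param min_blob_snr Minimum integrated contrast-to-noise ratio of the
#'   final mask, `sum(intensity - background) / (sd * sqrt(area))`
#'   (default 8). A genuine punctate focus integrates contrast over its
#'   whole extent, while a chance cluster of bright noise pixels does not,
#'   so this separates the two far more sharply than any single-pixel test.
#' @return An `extraction_params` list.
#' @export
extraction_params <- function(k_sigma = 3.0, min_area = 2L, max_area = 40L,
                              max_elongation = 3.0, min_contrast = 10,
                              connectivity = 8L, local_window = 15L,
                              seed_k_sigma = k_sigma + 1.5, min_blob_snr = 8) {
  if (min_area > max_area) stop("min_area must be <= max_area", call. = FALSE)
  if (max_elongation < 1) stop("max_elongation must be >= 1", call. = FALSE)
  if (k_sigma <= 0) stop("k_sigma must be > 0", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  structure(list(
    k_sigma = k_sigma, min_area = as.integer(min_area),
    max_area = as.integer(max_area), max_elongation = max_elongation,
    min_contrast = min_contrast, connectivity = as.integer(connectivity),
    local_window = as.integer(local_window), seed_k_sigma = seed_k_sigma,
    min_blob_snr = min_blob_snr
  ), class = "extraction_params")
}

# sliding-window robust location/scale: median and scaled MAD. Robust
# statistics matter here because windows near tissue interfaces contain a
# minority of much brighter or darker pixels that would wreck a mean/SD
# estimate of the local white-matter background. The scale is floored at
# 0.75 (half a quantization level times 1.4826) so flat synthetic regions
# do not yield a zero threshold.
local_stats <- function(x, window) {
  r <- max(1L, window) # window radius in pixels
  med <- EBImage::medianFilter(x / 255, r) * 255
  mad <- EBImage::medianFilter(abs(x - med) / 255, r) * 255
  sig <- 1.4826 * mad
  sig[sig < 0.75] <- 0.75
  list(median = med, sigma = sig)
}

# connected-component labels; EBImage::bwlabel is 4-connected, so for
# 8-connectivity labels touching diagonally are merged by union-find
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4L || max(lab) <= 1L) return(lab)
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) { # the two diagonal neighbour offsets
    r1 <- seq_len(nr - 1L); c1 <- if (sh[2L] > 0) seq_len(nc - 1L) else seq(2L, nc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + 1L, c1 + sh[2L], drop = FALSE]
    hit <- which(a > 0L & b > 0L & a != b)
    for (h in hit) unite(a[h], b[h])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# elongation of a pixel set: sqrt ratio of principal second central moments,
# each augmented by the 1/12 moment of a unit pixel
mask_elongation <- function(rows, cols) {
  if (length(rows) == 1L) return(1)
  cy <- mean(rows); cx <- mean(cols)
  sxx <- mean((cols - cx)^2) + 1 / 12
  syy <- mean((rows - cy)^2) + 1 / 12
  sxy <- mean((cols - cx) * (rows - cy))
  tr <- sxx + syy
  det <- sxx * syy - sxy * sxy
  disc <- sqrt(max(tr * tr / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-9)
  sqrt(l1 / l2)
}

# one-step binary dilation by logical shifts (no convolution overhead)
dilate1 <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-nr, ]
  out[-nr, ] <- out[-nr, ] | m[-1, ]
  out[, -1] <- out[, -1] | m[, -nc]
  out[, -nc] <- out[, -nc] | m[, -1]
  if (connectivity == 8L) {
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
  }
  out
}

# 8- or 4-connected region of `thr_mask` containing `seed_mask`, grown by
# iterated dilation restricted to thr_mask (both small window crops)
grow_region <- function(seed_mask, thr_mask, connectivity = 8L) {
  cur <- seed_mask & thr_mask
  repeat {
    grown <- dilate1(cur, connectivity) & thr_mask
    if (sum(grown) == sum(cur)) return(cur)
    cur <- grown
  }
}

#' A lesion patch
#'
#' A cropped intensity patch with its binary lesion mask and provenance.
#'
#' @param patch Numeric intensity matrix (crop of the source slice).
#' @param mask Logical matrix, same shape; the lesion's pixel support.
#' @param source_id Identifier of the source case/slice.
#' @param bbox_in_source One-row box data frame: the tight mask bounding box
#'   in source-slice coordinates (0-based, half-open).
#' @param centroid Numeric `c(x, y)`: mask centroid in source coordinates.
#' @param threshold Intensity level defining the mask (recorded by
#'   [extract_lesions()]; `NA` for patches built by hand).
#' @return A `lesion_patch` object.
#' @export
lesion_patch <- function(patch, mask, source_id, bbox_in_source, centroid,
                         threshold = NA_real_) {
  stopifnot(all(dim(patch) == dim(mask)), any(mask))
  structure(list(
    patch = patch, mask = mask, source_id = source_id,
    bbox_in_source = bbox_in_source, centroid = centroid,
    threshold = threshold
  ), class = "lesion_patch")
}

#' @export
print.lesion_patch <- function(x, ...) {
  cat(sprintf("<lesion_patch> %dx%d px, area %d, from %s\n",
              ncol(x$patch), nrow(x$patch), sum(x$mask), x$source_id))
  invisible(x)
}

#' Extract punctate lesion patches from a slice
#'
#' Finds bright foci that exceed the local background by
#' `k_sigma` local standard deviations, requires each focus to contain a
#' seed pixel at `seed_k_sigma` (rejecting chance noise clusters), refines
#' the local background statistics in a window around each focus with the
#' candidate pixels excluded, region-grows the lesion mask at the refined
#' threshold, and applies the punctate inclusion rules (area window,
#' elongation, minimum contrast, white-matter centroid). Patches store the
#' raw source intensities; blending decisions belong to the paste step.
#'
#' @param image Normalized [image_slice()].
#' @param wm_mask Optional tissue label matrix; when given, candidates whose
#'   centroid is not labelled white matter are excluded.
#' @param params An [extraction_params()].
#' @param source_id Identifier recorded on each patch.
#' @return List of [lesion_patch()] objects (possibly empty).
#' @export
extract_lesions <- function(image, wm_mask = NULL, params = extraction_params(),
                            source_id = "slice") {
  stopifnot(inherits(params, "extraction_params"))
  x <- unclass(image)
  nr <- nrow(x); nc <- ncol(x)
  st <- local_stats(x, params$local_window)
  cand <- x > st$median + params$k_sigma * st$sigma
  if (!any(cand)) return(list())
  # lightly smoothed copy used for the mask level set (see below)
  xs <- EBImage::gblur(x, sigma = 0.5, boundary = "replicate")
  lab <- label_components(cand, params$connectivity)
  ncomp <- max(lab)
  accepted <- matrix(FALSE, nr, nc)
  out <- list()
  for (ci in seq_len(ncomp)) {
    px <- which(lab == ci, arr.ind = TRUE)
    if (nrow(px) > 8L * params$max_area) next # widespread (e.g. a tissue interface)
    rows <- px[, 1L]; cols <- px[, 2L]
    # analysis window: component bbox expanded by the local window size
    r0 <- max(1L, min(rows) - params$local_window)
    r1 <- min(nr, max(rows) + params$local_window)
    c0 <- max(1L, min(cols) - params$local_window)
    c1 <- min(nc, max(cols) + params$local_window)
    win <- x[r0:r1, c0:c1, drop = FALSE]
    # the mask level set is computed on a lightly smoothed copy so single
    # noise pixels at the lesion rim do not flip in or out of the mask;
    # patch intensities stay raw
    win_s <- xs[r0:r1, c0:c1, drop = FALSE]
    # local white-matter background: window pixels away from any candidate
    # (1-px guard ring), restricted to white matter when a tissue map is
    # available; otherwise a one-step mode trim discards pixels of other
    # tissues caught in the window (cortex, CSF), which would inflate a
    # plain MAD near interfaces
    guard <- dilate1(cand[r0:r1, c0:c1, drop = FALSE], 8L)
    sel <- !guard
    if (!is.null(wm_mask)) {
      sel <- sel & (wm_mask[r0:r1, c0:c1, drop = FALSE] == TISSUE_LABELS[["white_matter"]])
    }
    bg <- win[sel]
    if (length(bg) < 30L) bg <- win[!guard]
    if (is.null(wm_mask)) {
      mad0 <- 1.4826 * stats::mad(bg, constant = 1)
      if (mad0 > 0) bg <- bg[abs(bg - stats::median(bg)) <= 3 * mad0]
    }
    mu_l <- stats::median(bg)
    sd_l <- max(1.4826 * stats::mad(bg, center = mu_l, constant = 1), 0.75)
    peak <- max(x[px])
    if (peak < mu_l + params$seed_k_sigma * sd_l) next # indistinct from noise
    if (peak - mu_l < params$min_contrast) next        # faint
    # mask level: the quarter-peak level set (the morphological extent of a
    # punctate focus), clamped to at least 2/3 of the detection threshold
    # so the mask cannot reach into background noise
    thr <- mu_l + max(min(params$k_sigma * sd_l, 0.25 * (peak - mu_l)),
                      2 / 3 * params$k_sigma * sd_l)
    comp_win <- lab[r0:r1, c0:c1, drop = FALSE] == ci
    m <- grow_region(comp_win, win_s > thr, params$connectivity)
    mp <- which(m, arr.ind = TRUE)
    if (nrow(mp) < params$min_area || nrow(mp) > params$max_area) next
    if (mask_elongation(mp[, 1L], mp[, 2L]) > params$max_elongation) next
    blob_snr <- sum(win[m] - mu_l) / (sd_l * sqrt(nrow(mp)))
    if (blob_snr < params$min_blob_snr) next # integrated contrast too weak
    # global coordinates of the grown mask
    g_rows <- mp[, 1L] + r0 - 1L
    g_cols <- mp[, 2L] + c0 - 1L
    if (any(accepted[cbind(g_rows, g_cols)])) next # merged with a prior find
    centroid <- c(x = mean(g_cols) - 0.5, y = mean(g_rows) - 0.5)
    if (!is.null(wm_mask)) {
      ctr <- c(round(centroid[["y"]] + 0.5), round(centroid[["x"]] + 0.5))
      ctr <- pmin(pmax(ctr, 1L), c(nr, nc))
      if (wm_mask[ctr[1L], ctr[2L]] != TISSUE_LABELS[["white_matter"]]) next
    }
    accepted[cbind(g_rows, g_cols)] <- TRUE
    bb <- bbox(min(g_cols) - 1L, min(g_rows) - 1L, max(g_cols), max(g_rows))
    crop_r <- min(g_rows):max(g_rows); crop_c <- min(g_cols):max(g_cols)
    mask_crop <- matrix(FALSE, length(crop_r), length(crop_c))
    mask_crop[cbind(g_rows - min(g_rows) + 1L, g_cols - min(g_cols) + 1L)] <- TRUE
    out[[length(out) + 1L]] <- lesion_patch(
      patch = x[crop_r, crop_c, drop = FALSE], mask = mask_crop,
      source_id = source_id, bbox_in_source = bb, centroid = centroid,
      threshold = thr
    )
  }
  out
}

#' Write / read a lesion-patch bank
#'
#' The bank is a directory of paired patch/mask PNGs plus a `bank.csv`
#' table (source id, bounding box in the source slice, area, elongation,
#' contrast proxy, centroid).
#'
#' @param patches List of [lesion_patch()] objects.
#' @param dir Bank directory (created if needed).
#' @return `write_bank` returns `dir` invisibly; `read_bank` the patch list.
#' @export
write_bank <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    id <- sprintf("patch_%04d", i)
    write_slice_png(p$patch, file.path(dir, paste0(id, ".png")))
    write_mask_png(p$mask * 255L, file.path(dir, paste0(id, "_mask.png")))
    b <- p$bbox_in_source
    data.frame(
      patch_id = id, source_id = p$source_id,
      x_min = b$x_min, y_min = b$y_min, x_max = b$x_max, y_max = b$y_max,
      area = sum(p$mask),
      elongation = {
        mp <- which(p$mask, arr.ind = TRUE)
        mask_elongation(mp[, 1L], mp[, 2L])
      },
      contrast = max(p$patch[p$mask]) - mean(p$patch[!p$mask]),
      centroid_x = p$centroid[["x"]], centroid_y = p$centroid[["y"]],
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "bank.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bank
#' @export
read_bank <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "bank.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    patch <- unclass(read_slice_png(file.path(dir, paste0(r$patch_id, ".png"))))
    mask <- read_mask_png(file.path(dir, paste0(r$patch_id, "_mask.png"))) > 0
    lesion_patch(
      patch = patch, mask = mask, source_id = r$source_id,
      bbox_in_source = bbox(r$x_min, r$y_min, r$x_max, r$y_max),
      centroid = c(x = r$centroid_x, y = r$centroid_y)
    )
  })
}
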