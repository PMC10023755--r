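#' Paste constraints
#'
#' Anatomical constraints for pasting lesion patches onto normal slices.
#' Lesions are only pasted into white matter, at least `margin` pixels away
#' from any non-white-matter pixel, and the white matter is divided into
#' `n_regions` equal anterior-to-posterior bands (frontal through parietal)
#' so that the coarse spatial distribution of the source lesions is
#' preserved: each patch is assigned a band by the anterior-posterior rank
#' of its source centroid and is pasted somewhere in that band.
#'
#' @param allowed_tissue Tissue label name patches may cover (default
#'   `"white_matter"`).
#' @param n_regions Number of anterior-posterior bands (default 3).
#' @param margin Minimum distance, in pixels, from any pasted lesion pixel
#'   to the nearest non-allowed pixel (default 2).
#' @param max_attempts Rejection-sampling cap per patch placement.
#' @param feather Apply a 1-px Gaussian feather inside the pasted mask edge
#'   (default `TRUE`); pixels outside the mask are never touched.
#' @return A `paste_constraints` list.
#' @export
paste_constraints <- function(allowed_tissue = "white_matter", n_regions = 3L,
                              margin = 2L, max_attempts = 100L, feather = TRUE) {
  if (margin < 0) stop("margin must be >= 0", call. = FALSE)
  if (!allowed_tissue %in% names(TISSUE_LABELS)) {
    stop("unknown tissue label: ", allowed_tissue, call. = FALSE)
  }
  structure(list(
    allowed_tissue = allowed_tissue, n_regions = as.integer(n_regions),
    margin = as.integer(margin), max_attempts = as.integer(max_attempts),
    feather = isTRUE(feather)
  ), class = "paste_constraints")
}

# anterior->posterior band index (1..n) for each pixel of the allowed mask:
# the allowed region's y-extent is cut into n equal-width horizontal bands
tissue_bands <- function(allowed, n_regions) {
  idx <- which(allowed, arr.ind = TRUE)
  ys <- range(idx[, 1L])
  edges <- seq(ys[1L], ys[2L] + 1L, length.out = n_regions + 1L)
  band <- matrix(NA_integer_, nrow(allowed), ncol(allowed))
  band[allowed] <- pmin(findInterval(idx[, 1L], edges, rightmost.closed = TRUE), n_regions)
  band
}

# feathered alpha inside the mask: edge pixels blend toward the background
# (the mask is padded so patches narrower than the kernel still feather)
feather_alpha <- function(mask) {
  k <- EBImage::makeBrush(3, "gaussian", sigma = 0.5)
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  a <- EBImage::filter2(pad, k / sum(k), boundary = 0)
  a <- a[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
  a[!mask] <- 0
  a[a > 1] <- 1
  a
}

#' Paste one lesion patch onto a background slice
#'
#' Places the patch with its top-left corner at `location` (0-based pixel
#' coordinates). Every mask-true pixel must land on the allowed tissue with
#' the required margin; otherwise a placement error names the violated
#' rule. Where the patch mask is true the background takes the patch values
#' (with an optional 1-px feather at the mask edge); all other pixels are
#' bit-identical to the background.
#'
#' @param background Background [image_slice()].
#' @param patch A [lesion_patch()].
#' @param location Integer `c(x, y)` top-left placement, 0-based.
#' @param mask Tissue label matrix of the background.
#' @param constraints A [paste_constraints()].
#' @return List with `image` (composited slice) and `box` (the pasted
#'   mask's tight bounding box).
#' @export
paste_lesion <- function(background, patch, location, mask,
                         constraints = paste_constraints()) {
  allowed <- mask == TISSUE_LABELS[[constraints$allowed_tissue]]
  dist_ok <- EBImage::distmap(allowed) >= max(constraints$margin, 1L)
  res <- paste_lesion_impl(unclass(background), patch, location, dist_ok, constraints)
  list(
    image = image_slice(res$image, attr(background, "pixel_size_mm") %||% 0.83),
    box = res$box
  )
}

# core paste against a precomputed margin-eroded allowed map
paste_lesion_impl <- function(bg, patch, location, dist_ok, constraints,
                              occupied = NULL) {
  ph <- nrow(patch$mask); pw <- ncol(patch$mask)
  x0 <- location[1L]; y0 <- location[2L] # 0-based top-left
  nr <- nrow(bg); nc <- ncol(bg)
  if (x0 < 0 || y0 < 0 || x0 + pw > nc || y0 + ph > nr) {
    stop("placement error: patch extends outside the canvas", call. = FALSE)
  }
  rows <- (y0 + 1L):(y0 + ph); cols <- (x0 + 1L):(x0 + pw)
  ok <- dist_ok[rows, cols, drop = FALSE]
  if (any(patch$mask & !ok)) {
    stop("placement error: lesion pixels leave the allowed tissue (margin rule)",
      call. = FALSE)
  }
  if (!is.null(occupied) && any(patch$mask & occupied[rows, cols])) {
    stop("placement error: overlap with a previously pasted lesion", call. = FALSE)
  }
  sub <- bg[rows, cols, drop = FALSE]
  if (constraints$feather) {
    a <- feather_alpha(patch$mask)
    sub[patch$mask] <- quantize8(a[patch$mask] * patch$patch[patch$mask] +
                                   (1 - a[patch$mask]) * sub[patch$mask])
  } else {
    sub[patch$mask] <- quantize8(patch$patch[patch$mask])
  }
  bg[rows, cols] <- sub
  b <- mask_bbox(patch$mask)
  b$x_min <- b$x_min + x0; b$x_max <- b$x_max + x0
  b$y_min <- b$y_min + y0; b$y_max <- b$y_max + y0
  list(image = bg, box = b)
}

#' A composite record
#'
#' One composite training image: a normal background slice with the patches
#' of one lesion-bearing slice pasted in, its ground-truth boxes, and
#' provenance.
#'
#' @param image Composited [image_slice()] or `NULL` when images are not
#'   retained.
#' @param boxes Ground-truth box data frame.
#' @param background_id,lesion_slice_id Provenance identifiers.
#' @param transform_tag Augmentation tag (`"orig"` before augmentation).
#' @param id Record identifier.
#' @return A `composite_record` list.
#' @export
composite_record <- function(image, boxes, background_id, lesion_slice_id,
                             transform_tag = "orig", id = NULL) {
  structure(list(
    image = image, boxes = boxes, background_id = background_id,
    lesion_slice_id = lesion_slice_id, transform_tag = transform_tag,
    id = id %||% paste(lesion_slice_id, background_id, transform_tag, sep = "__")
  ), class = "composite_record")
}

#' @export
print.composite_record <- function(x, ...) {
  cat(sprintf("<composite_record> %s: %d box(es), transform %s\n",
              x$id, nrow(x$boxes), x$transform_tag))
  invisible(x)
}

#' Build the full composite corpus
#'
#' Pairs every lesion-bearing slice with every background: the patches of a
#' lesion slice are copied onto each of the backgrounds in turn, so
#' `L` lesion slices and `B` backgrounds always yield `L x B` composites
#' (13 slices x 72 backgrounds gives the canonical 936). Within a
#' composite, each patch is placed once by rejection sampling over its
#' anterior-posterior band, without overlap between patches. Deterministic
#' for a fixed seed.
#'
#' @param lesion_slices List of lists, each with `id` and `patches` (a
#'   non-empty list of [lesion_patch()]).
#' @param backgrounds List of lists, each with `id`, `image`
#'   ([image_slice()]) and `mask` (tissue labels).
#' @param constraints A [paste_constraints()].
#' @param seed Integer seed.
#' @param keep_images Retain composited images in the records (default
#'   `TRUE`); with `FALSE` only boxes and provenance are kept, which makes
#'   corpus-scale cardinality and geometry checks cheap.
#' @return List of [composite_record()]s, length `L x B`.
#' @export
build_composites <- function(lesion_slices, backgrounds,
                             constraints = paste_constraints(), seed = 1L,
                             keep_images = TRUE) {
  stopifnot(length(lesion_slices) >= 1L, length(backgrounds) >= 1L)
  for (ls in lesion_slices) {
    if (length(ls$patches) < 1L) {
      stop("lesion slice ", ls$id, " has no patches", call. = FALSE)
    }
  }
  # per-background allowed maps with margin, plus band maps
  bg_aux <- lapply(backgrounds, function(b) {
    allowed <- b$mask == TISSUE_LABELS[[constraints$allowed_tissue]]
    dist <- EBImage::distmap(allowed)
    list(
      dist = dist,
      dist_ok = dist >= max(constraints$margin, 1L),
      band = tissue_bands(allowed, constraints$n_regions)
    )
  })
  # band assignment per patch: anterior-posterior rank of source centroid
  patch_bands <- lapply(lesion_slices, function(ls) {
    cy <- vapply(ls$patches, function(p) p$centroid[["y"]], numeric(1))
    rk <- rank(cy, ties.method = "first")
    as.integer(ceiling(rk / length(rk) * constraints$n_regions))
  })
  out <- vector("list", length(lesion_slices) * length(backgrounds))
  pair <- 0L
  for (li in seq_along(lesion_slices)) {
    ls <- lesion_slices[[li]]
    for (bi in seq_along(backgrounds)) {
      pair <- pair + 1L
      bg <- backgrounds[[bi]]
      aux <- bg_aux[[bi]]
      img <- unclass(bg$image)
      occupied <- matrix(FALSE, nrow(img), ncol(img))
      boxes <- NULL
      with_substream(derive_seed(seed, "compose", pair), {
        for (pi in seq_along(ls$patches)) {
          p <- ls$patches[[pi]]
          band <- patch_bands[[li]][pi]
          half_r <- (nrow(p$mask) - 1L) / 2
          half_c <- (ncol(p$mask) - 1L) / 2
          # radius of the mask footprint about the patch centre: centres at
          # distance >= margin + radius are guaranteed admissible, so the
          # rejection loop only ever has to resolve overlaps
          mp <- which(p$mask, arr.ind = TRUE)
          r_pat <- sqrt(max((mp[, 1L] - 1 - half_r)^2 + (mp[, 2L] - 1 - half_c)^2)) + 1.5
          in_band <- !is.na(aux$band) & aux$band == band
          cand <- which(in_band & (aux$dist >= max(constraints$margin, 1L) + r_pat))
          if (length(cand) == 0L) cand <- which(in_band & aux$dist_ok)
          if (length(cand) == 0L) {
            stop(sprintf("placement error [%s x %s]: band %d has no admissible pixels",
                         ls$id, bg$id, band), call. = FALSE)
          }
          placed <- FALSE
          for (attempt in seq_len(constraints$max_attempts)) {
            ci <- cand[sample.int(length(cand), 1L)]
            cy <- ((ci - 1L) %% nrow(img)) + 1L
            cx <- ((ci - 1L) %/% nrow(img)) + 1L
            x0 <- as.integer(round(cx - 1L - half_c))
            y0 <- as.integer(round(cy - 1L - half_r))
            res <- tryCatch(
              paste_lesion_impl(img, p, c(x0, y0), aux$dist_ok, constraints, occupied),
              error = function(e) {
                if (grepl("^placement error", conditionMessage(e))) NULL else stop(e)
              }
            )
            if (is.null(res)) next
            img <- res$image
            rows <- (y0 + 1L):(y0 + nrow(p$mask))
            cols <- (x0 + 1L):(x0 + ncol(p$mask))
            occupied[rows, cols] <- occupied[rows, cols] | p$mask
            boxes <- rbind(boxes, res$box)
            placed <- TRUE
            break
          }
          if (!placed) {
            stop(sprintf("placement error [%s x %s]: patch %d unplaceable after %d attempts",
                         ls$id, bg$id, pi, constraints$max_attempts), call. = FALSE)
          }
        }
      })
      out[[pair]] <- composite_record(
        image = if (keep_images) image_slice(img, attr(bg$image, "pixel_size_mm") %||% 0.83),
        boxes = boxes, background_id = bg$id, lesion_slice_id = ls$id
      )
    }
  }
  out
}

#' Build the two-source-case lesion fixture
#'
#' Emulates the source material for compositing: two synthetic cases whose
#' punctate lesions span 13 slices in total, carrying 19 and 17 lesions.
#' Each slice is generated, lesioned, normalized and run through
#' [extract_lesions()], so the returned lesion slices carry real extracted
#' patches, not injection records.
#'
#' @param seed Integer seed.
#' @param params [phantom_params()] for the source slices.
#' @param extraction [extraction_params()] used to harvest the patches.
#' @param case_counts Integer vector of per-case lesion totals
#'   (default `c(19, 17)`).
#' @param case_slices Integer vector of per-case slice counts summing to the
#'   emulated 13 slices (default `c(7, 6)`).
#' @return List of lesion-slice lists (`id`, `patches`, `n_injected`).
#' @export
make_source_cases <- function(seed = 1L, params = phantom_params(),
                              extraction = extraction_params(),
                              case_counts = c(19L, 17L),
                              case_slices = c(7L, 6L)) {
  stopifnot(length(case_counts) == length(case_slices))
  out <- list()
  for (ca in seq_along(case_counts)) {
    # spread the case's lesion count over its slices as evenly as possible
    k <- case_slices[ca]
    per <- rep(case_counts[ca] %/% k, k)
    extra <- case_counts[ca] %% k
    if (extra > 0L) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    for (sl in seq_len(k)) {
      sseed <- derive_seed(seed, sprintf("source-case-%d", ca), sl)
      slice <- generate_slice(params, seed = sseed)
      inj <- inject_lesions(slice$image, slice$mask,
                            lesion_spec(per[sl], diameter_px = c(3, 6)),
                            seed = sseed)
      norm <- auto_contrast(inj$image)
      id <- sprintf("case%d_slice%d", ca, sl)
      patches <- extract_lesions(norm, slice$mask, extraction, source_id = id)
      out[[length(out) + 1L]] <- list(id = id, patches = patches, n_injected = per[sl])
    }
  }
  out
}
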