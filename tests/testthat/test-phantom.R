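test_that("slice generation is deterministic and labels partition the canvas", {
  p <- small_params()
  a <- generate_slice(p, seed = 1L)
  b <- generate_slice(p, seed = 1L)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$mask, b$mask)

  counts <- table(a$mask)
  expect_setequal(as.integer(names(counts)), unname(TISSUE_LABELS))
  expect_equal(sum(counts), p$image_size^2)
  expect_gt(sum(a$mask == TISSUE_LABELS[["white_matter"]]), 0)
  expect_gt(sum(a$mask == TISSUE_LABELS[["cortex"]]), 0)

  # a different seed gives a different slice
  expect_false(identical(unclass(generate_slice(p, seed = 2L)$image),
                         unclass(a$image)))
})

test_that("label histogram agrees with an independent flood-fill oracle", {
  sl <- generate_slice(small_params(96L), seed = 2L)
  areas <- oracle_flood_areas(sl$mask)
  hist <- table(sl$mask)
  expect_equal(sort(names(areas)), sort(names(hist)))
  for (k in names(hist)) {
    expect_equal(unname(areas[k]), unname(as.integer(hist[k])))
  }
})

test_that("white matter forms a single connected region inside the cortex", {
  sl <- fix_slice(3L)
  wm <- sl$mask == TISSUE_LABELS[["white_matter"]]
  lab <- EBImage::bwlabel(wm)
  expect_equal(max(lab), 1)
  # every WM pixel is strictly interior to the brain outline
  border <- c(sl$mask[1, ], sl$mask[nrow(sl$mask), ], sl$mask[, 1], sl$mask[, ncol(sl$mask)])
  expect_true(all(border == TISSUE_LABELS[["background"]]))
})

test_that("parameter validation rejects impossible phantoms", {
  expect_error(phantom_params(image_size = 32L), "image_size")
  expect_error(phantom_params(wm_mean = 300), "means")
  expect_error(phantom_params(noise_sd = -1), "noise_sd")
  expect_error(lesion_spec(-1), "count")
  expect_error(lesion_spec(3, diameter_px = c(0.5, 20)), "diameter")
  expect_error(lesion_spec(3, contrast = 0), "contrast")
})

test_that("lesion injection returns tight in-WM boxes and conserves other pixels", {
  sl <- fix_slice(1L)

  # empty case: nothing changes
  out0 <- inject_lesions(sl$image, sl$mask, lesion_spec(0), seed = 5L)
  expect_identical(unclass(out0$image), unclass(sl$image))
  expect_equal(nrow(out0$boxes), 0)

  out <- inject_lesions(sl$image, sl$mask, lesion_spec(7), seed = 3L)
  expect_equal(nrow(out$boxes), 7)

  recs <- attr(out$boxes, "injections")
  changed <- unclass(out$image) != unclass(sl$image)
  for (i in seq_len(7)) {
    b <- out$boxes[i, ]
    # every box pixel is white matter (mask-membership oracle)
    rows <- (b$y_min + 1):b$y_max
    cols <- (b$x_min + 1):b$x_max
    expect_true(all(sl$mask[rows, cols] == TISSUE_LABELS[["white_matter"]]))
    # the box is the tight bbox of the recorded lesion mask
    r <- recs[[i]]
    expect_equal(b$x_min, min(r$mask_cols) - 1)
    expect_equal(b$x_max, max(r$mask_cols))
    expect_equal(b$y_min, min(r$mask_rows) - 1)
    expect_equal(b$y_max, max(r$mask_rows))
  }
  # conservation: all changed pixels lie inside some truncated footprint,
  # i.e. within 2*sigma of a lesion centre
  idx <- which(changed, arr.ind = TRUE)
  near <- vapply(seq_len(nrow(idx)), function(k) {
    any(vapply(recs, function(r) {
      d2 <- (idx[k, 2] - 0.5 - r$center[["x"]])^2 + (idx[k, 1] - 0.5 - r$center[["y"]])^2
      d2 <= (2 * r$sigma + 1)^2
    }, logical(1)))
  }, logical(1))
  expect_true(all(near))
})

test_that("injected lesions carry the requested contrast above surrounding WM", {
  sl <- fix_slice(4L)
  contrast <- 40
  out <- inject_lesions(sl$image, sl$mask,
                        lesion_spec(5, diameter_px = c(4, 6), contrast = contrast),
                        seed = 10L)
  recs <- attr(out$boxes, "injections")
  img <- unclass(out$image)
  base <- unclass(sl$image)
  for (r in recs) {
    inside <- img[cbind(r$mask_rows, r$mask_cols)]
    wm_before <- base[cbind(r$mask_rows, r$mask_cols)]
    expect_gte(mean(inside) - mean(wm_before), 0.5 * contrast)
  }
})

test_that("per-case lesion counts respect the sampling distribution bounds", {
  counts <- sample_lesion_counts(200L, list(min = 1, max = 19, mean = 6, sd = 5.4),
                                 seed = 42L)
  expect_true(all(counts >= 1 & counts <= 19))
  expect_gt(mean(counts), 4)
  expect_lt(mean(counts), 9)
  expect_identical(counts,
                   sample_lesion_counts(200L, list(min = 1, max = 19, mean = 6, sd = 5.4),
                                        seed = 42L))
})
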