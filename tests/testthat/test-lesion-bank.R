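test_that("a featureless slice yields no patches", {
  flat <- image_slice(matrix(100, 64, 64))
  expect_length(extract_lesions(flat, NULL, extraction_params()), 0)
  sl <- fix_slice(6L)
  expect_length(extract_lesions(auto_contrast(sl$image), sl$mask,
                                extraction_params(), "clean"), 0)
})

test_that("injected lesions are recovered with boxes overlapping injections", {
  les <- fix_lesioned(1L, n = 5L, d = c(4, 6))
  patches <- extract_lesions(les$norm, les$mask, extraction_params(), "fix1")
  expect_length(patches, 5)
  eb <- do.call(rbind, lapply(patches, function(p) p$bbox_in_source))
  iou <- box_iou(les$boxes, eb)
  expect_true(all(apply(iou, 1, max) >= 0.5))
  # patch invariants: shapes match, bbox is the tight mask bbox
  for (p in patches) {
    expect_identical(dim(p$patch), dim(p$mask))
    mb <- mask_bbox(p$mask)
    b <- p$bbox_in_source
    expect_equal(b$x_max - b$x_min, mb$x_max - mb$x_min)
    expect_equal(b$y_max - b$y_min, mb$y_max - mb$y_min)
  }
})

test_that("elongated streaks are excluded by the linearity rule", {
  # 2 x 10 streak: area 20 is inside the area window, so only the
  # elongation rule can reject it
  img <- streak_image(2L, 10L, value = 40)
  mp <- which(unclass(img) > 100, arr.ind = TRUE)
  # independent second-moments oracle
  vr <- var(mp[, 1]) * (nrow(mp) - 1) / nrow(mp) + 1 / 12
  vc <- var(mp[, 2]) * (nrow(mp) - 1) / nrow(mp) + 1 / 12
  expect_equal(sqrt(max(vr, vc) / min(vr, vc)), 5, tolerance = 1e-6)
  expect_length(extract_lesions(img, NULL, extraction_params()), 0)

  # 3 x 15 streak (also over the area cap): excluded as well
  expect_length(extract_lesions(streak_image(3L, 15L, value = 40), NULL,
                                extraction_params()), 0)

  # control: a compact 4 x 5 blob of the same contrast is kept
  kept <- extract_lesions(streak_image(4L, 5L, value = 40), NULL, extraction_params())
  expect_length(kept, 1)
})

test_that("faint foci below min_contrast are excluded", {
  img <- streak_image(3L, 3L, value = 8) # below the default min_contrast of 10
  expect_length(extract_lesions(img, NULL, extraction_params()), 0)
  img2 <- streak_image(3L, 3L, value = 30)
  expect_length(extract_lesions(img2, NULL, extraction_params()), 1)
})

test_that("extraction recovers all injected lesions exactly over random phantoms", {
  # recall and precision both 1.0, judged by injection centres falling in
  # extracted patch boxes (the appropriate criterion for punctate targets)
  for (s in 11:16) {
    les <- fix_lesioned(s, n = 6L, d = c(3, 6))
    patches <- extract_lesions(les$norm, les$mask, extraction_params(),
                               sprintf("ph%d", s))
    expect_length(patches, 6)
    eb <- do.call(rbind, lapply(patches, function(p) p$bbox_in_source))
    recs <- attr(les$boxes, "injections")
    for (r in recs) {
      expect_equal(sum(eb$x_min <= r$center[["x"]] & r$center[["x"]] <= eb$x_max &
                       eb$y_min <= r$center[["y"]] & r$center[["y"]] <= eb$y_max), 1)
    }
  }
})

test_that("masks are tight against their defining threshold", {
  les <- fix_lesioned(3L, n = 4L, d = c(4, 6))
  patches <- extract_lesions(les$norm, les$mask, extraction_params(), "tight")
  xs <- EBImage::gblur(unclass(les$norm), sigma = 0.5, boundary = "replicate")
  for (p in patches) {
    b <- p$bbox_in_source
    rows <- (b$y_min + 1):b$y_max
    cols <- (b$x_min + 1):b$x_max
    sm <- xs[rows, cols]
    # every mask pixel exceeds the recorded threshold
    expect_true(all(sm[p$mask] > p$threshold))
    # no 8-connected neighbour outside the mask exceeds it (within the crop)
    ring <- pwmltools:::dilate1(p$mask, 8L) & !p$mask
    expect_true(all(sm[ring] <= p$threshold))
  }
})

test_that("the patch bank round-trips through disk", {
  les <- fix_lesioned(5L, n = 3L, d = c(4, 6))
  patches <- extract_lesions(les$norm, les$mask, extraction_params(), "bank")
  dir <- withr::local_tempdir()
  write_bank(patches, dir)
  back <- read_bank(dir)
  expect_length(back, length(patches))
  for (i in seq_along(patches)) {
    expect_equal(unclass(back[[i]]$patch), patches[[i]]$patch, ignore_attr = TRUE)
    expect_identical(back[[i]]$mask, patches[[i]]$mask)
    expect_equal(back[[i]]$bbox_in_source[, 1:4], patches[[i]]$bbox_in_source[, 1:4])
  }
})
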