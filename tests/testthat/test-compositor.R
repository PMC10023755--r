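test_that("pasting conserves all pixels outside the patch mask", {
  sl <- fix_slice(1L)
  bg <- auto_contrast(sl$image)
  patch <- toy_patch(5L)
  # pick an interior WM location (top-left placement)
  wm <- sl$mask == TISSUE_LABELS[["white_matter"]]
  dist_wm <- EBImage::distmap(wm)
  ctr <- which(dist_wm == max(dist_wm), arr.ind = TRUE)[1, ]
  loc <- unname(c(ctr[2] - 3, ctr[1] - 3))
  out <- paste_lesion(bg, patch, loc, sl$mask, paste_constraints())
  diff <- unclass(out$image) != unclass(bg)
  # changes confined to the patch footprint
  changed <- which(diff, arr.ind = TRUE)
  expect_true(all(changed[, 1] > loc[2] & changed[, 1] <= loc[2] + 5))
  expect_true(all(changed[, 2] > loc[1] & changed[, 2] <= loc[1] + 5))
  # returned box is the pasted mask's tight bbox
  expect_equal(out$box$x_min, loc[1]); expect_equal(out$box$x_max, loc[1] + 5)
  expect_equal(out$box$y_min, loc[2]); expect_equal(out$box$y_max, loc[2] + 5)
})

test_that("pasting outside the allowed tissue raises a placement error", {
  sl <- fix_slice(1L)
  bg <- auto_contrast(sl$image)
  patch <- toy_patch(5L)
  # a location straddling the cortex ribbon
  ctx <- which(sl$mask == TISSUE_LABELS[["cortex"]], arr.ind = TRUE)
  loc <- c(ctx[1, 2] - 3, ctx[1, 1] - 3)
  expect_error(paste_lesion(bg, patch, loc, sl$mask), "placement error")
  # off-canvas
  expect_error(paste_lesion(bg, patch, c(-2, 10), sl$mask), "canvas")
})

test_that("difference-image support reproduces the returned boxes", {
  sl <- fix_slice(2L)
  bg <- auto_contrast(sl$image)
  wm <- sl$mask == TISSUE_LABELS[["white_matter"]]
  dist_wm <- EBImage::distmap(wm)
  ok <- which(dist_wm > 8, arr.ind = TRUE)
  cons <- paste_constraints(feather = FALSE)
  img <- bg
  boxes <- NULL
  for (k in c(1L, nrow(ok) %/% 2L, nrow(ok))) {
    loc <- c(ok[k, 2] - 2, ok[k, 1] - 2)
    res <- paste_lesion(img, toy_patch(4L, value = 240), loc, sl$mask, cons)
    img <- res$image
    boxes <- rbind(boxes, res$box)
  }
  diff <- unclass(img) != unclass(bg)
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    sub <- diff[(b$y_min + 1):b$y_max, (b$x_min + 1):b$x_max]
    rb <- mask_bbox(sub)
    expect_equal(rb$x_min, 0); expect_equal(rb$y_min, 0)
    expect_equal(rb$x_max, b$x_max - b$x_min)
    expect_equal(rb$y_max, b$y_max - b$y_min)
  }
})

test_that("composite corpus is the full lesion-slice x background cross product", {
  les <- lapply(1:3, function(i) {
    l <- fix_lesioned(20L + i, n = 2L, d = c(4, 6))
    list(id = sprintf("ls%d", i),
         patches = extract_lesions(l$norm, l$mask, extraction_params(),
                                   sprintf("ls%d", i)))
  })
  bgs <- lapply(1:4, function(i) {
    sl <- fix_slice(30L + i)
    list(id = sprintf("bg%d", i), image = auto_contrast(sl$image), mask = sl$mask)
  })
  recs <- build_composites(les, bgs, paste_constraints(), seed = 5L)
  expect_length(recs, 12)
  # each background id appears exactly 3 times (counting oracle)
  expect_true(all(table(vapply(recs, function(r) r$background_id, character(1))) == 3))
  # per-composite box count equals the source slice's patch count
  for (r in recs) {
    src <- les[[match(r$lesion_slice_id, vapply(les, `[[`, "", "id"))]]
    expect_equal(nrow(r$boxes), length(src$patches))
  }
  # unit case
  one <- build_composites(les[1], bgs[1], paste_constraints(), seed = 5L)
  expect_length(one, 1)
  # determinism
  recs2 <- build_composites(les, bgs, paste_constraints(), seed = 5L)
  expect_identical(lapply(recs, `[[`, "boxes"), lapply(recs2, `[[`, "boxes"))
  expect_identical(unclass(recs[[7]]$image), unclass(recs2[[7]]$image))
})

test_that("pasted lesions respect the white-matter margin", {
  les <- list(list(id = "l", patches = {
    l <- fix_lesioned(25L, n = 3L, d = c(4, 6))
    extract_lesions(l$norm, l$mask, extraction_params(), "l")
  }))
  sl <- fix_slice(26L)
  bgs <- list(list(id = "b", image = auto_contrast(sl$image), mask = sl$mask))
  cons <- paste_constraints(margin = 2L)
  recs <- build_composites(les, bgs, cons, seed = 8L)
  wm <- sl$mask == TISSUE_LABELS[["white_matter"]]
  dist_wm <- EBImage::distmap(wm)
  for (b in seq_len(nrow(recs[[1]]$boxes))) {
    bx <- recs[[1]]$boxes[b, ]
    diff <- unclass(recs[[1]]$image)[(bx$y_min + 1):bx$y_max, (bx$x_min + 1):bx$x_max] !=
      unclass(bgs[[1]]$image)[(bx$y_min + 1):bx$y_max, (bx$x_min + 1):bx$x_max]
    sub <- dist_wm[(bx$y_min + 1):bx$y_max, (bx$x_min + 1):bx$x_max]
    expect_true(all(sub[diff] >= cons$margin))
  }
})

test_that("band assignment follows the anterior-posterior source layout", {
  wm <- matrix(FALSE, 30, 30); wm[6:25, 6:25] <- TRUE
  band <- pwmltools:::tissue_bands(wm, 3L)
  expect_true(all(is.na(band[!wm])))
  expect_equal(sort(unique(band[wm])), 1:3)
  # anterior (small y) rows get band 1, posterior band 3
  expect_true(all(band[6, 6:25] == 1))
  expect_true(all(band[25, 6:25] == 3))
})

test_that("source-case fixture spans 13 slices with 19 + 17 lesions", {
  src <- memo("source_cases_small",
              make_source_cases(seed = 2L, params = small_params()))
  expect_length(src, 13)
  n_inj <- vapply(src, `[[`, integer(1), "n_injected")
  case1 <- grepl("^case1", vapply(src, `[[`, "", "id"))
  expect_equal(sum(n_inj[case1]), 19)
  expect_equal(sum(n_inj[!case1]), 17)
  # every slice contributed at least one usable patch
  expect_true(all(vapply(src, function(s) length(s$patches), integer(1)) >= 1))
})
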