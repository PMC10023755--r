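as_dets <- function(boxes, probs, id = "img") {
  data.frame(image_id = id, x_min = boxes$x_min, y_min = boxes$y_min,
             x_max = boxes$x_max, y_max = boxes$y_max,
             probability_percent = probs, stringsAsFactors = FALSE)
}

test_that("perfect detections match one-to-one; absent detections are all FN", {
  truths <- bbox(c(10, 50, 90), c(10, 50, 90), c(20, 60, 100), c(20, 60, 100))
  d <- as_dets(truths, c(90, 80, 70))
  m <- match_detections(d, truths, match_criterion())
  expect_equal(nrow(m$tp), 3); expect_equal(nrow(m$fp), 0); expect_equal(nrow(m$fn), 0)

  m0 <- match_detections(empty_detections(), truths, match_criterion())
  expect_equal(nrow(m0$fn), 3)
})

test_that("greedy matching attains the exhaustive maximum on small instances", {
  # truths are disjoint boxes, as lesion ground truth always is here
  for (s in 1:25) {
    set.seed(s)
    nt <- sample(1:3, 1); nd <- sample(1:3, 1)
    cx <- sample(seq(10, 90, by = 25), nt)
    truths <- bbox(cx, 40, cx + 8, 48)
    di <- sample(nt, nd, replace = TRUE)
    x0 <- truths$x_min[di] + sample(-6:6, nd, TRUE)
    y0 <- 40 + sample(-6:6, nd, TRUE)
    dets <- as_dets(bbox(x0, y0, x0 + 8, y0 + 8), sample(10:99, nd))
    crit <- match_criterion("iou", 0.3)
    m <- match_detections(dets, truths, crit)
    sc <- pwmltools:::match_scores(dets, truths, crit)
    expect_equal(nrow(m$tp), oracle_max_matching(sc >= 0))
    # bookkeeping identities
    expect_equal(nrow(m$tp) + nrow(m$fn), nt)
    expect_equal(nrow(m$tp) + nrow(m$fp), nd)
  }
})

test_that("threshold sweep arithmetic matches direct computation", {
  # counts as in a resident-reader style confusion: TP 119, FN 44, FP 4
  tp <- 119L; fn <- 44L; fp <- 4L
  x0 <- seq_len(tp + fn) * 20
  truths <- bbox(x0, 10, x0 + 10, 20)
  dets <- rbind(
    as_dets(truths[seq_len(tp), ], rep(80, tp)),
    as_dets(bbox(x0[seq_len(fp)], 200, x0[seq_len(fp)] + 10, 210), rep(80, fp))
  )
  et <- sweep_thresholds(dets, list(img = truths), match_criterion(), thresholds = 20)
  expect_equal(et$TP, tp); expect_equal(et$FP, fp); expect_equal(et$FN, fn)
  expect_equal(round(et$sensitivity, 3), 0.730)
  expect_equal(round(et$PPV, 3), 0.967)
})

test_that("TP is monotone non-increasing in the threshold and TP+FN is conserved", {
  les <- fix_lesioned(15L, n = 5L, d = c(4, 6), contrast = 60, size = 256L)
  d <- detect_lesions(les$norm, image_id = "t")
  et <- sweep_thresholds(d, list(t = les$boxes), match_criterion("center_in_box"))
  expect_true(all(diff(et$TP) <= 0))
  expect_true(all(et$TP + et$FN == nrow(les$boxes)))
  expect_true(all(et$sensitivity >= 0 & et$sensitivity <= 1, na.rm = TRUE))
  # degenerate: no truths at all flags sensitivity as undefined
  expect_warning(et0 <- sweep_thresholds(d, list(t = empty_boxes()), match_criterion()),
                 "undefined")
  expect_true(all(is.na(et0$sensitivity)))
})

test_that("false positives are localized by majority tissue label", {
  mask <- matrix(TISSUE_LABELS[["background"]], 40, 40)
  mask[11:30, 11:30] <- TISSUE_LABELS[["white_matter"]]
  mask[11:30, 11:14] <- TISSUE_LABELS[["cortex"]]
  expect_equal(unname(classify_fp_locations(bbox(10, 12, 13, 16), mask)["cerebral_cortex"]), 1L)
  expect_equal(unname(classify_fp_locations(bbox(20, 20, 25, 25), mask)["cerebral_white_matter"]), 1L)
  expect_equal(unname(classify_fp_locations(bbox(0, 0, 5, 5), mask)["other"]), 1L)
  # straddling box: per-pixel count oracle
  b <- bbox(12, 12, 18, 18)
  lab <- mask[13:18, 13:18]
  n_ctx <- sum(lab == TISSUE_LABELS[["cortex"]])
  n_wm <- sum(lab == TISSUE_LABELS[["white_matter"]])
  got <- classify_fp_locations(b, mask)
  want <- if (n_ctx >= n_wm) "cerebral_cortex" else "cerebral_white_matter"
  expect_equal(unname(got[want]), 1L)
  expect_error(classify_fp_locations(b, NULL), "mask")
})

test_that("Mann-Whitney matches symmetry and enumeration oracles", {
  sym <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sym$U, 4.5)
  expect_equal(sym$p_two_sided, 1)

  sep <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_two_sided, oracle_mw_p(c(1, 2), c(3, 4)))
  expect_equal(sep$p_two_sided, 1 / 3, tolerance = 1e-12)

  set.seed(11)
  x <- rnorm(6); y <- rnorm(5) + 0.5
  expect_equal(mann_whitney(x, y)$p_two_sided, oracle_mw_p(x, y), tolerance = 1e-9)
  # U_x + U_y = n1 * n2
  expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 30)
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("exact and approximate Mann-Whitney branches agree on tie-free samples", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(10); y <- rnorm(10) + runif(1, 0, 1)
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    p_approx <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lte(abs(p_exact - p_approx), 0.01)
    expect_equal(mann_whitney(x, y)$p_two_sided, p_exact)
  }
})

test_that("average precision reproduces hand-computed PR curves", {
  truths <- bbox(c(10, 50), c(10, 10), c(20, 60), c(20, 20))
  # ranked [TP, FP, TP] over 2 truths: AP = 0.5 * 1 + 0.5 * (2/3)
  dets <- as_dets(bbox(c(10, 80, 50), c(10, 80, 10), c(20, 90, 60), c(20, 90, 20)),
                  c(90, 80, 70))
  expect_equal(average_precision(dets, list(img = truths), match_criterion()),
               0.5 + 0.5 * 2 / 3, tolerance = 1e-12)
  # perfect ranking
  perfect <- as_dets(truths, c(99, 98))
  expect_equal(average_precision(perfect, list(img = truths), match_criterion()), 1)
  # no true positives
  none <- as_dets(bbox(200, 200, 210, 210), 50)
  expect_equal(average_precision(none, list(img = truths), match_criterion()), 0)
})

test_that("evaluation summaries carry exact percentage arithmetic and round-trip", {
  et <- sweep_thresholds(
    as_dets(bbox(10, 10, 20, 20), 90),
    list(img = bbox(10, 10, 20, 20)), match_criterion(), thresholds = c(20, 50)
  )
  fp_loc <- rbind(t20 = c(cerebral_cortex = 224L, cerebral_white_matter = 37L, other = 0L),
                  t50 = c(cerebral_cortex = 0L, cerebral_white_matter = 0L, other = 0L))
  dir <- withr::local_tempdir()
  res <- summarize_evaluation(et, fp_loc,
                              compare_probabilities(c(50, 60, 70), c(20, 25, 30)),
                              dir = dir)
  expect_equal(res$table2$cerebral_cortex_pct[1], 85.8)
  expect_equal(res$table2$cerebral_white_matter_pct[1], 14.2)
  expect_equal(res$table2$cerebral_cortex_pct[2], 0)
  # regenerating the report from its own CSV reproduces the values
  back <- utils::read.csv(file.path(dir, "table2.csv"))
  expect_equal(back$cerebral_cortex_pct, res$table2$cerebral_cortex_pct)
  back1 <- utils::read.csv(file.path(dir, "table1.csv"))
  expect_equal(back1$sensitivity, res$table1$sensitivity)
})
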