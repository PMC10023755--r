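#' Match criterion for detection scoring
#'
#' How a detection is judged to hit a ground-truth lesion. `"iou"` requires
#' intersection-over-union at or above `iou_threshold` (default 0.5, the
#' object-detection convention). `"center_in_box"` accepts a detection
#' whose box contains the centre of the ground-truth box -- appropriate for
#' punctate targets a few pixels across, where IoU between two honest
#' small boxes is dominated by quantization.
#'
#' @param mode `"iou"` or `"center_in_box"`.
#' @param iou_threshold IoU threshold in (0, 1], used by mode `"iou"`.
#' @return A `match_criterion` list.
#' @export
match_criterion <- function(mode = c("iou", "center_in_box"), iou_threshold = 0.5) {
  mode <- match.arg(mode)
  if (iou_threshold <= 0 || iou_threshold > 1) {
    stop("iou_threshold must lie in (0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, iou_threshold = iou_threshold),
            class = "match_criterion")
}

# detection-vs-truth score matrix; entries >= 0 count as eligible matches
match_scores <- function(dets, truths, crit) {
  if (crit$mode == "iou") {
    m <- box_iou(dets, truths)
    m[m < crit$iou_threshold] <- -1
    m
  } else {
    cx <- (truths$x_min + truths$x_max) / 2
    cy <- (truths$y_min + truths$y_max) / 2
    m <- matrix(-1, nrow(dets), nrow(truths))
    for (j in seq_len(nrow(truths))) {
      inside <- dets$x_min <= cx[j] & cx[j] <= dets$x_max &
        dets$y_min <= cy[j] & cy[j] <= dets$y_max
      # rank eligible pairs by IoU so the closest box is preferred
      m[inside, j] <- box_iou(dets[inside, , drop = FALSE],
                              truths[j, , drop = FALSE])
    }
    m
  }
}

#' Greedily match detections to ground truth
#'
#' Detections are taken in descending probability order; each claims the
#' best still-unmatched truth it is eligible for under the criterion
#' (one-to-one). The rest are false positives; unclaimed truths are false
#' negatives.
#'
#' @param dets Detection data frame for one image.
#' @param truths Ground-truth box data frame for the same image.
#' @param crit A [match_criterion()].
#' @return List with `tp` (data frame of matched pairs: `det`, `truth`
#'   row indices and `probability_percent`), `fp` (unmatched detection
#'   rows) and `fn` (unmatched truth rows).
#' @export
match_detections <- function(dets, truths, crit = match_criterion()) {
  nd <- nrow(dets); nt <- nrow(truths)
  if (nd == 0L) {
    return(list(
      tp = data.frame(det = integer(0), truth = integer(0),
                      probability_percent = numeric(0)),
      fp = dets, fn = truths
    ))
  }
  ord <- order(dets$probability_percent, decreasing = TRUE)
  matched_truth <- rep(FALSE, nt)
  tp_det <- integer(0); tp_truth <- integer(0)
  if (nt > 0L) {
    sc <- match_scores(dets, truths, crit)
    for (i in ord) {
      elig <- which(!matched_truth & sc[i, ] >= 0)
      if (length(elig) == 0L) next
      j <- elig[which.max(sc[i, elig])]
      matched_truth[j] <- TRUE
      tp_det <- c(tp_det, i); tp_truth <- c(tp_truth, j)
    }
  }
  list(
    tp = data.frame(det = tp_det, truth = tp_truth,
                    probability_percent = dets$probability_percent[tp_det]),
    fp = dets[setdiff(seq_len(nd), tp_det), , drop = FALSE],
    fn = truths[which(!matched_truth), , drop = FALSE]
  )
}

#' Threshold-swept sensitivity and PPV
#'
#' At each probability threshold only detections at or above the threshold
#' participate in matching; sensitivity is TP/(TP+FN) over ground-truth
#' lesions and PPV is TP/(TP+FP) over retained detections. TP + FN always
#' equals the number of ground-truth lesions, and TP is non-increasing in
#' the threshold. When a denominator is zero the ratio is reported as
#' `NA` (undefined) rather than forced to zero.
#'
#' @param dets Detection data frame (any number of images; matched within
#'   `image_id`).
#' @param truths Named list: per `image_id`, the ground-truth box data
#'   frame.
#' @param crit A [match_criterion()].
#' @param thresholds Probability thresholds in percent (default
#'   `c(20, 30, 40, 50)`).
#' @return An `eval_table` data frame with one row per threshold: `TP`,
#'   `FP`, `FN`, `sensitivity`, `PPV`.
#' @export
sweep_thresholds <- function(dets, truths, crit = match_criterion(),
                             thresholds = c(20, 30, 40, 50)) {
  if (anyNA(dets$probability_percent) ||
      any(dets$probability_percent < 0 | dets$probability_percent > 100)) {
    stop("probabilities must lie in [0, 100] (got ",
         paste(range(dets$probability_percent), collapse = " .. "), ")",
         call. = FALSE)
  }
  n_truth <- sum(vapply(truths, nrow, integer(1)))
  if (n_truth == 0L) warning("no ground-truth lesions: sensitivity undefined", call. = FALSE)
  rows <- lapply(thresholds, function(t) {
    kept <- dets[dets$probability_percent >= t, , drop = FALSE]
    tp <- 0L; fp <- 0L; fn <- 0L
    ids <- union(names(truths), unique(kept$image_id))
    for (id in ids) {
      d <- kept[kept$image_id == id, , drop = FALSE]
      g <- truths[[id]] %||% empty_boxes()
      m <- match_detections(d, g, crit)
      tp <- tp + nrow(m$tp); fp <- fp + nrow(m$fp); fn <- fn + nrow(m$fn)
    }
    data.frame(
      threshold = t, TP = tp, FP = fp, FN = fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_table", class(out))
  out
}

#' Classify false-positive detections by anatomical location
#'
#' Each false-positive box is assigned the majority tissue label among its
#' in-box pixels, restricted to cerebral cortex vs cerebral white matter;
#' ties go to cortex, and boxes covering neither label are counted as
#' `other`.
#'
#' @param fp_boxes Box data frame of false positives (one image).
#' @param tissue_mask Tissue label matrix aligned with that image.
#' @return Named integer vector
#'   `c(cerebral_cortex, cerebral_white_matter, other)`.
#' @export
classify_fp_locations <- function(fp_boxes, tissue_mask) {
  if (is.null(tissue_mask)) stop("tissue mask required", call. = FALSE)
  counts <- c(cerebral_cortex = 0L, cerebral_white_matter = 0L, other = 0L)
  nr <- nrow(tissue_mask); nc <- ncol(tissue_mask)
  for (i in seq_len(nrow(fp_boxes))) {
    rows <- max(1L, floor(fp_boxes$y_min[i]) + 1L):min(nr, ceiling(fp_boxes$y_max[i]))
    cols <- max(1L, floor(fp_boxes$x_min[i]) + 1L):min(nc, ceiling(fp_boxes$x_max[i]))
    lab <- tissue_mask[rows, cols]
    n_ctx <- sum(lab == TISSUE_LABELS[["cortex"]])
    n_wm <- sum(lab == TISSUE_LABELS[["white_matter"]])
    cls <- if (n_ctx == 0L && n_wm == 0L) "other" else
      if (n_ctx >= n_wm) "cerebral_cortex" else "cerebral_white_matter"
    counts[cls] <- counts[cls] + 1L
  }
  counts
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with tie-adjusted midranks: exact
#' enumeration when `n1 * n2 <= 400` and there are no ties, otherwise the
#' normal approximation with tie and continuity correction (the behaviour
#' of [stats::wilcox.test()], which this wraps). The returned `U` is the
#' statistic for the first sample, so `U_x + U_y = n1 * n2`.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U`, `p_two_sided`, `n1`, `n2` and whether the exact
#'   branch was used.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !has_ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(
    U = unname(wt$statistic), p_two_sided = wt$p.value,
    n1 = length(x), n2 = length(y), exact = exact
  )
}

#' Compare detection probabilities of true vs false positives
#'
#' Medians and interquartile ranges (linear-interpolation quantiles) of the
#' two score samples, plus the Mann-Whitney comparison.
#'
#' @param tp_probs,fp_probs Probability-percent samples.
#' @return A `probability_comparison` list.
#' @export
compare_probabilities <- function(tp_probs, fp_probs) {
  mw <- mann_whitney(tp_probs, fp_probs)
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  qt <- qs(tp_probs); qf <- qs(fp_probs)
  structure(list(
    tp_probs = tp_probs, fp_probs = fp_probs,
    tp_median = qt[2L], tp_iqr = qt[c(1L, 3L)],
    fp_median = qf[2L], fp_iqr = qf[c(1L, 3L)],
    U = mw$U, p_two_sided = mw$p_two_sided
  ), class = "probability_comparison")
}

#' Single-class average precision
#'
#' All detections are ranked by descending probability across images; each
#' is flagged TP or FP by greedy one-to-one matching within its image.
#' Precision is replaced by its running maximum to the right (the
#' precision envelope) and AP is the area under the resulting
#' precision-recall step curve over all points.
#'
#' @inheritParams sweep_thresholds
#' @return AP in `[0, 1]` (0 when there are no true positives).
#' @export
average_precision <- function(dets, truths, crit = match_criterion()) {
  n_truth <- sum(vapply(truths, nrow, integer(1)))
  if (n_truth == 0L || nrow(dets) == 0L) return(0)
  # per-image greedy matching in global rank order
  flags <- logical(0); probs <- numeric(0)
  for (id in union(names(truths), unique(dets$image_id))) {
    d <- dets[dets$image_id == id, , drop = FALSE]
    if (nrow(d) == 0L) next
    m <- match_detections(d, truths[[id]] %||% empty_boxes(), crit)
    f <- logical(nrow(d)); f[m$tp$det] <- TRUE
    flags <- c(flags, f); probs <- c(probs, d$probability_percent)
  }
  ord <- order(probs, decreasing = TRUE)
  tp_cum <- cumsum(flags[ord])
  fp_cum <- cumsum(!flags[ord])
  recall <- tp_cum / n_truth
  precision <- tp_cum / (tp_cum + fp_cum)
  # precision envelope, then area over recall increments
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Summarize an evaluation run
#'
#' Produces the two standard report tables: per-threshold sensitivity/PPV
#' (with TP/FP/FN counts) and false-positive location counts with
#' percentages, plus the true-vs-false-positive probability comparison.
#' Percentages are shown to one decimal (so cortex/white-matter counts of
#' 224 and 37 print as 85.8 and 14.2). Optionally writes
#' `table1.csv`, `table2.csv` and `stats.json` to a directory.
#'
#' @param eval_table Output of [sweep_thresholds()].
#' @param fp_locations Named counts from [classify_fp_locations()], or a
#'   matrix with one row per threshold.
#' @param prob_comparison Optional [compare_probabilities()] result.
#' @param dir Optional output directory.
#' @return List with `table1` and `table2` data frames (and `stats` when a
#'   probability comparison is given).
#' @export
summarize_evaluation <- function(eval_table, fp_locations = NULL,
                                 prob_comparison = NULL, dir = NULL) {
  table1 <- data.frame(
    threshold = eval_table$threshold,
    TP = eval_table$TP, FP = eval_table$FP, FN = eval_table$FN,
    sensitivity = round(eval_table$sensitivity, 3),
    PPV = round(eval_table$PPV, 3)
  )
  table2 <- NULL
  if (!is.null(fp_locations)) {
    if (is.null(dim(fp_locations))) fp_locations <- t(as.matrix(fp_locations))
    loc <- fp_locations[, c("cerebral_cortex", "cerebral_white_matter"), drop = FALSE]
    tot <- rowSums(loc)
    pct <- function(k) ifelse(tot > 0, round(100 * k / tot, 1), 0)
    table2 <- data.frame(
      cerebral_cortex = loc[, 1L],
      cerebral_cortex_pct = pct(loc[, 1L]),
      cerebral_white_matter = loc[, 2L],
      cerebral_white_matter_pct = pct(loc[, 2L])
    )
  }
  stats <- if (!is.null(prob_comparison)) {
    list(
      tp_median = prob_comparison$tp_median, tp_iqr = prob_comparison$tp_iqr,
      fp_median = prob_comparison$fp_median, fp_iqr = prob_comparison$fp_iqr,
      U = prob_comparison$U, p_two_sided = prob_comparison$p_two_sided
    )
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table1, file.path(dir, "table1.csv"), row.names = FALSE)
    if (!is.null(table2)) {
      utils::write.csv(table2, file.path(dir, "table2.csv"), row.names = FALSE)
    }
    if (!is.null(stats)) {
      jsonlite::write_json(stats, file.path(dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  out <- list(table1 = table1, table2 = table2)
  if (!is.null(stats)) out$stats <- stats
  out
}
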