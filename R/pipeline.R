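#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline: phantom generation,
#' normalization, lesion extraction, compositing, subset sampling,
#' augmentation, train/validation split, detection on a held-out test set,
#' and evaluation. Defaults reproduce the canonical study conditions: 72
#' normal background slices, two source cases carrying 19 and 17 lesions
#' over 13 slices (hence 936 composites), pre-augmentation set sizes 100 /
#' 200 / 400 / 600, an 80/20 split, and detection-probability thresholds
#' of 20/30/40/50 percent. Evaluation runs on a held-out group of test
#' cases that are never composited, mirroring the assessment-on-unseen-
#' patients protocol; test-case lesion counts default to the held-out
#' group's distribution (1--17, mean 5.1, SD 4.7).
#'
#' @param seed Global integer seed; every stage derives a named substream
#'   from it.
#' @param out_root Optional output directory; when given, images,
#'   annotations and the manifest are written there.
#' @param n_normal Number of normal background slices (default 72).
#' @param case_counts,case_slices Source-case lesion totals and slice
#'   counts (defaults `c(19, 17)` over `c(7, 6)` slices).
#' @param set_sizes Pre-augmentation subset sizes (default
#'   `c(100, 200, 400, 600)`; each must not exceed the composite count).
#' @param train_frac Training fraction for the split (default 0.8).
#' @param n_test Held-out test cases for detection scoring (default 32).
#' @param test_count_distribution Lesion-count model for test cases.
#' @param thresholds Detection-probability thresholds in percent.
#' @param match_mode,iou_threshold Matching rule for scoring (default
#'   `"center_in_box"`, the appropriate rule for punctate targets; see
#'   [match_criterion()]).
#' @param phantom,extraction,constraints,detector,augmentation Stage
#'   parameter objects; defaults are the package defaults.
#' @param keep_images Retain images in memory through compose/augment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_root = NULL,
                            n_normal = 72L,
                            case_counts = c(19L, 17L), case_slices = c(7L, 6L),
                            set_sizes = c(100L, 200L, 400L, 600L),
                            train_frac = 0.8,
                            n_test = 32L,
                            test_count_distribution = list(min = 1, max = 17, mean = 5.1, sd = 4.7),
                            thresholds = c(20, 30, 40, 50),
                            match_mode = "center_in_box", iou_threshold = 0.5,
                            phantom = phantom_params(),
                            extraction = extraction_params(),
                            constraints = paste_constraints(),
                            detector = detector_params(),
                            augmentation = augmentation_spec(),
                            keep_images = TRUE) {
  n_composites <- sum(case_slices) * n_normal
  if (any(set_sizes <= 0) || any(set_sizes > n_composites)) {
    stop("parameter error: set_sizes must be positive and <= the composite count (",
         n_composites, ")", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), out_root = out_root, n_normal = as.integer(n_normal),
    case_counts = case_counts, case_slices = case_slices,
    set_sizes = as.integer(set_sizes), train_frac = train_frac,
    n_test = as.integer(n_test), test_count_distribution = test_count_distribution,
    thresholds = thresholds, match_mode = match_mode, iou_threshold = iou_threshold,
    phantom = phantom, extraction = extraction, constraints = constraints,
    detector = detector, augmentation = augmentation, keep_images = keep_images
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the nested
#' `phantom`, `extraction`, `constraints` and `detector` blocks map to the
#' corresponding parameter constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (block in c("phantom", "extraction", "constraints", "detector")) {
    if (!is.null(y[[block]])) {
      ctor <- switch(block, phantom = phantom_params, extraction = extraction_params,
                     constraints = paste_constraints, detector = detector_params)
      y[[block]] <- do.call(ctor, y[[block]])
    }
  }
  do.call(pipeline_config, y)
}

#' Draw named subsets of the composite corpus
#'
#' Each requested size is drawn without replacement, independently per
#' size, deterministically under the seed.
#'
#' @param composites List of [composite_record()]s.
#' @param set_sizes Integer sizes (each `<= length(composites)`).
#' @param seed Integer seed.
#' @return Named list (`set<k>`) of composite-record lists.
#' @export
subsample_sets <- function(composites, set_sizes, seed = 1L) {
  if (any(set_sizes > length(composites))) {
    stop("parameter error: subset size exceeds number of composites", call. = FALSE)
  }
  out <- lapply(seq_along(set_sizes), function(i) {
    k <- set_sizes[i]
    idx <- with_substream(derive_seed(seed, "subsample", i),
                          sample.int(length(composites), k))
    composites[idx]
  })
  names(out) <- paste0("set", set_sizes)
  out
}

# 31-bit fold hash of a configuration, for the run manifest
config_hash <- function(config) {
  txt <- yaml::as.yaml(lapply(unclass(config), function(v) {
    if (is.list(v)) unclass(v) else v
  }))
  sprintf("%08x", derive_seed(0L, txt))
}

#' Run the full pipeline
#'
#' Executes the stages in order -- background phantoms, normalization,
#' source-case lesion extraction, compositing, subset sampling,
#' augmentation, train/validation split, held-out test-set generation,
#' detection, evaluation -- and returns a run manifest with per-stage
#' counts, the seed and a configuration hash. Re-running with the same
#' configuration reproduces the outputs bit for bit. With
#' `config$out_root` set, composite and augmented images are written as
#' PNG with Pascal VOC XML annotations, along with `manifest.csv`,
#' detection JSON and the report CSVs.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest (list), invisibly containing `evaluation`
#'   (report tables), `sets` (per-set counts) and `counts`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  crit <- match_criterion(config$match_mode, config$iou_threshold)

  backgrounds <- lapply(seq_len(config$n_normal), function(i) {
    sl <- generate_slice(config$phantom, seed = derive_seed(seed, "background", i))
    list(id = sprintf("normal_%03d", i), image = auto_contrast(sl$image), mask = sl$mask)
  })
  lesion_slices <- make_source_cases(seed, config$phantom, config$extraction,
                                     config$case_counts, config$case_slices)
  n_patches <- vapply(lesion_slices, function(ls) length(ls$patches), integer(1))
  composites <- build_composites(lesion_slices, backgrounds, config$constraints,
                                 seed = seed, keep_images = config$keep_images)
  sets <- subsample_sets(composites, config$set_sizes, seed)

  canvas <- c(config$phantom$image_size, config$phantom$image_size)
  set_info <- lapply(names(sets), function(nm) {
    aug <- augment_set(sets[[nm]], config$augmentation,
                       keep_images = config$keep_images, size = canvas)
    ids <- vapply(aug, function(r) r$id, character(1))
    sp <- split_dataset(ids, config$train_frac, derive_seed(seed, "split", match(nm, names(sets))))
    list(name = nm, n_subset = length(sets[[nm]]), n_augmented = length(aug),
         n_train = length(sp$train_ids), n_val = length(sp$val_ids),
         augmented = aug, split = sp)
  })
  names(set_info) <- names(sets)

  # held-out test group: lesioned phantoms never seen by the compositor
  test_counts <- sample_lesion_counts(config$n_test, config$test_count_distribution,
                                      seed = derive_seed(seed, "test-counts"))
  dets <- NULL; truths <- list(); test_masks <- list()
  for (i in seq_len(config$n_test)) {
    sseed <- derive_seed(seed, "test-case", i)
    sl <- generate_slice(config$phantom, seed = sseed)
    inj <- inject_lesions(sl$image, sl$mask, lesion_spec(test_counts[i], diameter_px = c(3, 6)),
                          seed = sseed)
    id <- sprintf("test_%03d", i)
    norm <- auto_contrast(inj$image)
    truths[[id]] <- inj$boxes
    test_masks[[id]] <- sl$mask
    dets <- rbind(dets, detect_lesions(norm, config$detector, image_id = id))
  }

  eval_table <- sweep_thresholds(dets, truths, crit, config$thresholds)
  fp_loc <- t(vapply(config$thresholds, function(t) {
    kept <- dets[dets$probability_percent >= t, , drop = FALSE]
    counts <- c(cerebral_cortex = 0L, cerebral_white_matter = 0L, other = 0L)
    for (id in names(truths)) {
      d <- kept[kept$image_id == id, , drop = FALSE]
      m <- match_detections(d, truths[[id]], crit)
      counts <- counts + classify_fp_locations(m$fp, test_masks[[id]])
    }
    counts
  }, integer(3)))
  rownames(fp_loc) <- paste0("t", config$thresholds)

  # TP vs FP probability comparison at the lowest (most inclusive) threshold
  t0 <- min(config$thresholds)
  kept <- dets[dets$probability_percent >= t0, , drop = FALSE]
  tp_probs <- numeric(0); fp_probs <- numeric(0)
  for (id in names(truths)) {
    m <- match_detections(kept[kept$image_id == id, , drop = FALSE], truths[[id]], crit)
    tp_probs <- c(tp_probs, m$tp$probability_percent)
    fp_probs <- c(fp_probs, m$fp$probability_percent)
  }
  prob_cmp <- if (length(tp_probs) > 0 && length(fp_probs) > 0) {
    compare_probabilities(tp_probs, fp_probs)
  }
  ap <- average_precision(dets, truths, crit)
  report <- summarize_evaluation(eval_table, fp_loc, prob_cmp,
                                 dir = if (!is.null(config$out_root)) {
                                   file.path(config$out_root, "report")
                                 })

  manifest <- list(
    seed = seed,
    config_hash = config_hash(config),
    counts = list(
      n_backgrounds = length(backgrounds),
      n_lesion_slices = length(lesion_slices),
      n_patches = sum(n_patches),
      n_composites = length(composites),
      n_test_cases = config$n_test,
      n_test_lesions = sum(vapply(truths, nrow, integer(1))),
      n_detections = nrow(dets)
    ),
    sets = lapply(set_info, function(s) s[c("name", "n_subset", "n_augmented",
                                            "n_train", "n_val")]),
    average_precision = ap,
    evaluation = report
  )

  if (!is.null(config$out_root)) {
    write_pipeline_outputs(config, composites, set_info, dets, manifest)
  }
  invisible(manifest)
}

# side-effect stage: materialize images, annotations and the manifest
write_pipeline_outputs <- function(config, composites, set_info, dets, manifest) {
  root <- config$out_root
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  if (config$keep_images) {
    img_dir <- file.path(root, "composites")
    dir.create(img_dir, showWarnings = FALSE)
    for (rec in composites) {
      base <- file.path(img_dir, rec$id)
      write_slice_png(rec$image, paste0(base, ".png"))
      write_voc(rec$boxes, image_size(rec$image), paste0(base, ".xml"),
                filename = paste0(rec$id, ".png"))
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$id, role = "composite", background_id = rec$background_id,
        lesion_slice_id = rec$lesion_slice_id, transform = rec$transform_tag,
        n_boxes = nrow(rec$boxes), stringsAsFactors = FALSE
      )
    }
    for (s in set_info) {
      set_dir <- file.path(root, s$name)
      dir.create(set_dir, showWarnings = FALSE)
      for (rec in s$augmented) {
        base <- file.path(set_dir, rec$id)
        write_slice_png(rec$image, paste0(base, ".png"))
        write_voc(rec$boxes, image_size(rec$image), paste0(base, ".xml"),
                  filename = paste0(rec$id, ".png"))
      }
    }
  }
  write_detections(dets, file.path(root, "detections.json"))
  if (length(rows) > 0L) {
    utils::write.csv(do.call(rbind, rows), file.path(root, "manifest.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    manifest[c("seed", "config_hash", "counts", "sets", "average_precision")],
    file.path(root, "manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(root)
}
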