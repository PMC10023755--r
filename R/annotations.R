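#' Write / read Pascal VOC XML annotations
#'
#' The VOC dialect written by the labelImg annotation tool stores 1-based,
#' closed integer pixel corners. The package's internal convention is
#' 0-based half-open, so the conversion is `xmin_voc = x_min + 1`,
#' `xmax_voc = x_max` (same for y), which round-trips exactly for integer
#' boxes.
#'
#' @param boxes Box data frame ([bbox()]).
#' @param size Image `c(width, height)` in pixels.
#' @param path Output XML path.
#' @param filename Image filename recorded in the annotation.
#' @return `write_voc` returns `path` invisibly; `read_voc` returns a list
#'   with `boxes`, `size` and `filename`.
#' @export
write_voc <- function(boxes, size, path, filename = basename(path)) {
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", filename)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(as.integer(size[1L])))
  xml2::xml_add_child(sz, "height", as.character(as.integer(size[2L])))
  xml2::xml_add_child(sz, "depth", "1")
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(boxes))) {
    ob <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(ob, "name", boxes$label[i])
    xml2::xml_add_child(ob, "pose", "Unspecified")
    xml2::xml_add_child(ob, "truncated", "0")
    xml2::xml_add_child(ob, "difficult", "0")
    bb <- xml2::xml_add_child(ob, "bndbox")
    xml2::xml_add_child(bb, "xmin", as.character(as.integer(boxes$x_min[i] + 1)))
    xml2::xml_add_child(bb, "ymin", as.character(as.integer(boxes$y_min[i] + 1)))
    xml2::xml_add_child(bb, "xmax", as.character(as.integer(boxes$x_max[i])))
    xml2::xml_add_child(bb, "ymax", as.character(as.integer(boxes$y_max[i])))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_voc
#' @export
read_voc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("format error: malformed XML in ", path, call. = FALSE)
  })
  sz <- xml2::xml_find_first(doc, "./size")
  if (inherits(sz, "xml_missing")) {
    stop("format error: missing <size> element in ", path, call. = FALSE)
  }
  size <- c(
    as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./width"))),
    as.integer(xml2::xml_text(xml2::xml_find_first(sz, "./height")))
  )
  objs <- xml2::xml_find_all(doc, "./object")
  boxes <- if (length(objs) == 0L) empty_boxes() else {
    num <- function(o, tag) as.numeric(xml2::xml_text(xml2::xml_find_first(o, paste0("./bndbox/", tag))))
    do.call(rbind, lapply(objs, function(o) {
      bbox(
        x_min = num(o, "xmin") - 1, y_min = num(o, "ymin") - 1,
        x_max = num(o, "xmax"), y_max = num(o, "ymax"),
        label = xml2::xml_text(xml2::xml_find_first(o, "./name"))
      )
    }))
  }
  list(
    boxes = boxes, size = size,
    filename = xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  )
}

#' Write / read YOLO darknet annotations
#'
#' One line per box: `class x_center y_center width height`, all
#' coordinates normalized to `[0, 1]` and printed with six decimals, so a
#' round trip recovers integer boxes to well within one pixel at a 256-px
#' canvas.
#'
#' @param boxes Box data frame.
#' @param size Image `c(width, height)`.
#' @param path Output txt path.
#' @param class_map Named integer vector mapping label to class id
#'   (default `c(PWML = 0)`).
#' @return `write_yolo` returns `path` invisibly; `read_yolo` a box data
#'   frame.
#' @export
write_yolo <- function(boxes, size, path, class_map = c(PWML = 0L)) {
  w <- size[1L]; h <- size[2L]
  lines <- character(0)
  if (nrow(boxes) > 0L) {
    xc <- (boxes$x_min + boxes$x_max) / 2 / w
    yc <- (boxes$y_min + boxes$y_max) / 2 / h
    bw <- (boxes$x_max - boxes$x_min) / w
    bh <- (boxes$y_max - boxes$y_min) / h
    if (any(c(xc, yc, bw, bh) < 0) || any(c(xc, yc, bw, bh) > 1)) {
      stop("format error: normalized coordinates outside [0, 1]", call. = FALSE)
    }
    cls <- class_map[boxes$label]
    if (any(is.na(cls))) stop("format error: label missing from class_map", call. = FALSE)
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", cls, xc, yc, bw, bh)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_yolo
#' @export
read_yolo <- function(path, size, class_map = c(PWML = 0L)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_boxes())
  w <- size[1L]; h <- size[2L]
  parts <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  if (ncol(parts) != 5L) stop("format error: expected 5 fields per line", call. = FALSE)
  if (any(parts[, 2:5] < 0) || any(parts[, 2:5] > 1)) {
    stop("format error: normalized values outside [0, 1]", call. = FALSE)
  }
  lab <- names(class_map)[match(parts[, 1L], class_map)]
  bbox(
    x_min = parts[, 2L] * w - parts[, 4L] * w / 2,
    y_min = parts[, 3L] * h - parts[, 5L] * h / 2,
    x_max = parts[, 2L] * w + parts[, 4L] * w / 2,
    y_max = parts[, 3L] * h + parts[, 5L] * h / 2,
    label = ifelse(is.na(lab), "unknown", lab)
  )
}

#' Split identifiers into training and validation sets
#'
#' Deterministic shuffle under `seed`; the training set takes the first
#' `floor(train_frac * N)` shuffled ids (so 936 ids at the default 80%
#' fraction split 748/188).
#'
#' @param ids Character or integer identifier vector (`N >= 2`).
#' @param train_frac Training fraction in (0, 1), default 0.8.
#' @param seed Integer seed.
#' @return A `dataset_split` list with `train_ids`, `val_ids`,
#'   `train_frac`, `seed`.
#' @export
split_dataset <- function(ids, train_frac = 0.8, seed = 1L) {
  if (length(ids) < 2L) stop("need at least 2 ids", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("parameter error: train_frac must lie in (0, 1)", call. = FALSE)
  }
  shuffled <- with_substream(derive_seed(seed, "split"), sample(ids))
  n_train <- floor(train_frac * length(ids))
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[setdiff(seq_along(ids), seq_len(n_train))],
    train_frac = train_frac, seed = seed
  ), class = "dataset_split")
}

#' Write / read detection JSON
#'
#' The interchange schema for detector output, from any source:
#' `[{"image_id": str, "box": [x_min, y_min, x_max, y_max],
#' "probability_percent": float}]` with probabilities in percent
#' (`[0, 100]`) and boxes in the internal 0-based half-open convention.
#'
#' @param dets Detection data frame with columns `image_id`, `x_min`,
#'   `y_min`, `x_max`, `y_max`, `probability_percent`.
#' @param path JSON path.
#' @return `write_detections` returns `path` invisibly; `read_detections`
#'   the validated detection data frame.
#' @export
write_detections <- function(dets, path) {
  validate_detections(dets)
  recs <- lapply(seq_len(nrow(dets)), function(i) {
    list(
      image_id = dets$image_id[i],
      box = c(dets$x_min[i], dets$y_min[i], dets$x_max[i], dets$y_max[i]),
      probability_percent = dets$probability_percent[i]
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0L) return(empty_detections())
  dets <- do.call(rbind, lapply(recs, function(r) {
    if (is.null(r$box) || length(r$box) != 4L) {
      stop("format error: detection box must have 4 numbers", call. = FALSE)
    }
    b <- as.numeric(r$box)
    data.frame(
      image_id = as.character(r$image_id),
      x_min = b[1L], y_min = b[2L], x_max = b[3L], y_max = b[4L],
      probability_percent = as.numeric(r$probability_percent),
      stringsAsFactors = FALSE
    )
  }))
  validate_detections(dets)
  dets
}

#' @rdname write_detections
#' @export
empty_detections <- function() {
  data.frame(
    image_id = character(0), x_min = numeric(0), y_min = numeric(0),
    x_max = numeric(0), y_max = numeric(0),
    probability_percent = numeric(0), stringsAsFactors = FALSE
  )
}

validate_detections <- function(dets) {
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "probability_percent")
  if (!all(need %in% names(dets))) {
    stop("format error: detection table missing columns", call. = FALSE)
  }
  if (any(dets$probability_percent < 0 | dets$probability_percent > 100)) {
    stop("format error: probability_percent outside [0, 100]", call. = FALSE)
  }
  if (any(dets$x_min >= dets$x_max | dets$y_min >= dets$y_max)) {
    stop("format error: degenerate detection box", call. = FALSE)
  }
  invisible(dets)
}
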