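#' Read YOLO-format label files
#'
#' Parses the plain-text annotation dialect used by box-labelling tools: one
#' object per line, \code{class cx cy w h}, with center/size coordinates
#' normalized to \code{[0, 1]}. Records are converted to corner-format pixel
#' boxes and returned as [detections()] with \code{conf = 1} (labels are
#' ground truth). Blank lines are skipped; anything else malformed is an
#' error naming the file and line.
#'
#' @param path Label file path.
#' @param image_size Length-2 vector \code{c(width, height)} in pixels.
#' @param class_map Named integer vector mapping \code{stem}/\code{bunch} to
#'   class ids.
#' @return A [detections()] data frame.
#' @export
read_yolo_labels <- function(path, image_size = c(2448, 2048),
                             class_map = c(stem = 0, bunch = 1)) {
  stopifnot(length(image_size) == 2L, all(image_size > 0))
  .chk_class_map(class_map)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != 5L) {
      stop(sprintf("%s:%d: expected 5 fields (class cx cy w h), got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("%s:%d: non-numeric field in '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    if (any(vals[2:5] < 0 | vals[2:5] > 1)) {
      stop(sprintf("%s:%d: normalized coordinate outside [0, 1]", path, i),
           call. = FALSE)
    }
    lab <- names(class_map)[match(vals[1], class_map)]
    if (is.na(lab)) {
      stop(sprintf("%s:%d: class id %g not in class map", path, i, vals[1]),
           call. = FALSE)
    }
    cx <- vals[2] * image_size[1]; cy <- vals[3] * image_size[2]
    w <- vals[4] * image_size[1]; h <- vals[5] * image_size[2]
    data.frame(x1 = cx - w / 2, y1 = cy - h / 2,
               x2 = cx + w / 2, y2 = cy + h / 2,
               conf = 1, label = lab)
  })
  if (!length(rows)) return(detections())
  validate_detections(do.call(rbind, rows))
}

#' Write YOLO-format labels
#'
#' Inverse of [read_yolo_labels()]: corner-format pixel boxes are converted
#' back to normalized center format and written one object per line, with
#' 6-decimal coordinates so a write/read round trip is exact to 1e-6 of the
#' frame.
#'
#' @param dets A [detections()] data frame.
#' @param path Output path.
#' @param image_size Length-2 vector \code{c(width, height)}.
#' @param class_map Named integer vector mapping labels to class ids.
#' @return The path, invisibly.
#' @export
write_yolo_labels <- function(dets, path, image_size = c(2448, 2048),
                              class_map = c(stem = 0, bunch = 1)) {
  dets <- validate_detections(dets)
  .chk_class_map(class_map)
  ids <- unname(class_map[dets$label])
  cx <- (dets$x1 + dets$x2) / 2 / image_size[1]
  cy <- (dets$y1 + dets$y2) / 2 / image_size[2]
  w <- (dets$x2 - dets$x1) / image_size[1]
  h <- (dets$y2 - dets$y1) / image_size[2]
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f", ids, cx, cy, w, h), path)
  invisible(path)
}

#' Read corner-format detection records
#'
#' Reads the detector's output contract — one record per predicted box,
#' \code{x1 y1 x2 y2 conf class} — from whitespace-separated text (trailing
#' \code{#} comments ignored) or a JSON array of 6-element rows. Confidences
#' outside \code{[0, 1]}, degenerate boxes and unknown class ids are
#' rejected with the offending file and line.
#'
#' @param path Input path.
#' @param class_map Named integer vector mapping labels to class ids.
#' @param format \code{"text"}, \code{"json"}, or \code{"auto"} (by file
#'   extension).
#' @return A [detections()] data frame.
#' @export
read_detections <- function(path, class_map = c(stem = 0, bunch = 1),
                            format = c("auto", "text", "json")) {
  format <- match.arg(format)
  .chk_class_map(class_map)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "text"
  }
  if (format == "json") {
    m <- jsonlite::fromJSON(path)
    if (length(m) == 0L) return(detections())
    m <- rbind(m)  # a single record parses as a vector
    if (ncol(m) != 6L) {
      stop(path, ": each JSON record needs 6 numbers ",
           "(x1 y1 x2 y2 conf class)", call. = FALSE)
    }
    return(.decode_det_matrix(m, class_map, path,
                              line_no = seq_len(nrow(m))))
  }
  lines <- readLines(path)
  lines_clean <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines_clean)))
  if (!length(keep)) return(detections())
  rows <- matrix(NA_real_, nrow = length(keep), ncol = 6L)
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(trimws(lines_clean[i]), "\\s+")[[1]]
    if (length(fields) != 6L) {
      stop(sprintf("%s:%d: expected 6 fields (x1 y1 x2 y2 conf class), got %d",
                   path, i, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop(sprintf("%s:%d: non-numeric field in '%s'", path, i, lines[i]),
           call. = FALSE)
    }
    rows[j, ] <- vals
  }
  .decode_det_matrix(rows, class_map, path, line_no = keep)
}

.decode_det_matrix <- function(m, class_map, path, line_no) {
  bad_conf <- which(m[, 5L] < 0 | m[, 5L] > 1)
  if (length(bad_conf)) {
    stop(sprintf("%s:%d: confidence %g outside [0, 1]",
                 path, line_no[bad_conf[1L]], m[bad_conf[1L], 5L]),
         call. = FALSE)
  }
  lab <- names(class_map)[match(m[, 6L], class_map)]
  bad_cls <- which(is.na(lab))
  if (length(bad_cls)) {
    stop(sprintf("%s:%d: class id %g not in class map",
                 path, line_no[bad_cls[1L]], m[bad_cls[1L], 6L]),
         call. = FALSE)
  }
  bad_box <- which(m[, 3L] <= m[, 1L] | m[, 4L] <= m[, 2L])
  if (length(bad_box)) {
    stop(sprintf("%s:%d: degenerate box", path, line_no[bad_box[1L]]),
         call. = FALSE)
  }
  detections(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], lab)
}

#' Write corner-format detection records
#'
#' One whitespace-separated record per line, \code{x1 y1 x2 y2 conf class},
#' with 6-decimal coordinates. Round-trips with [read_detections()].
#'
#' @param dets A [detections()] data frame.
#' @param path Output path.
#' @param class_map Named integer vector mapping labels to class ids.
#' @return The path, invisibly.
#' @export
write_detections <- function(dets, path, class_map = c(stem = 0, bunch = 1)) {
  dets <- validate_detections(dets)
  .chk_class_map(class_map)
  ids <- unname(class_map[dets$label])
  writeLines(sprintf("%.6f %.6f %.6f %.6f %.6f %d",
                     dets$x1, dets$y1, dets$x2, dets$y2, dets$conf, ids),
             path)
  invisible(path)
}

.chk_class_map <- function(class_map) {
  if (is.null(names(class_map)) ||
      !setequal(names(class_map), c("stem", "bunch")) ||
      anyDuplicated(class_map)) {
    stop("class_map must map exactly 'stem' and 'bunch' to distinct ids",
         call. = FALSE)
  }
  invisible(class_map)
}

#' Run configuration
#'
#' Loads (or constructs) the full run configuration: the loosening
#' parameters (\code{lambda = 8}, \code{conf_threshold = 0.30} — the
#' deployed operating point), class-id mapping, matcher threshold, frame
#' size, loss selection, and the sweep grid. Unknown keys and out-of-range
#' values are rejected.
#'
#' @param lambda,conf_threshold,multi_overlap_rule See [loosening_config()].
#' @param class_map Named vector mapping \code{stem}/\code{bunch} to ids.
#' @param iou_match_threshold Matcher IoU cutoff in \code{(0, 1]}.
#' @param image_width,image_height Frame size, pixels.
#' @param loss Loss name from [bbox_loss_names()].
#' @param loss_gamma,loss_momentum WIoU v2 focusing/EMA parameters.
#' @param fusion_eps Fast-normalized-fusion stabilizer.
#' @param sweep_thresholds Ascending confidence grid for sweeps.
#' @param seed Integer RNG seed.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(lambda = 8, conf_threshold = 0.30,
                       multi_overlap_rule = "max_intersection",
                       class_map = c(stem = 0, bunch = 1),
                       iou_match_threshold = 0.5,
                       image_width = 2448, image_height = 2048,
                       loss = "wiou_v2", loss_gamma = 1,
                       loss_momentum = 0.01, fusion_eps = 1e-4,
                       sweep_thresholds = seq(0.25, 0.45, by = 0.05),
                       seed = 1) {
  loosening <- loosening_config(lambda, conf_threshold, multi_overlap_rule)
  .chk_class_map(class_map)
  stopifnot(iou_match_threshold > 0, iou_match_threshold <= 1,
            image_width > 0, image_height > 0,
            loss %in% bbox_loss_names(),
            loss_gamma >= 0, loss_momentum > 0, loss_momentum <= 1,
            fusion_eps >= 0,
            is.numeric(sweep_thresholds), !is.unsorted(sweep_thresholds),
            all(sweep_thresholds >= 0), all(sweep_thresholds <= 1))
  structure(list(
    lambda = loosening$lambda,
    conf_threshold = loosening$conf_threshold,
    multi_overlap_rule = loosening$multi_overlap_rule,
    class_map = class_map,
    iou_match_threshold = iou_match_threshold,
    image_width = image_width, image_height = image_height,
    loss = loss, loss_gamma = loss_gamma, loss_momentum = loss_momentum,
    fusion_eps = fusion_eps,
    sweep_thresholds = sweep_thresholds,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path A YAML (or JSON) configuration file; keys override the
#'   defaults above. An empty file yields all defaults.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(path, ": unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(vals$class_map)) vals$class_map <- unlist(vals$class_map)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @export
as_loosening_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  loosening_config(config$lambda, config$conf_threshold,
                   config$multi_overlap_rule)
}

#' Reference deployment results
#'
#' Bundled plain-text records from the reference conveyor-belt deployment of
#' the stem/bunch detector feeding this algorithm, used as worked-example
#' inputs and as fixed inputs for reproducing the headline numbers.
#'
#' \code{field_sweep_counts()} returns the bunch-level confusion counts
#' observed at five detector confidence cutoffs (columns
#' \code{conf_threshold, tp, tn, fp, fn}; positive class = unqualified).
#'
#' \code{field_bunch_records()} returns the per-bunch record at the 0.30
#' operating point: columns \code{bunch} (id), \code{status}
#' (\code{matched} — detected bunch paired with a real one; \code{spurious}
#' — detected bunch with no real counterpart; \code{missed} — real bunch
#' the detector did not report), \code{actual} and \code{predicted} verdicts
#' (\code{NA} where the status makes one side implicit).
#'
#' @return A data frame.
#' @examples
#' sweep_metrics(field_sweep_counts())
#' @export
field_sweep_counts <- function() {
  utils::read.delim(
    system.file("extdata", "field_sweep_counts.tsv", package = "loosenrate",
                mustWork = TRUE),
    stringsAsFactors = FALSE)
}

#' @rdname field_sweep_counts
#' @export
field_bunch_records <- function() {
  utils::read.delim(
    system.file("extdata", "field_bunch_records.tsv", package = "loosenrate",
                mustWork = TRUE),
    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Tally the bundled per-bunch records
#'
#' Convenience wrapper feeding [field_bunch_records()] through
#' [tally_bunches()]: matched rows use their recorded verdict pair, spurious
#' rows their predicted verdict, missed rows their actual verdict.
#'
#' @param records A data frame in the [field_bunch_records()] layout.
#' @return A [confusion_counts()].
#' @export
tally_bunch_records <- function(records = field_bunch_records()) {
  matched <- records[records$status == "matched", , drop = FALSE]
  tally_bunches(
    predicted = matched$predicted,
    truth = matched$actual,
    spurious_predicted =
      records$predicted[records$status == "spurious"],
    missed_truth = records$actual[records$status == "missed"]
  )
}
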