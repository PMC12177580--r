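#' Detection records
#'
#' A set of detector outputs for one image, as a data frame with one row per
#' predicted box: corner coordinates \code{x1, y1, x2, y2} (pixels), a
#' confidence \code{conf} in \code{[0, 1]}, and a class \code{label} —
#' \code{"stem"} for a single visible tobacco stem, \code{"bunch"} for a
#' region of overlapping stems (a bundle not yet loosened apart).
#'
#' @param x1,y1,x2,y2 Numeric vectors of box corners (top-left, bottom-right).
#' @param conf Confidences in \code{[0, 1]}.
#' @param label Character vector of class labels, each \code{"stem"} or
#'   \code{"bunch"}.
#' @return A data frame of class \code{"detections"}.
#' @examples
#' detections(0, 0, 10, 10, conf = 0.9, label = "stem")
#' @export
detections <- function(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                       y2 = numeric(), conf = numeric(),
                       label = character()) {
  d <- data.frame(x1 = as.numeric(x1), y1 = as.numeric(y1),
                  x2 = as.numeric(x2), y2 = as.numeric(y2),
                  conf = as.numeric(conf), label = as.character(label),
                  stringsAsFactors = FALSE)
  validate_detections(d)
}

#' @rdname detections
#' @param d A detections data frame (any data frame with the six columns).
#' @export
validate_detections <- function(d) {
  need <- c("x1", "y1", "x2", "y2", "conf", "label")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop("detections are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(d)) {
    bad <- which(d$x2 <= d$x1 | d$y2 <= d$y1 |
                   !is.finite(d$x1) | !is.finite(d$y1) |
                   !is.finite(d$x2) | !is.finite(d$y2))
    if (length(bad)) {
      stop("degenerate detection box at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(d$conf) | d$conf < 0 | d$conf > 1)) {
      stop("detection confidence must lie in [0, 1]", call. = FALSE)
    }
    if (!all(d$label %in% c("stem", "bunch"))) {
      stop("detection label must be 'stem' or 'bunch'", call. = FALSE)
    }
  }
  class(d) <- unique(c("detections", class(d)))
  d
}

.det_boxes <- function(d) as.matrix(d[, c("x1", "y1", "x2", "y2")])

#' Loosening-rate configuration
#'
#' Parameters of the loosening-rate algorithm. \code{lambda} is the
#' operator-set maximum number of stems a qualified bunch may contain; a
#' bunch with \code{x >= lambda} member stems is unqualified. Detections
#' below \code{conf_threshold} are discarded before association. When a stem
#' box overlaps several bunch boxes, \code{multi_overlap_rule} decides where
#' it counts: \code{"max_intersection"} assigns it to the bunch it overlaps
#' most (ties to the lowest bunch index), \code{"all"} counts it in every
#' overlapped bunch.
#'
#' @param lambda Positive integer, default 8.
#' @param conf_threshold Confidence cutoff in \code{[0, 1]}, default 0.30
#'   (the operating point selected by the confidence sweep).
#' @param multi_overlap_rule \code{"max_intersection"} (default) or
#'   \code{"all"}.
#' @return A list of class \code{"loosening_config"}.
#' @export
loosening_config <- function(lambda = 8, conf_threshold = 0.30,
                             multi_overlap_rule = c("max_intersection",
                                                    "all")) {
  multi_overlap_rule <- match.arg(multi_overlap_rule)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 1 ||
      lambda != round(lambda)) {
    stop("lambda must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(conf_threshold) || length(conf_threshold) != 1L ||
      conf_threshold < 0 || conf_threshold > 1) {
    stop("conf_threshold must lie in [0, 1]", call. = FALSE)
  }
  structure(list(lambda = as.integer(lambda),
                 conf_threshold = as.numeric(conf_threshold),
                 multi_overlap_rule = multi_overlap_rule),
            class = "loosening_config")
}

#' Filter detections by confidence
#'
#' Keeps exactly the detections with \code{conf >= threshold}, preserving
#' order. The boundary survives: sweeping the detector's confidence cutoff is
#' how the operating point is chosen, and a detection sitting exactly at the
#' cutoff is kept.
#'
#' @param dets A [detections()] data frame.
#' @param threshold Cutoff in \code{[0, 1]}.
#' @return The surviving detections.
#' @export
filter_by_confidence <- function(dets, threshold) {
  dets <- validate_detections(dets)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  dets[dets$conf >= threshold, , drop = FALSE]
}

#' Count member stems per bunch
#'
#' Associates each stem detection with the bunch boxes it overlaps (strictly
#' positive intersection area; edge contact does not count) and returns the
#' member-stem count \code{x} for every bunch. A stem overlapping no bunch
#' contributes nowhere; a bunch overlapped by no stem gets \code{x = 0}.
#' Under \code{rule = "max_intersection"} a stem overlapping several bunches
#' is counted once, in the bunch it overlaps most (ties broken toward the
#' lowest bunch index); under \code{rule = "all"} it is counted in each.
#'
#' @param stems Detections labelled \code{"stem"}.
#' @param bunches Detections labelled \code{"bunch"}.
#' @param rule \code{"max_intersection"} or \code{"all"}.
#' @return Integer vector of length \code{nrow(bunches)}: member-stem counts.
#' @export
assign_stems_to_bunches <- function(stems, bunches,
                                    rule = c("max_intersection", "all")) {
  rule <- match.arg(rule)
  stems <- validate_detections(stems)
  bunches <- validate_detections(bunches)
  n_b <- nrow(bunches)
  if (n_b == 0L) return(integer(0))
  x <- integer(n_b)
  if (nrow(stems) == 0L) return(x)
  inter <- pairwise_intersection(.det_boxes(stems), .det_boxes(bunches))
  if (rule == "all") {
    return(as.integer(colSums(inter > 0)))
  }
  for (s in seq_len(nrow(stems))) {
    row <- inter[s, ]
    if (any(row > 0)) {
      # which.max returns the first (lowest-index) maximizer: the tie-break.
      b <- which.max(row)
      x[b] <- x[b] + 1L
    }
  }
  x
}

#' Loosening rate of a bunch
#'
#' \code{R = lambda / x * 100} percent, where \code{x} is the number of stem
#' detections counted inside the bunch and \code{lambda} the operator-set
#' maximum. A rate above 100% means the bunch holds fewer than \code{lambda}
#' stems — well loosened; at or below 100% the loosening is poor. Undefined
#' (returns \code{NA}) when \code{x = 0}.
#'
#' @param x Non-negative integer stem count (vectorized).
#' @param lambda Positive integer maximum.
#' @return Rate in percent, \code{NA} where \code{x = 0}.
#' @examples
#' loosening_rate(c(4, 8, 16), lambda = 8) # 200 100 50
#' @export
loosening_rate <- function(x, lambda = 8) {
  stopifnot(is.numeric(x), all(x >= 0), all(x == round(x)),
            is.numeric(lambda), length(lambda) == 1L, lambda >= 1)
  ifelse(x >= 1, 100 * lambda / x, NA_real_)
}

#' Classify a bunch as qualified or unqualified
#'
#' A bunch with fewer than \code{lambda} member stems is qualified; one with
#' \code{lambda} or more is unqualified (equivalently, qualified iff the
#' loosening rate exceeds 100%). A bunch with \code{x = 0} — a detector can
#' emit a bunch box whose member stems it failed to resolve — is treated as
#' qualified, with a warning rather than an error.
#'
#' @param x Non-negative integer stem count (vectorized).
#' @param lambda Positive integer maximum.
#' @param warn Warn on \code{x = 0} bunches (default TRUE).
#' @return Character vector, \code{"qualified"} or \code{"unqualified"}.
#' @export
classify_bunch <- function(x, lambda = 8, warn = TRUE) {
  stopifnot(is.numeric(x), all(x >= 0), all(x == round(x)),
            is.numeric(lambda), length(lambda) == 1L, lambda >= 1)
  if (warn && any(x == 0)) {
    warning(sum(x == 0), " bunch(es) with no overlapping stem detections; ",
            "classified qualified", call. = FALSE)
  }
  ifelse(x < lambda, "qualified", "unqualified")
}

#' Assess a detection scene
#'
#' The end-to-end loosening-rate pipeline for one image: filter detections by
#' confidence, split stems from bunches, count member stems per bunch,
#' compute each bunch's loosening rate and verdict. Deterministic for fixed
#' input. A scene whose filtered detections contain no bunch returns a
#' zero-row result (downstream: nothing to flag, fully qualified).
#'
#' @param dets A [detections()] data frame (one image's detector output).
#' @param config A [loosening_config()].
#' @return A data frame of class \code{"bunch_assessments"}, one row per
#'   surviving bunch detection: the bunch box and confidence, member-stem
#'   count \code{x}, \code{rate} in percent (\code{NA} when \code{x = 0}),
#'   and \code{verdict}.
#' @examples
#' dets <- rbind(
#'   detections(0, 0, 100, 100, 0.9, "bunch"),
#'   detections(10 * 0:8, 10, 10 * 0:8 + 8, 30, rep(0.9, 9), rep("stem", 9))
#' )
#' assess_scene(dets, loosening_config(lambda = 8))
#' @export
assess_scene <- function(dets, config = loosening_config()) {
  stopifnot(inherits(config, "loosening_config"))
  dets <- validate_detections(dets)
  kept <- filter_by_confidence(dets, config$conf_threshold)
  stems <- kept[kept$label == "stem", , drop = FALSE]
  bunches <- kept[kept$label == "bunch", , drop = FALSE]
  x <- assign_stems_to_bunches(stems, bunches,
                               rule = config$multi_overlap_rule)
  out <- data.frame(
    x1 = bunches$x1, y1 = bunches$y1, x2 = bunches$x2, y2 = bunches$y2,
    conf = bunches$conf,
    x = x,
    rate = loosening_rate(x, config$lambda),
    verdict = classify_bunch(x, config$lambda, warn = FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- unique(c("bunch_assessments", class(out)))
  out
}
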