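#' Axis-aligned bounding box
#'
#' Constructs a box from its top-left corner \code{(x1, y1)} and bottom-right
#' corner \code{(x2, y2)} in continuous pixel coordinates (origin at the image
#' top-left, x rightward, y downward). Boxes must have strictly positive area.
#'
#' @param x1,y1 Top-left corner coordinates.
#' @param x2,y2 Bottom-right corner coordinates; must satisfy \code{x2 > x1}
#'   and \code{y2 > y1}.
#' @return A named numeric vector of class \code{"box"} with elements
#'   \code{x1, y1, x2, y2}.
#' @examples
#' b <- box(0, 0, 10, 5)
#' box_area(b)
#' @export
box <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_box(b)
  class(b) <- "box"
  b
}

#' Validate a box
#'
#' Checks that a numeric vector is a valid axis-aligned box: four finite
#' coordinates with strictly positive width and height. Degenerate
#' (zero/negative area) boxes are rejected everywhere in the package.
#'
#' @param b A box or numeric vector \code{c(x1, y1, x2, y2)}.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_box <- function(b) {
  if (!is.numeric(b) || length(b) != 4L) {
    stop("a box must be a numeric vector of length 4 (x1, y1, x2, y2)",
         call. = FALSE)
  }
  if (any(!is.finite(b))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  if (b[[3L]] <= b[[1L]] || b[[4L]] <= b[[2L]]) {
    stop(sprintf(
      "degenerate box: need x2 > x1 and y2 > y1, got (%g, %g, %g, %g)",
      b[[1L]], b[[2L]], b[[3L]], b[[4L]]), call. = FALSE)
  }
  invisible(b)
}

#' @rdname box
#' @param b A valid box.
#' @export
box_area <- function(b) {
  validate_box(b)
  (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
}

#' @rdname box
#' @export
box_width <- function(b) {
  validate_box(b)
  b[[3L]] - b[[1L]]
}

#' @rdname box
#' @export
box_height <- function(b) {
  validate_box(b)
  b[[4L]] - b[[2L]]
}

#' @rdname box
#' @export
box_center <- function(b) {
  validate_box(b)
  c(x = (b[[1L]] + b[[3L]]) / 2, y = (b[[2L]] + b[[4L]]) / 2)
}

#' Intersection area of two boxes
#'
#' Overlap area of two axis-aligned boxes. Edge contact (shared boundary with
#' zero-area overlap) counts as no overlap: the result is 0.
#'
#' @param a,b Valid boxes.
#' @return Non-negative scalar area.
#' @examples
#' intersection_area(box(0, 0, 2, 2), box(1, 0, 3, 2)) # 2
#' @export
intersection_area <- function(a, b) {
  validate_box(a)
  validate_box(b)
  iw <- min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]])
  ih <- min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]])
  if (iw <= 0 || ih <= 0) return(0)
  iw * ih
}

#' Intersection over union of two boxes
#'
#' \code{|a intersect b| / |a union b|}, the overlap measure underlying every
#' regression loss in the package and the detection matcher. Symmetric in its
#' arguments; 0 for disjoint interiors, 1 for identical boxes.
#'
#' @param a,b Valid boxes.
#' @return Ratio in \code{[0, 1]}.
#' @examples
#' iou(box(0, 0, 2, 2), box(1, 0, 3, 2)) # 1/3
#' @export
iou <- function(a, b) {
  inter <- intersection_area(a, b)
  inter / (box_area(a) + box_area(b) - inter)
}

#' Smallest enclosing box
#'
#' The smallest axis-aligned box containing both inputs (coordinate-wise
#' min of the top-left corners, max of the bottom-right corners). Its diagonal
#' is the normalizer of the center-distance penalty in DIoU/CIoU, and its
#' width/height normalize the WIoU distance penalty.
#'
#' @param a,b Valid boxes.
#' @return A box containing both inputs.
#' @export
enclosing_box <- function(a, b) {
  validate_box(a)
  validate_box(b)
  box(min(a[[1L]], b[[1L]]), min(a[[2L]], b[[2L]]),
      max(a[[3L]], b[[3L]]), max(a[[4L]], b[[4L]]))
}

#' Squared distance between box centers
#'
#' Squared Euclidean distance between the centers of two boxes (the rho^2 term
#' of the DIoU/CIoU penalties). 0 exactly when the centers coincide.
#'
#' @param a,b Valid boxes.
#' @return Non-negative scalar, squared pixels.
#' @export
center_distance_sq <- function(a, b) {
  ca <- box_center(a)
  cb <- box_center(b)
  sum((ca - cb)^2)
}

# Pairwise intersection areas between two sets of boxes, given as n x 4
# matrices of corner coordinates. Returns an n_a x n_b matrix. Used by the
# association step and the matcher; vectorized so randomized-scene oracles
# stay cheap.
pairwise_intersection <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(matrix(0, nrow = nrow(a), ncol = nrow(b)))
  }
  iw <- outer(a[, 3L], b[, 3L], pmin) - outer(a[, 1L], b[, 1L], pmax)
  ih <- outer(a[, 4L], b[, 4L], pmin) - outer(a[, 2L], b[, 2L], pmax)
  pmax(iw, 0) * pmax(ih, 0)
}

pairwise_iou <- function(a, b) {
  inter <- pairwise_intersection(a, b)
  if (length(inter) == 0L) return(inter)
  area_a <- (a[, 3L] - a[, 1L]) * (a[, 4L] - a[, 2L])
  area_b <- (b[, 3L] - b[, 1L]) * (b[, 4L] - b[, 2L])
  inter / (outer(area_a, area_b, `+`) - inter)
}
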