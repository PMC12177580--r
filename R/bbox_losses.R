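#' Bounding-box regression losses
#'
#' Scalar IoU-family regression losses for a single (predicted, ground-truth)
#' box pair. These are the losses single-stage detectors minimize when
#' regressing anchor boxes onto annotated objects; here they are exposed as
#' pure functions so their arithmetic can be verified independently of any
#' training loop. Batching and reduction over anchors are the caller's
#' concern.
#'
#' \describe{
#'   \item{CIoU}{\code{1 - IoU + rho^2/c^2 + alpha * v}, where \code{rho^2} is
#'     the squared center distance, \code{c} the diagonal of the smallest
#'     enclosing box, \code{v = (4/pi^2) (atan(w_gt/h_gt) - atan(w/h))^2}
#'     measures aspect-ratio mismatch and \code{alpha = v / ((1 - IoU) + v)}.
#'     When the pair is a perfect match (\code{IoU = 1}, \code{v = 0}) the
#'     \code{alpha * v} term is taken as 0 (the 0/0 limit).}
#'   \item{WIoU v1}{\code{R_WIoU * L_IoU} with \code{L_IoU = 1 - IoU} and
#'     \code{R_WIoU = exp(((x - x_gt)^2 + (y - y_gt)^2) / (W_g^2 + H_g^2))},
#'     centers \code{(x, y)}, enclosing-box width/height \code{W_g, H_g}. The
#'     denominator is treated as a constant under differentiation; a scalar
#'     library has no gradients, so it is reported among the components
#'     (\code{wg2_hg2}) for an autodiff consumer to detach.}
#'   \item{WIoU v2}{\code{(L_IoU / mean(L_IoU))^gamma * L_WIoUv1}: a monotonic
#'     focusing multiplier that down-weights easy pairs (small \code{L_IoU})
#'     relative to a running mean of \code{L_IoU}, so hard, occluded objects
#'     dominate the loss. See [wiou_state()].}
#' }
#'
#' @param pred,gt Valid boxes (predicted and ground truth).
#' @return A [loss_result()]: the loss value plus named intermediate
#'   components for inspection.
#' @examples
#' ciou_loss(box(2, 2, 4, 4), box(0, 0, 2, 2))$value # 1.25
#' wiou_v1_loss(box(2, 2, 4, 4), box(0, 0, 2, 2))$value # exp(1/4)
#' @name bbox_losses
NULL

#' Loss result container
#'
#' A non-negative scalar loss value together with the named intermediate
#' quantities (IoU, penalty terms, focusing coefficient, ...) that produced
#' it, so tests and users can inspect the arithmetic.
#'
#' @param value Non-negative scalar loss.
#' @param components Named list of intermediate quantities.
#' @return An object of class \code{"loss_result"} with elements
#'   \code{value} and \code{components}.
#' @export
loss_result <- function(value, components = list()) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(list(value = as.numeric(value), components = components),
            class = "loss_result")
}

#' @export
print.loss_result <- function(x, ...) {
  cat(sprintf("<loss_result> value = %.6g\n", x$value))
  if (length(x$components)) {
    comp <- vapply(x$components, function(v) sprintf("%.6g", v), character(1))
    cat(paste0("  ", names(comp), " = ", comp, collapse = "\n"), "\n")
  }
  invisible(x)
}

# Shared geometric ingredients of the IoU-family penalties.
.loss_geometry <- function(pred, gt) {
  validate_box(pred)
  validate_box(gt)
  enc <- enclosing_box(pred, gt)
  list(
    iou = iou(pred, gt),
    rho2 = center_distance_sq(pred, gt),
    wg = box_width(enc), hg = box_height(enc),
    enc_area = box_area(enc),
    w = box_width(pred), h = box_height(pred),
    wgt = box_width(gt), hgt = box_height(gt)
  )
}

#' @rdname bbox_losses
#' @export
ciou_loss <- function(pred, gt) {
  g <- .loss_geometry(pred, gt)
  c2 <- g$wg^2 + g$hg^2
  v <- (4 / pi^2) * (atan(g$wgt / g$hgt) - atan(g$w / g$h))^2
  # 0/0 guard: at a perfect match both v and 1 - IoU vanish and the alpha*v
  # term has limit 0.
  denom <- (1 - g$iou) + v
  alpha <- if (denom == 0) 0 else v / denom
  value <- 1 - g$iou + g$rho2 / c2 + alpha * v
  loss_result(value, list(
    iou = g$iou, rho2 = g$rho2, c2 = c2, v = v, alpha = alpha,
    r_ciou = g$rho2 / c2 + alpha * v
  ))
}

#' @rdname bbox_losses
#' @export
wiou_v1_loss <- function(pred, gt) {
  g <- .loss_geometry(pred, gt)
  l_iou <- 1 - g$iou
  wg2_hg2 <- g$wg^2 + g$hg^2
  r_wiou <- exp(g$rho2 / wg2_hg2)
  loss_result(r_wiou * l_iou, list(
    iou = g$iou, l_iou = l_iou, rho2 = g$rho2,
    wg2_hg2 = wg2_hg2, r_wiou = r_wiou
  ))
}

#' Running state for the WIoU v2 focusing mechanism
#'
#' WIoU v2 scales the v1 loss by \code{(L_IoU / mean)^gamma}, where
#' \code{mean} is an exponential moving average of \code{L_IoU} over the pairs
#' observed so far. The mean starts at 1 (the neutral multiplier for the first
#' observation under \code{gamma = 1} when \code{L_IoU = 1}) and is updated
#' \emph{after} each loss evaluation: \code{mean <- (1 - momentum) * mean +
#' momentum * L_IoU}. Neither \code{gamma} nor the momentum is pinned down by
#' the loss's definition; both are configuration.
#'
#' @param gamma Focusing exponent, \code{>= 0}. Default 1.
#' @param momentum EMA update weight in \code{(0, 1]}. Default 0.01.
#' @param mean Initial running mean of \code{L_IoU}. Default 1.
#' @return An object of class \code{"wiou_state"}.
#' @export
wiou_state <- function(gamma = 1, momentum = 0.01, mean = 1) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma >= 0,
            is.numeric(momentum), length(momentum) == 1L,
            momentum > 0, momentum <= 1,
            is.numeric(mean), length(mean) == 1L, mean >= 0)
  structure(list(gamma = gamma, momentum = momentum, mean = mean),
            class = "wiou_state")
}

# Floor on the running mean: the focusing ratio is undefined at mean 0.
.WIOU_MEAN_FLOOR <- 1e-8

#' @rdname bbox_losses
#' @param state A [wiou_state()]. The focusing multiplier uses the mean as it
#'   stood \emph{before} this pair; the updated state is returned in the
#'   result's \code{$state}.
#' @export
wiou_v2_loss <- function(pred, gt, state = wiou_state()) {
  stopifnot(inherits(state, "wiou_state"))
  v1 <- wiou_v1_loss(pred, gt)
  l_iou <- v1$components$l_iou
  mean_pre <- max(state$mean, .WIOU_MEAN_FLOOR)
  focus <- (l_iou / mean_pre)^state$gamma
  new_state <- wiou_state(
    gamma = state$gamma, momentum = state$momentum,
    mean = (1 - state$momentum) * state$mean + state$momentum * l_iou
  )
  out <- loss_result(focus * v1$value, c(
    v1$components,
    list(focus = focus, mean_pre_update = mean_pre, l_wiou_v1 = v1$value)
  ))
  out$state <- new_state
  out
}

# ---- comparator losses -----------------------------------------------------

.giou_loss <- function(pred, gt) {
  g <- .loss_geometry(pred, gt)
  union_area <- box_area(pred) + box_area(gt) - intersection_area(pred, gt)
  giou <- g$iou - (g$enc_area - union_area) / g$enc_area
  loss_result(1 - giou, list(iou = g$iou, giou = giou, enc_area = g$enc_area))
}

.diou_loss <- function(pred, gt) {
  g <- .loss_geometry(pred, gt)
  c2 <- g$wg^2 + g$hg^2
  loss_result(1 - g$iou + g$rho2 / c2,
              list(iou = g$iou, rho2 = g$rho2, c2 = c2))
}

.eiou_loss <- function(pred, gt) {
  g <- .loss_geometry(pred, gt)
  c2 <- g$wg^2 + g$hg^2
  value <- 1 - g$iou + g$rho2 / c2 +
    (g$w - g$wgt)^2 / g$wg^2 + (g$h - g$hgt)^2 / g$hg^2
  loss_result(value, list(
    iou = g$iou, rho2 = g$rho2, c2 = c2,
    w_term = (g$w - g$wgt)^2 / g$wg^2, h_term = (g$h - g$hgt)^2 / g$hg^2
  ))
}

.focal_eiou_loss <- function(pred, gt, focal_gamma = 0.5) {
  e <- .eiou_loss(pred, gt)
  g_iou <- e$components$iou
  loss_result(g_iou^focal_gamma * e$value,
              c(e$components, list(focal = g_iou^focal_gamma)))
}

.loss_registry <- new.env(parent = emptyenv())

#' Bounding-box loss registry
#'
#' Losses are addressable by name so a configuration file can select one
#' (\code{loss: wiou_v2}). The registry ships with \code{ciou},
#' \code{wiou_v1}, \code{wiou_v2}, \code{giou}, \code{diou}, \code{eiou} and
#' \code{focal_eiou}, and is extensible via [register_bbox_loss()].
#'
#' @param name Loss name (character scalar).
#' @param pred,gt Valid boxes.
#' @param ... Passed to the underlying loss (e.g. \code{state} for
#'   \code{wiou_v2}).
#' @return A [loss_result()].
#' @examples
#' bbox_loss("diou", box(2, 2, 4, 4), box(0, 0, 2, 2))$value # 1.25
#' @export
bbox_loss <- function(name, pred, gt, ...) {
  stopifnot(is.character(name), length(name) == 1L)
  fn <- .loss_registry[[name]]
  if (is.null(fn)) {
    stop(sprintf("unknown bounding-box loss '%s'; available: %s",
                 name, paste(sort(ls(.loss_registry)), collapse = ", ")),
         call. = FALSE)
  }
  fn(pred, gt, ...)
}

#' @rdname bbox_loss
#' @param fn A function \code{(pred, gt, ...) -> loss_result}.
#' @export
register_bbox_loss <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .loss_registry)
  invisible(name)
}

#' @rdname bbox_loss
#' @export
bbox_loss_names <- function() sort(ls(.loss_registry))

register_bbox_loss("ciou", ciou_loss)
register_bbox_loss("wiou_v1", wiou_v1_loss)
register_bbox_loss("wiou_v2", wiou_v2_loss)
register_bbox_loss("giou", .giou_loss)
register_bbox_loss("diou", .diou_loss)
register_bbox_loss("eiou", .eiou_loss)
register_bbox_loss("focal_eiou", .focal_eiou_loss)
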