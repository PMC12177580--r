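#' Bunch-level confusion counts
#'
#' Confusion counts for the binary bunch verdict. The positive class is the
#' \emph{unqualified} bunch: the algorithm exists to flag poorly loosened
#' bundles, so a true positive is an unqualified bunch correctly flagged.
#' (This inverts the intuitive "positive = good" reading.)
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A list of class \code{"confusion_counts"}.
#' @export
confusion_counts <- function(tp = 0, tn = 0, fp = 0, fn = 0) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts) | counts < 0 | counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_counts")
}

.as_counts <- function(counts) {
  if (inherits(counts, "confusion_counts")) return(counts)
  do.call(confusion_counts, as.list(counts))
}

#' Precision, recall and F1
#'
#' \code{precision = TP/(TP+FP)}, \code{recall = TP/(TP+FN)},
#' \code{f1 = 2PR/(P+R)} — the harmonic mean of precision and recall. A zero
#' denominator yields 0 by convention (no positive predictions, no positive
#' truths).
#'
#' @param counts A [confusion_counts()] (or a list/vector with elements
#'   \code{tp, tn, fp, fn}).
#' @return A scalar in \code{[0, 1]}.
#' @examples
#' f1_score(confusion_counts(tp = 23, tn = 8, fp = 6, fn = 3)) # 0.836...
#' @export
precision <- function(counts) {
  counts <- .as_counts(counts)
  .safe_ratio(counts$tp, counts$tp + counts$fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  counts <- .as_counts(counts)
  .safe_ratio(counts$tp, counts$tp + counts$fn)
}

#' @rdname precision
#' @export
f1_score <- function(counts) {
  p <- precision(counts)
  r <- recall(counts)
  .safe_ratio(2 * p * r, p + r)
}

.safe_ratio <- function(num, den) if (den == 0) 0 else num / den

#' Accuracy breakdown
#'
#' Overall accuracy \code{(TP+TN)/total} plus the per-predicted-class
#' accuracies: among bunches predicted unqualified, the fraction truly
#' unqualified (\code{TP/(TP+FP)}); among bunches predicted qualified, the
#' fraction truly qualified (\code{TN/(TN+FN)}). Zero denominators yield 0.
#'
#' @param counts A [confusion_counts()].
#' @return Named numeric vector \code{overall},
#'   \code{predicted_unqualified}, \code{predicted_qualified}.
#' @examples
#' accuracy_breakdown(confusion_counts(tp = 23, tn = 8, fp = 6, fn = 3))
#' @export
accuracy_breakdown <- function(counts) {
  counts <- .as_counts(counts)
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  c(overall = .safe_ratio(counts$tp + counts$tn, total),
    predicted_unqualified = .safe_ratio(counts$tp, counts$tp + counts$fp),
    predicted_qualified = .safe_ratio(counts$tn, counts$tn + counts$fn))
}

#' Tally bunch verdicts into confusion counts
#'
#' Compares per-bunch predicted verdicts against ground truth and tallies the
#' bunch-level confusion matrix, with \emph{unqualified} as the positive
#' class. \code{predicted} and \code{truth} are aligned vectors for the
#' matched bunches. Detected bunches with no ground-truth counterpart
#' (spurious) are tallied against an implicit \emph{qualified} truth; missed
#' ground-truth bunches are tallied as implicitly predicted \emph{qualified}.
#' Thus a spurious bunch flagged unqualified costs a false positive, and a
#' missed unqualified bunch costs a false negative.
#'
#' @param predicted,truth Character vectors (\code{"qualified"} /
#'   \code{"unqualified"}) of equal length: verdicts for matched bunches.
#' @param spurious_predicted Verdicts of detected bunches with no
#'   ground-truth match.
#' @param missed_truth True verdicts of ground-truth bunches with no
#'   detection.
#' @return A [confusion_counts()].
#' @export
tally_bunches <- function(predicted, truth,
                          spurious_predicted = character(),
                          missed_truth = character()) {
  stopifnot(length(predicted) == length(truth))
  .chk_verdict <- function(v, what) {
    if (!all(v %in% c("qualified", "unqualified"))) {
      stop(what, " verdicts must be 'qualified' or 'unqualified'",
           call. = FALSE)
    }
    v
  }
  pred <- c(.chk_verdict(predicted, "predicted"),
            .chk_verdict(spurious_predicted, "spurious"),
            rep("qualified", length(missed_truth)))
  act <- c(.chk_verdict(truth, "truth"),
           rep("qualified", length(spurious_predicted)),
           .chk_verdict(missed_truth, "missed"))
  pos <- "unqualified"
  confusion_counts(
    tp = sum(pred == pos & act == pos),
    tn = sum(pred != pos & act != pos),
    fp = sum(pred == pos & act != pos),
    fn = sum(pred != pos & act == pos)
  )
}

#' Greedy IoU matching of detections to ground truth
#'
#' Standard one-to-one detection matching: detections are visited in
#' descending confidence order and each is matched to the unmatched
#' ground-truth box of the same class with the highest IoU, provided that IoU
#' reaches \code{iou_threshold}. Used both for average precision and for
#' aligning detected bunches with ground-truth bunches before tallying.
#'
#' @param dets,truth [detections()] data frames (truth confidences are
#'   ignored).
#' @param iou_threshold Minimum IoU for a match, default 0.5.
#' @return A list: \code{matches} (data frame with columns \code{det},
#'   \code{truth}, \code{iou} — row indices into the inputs),
#'   \code{unmatched_det} and \code{unmatched_truth} (integer index vectors).
#' @export
match_detections <- function(dets, truth, iou_threshold = 0.5) {
  dets <- validate_detections(dets)
  truth <- validate_detections(truth)
  n_d <- nrow(dets); n_t <- nrow(truth)
  matched_t <- logical(n_t)
  res <- list(det = integer(), truth = integer(), iou = numeric())
  if (n_d > 0L && n_t > 0L) {
    ious <- pairwise_iou(.det_boxes(dets), .det_boxes(truth))
    same_class <- outer(dets$label, truth$label, `==`)
    ious[!same_class] <- -Inf
    order_d <- order(-dets$conf)
    for (d in order_d) {
      cand <- ious[d, ]
      cand[matched_t] <- -Inf
      best <- which.max(cand)
      if (is.finite(cand[best]) && cand[best] >= iou_threshold) {
        matched_t[best] <- TRUE
        res$det <- c(res$det, d)
        res$truth <- c(res$truth, best)
        res$iou <- c(res$iou, cand[best])
      }
    }
  }
  list(
    matches = data.frame(det = res$det, truth = res$truth, iou = res$iou),
    unmatched_det = setdiff(seq_len(n_d), res$det),
    unmatched_truth = which(!matched_t)
  )
}

#' Average precision and mean average precision
#'
#' \code{average_precision()} computes the area under the
#' precision–recall curve for one class using all-point interpolation: the
#' precision envelope (running maximum of precision at recall at least r) is
#' integrated over the recall increments of the confidence-ranked detection
#' list. \code{mean_ap()} averages per-class AP values.
#'
#' @param dets Detections of a single class.
#' @param truth Ground-truth boxes of the same class.
#' @param iou_threshold Matching threshold, default 0.5.
#' @return \code{average_precision()}: scalar AP in \code{[0, 1]};
#'   \code{pr_curve()}: data frame of ranked \code{(recall, precision)}
#'   points.
#' @export
average_precision <- function(dets, truth, iou_threshold = 0.5) {
  curve <- pr_curve(dets, truth, iou_threshold)
  if (nrow(curve) == 0L) return(0)
  # All-point interpolation: integrate the precision envelope over recall.
  rec <- c(0, curve$recall)
  prec_env <- rev(cummax(rev(curve$precision)))
  sum(diff(rec) * prec_env)
}

#' @rdname average_precision
#' @export
pr_curve <- function(dets, truth, iou_threshold = 0.5) {
  dets <- validate_detections(dets)
  truth <- validate_detections(truth)
  n_t <- nrow(truth)
  if (nrow(dets) == 0L || n_t == 0L) {
    return(data.frame(recall = numeric(), precision = numeric()))
  }
  m <- match_detections(dets, truth, iou_threshold)
  hit <- seq_len(nrow(dets)) %in% m$matches$det
  ord <- order(-dets$conf)
  tp_cum <- cumsum(hit[ord])
  fp_cum <- cumsum(!hit[ord])
  data.frame(recall = tp_cum / n_t, precision = tp_cum / (tp_cum + fp_cum))
}

#' @rdname average_precision
#' @param per_class_ap Numeric vector of per-class AP values.
#' @export
mean_ap <- function(per_class_ap) {
  stopifnot(is.numeric(per_class_ap), length(per_class_ap) >= 1L)
  mean(per_class_ap)
}

#' Confidence-threshold sweep
#'
#' Runs the full loosening-rate pipeline at each candidate confidence cutoff
#' and tallies bunch-level confusion counts against ground truth, pooling
#' over scenes. For each threshold, each scene's detections are assessed
#' ([assess_scene()]) at that cutoff, detected bunches are aligned with
#' ground-truth bunches by greedy IoU matching, verdicts are tallied
#' ([tally_bunches()]) and the metrics recomputed. The F1-maximizing row is
#' the operating point.
#'
#' @param dets A [detections()] data frame or a list of them (one per scene).
#' @param truth Matching ground-truth scene(s): detections with \code{conf =
#'   1}, both stems and bunches (true verdicts are derived by assessing the
#'   truth itself at threshold 0).
#' @param thresholds Ascending numeric vector of confidence cutoffs.
#' @param config A [loosening_config()] (its own \code{conf_threshold} is
#'   overridden per row).
#' @param iou_match_threshold IoU needed to pair a detected bunch with a true
#'   bunch, default 0.5.
#' @return Data frame with one row per threshold: \code{conf_threshold},
#'   \code{tp, tn, fp, fn}, \code{precision}, \code{recall}, \code{f1}.
#' @export
confidence_sweep <- function(dets, truth, thresholds,
                             config = loosening_config(),
                             iou_match_threshold = 0.5) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L,
            !is.unsorted(thresholds))
  if (is.data.frame(dets)) dets <- list(dets)
  if (is.data.frame(truth)) truth <- list(truth)
  stopifnot(length(dets) == length(truth))
  truth_cfg <- loosening_config(lambda = config$lambda, conf_threshold = 0,
                                multi_overlap_rule =
                                  config$multi_overlap_rule)
  truth_assess <- lapply(truth, assess_scene, config = truth_cfg)
  rows <- lapply(thresholds, function(thr) {
    cfg <- loosening_config(lambda = config$lambda, conf_threshold = thr,
                            multi_overlap_rule = config$multi_overlap_rule)
    counts <- confusion_counts()
    for (i in seq_along(dets)) {
      counts_i <- .tally_scene(dets[[i]], truth[[i]], truth_assess[[i]],
                               cfg, iou_match_threshold)
      counts <- confusion_counts(tp = counts$tp + counts_i$tp,
                                 tn = counts$tn + counts_i$tn,
                                 fp = counts$fp + counts_i$fp,
                                 fn = counts$fn + counts_i$fn)
    }
    data.frame(conf_threshold = thr, tp = counts$tp, tn = counts$tn,
               fp = counts$fp, fn = counts$fn,
               precision = precision(counts), recall = recall(counts),
               f1 = f1_score(counts))
  })
  do.call(rbind, rows)
}

# One scene's bunch-level tally at one threshold: assess, align detected
# bunches with true bunches by greedy IoU, tally with implicit-qualified
# conventions for spurious/missed bunches.
.tally_scene <- function(dets_i, truth_i, truth_assess_i, cfg,
                         iou_match_threshold) {
  assess <- assess_scene(dets_i, cfg)
  det_bunches <- detections(assess$x1, assess$y1, assess$x2, assess$y2,
                            assess$conf, rep("bunch", nrow(assess)))
  truth_i <- validate_detections(truth_i)
  true_bunches <- truth_i[truth_i$label == "bunch", , drop = FALSE]
  m <- match_detections(det_bunches, true_bunches, iou_match_threshold)
  tally_bunches(
    predicted = assess$verdict[m$matches$det],
    truth = truth_assess_i$verdict[m$matches$truth],
    spurious_predicted = assess$verdict[m$unmatched_det],
    missed_truth = truth_assess_i$verdict[m$unmatched_truth]
  )
}

#' Metrics for pre-tabulated sweep counts
#'
#' Recomputes precision, recall and F1 for rows of already-tallied confusion
#' counts (one row per confidence threshold), e.g. the bundled reference
#' deployment counts, and flags the F1-maximizing threshold.
#'
#' @param counts_df Data frame with columns \code{conf_threshold, tp, tn, fp,
#'   fn}.
#' @return The input with \code{precision}, \code{recall}, \code{f1} and
#'   logical \code{best} columns appended.
#' @examples
#' sweep_metrics(field_sweep_counts())
#' @export
sweep_metrics <- function(counts_df) {
  need <- c("conf_threshold", "tp", "tn", "fp", "fn")
  stopifnot(all(need %in% names(counts_df)))
  metr <- t(vapply(seq_len(nrow(counts_df)), function(i) {
    cc <- confusion_counts(tp = counts_df$tp[i], tn = counts_df$tn[i],
                           fp = counts_df$fp[i], fn = counts_df$fn[i])
    c(precision = precision(cc), recall = recall(cc), f1 = f1_score(cc))
  }, numeric(3)))
  out <- cbind(counts_df, as.data.frame(metr))
  out$best <- seq_len(nrow(out)) == which.max(out$f1)
  out
}

#' Is a metric curve unimodal with an interior peak?
#'
#' Checks (up to a numeric tolerance) that a sequence rises to its maximum
#' and falls afterwards, and that the maximum is not at either end — the
#' shape an F1-vs-confidence curve takes when low cutoffs admit spurious
#' detections and high cutoffs drop true ones.
#'
#' @param y Numeric vector of metric values at ascending thresholds.
#' @param tol Tolerated non-monotonicity per step, default 1e-9.
#' @return Logical scalar.
#' @export
is_unimodal_interior <- function(y, tol = 1e-9) {
  stopifnot(is.numeric(y), length(y) >= 3L)
  peak <- which.max(y)
  if (peak == 1L || peak == length(y)) return(FALSE)
  rising <- all(diff(y[seq_len(peak)]) >= -tol)
  falling <- all(diff(y[peak:length(y)]) <= tol)
  rising && falling
}
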