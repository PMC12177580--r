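# Independent oracles used across the suite. These deliberately avoid the
# package's geometry/loss code paths: plain min/max arithmetic, pixel
# counting, and exhaustive loops.

# Pixel-membership IoU for integer-coordinate boxes: count unit cells whose
# center lies in each box. Exact for integer corners.
raster_iou <- function(a, b) {
  xs <- seq(min(a[1], b[1]) + 0.5, max(a[3], b[3]) - 0.5, by = 1)
  ys <- seq(min(a[2], b[2]) + 0.5, max(a[4], b[4]) - 0.5, by = 1)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in_a <- gx > a[1] & gx < a[3] & gy > a[2] & gy < a[4]
  in_b <- gx > b[1] & gx < b[3] & gy > b[2] & gy < b[4]
  sum(in_a & in_b) / sum(in_a | in_b)
}

raster_intersection <- function(a, b) {
  xs <- seq(min(a[1], b[1]) + 0.5, max(a[3], b[3]) - 0.5, by = 1)
  ys <- seq(min(a[2], b[2]) + 0.5, max(a[4], b[4]) - 0.5, by = 1)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  sum(gx > a[1] & gx < a[3] & gy > a[2] & gy < a[4] &
        gx > b[1] & gx < b[3] & gy > b[2] & gy < b[4])
}

# Scalar-arithmetic loss oracles, written directly from the closed forms.
oracle_parts <- function(p, g) {
  p <- unname(unclass(p)); g <- unname(unclass(g))
  iw <- max(0, min(p[3], g[3]) - max(p[1], g[1]))
  ih <- max(0, min(p[4], g[4]) - max(p[2], g[2]))
  inter <- iw * ih
  area_p <- (p[3] - p[1]) * (p[4] - p[2])
  area_g <- (g[3] - g[1]) * (g[4] - g[2])
  iou <- inter / (area_p + area_g - inter)
  cx_p <- (p[1] + p[3]) / 2; cy_p <- (p[2] + p[4]) / 2
  cx_g <- (g[1] + g[3]) / 2; cy_g <- (g[2] + g[4]) / 2
  rho2 <- (cx_p - cx_g)^2 + (cy_p - cy_g)^2
  wg <- max(p[3], g[3]) - min(p[1], g[1])
  hg <- max(p[4], g[4]) - min(p[2], g[2])
  list(iou = iou, rho2 = rho2, wg = wg, hg = hg,
       union = area_p + area_g - inter,
       w = p[3] - p[1], h = p[4] - p[2],
       wgt = g[3] - g[1], hgt = g[4] - g[2])
}

oracle_ciou <- function(p, g) {
  o <- oracle_parts(p, g)
  v <- (4 / pi^2) * (atan(o$wgt / o$hgt) - atan(o$w / o$h))^2
  alpha <- if ((1 - o$iou) + v == 0) 0 else v / ((1 - o$iou) + v)
  1 - o$iou + o$rho2 / (o$wg^2 + o$hg^2) + alpha * v
}

oracle_wiou_v1 <- function(p, g) {
  o <- oracle_parts(p, g)
  exp(o$rho2 / (o$wg^2 + o$hg^2)) * (1 - o$iou)
}

oracle_giou <- function(p, g) {
  o <- oracle_parts(p, g)
  1 - (o$iou - (o$wg * o$hg - o$union) / (o$wg * o$hg))
}

oracle_diou <- function(p, g) {
  o <- oracle_parts(p, g)
  1 - o$iou + o$rho2 / (o$wg^2 + o$hg^2)
}

oracle_eiou <- function(p, g) {
  o <- oracle_parts(p, g)
  1 - o$iou + o$rho2 / (o$wg^2 + o$hg^2) +
    (o$w - o$wgt)^2 / o$wg^2 + (o$h - o$hgt)^2 / o$hg^2
}

# Exhaustive all-pairs stem-to-bunch assignment (max-intersection rule with
# lowest-index tie-break), written as nested loops over raw coordinates.
brute_force_assignment <- function(stem_boxes, bunch_boxes) {
  x <- integer(nrow(bunch_boxes))
  for (s in seq_len(nrow(stem_boxes))) {
    best_b <- 0L
    best_area <- 0
    for (b in seq_len(nrow(bunch_boxes))) {
      iw <- min(stem_boxes[s, 3], bunch_boxes[b, 3]) -
        max(stem_boxes[s, 1], bunch_boxes[b, 1])
      ih <- min(stem_boxes[s, 4], bunch_boxes[b, 4]) -
        max(stem_boxes[s, 2], bunch_boxes[b, 2])
      area <- max(0, iw) * max(0, ih)
      if (area > best_area) {
        best_area <- area
        best_b <- b
      }
    }
    if (best_b > 0L) x[best_b] <- x[best_b] + 1L
  }
  x
}

# Step-curve AP by explicit rectangle summation over a fine recall grid.
brute_force_ap <- function(hits_ranked, n_truth, grid = 1e-4) {
  tp <- cumsum(hits_ranked)
  fp <- cumsum(!hits_ranked)
  rec <- tp / n_truth
  prec <- tp / (tp + fp)
  r_grid <- seq(grid, 1, by = grid)
  p_at <- vapply(r_grid, function(r) {
    ok <- rec >= r - 1e-12
    if (!any(ok)) 0 else max(prec[ok])
  }, numeric(1))
  sum(p_at) * grid
}

# Random valid box with coordinates in [0, lim].
random_box <- function(lim = 64, integer_coords = FALSE) {
  repeat {
    v <- stats::runif(4, 0, lim)
    if (integer_coords) v <- round(v)
    b <- c(min(v[1], v[3]), min(v[2], v[4]), max(v[1], v[3]), max(v[2], v[4]))
    if (b[3] > b[1] && b[4] > b[2]) return(box(b[1], b[2], b[3], b[4]))
  }
}

random_detections <- function(n_stems, n_bunches, lim = 1000) {
  mk <- function(n, label, size_max) {
    if (n == 0L) return(detections())
    x1 <- stats::runif(n, 0, lim - size_max)
    y1 <- stats::runif(n, 0, lim - size_max)
    detections(x1, y1,
               x1 + stats::runif(n, 1, size_max),
               y1 + stats::runif(n, 1, size_max),
               stats::runif(n), rep(label, n))
  }
  rbind(mk(n_stems, "stem", 80), mk(n_bunches, "bunch", 300))
}
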