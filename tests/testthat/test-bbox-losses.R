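test_that("ciou_loss matches hand-derived scalar values", {
  b <- box(3, 1, 7, 6)
  expect_equal(ciou_loss(b, b)$value, 0)

  # disjoint unit-aspect squares: IoU 0, rho2 = 8, c2 = 32, v = 0
  r <- ciou_loss(box(2, 2, 4, 4), box(0, 0, 2, 2))
  expect_equal(r$value, 1.25)
  expect_equal(r$components$iou, 0)
  expect_equal(r$components$v, 0)

  # equal-area boxes with swapped aspect ratio: aspect penalty active
  p <- box(0, 0, 4, 2); g <- box(0, 0, 2, 4)
  r2 <- ciou_loss(p, g)
  expect_equal(r2$components$iou, 1 / 3)
  expect_gt(r2$components$v, 0)
  expect_equal(r2$value, oracle_ciou(p, g), tolerance = 1e-12)
})

test_that("wiou_v1_loss matches hand-derived scalar values", {
  b <- box(0, 0, 5, 5)
  expect_equal(wiou_v1_loss(b, b)$value, 0)

  r <- wiou_v1_loss(box(2, 2, 4, 4), box(0, 0, 2, 2))
  expect_equal(r$value, exp(8 / 32), tolerance = 1e-12)

  # concentric boxes: centers coincide, penalty factor is 1
  r2 <- wiou_v1_loss(box(0, 0, 4, 4), box(1, 1, 3, 3))
  expect_equal(r2$components$r_wiou, 1)
  expect_equal(r2$value, 0.75)
})

test_that("wiou_v2 focusing collapses to v1 in its neutral configurations", {
  p <- box(1, 2, 6, 5); g <- box(2, 1, 7, 6)
  v1 <- wiou_v1_loss(p, g)$value

  # perfect match: zero regardless of state
  expect_equal(wiou_v2_loss(g, g, wiou_state(gamma = 3, mean = 0.2))$value, 0)

  # mean equal to the current L_IoU, gamma 1: ratio is 1
  l_iou <- 1 - iou(p, g)
  expect_equal(wiou_v2_loss(p, g, wiou_state(gamma = 1, mean = l_iou))$value,
               v1, tolerance = 1e-12)

  # gamma 0 kills the focus term for any state
  expect_equal(wiou_v2_loss(p, g, wiou_state(gamma = 0, mean = 0.01))$value,
               v1, tolerance = 1e-12)
})

test_that("wiou_v2 uses the pre-update mean and then updates the EMA", {
  p <- box(0, 0, 2, 2); g <- box(1, 1, 3, 3)
  st <- wiou_state(gamma = 1, momentum = 0.25, mean = 0.5)
  r <- wiou_v2_loss(p, g, st)
  l_iou <- 1 - iou(p, g)
  expect_equal(r$components$mean_pre_update, 0.5)
  expect_equal(r$value, (l_iou / 0.5) * wiou_v1_loss(p, g)$value,
               tolerance = 1e-12)
  expect_equal(r$state$mean, 0.75 * 0.5 + 0.25 * l_iou)
})

test_that("the EMA converges geometrically under repeated observations", {
  st <- wiou_state(momentum = 0.1, mean = 1)
  p <- box(0, 0, 2, 2); g <- box(1, 1, 3, 3)
  v <- 1 - iou(p, g)
  for (k in 1:50) st <- wiou_v2_loss(p, g, st)$state
  expect_equal(st$mean, v + (1 - 0.1)^50 * (1 - v), tolerance = 1e-12)
})

test_that("comparator losses match their closed forms", {
  p <- box(2, 2, 4, 4); g <- box(0, 0, 2, 2)
  expect_equal(bbox_loss("giou", g, g)$value, 0)
  expect_equal(bbox_loss("diou", p, g)$value, 1.25)
  expect_equal(bbox_loss("giou", box(0, 0, 1, 1), box(2, 2, 3, 3))$value,
               16 / 9, tolerance = 1e-12)
  expect_equal(bbox_loss("eiou", p, g)$value, oracle_eiou(p, g),
               tolerance = 1e-12)
  # focal variant scales EIoU by IoU^0.5; zero when disjoint or perfect
  expect_equal(bbox_loss("focal_eiou", p, g)$value, 0)
  expect_equal(bbox_loss("focal_eiou", g, g)$value, 0)
  q <- box(1, 0, 3, 2)
  expect_equal(bbox_loss("focal_eiou", q, g)$value,
               iou(q, g)^0.5 * oracle_eiou(q, g), tolerance = 1e-12)
  expect_error(bbox_loss("not_a_loss", p, g), "unknown")
})

test_that("the registry is extensible", {
  register_bbox_loss("l_iou_only", function(pred, gt) {
    loss_result(1 - iou(pred, gt))
  })
  expect_true("l_iou_only" %in% bbox_loss_names())
  expect_equal(bbox_loss("l_iou_only", box(0, 0, 1, 1), box(0, 0, 1, 1))$value,
               0)
})

test_that("losses vanish exactly at a perfect match and are positive off it", {
  set.seed(11)
  names <- c("ciou", "wiou_v1", "giou", "diou", "eiou")
  for (i in 1:100) {
    a <- random_box()
    b <- random_box()
    for (nm in names) {
      expect_equal(bbox_loss(nm, a, a)$value, 0, tolerance = 1e-12)
      if (!isTRUE(all.equal(unclass(a), unclass(b)))) {
        expect_gt(bbox_loss(nm, a, b)$value, 0)
      }
    }
    expect_equal(wiou_v2_loss(a, a)$value, 0)
  }
})

test_that("losses are invariant to joint translation and scaling", {
  set.seed(12)
  shift_box <- function(b, dx, dy) box(b[1] + dx, b[2] + dy,
                                       b[3] + dx, b[4] + dy)
  scale_box <- function(b, s) box(s * b[1], s * b[2], s * b[3], s * b[4])
  names <- c("ciou", "wiou_v1", "giou", "diou", "eiou", "focal_eiou")
  for (i in 1:100) {
    a <- random_box(); b <- random_box()
    dx <- stats::runif(1, -50, 50); dy <- stats::runif(1, -50, 50)
    s <- stats::runif(1, 0.1, 10)
    st <- wiou_state(mean = stats::runif(1, 0.1, 1))
    base_v2 <- wiou_v2_loss(a, b, st)$value
    for (nm in names) {
      base <- bbox_loss(nm, a, b)$value
      expect_equal(bbox_loss(nm, shift_box(a, dx, dy),
                             shift_box(b, dx, dy))$value,
                   base, tolerance = 1e-9)
      expect_equal(bbox_loss(nm, scale_box(a, s), scale_box(b, s))$value,
                   base, tolerance = 1e-9)
    }
    expect_equal(wiou_v2_loss(shift_box(a, dx, dy), shift_box(b, dx, dy),
                              st)$value, base_v2, tolerance = 1e-9)
    expect_equal(wiou_v2_loss(scale_box(a, s), scale_box(b, s), st)$value,
                 base_v2, tolerance = 1e-9)
  }
})

test_that("wiou_v2 is monotone in L_IoU at fixed mean and geometry factor", {
  # same centers and enclosing box, growing mismatch => growing L_IoU
  st <- wiou_state(gamma = 1.5, mean = 0.4)
  g <- box(0, 0, 10, 10)
  vals <- vapply(c(9, 7, 5, 3), function(in_side) {
    off <- (10 - in_side) / 2
    wiou_v2_loss(box(off, off, off + in_side, off + in_side), g, st)$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
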