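test_that("precision, recall and F1 match the counting definitions", {
  cc <- confusion_counts(tp = 23, tn = 8, fp = 6, fn = 3)
  expect_equal(precision(cc), 23 / 29)
  expect_equal(recall(cc), 23 / 26)
  expect_equal(f1_score(cc), 46 / 55)
  expect_equal(round(f1_score(cc), 3), 0.836)

  zero <- confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_equal(precision(zero), 0)
  expect_equal(recall(zero), 0)
  expect_equal(f1_score(zero), 0)

  sym <- confusion_counts(tp = 10, fp = 10, fn = 10)
  expect_equal(c(precision(sym), recall(sym), f1_score(sym)),
               c(0.5, 0.5, 0.5))
  expect_error(confusion_counts(tp = -1), "non-negative")
})

test_that("F1 lies between precision and recall on randomized counts", {
  set.seed(31)
  for (i in 1:200) {
    cc <- confusion_counts(tp = sample(1:50, 1), tn = sample(0:50, 1),
                           fp = sample(0:50, 1), fn = sample(0:50, 1))
    p <- precision(cc); r <- recall(cc); f <- f1_score(cc)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("accuracy breakdown reproduces the deployment figures", {
  acc <- accuracy_breakdown(confusion_counts(tp = 23, tn = 8,
                                             fp = 6, fn = 3))
  expect_equal(unname(round(acc, 3)), c(0.775, 0.793, 0.727))
  all_tp <- accuracy_breakdown(confusion_counts(tp = 12))
  expect_equal(unname(all_tp), c(1, 1, 0))
  ones <- accuracy_breakdown(confusion_counts(1, 1, 1, 1))
  expect_equal(unname(ones), c(0.5, 0.5, 0.5))
})

test_that("tally_bunches applies the implicit-qualified conventions", {
  same <- rep("unqualified", 4)
  cc <- tally_bunches(same, same)
  expect_equal(cc$fp + cc$fn, 0L)

  # spurious bunch flagged unqualified: a false positive
  cc2 <- tally_bunches(character(), character(),
                       spurious_predicted = "unqualified")
  expect_equal(cc2$fp, 1L)
  # missed unqualified bunch: a false negative
  cc3 <- tally_bunches(character(), character(),
                       missed_truth = "unqualified")
  expect_equal(cc3$fn, 1L)

  # totals conserve: matched + spurious + missed
  set.seed(8)
  verd <- function(n) sample(c("qualified", "unqualified"), n, replace = TRUE)
  for (i in 1:20) {
    n_m <- sample(0:20, 1); n_s <- sample(0:5, 1); n_x <- sample(0:5, 1)
    cc <- tally_bunches(verd(n_m), verd(n_m), verd(n_s), verd(n_x))
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n_m + n_s + n_x)
  }
})

test_that("the bundled per-bunch records tally to the deployment counts", {
  cc <- tally_bunch_records()
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(23L, 8L, 6L, 3L))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 40L)
  expect_equal(cc$tp + cc$tn, 31L)
  expect_equal(accuracy_breakdown(cc)[["overall"]], 0.775)
})

test_that("greedy matching is one-to-one, class-aware, confidence-first", {
  t1 <- detections(c(0, 100), 0, c(50, 150), 50, c(1, 1), rep("stem", 2))
  m <- match_detections(t1, t1)
  expect_equal(nrow(m$matches), 2L)
  expect_equal(length(m$unmatched_det), 0L)

  none <- match_detections(t1, detections())
  expect_equal(nrow(none$matches), 0L)
  expect_equal(none$unmatched_det, 1:2)

  # two detections over one truth: the higher-confidence one wins
  truth <- detections(0, 0, 50, 50, 1, "stem")
  dets <- detections(c(1, 0), c(1, 0), c(51, 50), c(51, 50),
                     c(0.6, 0.9), rep("stem", 2))
  m2 <- match_detections(dets, truth)
  expect_equal(m2$matches$det, 2L)
  expect_equal(m2$unmatched_det, 1L)

  # class mismatch never matches
  bunch_truth <- detections(0, 0, 50, 50, 1, "bunch")
  m3 <- match_detections(dets, bunch_truth)
  expect_equal(nrow(m3$matches), 0L)
})

test_that("average precision matches the exhaustive step-curve oracle", {
  truth <- rbind(detections(0, 0, 50, 50, 1, "stem"),
                 detections(100, 100, 150, 150, 1, "stem"))
  # single correct detection covering all of one truth of one
  one <- detections(0, 0, 50, 50, 0.9, "stem")
  expect_equal(average_precision(one, truth[1, ]), 1)
  # no correct detections
  far <- detections(500, 500, 550, 550, 0.9, "stem")
  expect_equal(average_precision(far, truth), 0)

  # ranked (hit, miss, hit) over 2 truths: AP = 0.5*1 + 0.5*(2/3)
  dets <- rbind(detections(0, 0, 50, 50, 0.9, "stem"),
                detections(500, 500, 550, 550, 0.8, "stem"),
                detections(100, 100, 150, 150, 0.7, "stem"))
  ap <- average_precision(dets, truth)
  expect_equal(ap, 5 / 6)
  expect_equal(ap, brute_force_ap(c(TRUE, FALSE, TRUE), 2), tolerance = 1e-3)

  set.seed(77)
  for (i in 1:30) {
    n_t <- sample(1:6, 1)
    x <- 200 * (seq_len(n_t) - 1)
    tr <- detections(x, 0, x + 100, 100, rep(1, n_t), rep("stem", n_t))
    n_d <- sample(1:10, 1)
    hit_truth <- sample(c(NA, seq_len(n_t)), n_d, replace = TRUE)
    dx <- ifelse(is.na(hit_truth), 5000 + 200 * seq_len(n_d),
                 200 * (hit_truth - 1))
    dd <- detections(dx, 0, dx + 100, 100,
                     conf = seq(0.95, 0.05, length.out = n_d),
                     label = rep("stem", n_d))
    m <- match_detections(dd, tr)
    hits <- seq_len(n_d) %in% m$matches$det
    expect_equal(average_precision(dd, tr),
                 brute_force_ap(hits, n_t), tolerance = 2e-3)
  }
})

test_that("mean_ap averages per-class AP", {
  expect_equal(mean_ap(c(0.9, 0.7)), 0.8)
})

test_that("the confidence sweep recovers truth perfectly without noise", {
  scene <- generate_scene(scene_spec(bunch_sizes = c(4, 11)), seed = 2)
  dets <- corrupt_scene(scene, zero_noise(), seed = 3)
  sw <- confidence_sweep(dets, scene$truth, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(sw$fp, rep(0L, 3))
  expect_equal(sw$fn, rep(0L, 3))
  expect_equal(sw$tp, rep(1L, 3))  # the size-11 bunch
  expect_equal(sw$tn, rep(1L, 3))
  expect_equal(sw$f1, rep(1, 3))
})

test_that("a cutoff above every confidence turns unqualified truths into FN", {
  scene <- generate_scene(scene_spec(bunch_sizes = c(10)), seed = 4)
  dets <- corrupt_scene(scene, noise_model(p_miss = 0, fp_rate = 0,
                                           jitter_sd = 0), seed = 5)
  sw <- confidence_sweep(dets, scene$truth, thresholds = c(0.999999))
  expect_equal(sw$tp, 0L)
  expect_equal(sw$fn, 1L)
})

test_that("surviving detections are non-increasing in the threshold", {
  set.seed(13)
  d <- random_detections(30, 3)
  ths <- seq(0, 1, by = 0.1)
  n_kept <- vapply(ths, function(t) nrow(filter_by_confidence(d, t)),
                   integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("unimodality checker accepts interior peaks only", {
  expect_true(is_unimodal_interior(c(0.2, 0.5, 0.8, 0.6, 0.3)))
  expect_false(is_unimodal_interior(c(0.9, 0.5, 0.2)))
  expect_false(is_unimodal_interior(c(0.1, 0.5, 0.9)))
  expect_false(is_unimodal_interior(c(0.1, 0.8, 0.2, 0.7, 0.1)))
})
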