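#' Synthetic scene specification
#'
#' Describes one simulated conveyor-belt frame: the image size (default
#' 2448 x 2048, the acquisition camera's output resolution), a number of
#' isolated single stems, and a vector of bunch sizes — one entry per bunch,
#' giving its true member-stem count. The generator places bunch boxes
#' mutually disjoint, member stems inside their bunch box, and isolated
#' stems overlapping no bunch box, so every bunch's true \code{x} is exactly
#' its specified size.
#'
#' @param image_width,image_height Frame size in pixels.
#' @param n_isolated_stems Number of stems belonging to no bunch.
#' @param bunch_sizes Integer vector of member-stem counts, one per bunch.
#' @param stem_size_range Length-2 vector: min/max stem box long side
#'   (pixels); the short side is drawn from 25–45% of the long side, and
#'   orientation (horizontal/vertical) is random.
#' @param bunch_size_range Length-2 vector: min/max bunch box side (pixels).
#' @param max_attempts Rejection-sampling cap per object placement; crowded
#'   specs that exceed it raise an error rather than loop forever.
#' @return A list of class \code{"scene_spec"}.
#' @export
scene_spec <- function(image_width = 2448, image_height = 2048,
                       n_isolated_stems = 12, bunch_sizes = c(5, 10),
                       stem_size_range = c(120, 340),
                       bunch_size_range = c(420, 820),
                       max_attempts = 1000) {
  stopifnot(image_width > 0, image_height > 0,
            n_isolated_stems >= 0,
            all(bunch_sizes >= 1), all(bunch_sizes == round(bunch_sizes)),
            length(stem_size_range) == 2L,
            stem_size_range[1] > 0, diff(stem_size_range) >= 0,
            length(bunch_size_range) == 2L,
            bunch_size_range[1] > 0, diff(bunch_size_range) >= 0,
            bunch_size_range[2] <= min(image_width, image_height),
            max_attempts >= 1)
  structure(list(image_width = image_width, image_height = image_height,
                 n_isolated_stems = as.integer(n_isolated_stems),
                 bunch_sizes = as.integer(bunch_sizes),
                 stem_size_range = as.numeric(stem_size_range),
                 bunch_size_range = as.numeric(bunch_size_range),
                 max_attempts = as.integer(max_attempts)),
            class = "scene_spec")
}

#' Detector noise model
#'
#' Imperfections layered onto ground truth to emulate a real detector's
#' output: each true object is missed independently with probability
#' \code{p_miss}; surviving boxes get Gaussian corner jitter of standard
#' deviation \code{jitter_sd} pixels (re-clamped to stay valid and inside
#' the frame); a Poisson(\code{fp_rate}) number of spurious stem boxes is
#' added per scene. Spurious boxes are placed where detectors actually
#' hallucinate them — with probability \code{p_fp_in_bunch} inside a bunch
#' box (occluded, cluttered regions), otherwise near a random object — so
#' that admitting them inflates member counts the way a low cutoff does on a
#' real line. Confidences are drawn from Beta laws with different shapes for
#' true and spurious detections — by default Beta(8, 2) (mean 0.8) for true
#' and Beta(3, 7) (mean 0.3) for spurious — so a confidence cutoff can trade
#' the two error types, as in a real confidence sweep. The confidence law is
#' a test fixture, not a measured detector property.
#'
#' @param p_miss Per-object miss probability in \code{[0, 1]}.
#' @param fp_rate Expected spurious detections per scene.
#' @param jitter_sd Corner jitter standard deviation, pixels.
#' @param conf_true,conf_spurious Length-2 Beta shape vectors for true and
#'   spurious confidences. \code{conf_true = NULL} keeps the ground-truth
#'   confidences untouched (used by [zero_noise()]).
#' @param p_fp_in_bunch Probability that a spurious box is dropped inside a
#'   bunch box rather than near an arbitrary object.
#' @return A list of class \code{"noise_model"}.
#' @export
noise_model <- function(p_miss = 0.05, fp_rate = 5, jitter_sd = 4,
                        conf_true = c(8, 2), conf_spurious = c(3, 7),
                        p_fp_in_bunch = 0.7) {
  stopifnot(p_miss >= 0, p_miss <= 1, fp_rate >= 0, jitter_sd >= 0,
            is.null(conf_true) ||
              (length(conf_true) == 2L && all(conf_true > 0)),
            length(conf_spurious) == 2L, all(conf_spurious > 0),
            p_fp_in_bunch >= 0, p_fp_in_bunch <= 1)
  structure(list(p_miss = p_miss, fp_rate = fp_rate, jitter_sd = jitter_sd,
                 conf_true = conf_true, conf_spurious = conf_spurious,
                 p_fp_in_bunch = p_fp_in_bunch),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
zero_noise <- function() {
  noise_model(p_miss = 0, fp_rate = 0, jitter_sd = 0, conf_true = NULL)
}

# Sample a box of given width/height uniformly inside the frame, optionally
# constrained to a containing box.
.sample_box <- function(w, h, x_min, y_min, x_max, y_max) {
  x1 <- stats::runif(1, x_min, x_max - w)
  y1 <- stats::runif(1, y_min, y_max - h)
  c(x1, y1, x1 + w, y1 + h)
}

.overlaps_any <- function(b, others) {
  if (nrow(others) == 0L) return(FALSE)
  any(pairwise_intersection(matrix(b, nrow = 1), others) > 0)
}

#' Generate a synthetic ground-truth scene
#'
#' Places the specified bunches and stems and returns the scene's ground
#' truth: detections with \code{conf = 1} plus the true member count per
#' bunch. Deterministic for a fixed seed. Bunch boxes are mutually disjoint;
#' each bunch's member stems lie inside its box; isolated stems overlap no
#' bunch box — so re-running the loosening pipeline on the noiseless truth
#' recovers every \code{x} exactly.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer RNG seed.
#' @return A list of class \code{"scene"}: \code{spec}, \code{truth} (a
#'   [detections()] data frame), \code{bunch_x} (integer vector of true
#'   member counts, in bunch order).
#' @export
generate_scene <- function(spec = scene_spec(), seed = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(as.integer(seed))
  n_bunch <- length(spec$bunch_sizes)
  placed_bunches <- matrix(numeric(), ncol = 4)
  rows <- list()

  sample_until <- function(gen, reject) {
    for (i in seq_len(spec$max_attempts)) {
      b <- gen()
      if (!reject(b)) return(b)
    }
    stop("scene generation exceeded max_attempts (", spec$max_attempts,
         "); spec too crowded for the frame", call. = FALSE)
  }

  for (i in seq_len(n_bunch)) {
    side_w <- stats::runif(1, spec$bunch_size_range[1],
                           spec$bunch_size_range[2])
    side_h <- stats::runif(1, spec$bunch_size_range[1],
                           spec$bunch_size_range[2])
    b <- sample_until(
      function() .sample_box(side_w, side_h, 0, 0,
                             spec$image_width, spec$image_height),
      function(b) .overlaps_any(b, placed_bunches)
    )
    placed_bunches <- rbind(placed_bunches, b)
    rows[[length(rows) + 1L]] <-
      data.frame(x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
                 conf = 1, label = "bunch")
  }

  sample_stem <- function(x_min, y_min, x_max, y_max) {
    long <- stats::runif(1, spec$stem_size_range[1], spec$stem_size_range[2])
    long <- min(long, (x_max - x_min), (y_max - y_min))
    short <- stats::runif(1, 0.25, 0.45) * long
    if (stats::runif(1) < 0.5) .sample_box(long, short, x_min, y_min,
                                           x_max, y_max)
    else .sample_box(short, long, x_min, y_min, x_max, y_max)
  }

  # Member stems: anywhere inside their own bunch box (positive overlap is
  # then automatic, and max-intersection assignment resolves to this bunch
  # because the other bunches are disjoint from it).
  for (i in seq_len(n_bunch)) {
    bb <- placed_bunches[i, ]
    for (s in seq_len(spec$bunch_sizes[i])) {
      b <- sample_stem(bb[1], bb[2], bb[3], bb[4])
      rows[[length(rows) + 1L]] <-
        data.frame(x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
                   conf = 1, label = "stem")
    }
  }

  for (s in seq_len(spec$n_isolated_stems)) {
    b <- sample_until(
      function() sample_stem(0, 0, spec$image_width, spec$image_height),
      function(b) .overlaps_any(b, placed_bunches)
    )
    rows[[length(rows) + 1L]] <-
      data.frame(x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
                 conf = 1, label = "stem")
  }

  truth <- validate_detections(do.call(rbind, c(
    list(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                    y2 = numeric(), conf = numeric(),
                    label = character())), rows)))
  structure(list(spec = spec, truth = truth,
                 bunch_x = spec$bunch_sizes),
            class = "scene")
}

#' Corrupt a scene into simulated detector output
#'
#' Applies a [noise_model()] to a scene's ground truth: drops objects,
#' jitters surviving boxes, samples confidences, and appends spurious
#' detections. Spurious boxes reuse the scene's object size laws and are
#' placed near existing objects (detector false positives cluster around
#' belt texture and leaf matter, not uniformly over the empty belt).
#' Reproducible for a fixed seed.
#'
#' @param scene A [generate_scene()] result.
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed.
#' @return A [detections()] data frame of simulated detector output.
#' @export
corrupt_scene <- function(scene, noise = noise_model(), seed = 1) {
  stopifnot(inherits(scene, "scene"), inherits(noise, "noise_model"))
  set.seed(as.integer(seed))
  truth <- scene$truth
  spec <- scene$spec
  n <- nrow(truth)
  keep <- stats::runif(n) >= noise$p_miss
  out <- truth[keep, , drop = FALSE]
  n_k <- nrow(out)
  if (n_k > 0L) {
    jit <- matrix(stats::rnorm(4L * n_k, sd = noise$jitter_sd), ncol = 4L)
    m <- .det_boxes(out) + jit
    # re-clamp: keep boxes valid (min 2 px side) and inside the frame
    m[, 1L] <- pmin(pmax(m[, 1L], 0), spec$image_width - 2)
    m[, 2L] <- pmin(pmax(m[, 2L], 0), spec$image_height - 2)
    m[, 3L] <- pmin(pmax(m[, 3L], m[, 1L] + 2), spec$image_width)
    m[, 4L] <- pmin(pmax(m[, 4L], m[, 2L] + 2), spec$image_height)
    out$x1 <- m[, 1L]; out$y1 <- m[, 2L]
    out$x2 <- m[, 3L]; out$y2 <- m[, 4L]
    if (!is.null(noise$conf_true)) {
      out$conf <- stats::rbeta(n_k, noise$conf_true[1], noise$conf_true[2])
    }
  }
  n_fp <- stats::rpois(1, noise$fp_rate)
  if (n_fp > 0L && n > 0L) {
    bunch_boxes <- .det_boxes(truth[truth$label == "bunch", , drop = FALSE])
    fp_rows <- lapply(seq_len(n_fp), function(i) {
      w <- stats::runif(1, spec$stem_size_range[1], spec$stem_size_range[2])
      h <- stats::runif(1, 0.25, 0.45) * w
      if (stats::runif(1) < 0.5) { tmp <- w; w <- h; h <- tmp }
      in_bunch <- nrow(bunch_boxes) > 0L &&
        stats::runif(1) < noise$p_fp_in_bunch
      if (in_bunch) {
        bb <- bunch_boxes[sample.int(nrow(bunch_boxes), 1L), ]
        cx <- stats::runif(1, bb[1], bb[3])
        cy <- stats::runif(1, bb[2], bb[4])
      } else {
        anchor <- .det_boxes(truth)[sample.int(n, 1L), ]
        cx <- (anchor[1] + anchor[3]) / 2 + stats::rnorm(1, sd = 200)
        cy <- (anchor[2] + anchor[4]) / 2 + stats::rnorm(1, sd = 200)
      }
      x1 <- min(max(cx - w / 2, 0), spec$image_width - w)
      y1 <- min(max(cy - h / 2, 0), spec$image_height - h)
      data.frame(x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
                 conf = stats::rbeta(1, noise$conf_spurious[1],
                                     noise$conf_spurious[2]),
                 label = "stem")
    })
    out <- rbind(as.data.frame(out), do.call(rbind, fp_rows))
  }
  rownames(out) <- NULL
  validate_detections(out)
}

#' Draw a random scene specification
#'
#' Convenience sampler for dataset generation: bunch count uniform on
#' \code{n_bunches}, bunch sizes uniform on \code{bunch_size_support} (an
#' integer range straddling the default qualification maximum lambda = 8),
#' isolated-stem count uniform on \code{n_isolated}.
#'
#' @param seed Integer RNG seed.
#' @param n_bunches Integer vector to sample the bunch count from.
#' @param bunch_size_support Integer vector to sample member counts from.
#' @param n_isolated Integer vector to sample the isolated-stem count from.
#' @param ... Passed on to [scene_spec()].
#' @return A [scene_spec()].
#' @export
sample_scene_spec <- function(seed = 1, n_bunches = 1:3,
                              bunch_size_support = 2:14,
                              n_isolated = 6:18, ...) {
  set.seed(as.integer(seed))
  k <- sample(n_bunches, 1L)
  scene_spec(
    n_isolated_stems = sample(n_isolated, 1L),
    bunch_sizes = sample(bunch_size_support, k, replace = TRUE),
    ...
  )
}

#' Write a synthetic dataset to disk
#'
#' Generates \code{n_scenes} scenes, corrupts each with the noise model, and
#' writes per scene a YOLO-format ground-truth label file
#' (\code{scene_###.txt}), a corner-format detection file
#' (\code{scene_###_det.txt}), plus one \code{manifest.json} recording each
#' scene's true bunch counts and verdicts. Byte-identical across reruns with
#' the same arguments.
#'
#' @param n_scenes Number of scenes.
#' @param out_dir Output directory (created if needed).
#' @param noise A [noise_model()]; use zero rates for a noiseless set.
#' @param seed Master seed; per-scene seeds are derived from it.
#' @param lambda Qualification maximum used for the manifest verdicts.
#' @param spec_sampler Function \code{(seed) -> scene_spec}.
#' @return Invisibly, the manifest as a list.
#' @export
generate_dataset <- function(n_scenes, out_dir, noise = noise_model(),
                             seed = 1, lambda = 8,
                             spec_sampler = sample_scene_spec) {
  stopifnot(n_scenes >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = as.integer(seed), lambda = as.integer(lambda),
                   scenes = list())
  set.seed(as.integer(seed))
  scene_seeds <- if (n_scenes > 0L)
    sample.int(.Machine$integer.max - 1L, 3L * n_scenes) else integer()
  for (i in seq_len(n_scenes)) {
    scene_seed <- scene_seeds[3L * i - 2L]
    spec <- spec_sampler(seed = scene_seeds[3L * i - 1L])
    scene <- generate_scene(spec, seed = scene_seed)
    dets <- corrupt_scene(scene, noise, seed = scene_seeds[3L * i])
    stub <- sprintf("scene_%03d", i)
    write_yolo_labels(scene$truth, file.path(out_dir, paste0(stub, ".txt")),
                      image_size = c(spec$image_width, spec$image_height))
    write_detections(dets, file.path(out_dir, paste0(stub, "_det.txt")))
    manifest$scenes[[stub]] <- list(
      seed = scene_seed,
      bunch_x = as.integer(scene$bunch_x),
      verdicts = classify_bunch(scene$bunch_x, lambda, warn = FALSE)
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
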