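#' Feature grid
#'
#' A numeric grid (matrix, or 3-d array with a trailing channel dimension)
#' tagged with its pyramid level. In a bidirectional feature pyramid the
#' spatial size halves for each level step: at a 640-pixel input, levels
#' P2/P3/P4/P5 are 160/80/40/20 cells on a side.
#'
#' @param values Finite numeric matrix or 3-d array.
#' @param level Pyramid level tag, one of \code{"P2", "P3", "P4", "P5"}.
#' @return The array, classed \code{"feature_grid"} with a \code{level}
#'   attribute.
#' @export
feature_grid <- function(values, level = c("P2", "P3", "P4", "P5")) {
  level <- match.arg(level)
  if (!is.numeric(values) || !(length(dim(values)) %in% c(2L, 3L))) {
    stop("feature grid values must be a numeric matrix or 3-d array",
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("feature grid values must be finite",
                                    call. = FALSE)
  structure(values, level = level, class = "feature_grid")
}

#' @rdname feature_grid
#' @param x A feature grid.
#' @export
grid_level <- function(x) attr(x, "level")

#' @rdname feature_grid
#' @export
grid_values <- function(x) {
  v <- unclass(x)
  attr(v, "level") <- NULL
  v
}

.level_index <- function(level) match(level, c("P2", "P3", "P4", "P5"))

#' Fusion weights
#'
#' Per-input fusion weights for fast-normalized feature fusion. Raw weights
#' are clamped to be non-negative at use (learned weights can drift negative);
#' the stabilizer \code{eps} keeps the normalization defined when all weights
#' vanish.
#'
#' @param w Numeric vector of per-input weights.
#' @param eps Stabilizer added to the weight sum, \code{> 0} (an all-zero
#'   weight vector then yields a near-zero output rather than 0/0).
#' @return An object of class \code{"fusion_weights"}.
#' @export
fusion_weights <- function(w, eps = 1e-4) {
  stopifnot(is.numeric(w), length(w) >= 1L, all(is.finite(w)),
            is.numeric(eps), length(eps) == 1L, eps >= 0)
  structure(list(w = as.numeric(w), eps = as.numeric(eps)),
            class = "fusion_weights")
}

#' Fast-normalized weighted fusion
#'
#' The fusion arithmetic of the bidirectional feature pyramid: inputs are
#' combined as \code{transform(sum(w_i * input_i) / (sum(w_i) + eps))}, with
#' the weights clamped non-negative. With an identity transform and small
#' \code{eps} this is a near-convex combination, so the output is bounded by
#' the input range. The \code{transform} slot is where a network would apply
#' its (separable) convolution; it is an injected contract here so the fusion
#' math is testable without one.
#'
#' @param inputs List of two or more [feature_grid()]s of identical shape and
#'   level.
#' @param weights A [fusion_weights()] with one weight per input.
#' @param transform Function applied to the fused grid (default identity).
#' @return A [feature_grid()] at the common level.
#' @examples
#' g <- function(v) feature_grid(matrix(v, 4, 4), "P3")
#' fuse_grids(list(g(0), g(2)), fusion_weights(c(1, 1), eps = 0))[1, 1] # 1
#' @export
fuse_grids <- function(inputs, weights, transform = identity) {
  stopifnot(is.list(inputs), length(inputs) >= 2L,
            inherits(weights, "fusion_weights"))
  if (length(weights$w) != length(inputs)) {
    stop("need exactly one fusion weight per input", call. = FALSE)
  }
  dims <- lapply(inputs, dim)
  if (!all(vapply(dims[-1L], identical, logical(1), dims[[1L]]))) {
    stop("fusion inputs must share an identical shape", call. = FALSE)
  }
  levels <- vapply(inputs, grid_level, character(1))
  if (length(unique(levels)) != 1L) {
    stop("fusion inputs must share a pyramid level", call. = FALSE)
  }
  w <- pmax(weights$w, 0)
  acc <- array(0, dim = dims[[1L]])
  for (i in seq_along(inputs)) acc <- acc + w[i] * unclass(inputs[[i]])
  fused <- acc / (sum(w) + weights$eps)
  feature_grid(transform(fused), level = levels[[1L]])
}

#' Resize contracts
#'
#' Default spatial resampling used between pyramid levels: nearest-neighbour
#' doubling on the top-down pathway, 2x2 mean pooling on the bottom-up
#' pathway. Channel dimensions are preserved.
#'
#' @param x A [feature_grid()].
#' @param level Level tag for the result.
#' @return A [feature_grid()] at the new size.
#' @export
upsample_nearest <- function(x, level = grid_level(x)) {
  v <- unclass(x)
  d <- dim(v)
  idx_r <- rep(seq_len(d[1L]), each = 2L)
  idx_c <- rep(seq_len(d[2L]), each = 2L)
  out <- if (length(d) == 2L) v[idx_r, idx_c, drop = FALSE]
         else v[idx_r, idx_c, , drop = FALSE]
  feature_grid(out, level = level)
}

#' @rdname upsample_nearest
#' @export
downsample_mean <- function(x, level = grid_level(x)) {
  v <- unclass(x)
  d <- dim(v)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L) {
    stop("mean-pooling downsample needs even spatial dimensions",
         call. = FALSE)
  }
  odd_r <- seq(1L, d[1L], by = 2L); odd_c <- seq(1L, d[2L], by = 2L)
  pool <- function(m) {
    (m[odd_r, odd_c, drop = FALSE] + m[odd_r + 1L, odd_c, drop = FALSE] +
       m[odd_r, odd_c + 1L, drop = FALSE] +
       m[odd_r + 1L, odd_c + 1L, drop = FALSE]) / 4
  }
  out <- if (length(d) == 2L) pool(v) else {
    res <- array(0, dim = c(d[1L] / 2L, d[2L] / 2L, d[3L]))
    for (k in seq_len(d[3L])) res[, , k] <- pool(v[, , k])
    res
  }
  feature_grid(out, level = level)
}

#' Top-down fusion node
#'
#' Intermediate node on the top-down pathway: the same-level input is fused
#' with the next-coarser level's feature, upsampled to this level's
#' resolution.
#'
#' @param same_level Input feature at this level.
#' @param higher_level Feature one pyramid step coarser (half the spatial
#'   size).
#' @param weights A [fusion_weights()] of length 2
#'   (\code{w1} same-level, \code{w2} resized higher level).
#' @param resize Upsampling contract (default [upsample_nearest()]).
#' @param transform Post-fusion transform (default identity).
#' @return A [feature_grid()] at \code{same_level}'s level.
#' @export
td_node <- function(same_level, higher_level, weights,
                    resize = upsample_nearest, transform = identity) {
  if (.level_index(grid_level(higher_level)) !=
      .level_index(grid_level(same_level)) + 1L) {
    stop("higher_level must sit one pyramid step above same_level",
         call. = FALSE)
  }
  resized <- resize(higher_level, level = grid_level(same_level))
  fuse_grids(list(same_level, resized), weights, transform)
}

#' Bottom-up output node
#'
#' Output node on the bottom-up pathway: fuses this level's raw input, its
#' top-down intermediate feature, and the next-finer level's output
#' downsampled to this resolution.
#'
#' @param level_in Raw input feature at this level.
#' @param level_td Top-down intermediate feature at this level.
#' @param lower_out Output feature one pyramid step finer (twice the spatial
#'   size).
#' @param weights A [fusion_weights()] of length 3.
#' @param resize Downsampling contract (default [downsample_mean()]).
#' @param transform Post-fusion transform (default identity).
#' @return A [feature_grid()] at \code{level_in}'s level.
#' @export
out_node <- function(level_in, level_td, lower_out, weights,
                     resize = downsample_mean, transform = identity) {
  if (grid_level(level_in) != grid_level(level_td)) {
    stop("level_in and level_td must share a pyramid level", call. = FALSE)
  }
  if (.level_index(grid_level(lower_out)) !=
      .level_index(grid_level(level_in)) - 1L) {
    stop("lower_out must sit one pyramid step below level_in", call. = FALSE)
  }
  resized <- resize(lower_out, level = grid_level(level_in))
  fuse_grids(list(level_in, level_td, resized), weights, transform)
}
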