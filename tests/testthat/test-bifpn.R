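const_grid <- function(v, n = 4, level = "P3") {
  feature_grid(matrix(v, n, n), level)
}

test_that("fast-normalized fusion follows the weighted-sum formula", {
  eps <- 1e-4
  out <- fuse_grids(list(const_grid(3), const_grid(3)),
                    fusion_weights(c(1, 1), eps = eps))
  expect_equal(grid_values(out), matrix(6 / (2 + eps), 4, 4))

  out2 <- fuse_grids(list(const_grid(0), const_grid(2)),
                     fusion_weights(c(1, 1), eps = 0))
  expect_equal(grid_values(out2), matrix(1, 4, 4))

  out3 <- fuse_grids(list(const_grid(5), const_grid(9)),
                     fusion_weights(c(1, 0), eps = 0))
  expect_equal(grid_values(out3), matrix(5, 4, 4))
})

test_that("fusion validates shapes, weights, and levels", {
  expect_error(fuse_grids(list(const_grid(1), const_grid(1, n = 8)),
                          fusion_weights(c(1, 1))), "identical shape")
  expect_error(fuse_grids(list(const_grid(1)), fusion_weights(1)),
               "length")
  expect_error(fuse_grids(list(const_grid(1), const_grid(1)),
                          fusion_weights(c(1, 1, 1))), "one fusion weight")
  expect_error(fuse_grids(list(const_grid(1), const_grid(1, level = "P4")),
                          fusion_weights(c(1, 1))), "level")
  # all-zero weights: defined, near-zero output
  out <- fuse_grids(list(const_grid(7), const_grid(7)),
                    fusion_weights(c(0, 0), eps = 1e-4))
  expect_equal(grid_values(out), matrix(0, 4, 4))
  # negative raw weights are clamped, not propagated
  out2 <- fuse_grids(list(const_grid(5), const_grid(9)),
                     fusion_weights(c(1, -3), eps = 0))
  expect_equal(grid_values(out2), matrix(5, 4, 4))
})

test_that("top-down node fuses the upsampled coarser level", {
  same <- const_grid(2, n = 4, level = "P3")
  higher <- const_grid(2, n = 2, level = "P4")
  eps <- 1e-4
  out <- td_node(same, higher, fusion_weights(c(1, 1), eps = eps))
  expect_equal(grid_values(out), matrix(4 / (2 + eps), 4, 4))
  expect_equal(grid_level(out), "P3")

  # zero weight on the resized input: exactly the same-level feature
  out2 <- td_node(const_grid(3, 4, "P3"), const_grid(8, 2, "P4"),
                  fusion_weights(c(1, 0), eps = 0))
  expect_equal(grid_values(out2), matrix(3, 4, 4))

  m <- feature_grid(matrix(c(0, 4, 2, 6), 2, 2), "P4")  # [[0,2],[4,6]]
  zeros <- const_grid(0, 4, "P3")
  out3 <- td_node(zeros, m, fusion_weights(c(1, 1), eps = 0))
  up <- grid_values(upsample_nearest(m, "P3"))
  expect_equal(grid_values(out3), up / 2)

  expect_error(td_node(const_grid(1, 4, "P3"), const_grid(1, 2, "P5"),
                       fusion_weights(c(1, 1))), "one pyramid step")
})

test_that("bottom-up output node fuses three inputs with downsampling", {
  eps <- 1e-9
  lvl_in <- const_grid(1, 4, "P4")
  lvl_td <- const_grid(2, 4, "P4")
  lower <- const_grid(3, 8, "P3")
  out <- out_node(lvl_in, lvl_td, lower, fusion_weights(c(1, 1, 2), eps = 0))
  expect_equal(grid_values(out), matrix(9 / 4, 4, 4))

  same <- out_node(const_grid(5, 4, "P4"), const_grid(5, 4, "P4"),
                   const_grid(5, 8, "P3"),
                   fusion_weights(c(1, 1, 1), eps = eps))
  expect_equal(grid_values(same), matrix(5, 4, 4), tolerance = 1e-8)

  only3 <- out_node(lvl_in, lvl_td, lower,
                    fusion_weights(c(0, 0, 1), eps = 0))
  expect_equal(grid_values(only3), matrix(3, 4, 4))
})

test_that("resize contracts behave as nearest-neighbour and mean pooling", {
  m <- feature_grid(matrix(1:4, 2, 2), "P4")
  up <- upsample_nearest(m, "P3")
  expect_equal(dim(up), c(4L, 4L))
  expect_equal(grid_values(up)[1:2, 1:2], matrix(1, 2, 2))
  down <- downsample_mean(up, "P4")
  expect_equal(grid_values(down), matrix(as.numeric(1:4), 2, 2))
  expect_error(downsample_mean(feature_grid(matrix(0, 3, 3), "P3")), "even")
})

test_that("fusion is a bounded, permutation-equivariant combination", {
  set.seed(21)
  for (i in 1:50) {
    grids <- lapply(1:3, function(k) {
      feature_grid(matrix(stats::rnorm(16), 4, 4), "P2")
    })
    w <- stats::runif(3, 0, 2)
    out <- fuse_grids(grids, fusion_weights(w, eps = 0))
    lo <- do.call(pmin, lapply(grids, grid_values))
    hi <- do.call(pmax, lapply(grids, grid_values))
    expect_true(all(grid_values(out) >= lo - 1e-12))
    expect_true(all(grid_values(out) <= hi + 1e-12))

    perm <- sample(3)
    out_p <- fuse_grids(grids[perm], fusion_weights(w[perm], eps = 0))
    expect_equal(grid_values(out_p), grid_values(out), tolerance = 1e-12)

    # fixed point: identical inputs are returned unchanged at eps = 0
    fix <- fuse_grids(list(grids[[1]], grids[[1]]),
                      fusion_weights(c(0.3, 1.7), eps = 0))
    expect_equal(grid_values(fix), grid_values(grids[[1]]), tolerance = 1e-12)
  }
})
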