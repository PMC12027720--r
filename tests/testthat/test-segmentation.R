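make_field <- function(W, grid_dims = NULL) {
  # W: n x K matrix in row-major patch order
  if (is.null(grid_dims)) grid_dims <- c(1L, nrow(W))
  arr <- array(0, c(grid_dims, ncol(W)))
  for (k in seq_len(ncol(W)))
    arr[, , k] <- matrix(W[, k], grid_dims[1], grid_dims[2], byrow = TRUE)
  grid <- structure(list(patch_size = 2L, stride = 2L, grid_dims = grid_dims,
                         patch_origins = cbind(
                           rep(seq(1, by = 2, length.out = grid_dims[1]), each = grid_dims[2]),
                           rep(seq(1, by = 2, length.out = grid_dims[2]), grid_dims[1])),
                         image_dims = c(2L * grid_dims[1], 2L * grid_dims[2])),
                    class = "patch_grid")
  structure(list(weights = arr, grid = grid), class = "weight_field")
}

test_that("cluster_patch_weights recovers well-separated blobs exactly", {
  set.seed(1)
  W <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 5, 0.1), 20, 2))
  field <- make_field(W, c(4L, 10L))
  km <- cluster_patch_weights(field, C = 2, seed = 3)
  truth <- rep(1:2, each = 20)
  expect_equal(adjusted_rand_index(km$hard_labels, truth), 1)

  # determinism + brute-force nearest-center assignment
  km2 <- cluster_patch_weights(field, C = 2, seed = 3)
  expect_identical(km$centers, km2$centers)
  d2 <- as.matrix(dist(rbind(W, km$centers)))[1:40, 41:42]
  expect_equal(km$hard_labels, max.col(-d2, ties.method = "first"))

  flat <- make_field(matrix(1, 12, 3), c(3L, 4L))
  expect_error(cluster_patch_weights(flat, C = 2), "degenerate")
  expect_error(cluster_patch_weights(field, C = 99), "patch count")
})

test_that("soft_assignments behaves like a tempered Gaussian kernel", {
  W <- rbind(c(0, 0), c(10, 0), c(5, 5))
  field <- make_field(W)
  centers <- rbind(c(0, 0), c(10, 0))
  q <- soft_assignments(field, centers, tau = 0.1)
  expect_equal(q[1, ], c(1, 0), tolerance = 1e-10)   # at center 0
  expect_equal(q[2, ], c(0, 1), tolerance = 1e-10)
  qInf <- soft_assignments(field, centers, tau = 1e9)
  expect_true(all(abs(qInf - 0.5) < 1e-6))           # flat limit
  qm <- soft_assignments(field, centers)             # median-distance default
  expect_true(all(abs(rowSums(qm) - 1) < 1e-9))
  expect_error(soft_assignments(field, centers, tau = -1), "tau")
})

test_that("render_probability_map normalizes, argmaxes, and is label-symmetric", {
  W <- matrix(rnorm(24 * 3), 24, 3)
  field <- make_field(W, c(4L, 6L))
  C <- 4
  soft <- matrix(1 / C, 24, C)
  rp <- render_probability_map(field$grid, soft)
  expect_true(all(abs(rp$prob$probs - 1 / C) < 1e-12))
  expect_true(all(rp$labels == 0))

  # one-hot patches at s = p give an exact block-constant one-hot map
  oh <- matrix(0, 24, C); oh[cbind(1:24, rep(1:C, 6))] <- 1
  rp2 <- render_probability_map(field$grid, oh)
  sums <- apply(rp2$prob$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_equal(rp2$labels[1, 1], which(oh[1, ] == 1) - 1L)
  expect_true(all(rp2$prob$probs %in% c(0, 1)))

  # permuting classes permutes channels and relabels consistently
  prm <- c(2, 3, 4, 1)
  rp3 <- render_probability_map(field$grid, oh[, prm])
  expect_equal(rp3$prob$probs[, , 1], rp2$prob$probs[, , prm[1]])
  expect_equal(rp2$labels, matrix(prm, 1)[, rp3$labels + 1L] - 1L,
               ignore_attr = TRUE)
})

test_that("probability/label maps write deterministic artifacts", {
  W <- matrix(rnorm(12 * 2), 12, 2)
  field <- make_field(W, c(3L, 4L))
  km <- cluster_patch_weights(field, C = 2, seed = 0)
  soft <- soft_assignments(field, km$centers)
  rp <- render_probability_map(field$grid, soft)
  d1 <- file.path(tempdir(), "pm1"); d2 <- file.path(tempdir(), "pm2")
  p1 <- write_probability_map(rp$prob, rp$labels, d1, hash = "h")
  p2 <- write_probability_map(rp$prob, rp$labels, d2, hash = "h")
  for (i in seq_along(p1))
    expect_identical(readBin(p1[i], "raw", file.size(p1[i])),
                     readBin(p2[i], "raw", file.size(p2[i])))
})
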