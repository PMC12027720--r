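test_that("init_dictionary builds centroid atoms and a deterministic encoder", {
  fx <- fixture_covs_small()
  covs <- fx$covs[1:30]
  m1 <- init_dictionary(covs, 1, seed = 0)
  mean_tan <- Reduce(`+`, lapply(covs, spd_log)) / length(covs)
  expect_equal(m1$atoms[[1]], mean_tan, tolerance = 1e-8)

  m <- init_dictionary(covs, 3, seed = 2)
  expect_identical(m, init_dictionary(covs, 3, seed = 2))
  for (Z in m$atoms) expect_lt(max(abs(Z - t(Z))), 1e-10)
  expect_equal(dim(m$W), c(3, 21))
  expect_error(init_dictionary(covs, 99, seed = 0), "K")
})

test_that("encode_weights is the documented affine map", {
  fx <- fixture_covs_small()
  covs <- fx$covs
  m <- init_dictionary(covs[1:20], 4, seed = 1)
  A <- covs[[5]]
  # brute-force matrix-vector oracle
  z <- tangent_vectorize(spd_log(A))
  manual <- numeric(4)
  for (k in 1:4) manual[k] <- sum(m$W[k, ] * z) + m$bias[k]
  expect_equal(encode_weights(m, A), manual, tolerance = 1e-12)

  # constant encoder
  m0 <- m; m0$W[] <- 0; m0$bias <- c(1, 0, 0, 0)
  expect_equal(encode_weights(m0, A), c(1, 0, 0, 0))

  # affine in the tangent argument
  B <- covs[[9]]
  zB <- tangent_vectorize(spd_log(B))
  wsum <- encode_weights(m, spd_exp(tangent_unvectorize(z + zB)))
  expect_equal(wsum, encode_weights(m, A) + encode_weights(m, B) - m$bias,
               tolerance = 1e-8)
  expect_error(encode_weights(m, diag(3)), "dimension")
})

test_that("reconstruct_spd maps weights back to the manifold", {
  A <- random_spd(5, 50, 3)
  m <- list(atoms = list(spd_log(A)), W = matrix(0, 1, 15), bias = 0,
            alpha = 0, beta = 0, eps = 1e-6, d = 5, K = 1)
  class(m) <- "riem_dictionary"
  expect_lt(norm(reconstruct_spd(m, 1) - A, "F") / norm(A, "F"), 1e-8)
  expect_equal(reconstruct_spd(m, 0), diag(5), tolerance = 1e-12)

  # optimal scalar code beats the identity baseline (line-search oracle)
  sweep_ <- vapply(seq(-0.5, 1.5, by = 0.05), function(w)
    stein_divergence(A, reconstruct_spd(m, w)), numeric(1))
  expect_lte(min(sweep_), stein_divergence(A, diag(5)))

  # fuzz: any real weight vector yields a valid SPD matrix
  fx <- fixture_covs_small()
  md <- init_dictionary(fx$covs[1:15], 3, seed = 4)
  set.seed(8)
  for (r in 1:10) {
    Ahat <- reconstruct_spd(md, rnorm(3, sd = 2))
    expect_lt(max(abs(Ahat - t(Ahat))), 1e-8)
    expect_gt(min(eigen(Ahat, symmetric = TRUE)$values), 0)
  }
})

test_that("dictionary_loss matches the naive double-loop oracle", {
  fx <- fixture_covs_small()
  covs <- fx$covs[1:6]
  grid <- structure(list(patch_size = 16L, stride = 16L, grid_dims = c(2L, 3L),
                         patch_origins = cbind(rep(c(1, 17), each = 3), rep(c(1, 17, 33), 2)),
                         image_dims = c(48L, 48L)), class = "patch_grid")
  m <- init_dictionary(covs, 2, seed = 0, alpha = 0.05, beta = 0.2)
  field <- encode_weight_field(m, covs, grid)
  got <- dictionary_loss(m, covs, field)
  oracle <- naive_dictionary_loss(m, covs, field)
  expect_equal(got$parts$stein, oracle$stein, tolerance = 1e-10)
  expect_equal(got$parts$l1, oracle$l1, tolerance = 1e-10)
  expect_equal(got$parts$smooth, oracle$smooth, tolerance = 1e-10)
  expect_equal(got$total, oracle$total, tolerance = 1e-10)

  # perfect single-atom reconstruction with no penalties -> zero loss
  A <- random_spd(4, 10, 1)
  mp <- structure(list(atoms = list(spd_log(A)), W = matrix(0, 1, 10),
                       bias = 1, alpha = 0, beta = 0, eps = 1e-6, d = 4, K = 1),
                  class = "riem_dictionary")
  g1 <- structure(list(patch_size = 2L, stride = 2L, grid_dims = c(1L, 2L),
                       patch_origins = cbind(c(1, 1), c(1, 3)),
                       image_dims = c(2L, 4L)), class = "patch_grid")
  fld <- structure(list(weights = array(1, c(1, 2, 1)), grid = g1),
                   class = "weight_field")
  pl <- dictionary_loss(mp, list(A, A), fld)
  expect_lt(pl$total, 1e-12)
  # constant weight field has zero smoothness part even with beta > 0
  mp$beta <- 5
  expect_equal(dictionary_loss(mp, list(A, A), fld)$parts$smooth, 0)
})

test_that("analytic gradients match central finite differences", {
  fx <- fixture_covs_small()
  covs <- fx$covs[1:10]
  m <- init_dictionary(covs, 3, seed = 1)
  Zmat <- t(vapply(covs, function(A) tangent_vectorize(spd_log(A)), numeric(21)))
  gr <- riemcell:::.dictionary_loss_grad(m, covs, Zmat, NULL, "stein")
  ev <- function(mm) riemcell:::.dictionary_loss_grad(mm, covs, Zmat, NULL, "stein")$total
  h <- 1e-5
  idx <- order(abs(gr$dW))[length(gr$dW) - 0:4]  # largest-magnitude entries
  for (i in idx) {
    m1 <- m; m1$W[i] <- m1$W[i] + h
    m2 <- m; m2$W[i] <- m2$W[i] - h
    expect_equal((ev(m1) - ev(m2)) / (2 * h), gr$dW[i],
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
  set.seed(5)
  for (k in 1:3) {
    D <- matrix(rnorm(36), 6); D <- (D + t(D)) / 2
    m1 <- m; m1$atoms[[k]] <- m1$atoms[[k]] + h * D
    m2 <- m; m2$atoms[[k]] <- m2$atoms[[k]] - h * D
    expect_equal((ev(m1) - ev(m2)) / (2 * h), sum(gr$dAtoms[[k]] * D),
                 tolerance = 1e-4)
  }
})

test_that("fit_dictionary descends deterministically", {
  A <- random_spd(6, 10, 5)
  covs <- list(A, A, A)
  m <- init_dictionary(covs, 1, seed = 0, alpha = 0, beta = 0)
  # perturb so there is something to learn
  m$atoms[[1]] <- m$atoms[[1]] + 0.3 * diag(6)
  fit <- fit_dictionary(m, covs, NULL, epochs = 200, lr = 0.1)
  expect_length(fit$loss_history, 200)
  expect_lt(fit$final_loss, 1e-4)   # single-point fit drives Stein to ~0

  fx <- fixture_covs_small()
  m2 <- init_dictionary(fx$covs, 3, seed = 2)
  f1 <- fit_dictionary(m2, fx$covs, fx$grid, epochs = 30, lr = 1e-2)
  f2 <- fit_dictionary(m2, fx$covs, fx$grid, epochs = 30, lr = 1e-2)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_lt(f1$final_loss, f1$loss_history[1])
})

test_that("dictionary models survive a JSON round trip", {
  fx <- fixture_covs_small()
  m <- init_dictionary(fx$covs[1:12], 3, seed = 6)
  path <- tempfile(fileext = ".json")
  save_dictionary(m, path, hash = "abc")
  m2 <- load_dictionary(path)
  expect_equal(m2$W, m$W, tolerance = 1e-12)
  expect_equal(m2$atoms, m$atoms, tolerance = 1e-12)
  expect_equal(m2$bias, m$bias, tolerance = 1e-12)
  ww <- encode_weights(m, fx$covs[[1]])
  expect_equal(encode_weights(m2, fx$covs[[1]]), ww, tolerance = 1e-12)
})
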