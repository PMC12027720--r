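test_that("project_to_spd symmetrizes and clamps eigenvalues", {
  eps <- 1e-6
  # forced example: symmetrization then clamp of the zero eigenvalue
  M <- matrix(c(1, 0, 2, 1), 2)
  A <- project_to_spd(M, eps)
  S <- matrix(c(1, 1, 1, 1), 2)
  e <- eigen(S, symmetric = TRUE)
  expected <- e$vectors %*% (pmax(e$values, eps) * t(e$vectors))
  expect_equal(A, expected, tolerance = 1e-12)

  A2 <- project_to_spd(diag(c(1, -1)), eps)
  expect_equal(sort(eigen(A2)$values), c(eps, 1), tolerance = 1e-12)

  # already-SPD input is returned unchanged; projection is idempotent
  B <- random_spd(4, 10, 1)
  expect_equal(project_to_spd(B, eps), B, tolerance = 1e-10)
  M3 <- matrix(rnorm(25), 5)
  expect_equal(project_to_spd(project_to_spd(M3, eps), eps),
               project_to_spd(M3, eps), tolerance = 1e-10)

  expect_error(project_to_spd(matrix(1, 2, 3)), "square")
  expect_error(project_to_spd(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("spd_log / spd_exp are mutual inverses with the expected diagonal action", {
  expect_equal(spd_log(diag(2)), matrix(0, 2, 2))
  expect_equal(spd_log(diag(c(4, 1))), diag(c(log(4), 0)), tolerance = 1e-12)
  expect_equal(spd_exp(matrix(0, 3, 3)), diag(3))
  expect_equal(spd_exp(diag(c(log(2), log(3)))), diag(c(2, 3)), tolerance = 1e-12)

  for (s in 1:5) {
    A <- random_spd(5, 100, s)
    expect_lt(norm(spd_exp(spd_log(A)) - A, "F") / norm(A, "F"), 1e-8)
    Y <- spd_log(random_spd(4, 50, s + 10))
    expect_lt(norm(spd_log(spd_exp(Y)) - Y, "F") / max(norm(Y, "F"), 1e-12), 1e-8)
  }
  expect_error(spd_exp(matrix(2000, 1, 1)), "overflow")
})

test_that("tangent vectorization is a linear isometry with exact inverse", {
  Y <- diag(c(3, 7))
  expect_equal(tangent_vectorize(Y), c(3, 0, 7))
  for (s in 1:5) {
    Y1 <- spd_log(random_spd(5, 30, s)); Y2 <- spd_log(random_spd(5, 30, s + 50))
    expect_equal(sum(tangent_vectorize(Y1) * tangent_vectorize(Y2)),
                 sum(diag(Y1 %*% Y2)), tolerance = 1e-10)  # trace oracle
    expect_equal(tangent_unvectorize(tangent_vectorize(Y1)), Y1,
                 tolerance = 1e-14)  # exact up to one ulp of the sqrt(2) scaling
  }
  expect_error(tangent_unvectorize(1:4), "d\\(d\\+1\\)/2")
})

test_that("Stein divergence has its defining properties", {
  expect_equal(stein_divergence(diag(2), diag(c(4, 1))),
               log(2.5) - 0.5 * log(4), tolerance = 1e-12)
  set.seed(99)
  for (s in 1:5) {
    A <- random_spd(4, 100, s); B <- random_spd(4, 100, s + 20)
    expect_equal(stein_divergence(A, A), 0, tolerance = 1e-10)
    expect_gte(stein_divergence(A, B), 0)
    expect_equal(stein_divergence(A, B), stein_divergence(B, A), tolerance = 1e-10)
    M <- matrix(rnorm(16), 4)  # random invertible congruence
    expect_equal(stein_divergence(M %*% A %*% t(M), M %*% B %*% t(M)),
                 stein_divergence(A, B), tolerance = 1e-8)
  }
  expect_error(stein_divergence(diag(2), diag(3)), "dimension")
})

test_that("cholesky_factor returns the lower-triangular root", {
  expect_equal(cholesky_factor(diag(3)), diag(3))
  L <- cholesky_factor(matrix(c(4, 2, 2, 2), 2))
  expect_equal(L, matrix(c(2, 1, 0, 1), 2), tolerance = 1e-12)
  for (s in 1:5) {
    A <- random_spd(5, 1000, s)
    L <- cholesky_factor(A)
    expect_true(all(diag(L) > 0))
    expect_true(all(L[upper.tri(L)] == 0))
    expect_lt(norm(L %*% t(L) - A, "F") / norm(A, "F"), 1e-8)
  }
  expect_error(cholesky_factor(diag(c(1, -1))), "positive definite")
})

test_that("patch_covariance centers, regularizes, and matches the naive oracle", {
  eps <- 1e-6
  X <- matrix(5, 3, 10)
  expect_equal(patch_covariance(X, eps), diag(eps, 3), tolerance = 1e-12)
  expect_equal(patch_covariance(matrix(c(0, 2), 1, 2), eps),
               matrix(2 + eps, 1, 1), tolerance = 1e-12)
  set.seed(42)
  X <- matrix(rnorm(6 * 40), 6, 40)
  expect_equal(patch_covariance(X, eps), naive_covariance(X, eps), tolerance = 1e-10)
  expect_error(patch_covariance(matrix(1, 3, 1)), "2 pixels")
})
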