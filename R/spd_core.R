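#' @useDynLib riemcell, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd kmeans dist
NULL

# ---- SPD-manifold primitives ------------------------------------------------
#
# A "SPD matrix" in this package is a plain numeric d x d matrix that is
# symmetric and has all eigenvalues >= some floor eps.  project_to_spd() is the
# only constructor that guarantees this; everything downstream assumes it.

.check_square <- function(M, what = "M") {
  if (!is.matrix(M) || nrow(M) != ncol(M))
    stop(sprintf("'%s' must be a square matrix", what), call. = FALSE)
  if (!all(is.finite(M)))
    stop(sprintf("'%s' contains non-finite entries", what), call. = FALSE)
  invisible(M)
}

#' Project a square matrix onto the SPD cone
#'
#' Symmetrizes the input, `A = (M + t(M)) / 2`, eigendecomposes `A = Q L Q'`,
#' and clamps every eigenvalue below `eps` up to `eps`.  The result is the
#' canonical entry point to the SPD manifold: every covariance descriptor in
#' the package passes through it.
#'
#' @param M square numeric matrix with finite entries.
#' @param eps positive eigenvalue floor (default `1e-6`).
#' @return A symmetric matrix with smallest eigenvalue `>= eps`.
#' @examples
#' project_to_spd(diag(c(1, -1)))        # -1 clamped to eps
#' @export
project_to_spd <- function(M, eps = 1e-6) {
  .check_square(M)
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0)
  A <- (M + t(M)) / 2
  e <- eigen(A, symmetric = TRUE)
  lam <- pmax(e$values, eps)
  A2 <- e$vectors %*% (lam * t(e$vectors))
  (A2 + t(A2)) / 2
}

#' Matrix logarithm of an SPD matrix
#'
#' Maps an SPD matrix to the tangent space at the identity:
#' `log A = U diag(log sigma_i) U'` with `A = U diag(sigma_i) U'`.
#'
#' @param A SPD matrix (as produced by [project_to_spd()]).
#' @return A symmetric matrix (tangent-space element).
#' @export
spd_log <- function(A) {
  .check_square(A, "A")
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("spd_log: input is not positive definite (eigenvalue <= 0)", call. = FALSE)
  Y <- e$vectors %*% (log(e$values) * t(e$vectors))
  (Y + t(Y)) / 2
}

#' Matrix exponential of a symmetric matrix
#'
#' Inverse of [spd_log()]: `exp Y = V diag(exp gamma_i) V'`.  Always returns an
#' SPD matrix for symmetric finite input; signals an error instead of returning
#' non-finite values when entries of `Y` are extreme.
#'
#' @param Y symmetric numeric matrix.
#' @return An SPD matrix.
#' @export
spd_exp <- function(Y) {
  .check_square(Y, "Y")
  e <- eigen((Y + t(Y)) / 2, symmetric = TRUE)
  ex <- exp(e$values)
  if (!all(is.finite(ex)))
    stop("spd_exp: overflow in matrix exponential (eigenvalue too large)", call. = FALSE)
  A <- e$vectors %*% (ex * t(e$vectors))
  (A + t(A)) / 2
}

#' Isometric vectorization of a symmetric matrix
#'
#' Flattens the upper triangle of a symmetric `d x d` matrix to a vector of
#' length `d (d + 1) / 2`, scaling off-diagonal entries by `sqrt(2)` so that the
#' Euclidean inner product of two vectors equals the Frobenius inner product
#' `sum(Y1 * Y2)` of the matrices.  [tangent_unvectorize()] is the exact
#' inverse.
#'
#' @param Y symmetric numeric matrix.
#' @return Numeric vector of length `d (d + 1) / 2`, ordered along stacked
#'   upper-triangle rows: `(1,1), (1,2), ..., (1,d), (2,2), ...`.
#' @export
tangent_vectorize <- function(Y) {
  .check_square(Y, "Y")
  # row-wise upper triangle via the transpose: stable, documented order
  ut <- which(lower.tri(Y, diag = TRUE))
  Yt <- t(Y)
  scl <- ifelse(row(Y)[ut] == col(Y)[ut], 1, sqrt(2))
  as.numeric(Yt[ut] * scl)
}

#' @rdname tangent_vectorize
#' @param v numeric vector of length `d (d + 1) / 2`.
#' @param d matrix dimension; inferred from `length(v)` when missing.
#' @export
tangent_unvectorize <- function(v, d = NULL) {
  if (is.null(d)) d <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(d - round(d)) > 1e-8 || length(v) != d * (d + 1) / 2)
    stop("tangent_unvectorize: length(v) is not d(d+1)/2 for any integer d", call. = FALSE)
  d <- as.integer(round(d))
  Y <- matrix(0, d, d)
  ut <- which(lower.tri(Y, diag = TRUE))
  scl <- ifelse(row(Y)[ut] == col(Y)[ut], 1, sqrt(2))
  Yt <- t(Y)
  Yt[ut] <- v / scl
  Y <- t(Yt)
  Y[lower.tri(Y)] <- t(Y)[lower.tri(Y)]
  Y
}

.logdet_chol <- function(A) {
  L <- tryCatch(chol(A), error = function(e)
    stop("log-determinant: matrix is not positive definite", call. = FALSE))
  2 * sum(log(diag(L)))
}

#' Stein divergence between SPD matrices
#'
#' The symmetric Jensen-Bregman LogDet divergence
#' `S(A, B) = log det((A + B) / 2) - 1/2 log det(A) - 1/2 log det(B)`,
#' computed through Cholesky-based log-determinants.  It is nonnegative,
#' symmetric in its arguments, zero iff `A == B`, and invariant under
#' congruence `A -> M A M'`.
#'
#' @param A,B SPD matrices of equal dimension.
#' @return Nonnegative scalar.
#' @examples
#' stein_divergence(diag(2), diag(c(4, 1)))  # log 2.5 - 0.5 log 4
#' @export
stein_divergence <- function(A, B) {
  .check_square(A, "A"); .check_square(B, "B")
  if (nrow(A) != nrow(B))
    stop("stein_divergence: dimension mismatch", call. = FALSE)
  v <- .logdet_chol((A + B) / 2) - 0.5 * .logdet_chol(A) - 0.5 * .logdet_chol(B)
  max(v, 0)  # clip tiny negative round-off
}

#' Cholesky factor of an SPD matrix
#'
#' Lower-triangular `L` with positive diagonal such that `L %*% t(L) == A`.
#' Offered as the fast positive-definiteness check / log-determinant route; the
#' log/exp eigendecomposition remains the canonical tangent-space map.
#'
#' @param A SPD matrix.
#' @return Lower-triangular matrix `L`.
#' @export
cholesky_factor <- function(A) {
  .check_square(A, "A")
  U <- tryCatch(chol((A + t(A)) / 2), error = function(e)
    stop("cholesky_factor: input is not positive definite", call. = FALSE))
  t(U)
}

#' Regularized covariance of a feature-by-pixel matrix
#'
#' Sample covariance of the columns of `X` (features in rows, pixels in
#' columns): rows are centered, then
#' `Cov = (X - Xbar)(X - Xbar)' / (n - 1) + eps I`, and the result is passed
#' through [project_to_spd()] so it is a valid manifold element even for
#' degenerate patches (e.g. constant intensity).
#'
#' @param X numeric matrix, `d` feature rows by `n >= 2` pixel columns.
#' @param eps eigenvalue floor added as `eps * I` and enforced by projection.
#' @return `d x d` SPD matrix.
#' @export
patch_covariance <- function(X, eps = 1e-6) {
  if (!is.matrix(X) || !all(is.finite(X)))
    stop("patch_covariance: X must be a finite numeric matrix", call. = FALSE)
  n <- ncol(X)
  if (n < 2) stop("patch_covariance: need at least 2 pixels", call. = FALSE)
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (n - 1) + diag(eps, nrow(X))
  project_to_spd(C, eps)
}
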