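# ---- small shared utilities -------------------------------------------------

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.  Every stochastic operation in the package funnels
# through this so that a single integer seed fixes a whole run.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a run seed
#'
#' The documented seed-splitting rule of the pipeline: stage `k` of a run
#' seeded with `seed` uses `derive_seed(seed, k)` (k Lehmer steps, so every
#' derived seed stays inside the 32-bit integer range).
#'
#' @param seed integer run seed.
#' @param k stage index (`>= 1`).
#' @return A deterministic integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# 3x3 binomial blur with reflective borders (shared by the speckle texture and
# the autoencoder's input-noise augmentation).
blur3 <- function(img) {
  k <- c(1, 2, 1) / 4
  pad <- function(m) rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  conv_rows <- function(m) {
    p <- pad(m)
    k[1] * p[1:nrow(m), , drop = FALSE] +
      k[2] * p[2:(nrow(m) + 1), , drop = FALSE] +
      k[3] * p[3:(nrow(m) + 2), , drop = FALSE]
  }
  t(conv_rows(t(conv_rows(img))))
}

# Boolean mask of an ellipse with center (cy, cx) [1-based, pixel centers],
# semi-axes (a, b) along the rotated frame, rotation `theta` (radians).
ellipse_mask <- function(h, w, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * xx + sin(theta) * yy
  v <- -sin(theta) * xx + cos(theta) * yy
  (u / a)^2 + (v / b)^2 <= 1
}

#' Adjusted Rand index between two labelings
#'
#' Standard permutation-model-corrected agreement between two partitions of
#' the same items; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones.  Used throughout the test battery to score recovery of
#' known texture or shape classes.
#'
#' @param a,b integer vectors of equal length (any label coding).
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

# Write a numeric matrix as CSV with a metadata comment line (config hash);
# readers use comment.char = "#".  Fixed 15-digit formatting keeps reruns
# byte-identical.
write_matrix_csv <- function(m, path, hash = NULL, col_names = NULL) {
  con <- file(path, "wb")  # binary mode: LF line endings on every platform
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  if (!is.null(col_names)) writeLines(paste(col_names, collapse = ","), con)
  apply_fmt <- function(row) paste(formatC(row, digits = 15, format = "g"), collapse = ",")
  writeLines(vapply(seq_len(nrow(m)), function(i) apply_fmt(m[i, ]), ""), con)
  invisible(path)
}
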