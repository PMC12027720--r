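# ---- per-patch covariance descriptors ---------------------------------------
#
# An image becomes a FeatureStack (d feature planes), the stack a row-major
# PatchGrid of p x p patches with stride s, each patch a d x p^2 matrix whose
# covariance is the local SPD descriptor (region-covariance tradition).

# centered finite differences with reflective borders, along rows (dy) / cols (dx)
.diff_rows <- function(img) {
  h <- nrow(img)
  up <- img[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- img[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  (dn - up) / 2
}
.diff_cols <- function(img) t(.diff_rows(t(img)))

#' Per-pixel feature planes for covariance descriptors
#'
#' The default feature set `"derivatives6"` is a fixed, deterministic
#' differential filter bank: intensity, gradient magnitude, first derivatives
#' `dx`, `dy`, and second derivatives `dxx`, `dyy` (centered differences,
#' reflective borders), `d = 6`.  A fixed bank keeps the descriptor pipeline
#' fully reproducible; a learnable front-end can be slotted in later via a new
#' feature-set name.
#'
#' @param image 2-D numeric array (single channel, finite).
#' @param feature_set feature set name; only `"derivatives6"` is built in.
#' @return Object of class `feature_stack`: list with `channels` (list of d
#'   H x W matrices) and `feature_names`.
#' @export
feature_stack <- function(image, feature_set = "derivatives6") {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (!identical(feature_set, "derivatives6"))
    stop(sprintf("unknown feature_set '%s'", feature_set), call. = FALSE)
  dy <- .diff_rows(image); dx <- .diff_cols(image)
  dyy <- .diff_rows(dy);   dxx <- .diff_cols(dx)
  gm <- sqrt(dx^2 + dy^2)
  structure(list(channels = list(image, gm, dx, dy, dxx, dyy),
                 feature_names = c("intensity", "gradmag", "dx", "dy", "dxx", "dyy")),
            class = "feature_stack")
}

#' Unfold a feature stack into patches
#'
#' Patches of size `patch_size` are laid on a stride lattice starting at the
#' top-left corner and enumerated row-major.  When the right/bottom margin
#' does not fit a full patch, one extra patch clamped to the image edge covers
#' it, so every pixel belongs to at least one patch (required by
#' [fold_patches()]).
#'
#' @param stack a `feature_stack`.
#' @param patch_size patch side `p` in pixels (`<= min(H, W)`).
#' @param stride stride `s >= 1` in pixels.
#' @return List with `grid` (class `patch_grid`: `patch_size`, `stride`,
#'   `grid_dims` = c(rows, cols), `patch_origins` = n x 2 matrix of 1-based
#'   top-left corners, `image_dims`) and `patches` (list of d x p^2 matrices,
#'   columns in row-major pixel order within the patch).
#' @export
extract_patches <- function(stack, patch_size = 16, stride = 8) {
  stopifnot(inherits(stack, "feature_stack"), stride >= 1)
  H <- nrow(stack$channels[[1]]); W <- ncol(stack$channels[[1]])
  if (patch_size > min(H, W))
    stop("extract_patches: patch_size exceeds image dimension", call. = FALSE)
  starts <- function(n) {
    s <- seq.int(1L, max(1L, n - patch_size + 1L), by = stride)
    if (s[length(s)] + patch_size - 1L < n) s <- c(s, n - patch_size + 1L)
    s
  }
  ys <- starts(H); xs <- starts(W)
  origins <- cbind(rep(ys, each = length(xs)), rep(xs, times = length(ys)))
  grid <- structure(list(patch_size = as.integer(patch_size),
                         stride = as.integer(stride),
                         grid_dims = c(length(ys), length(xs)),
                         patch_origins = origins,
                         image_dims = c(H, W)),
                    class = "patch_grid")
  d <- length(stack$channels)
  p <- patch_size
  patches <- lapply(seq_len(nrow(origins)), function(i) {
    y0 <- origins[i, 1]; x0 <- origins[i, 2]
    X <- matrix(0, d, p * p)
    for (k in seq_len(d)) {
      blk <- stack$channels[[k]][y0:(y0 + p - 1), x0:(x0 + p - 1)]
      X[k, ] <- as.numeric(t(blk))  # row-major pixel order
    }
    X
  })
  list(grid = grid, patches = patches)
}

#' Covariance descriptor for every patch
#'
#' @param stack a `feature_stack`.
#' @param grid a `patch_grid` from [extract_patches()] (or `NULL` to build one
#'   with the given `patch_size`/`stride`).
#' @param eps eigenvalue floor passed to [patch_covariance()].
#' @param patch_size,stride used only when `grid` is `NULL`.
#' @return List of SPD matrices, one per patch, in grid (row-major) order.
#' @export
patch_covariance_grid <- function(stack, grid = NULL, eps = 1e-6,
                                  patch_size = 16, stride = 8) {
  if (is.null(grid)) {
    ex <- extract_patches(stack, patch_size, stride)
  } else {
    ex <- extract_patches(stack, grid$patch_size, grid$stride)
    if (!identical(ex$grid$grid_dims, grid$grid_dims))
      stop("patch_covariance_grid: grid does not match the stack", call. = FALSE)
  }
  lapply(ex$patches, patch_covariance, eps = eps)
}

#' Fold per-patch values back into spatial maps
#'
#' Every patch paints its value vector uniformly over its footprint;
#' overlapping footprints are averaged pixel-wise (sum / coverage count).
#' With edge-clamped extraction every pixel is covered at least once.
#'
#' @param grid a `patch_grid`.
#' @param per_patch_values numeric matrix `n_patches x C` (or a vector for
#'   `C = 1`), rows in grid order.
#' @param out_shape `(H, W)`; defaults to the grid's image dims.
#' @return 3-D array `H x W x C`.
#' @export
fold_patches <- function(grid, per_patch_values, out_shape = grid$image_dims) {
  stopifnot(inherits(grid, "patch_grid"))
  if (is.vector(per_patch_values)) per_patch_values <- matrix(per_patch_values, ncol = 1)
  n <- nrow(grid$patch_origins)
  if (nrow(per_patch_values) != n)
    stop("fold_patches: need one value vector per patch", call. = FALSE)
  H <- out_shape[1]; W <- out_shape[2]; C <- ncol(per_patch_values)
  p <- grid$patch_size
  acc <- array(0, c(H, W, C))
  cov_cnt <- matrix(0, H, W)
  for (i in seq_len(n)) {
    y <- grid$patch_origins[i, 1]:(grid$patch_origins[i, 1] + p - 1)
    x <- grid$patch_origins[i, 2]:(grid$patch_origins[i, 2] + p - 1)
    cov_cnt[y, x] <- cov_cnt[y, x] + 1
    for (c_ in seq_len(C))
      acc[y, x, c_] <- acc[y, x, c_] + per_patch_values[i, c_]
  }
  if (any(cov_cnt == 0))
    stop("fold_patches: coverage gap - grid/shape mismatch", call. = FALSE)
  for (c_ in seq_len(C)) acc[, , c_] <- acc[, , c_] / cov_cnt
  acc
}

# Majority ground-truth class per patch (for recovery scoring): the most
# frequent label inside each patch footprint, lowest label on ties.
patch_majority_labels <- function(grid, label_map) {
  p <- grid$patch_size
  vapply(seq_len(nrow(grid$patch_origins)), function(i) {
    y <- grid$patch_origins[i, 1]:(grid$patch_origins[i, 1] + p - 1)
    x <- grid$patch_origins[i, 2]:(grid$patch_origins[i, 2] + p - 1)
    tab <- table(label_map[y, x])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
}
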