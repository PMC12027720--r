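# ---- unsupervised segmentation from the weight field ------------------------
#
# The learned per-patch weight vectors are clustered with K-Means; distances
# to the cluster centers become per-patch class probabilities via a Gaussian
# kernel; folding the per-patch probability vectors back to pixel space (with
# overlap averaging and per-pixel renormalization) yields the probability map
# and its argmax label map.

#' Cluster patch weight vectors with K-Means
#'
#' K-Means++ initialization, 10 restarts, best within-cluster inertia kept;
#' assignment ties go to the lowest center index.  Deterministic per seed.
#'
#' @param field a `weight_field`.
#' @param C number of classes, `2 <= C <=` number of patches.
#' @param seed integer seed.
#' @param restarts number of K-Means++ restarts (default 10).
#' @return List `centers` (C x K matrix), `hard_labels` (per patch, 1-based,
#'   grid row-major order), `inertia`.
#' @export
cluster_patch_weights <- function(field, C = 5, seed = 0, restarts = 10) {
  stopifnot(inherits(field, "weight_field"), C >= 2)
  Om <- field_as_matrix(field)
  if (C > nrow(Om)) stop("cluster_patch_weights: C exceeds patch count", call. = FALSE)
  if (max(apply(Om, 2, function(x) diff(range(x)))) < 1e-12)
    stop("cluster_patch_weights: degenerate weight field (all patches identical)",
         call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      fit <- .lloyd(Om, .kmeanspp_centers(Om, C))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    list(centers = best$centers, hard_labels = best$cluster, inertia = best$inertia)
  })
}

#' Soft class assignments from distances to cluster centers
#'
#' `q_c` proportional to `exp(-||omega - center_c||^2 / (2 tau^2))`,
#' normalized to sum 1 per patch.  `tau` defaults to the median distance from
#' a patch to its nearest center (a scale-free choice); as `tau -> 0` this
#' approaches the hard K-Means one-hot assignment, as `tau -> Inf` the
#' uniform distribution.
#'
#' @param field a `weight_field`.
#' @param centers C x K center matrix from [cluster_patch_weights()].
#' @param tau positive temperature, or `NULL` for the median-nearest-distance
#'   default.
#' @return `n_patches x C` matrix of per-patch class probabilities.
#' @export
soft_assignments <- function(field, centers, tau = NULL) {
  Om <- field_as_matrix(field)
  d2 <- outer(rowSums(Om^2), rep(1, nrow(centers))) -
    2 * Om %*% t(centers) + outer(rep(1, nrow(Om)), rowSums(centers^2))
  d2 <- pmax(d2, 0)
  if (is.null(tau)) tau <- max(sqrt(stats::median(apply(d2, 1, min))), 1e-8)
  stopifnot(tau > 0)
  lg <- -d2 / (2 * tau^2)
  lg <- lg - apply(lg, 1, max)        # log-sum-exp stabilization
  q <- exp(lg)
  q / rowSums(q)
}

#' Render per-pixel probability and label maps
#'
#' Folds per-patch class-probability vectors to pixel space with overlap
#' averaging, renormalizes every pixel to sum 1, and takes the per-pixel
#' argmax (lowest class index on ties) as the label map.
#'
#' @param grid a `patch_grid`.
#' @param soft `n_patches x C` matrix from [soft_assignments()].
#' @param out_shape `(H, W)`, default the grid's image size.
#' @return List `prob` (class `probability_map`: `probs` H x W x C array,
#'   `class_count`) and `labels` (H x W integer matrix, classes `0..C-1`).
#' @export
render_probability_map <- function(grid, soft, out_shape = grid$image_dims) {
  probs <- fold_patches(grid, soft, out_shape)
  C <- dim(probs)[3]
  sums <- apply(probs, c(1, 2), sum)
  for (c_ in seq_len(C)) probs[, , c_] <- probs[, , c_] / sums
  flat <- matrix(probs, ncol = C)
  lab <- matrix(max.col(flat, ties.method = "first") - 1L,
                dim(probs)[1], dim(probs)[2])
  list(prob = structure(list(probs = probs, class_count = C),
                        class = "probability_map"),
       labels = lab)
}

#' Write probability and label maps to disk
#'
#' Per-class probability planes as full-precision CSVs (plain-text stand-in
#' for a multi-channel TIFF), the label map as an 8-bit PNG plus a JSON class
#' legend.
#'
#' @param pm a `probability_map`.
#' @param labels integer label matrix.
#' @param out_prefix path prefix.
#' @param hash optional config hash.
#' @return Invisibly, the paths written.
#' @export
write_probability_map <- function(pm, labels, out_prefix, hash = NULL) {
  C <- pm$class_count
  paths <- character(0)
  for (c_ in seq_len(C)) {
    p <- sprintf("%s_prob_class%d.csv", out_prefix, c_ - 1L)
    write_matrix_csv(pm$probs[, , c_], p, hash = hash)
    paths <- c(paths, p)
  }
  lp <- paste0(out_prefix, "_labels.png")
  png::writePNG(labels / max(1L, max(labels)), lp)
  jp <- paste0(out_prefix, "_legend.json")
  jsonlite::write_json(list(config_hash = hash, classes = 0:(C - 1L),
                            png_scale = max(1L, max(labels))),
                       jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, lp, jp))
}
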