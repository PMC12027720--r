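# ---- 2-D embedding and density clustering -----------------------------------

#' Project latent vectors to 2-D with Barnes-Hut t-SNE (cosine metric)
#'
#' Input affinities are computed from pairwise cosine distances
#' `1 - <u, v> / (|u||v|)` (for unit-norm latents simply `1 - <u, v>`); the
#' low-dimensional forces use the Barnes-Hut approximation with
#' `theta = 0.5`.  Output is centered at the origin.  Deterministic per seed.
#'
#' @param latents numeric matrix `n x d` (rows are cells).
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity`.
#' @param seed integer seed.
#' @param theta Barnes-Hut accuracy/speed trade-off (default 0.5).
#' @param max_iter gradient iterations (default 1000).
#' @return Numeric matrix `n x 2`, column means zero.
#' @export
tsne_project <- function(latents, perplexity = 30, seed = 0, theta = 0.5,
                         max_iter = 1000) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  if (n <= 3 * perplexity)
    stop("tsne_project: need n > 3 * perplexity points", call. = FALSE)
  nrm <- sqrt(rowSums(latents^2)); nrm[nrm < 1e-12] <- 1
  U <- latents / nrm
  D <- 1 - tcrossprod(U)
  D[D < 0] <- 0
  diag(D) <- 0
  fit <- with_seed(seed,
    Rtsne::Rtsne(stats::as.dist(D), is_distance = TRUE, dims = 2,
                 perplexity = perplexity, theta = theta, max_iter = max_iter,
                 verbose = FALSE))
  Y <- fit$Y
  sweep(Y, 2, colMeans(Y))
}

# ---- HDBSCAN ----------------------------------------------------------------
#
# Authored here because no package in the supported environment provides it.
# Standard construction: core distances at min_samples, mutual-reachability
# distances, minimum spanning tree, single-linkage hierarchy, condensation at
# min_cluster_size, excess-of-mass cluster selection; leftover points are
# noise (-1).  Validated against constructed ground truth in the test suite.

#' HDBSCAN clustering of low-dimensional points
#'
#' @param points numeric matrix `n x d` (typically a 2-D embedding).
#' @param min_cluster_size smallest cluster considered real (`>= 2`).
#' @param min_samples smoothing parameter for core distances (default equal
#'   to `min_cluster_size`).
#' @return Integer vector of labels: `-1` = noise, clusters numbered from 0.
#' @export
hdbscan_cluster <- function(points, min_cluster_size, min_samples = min_cluster_size) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 2, min_cluster_size >= 2)
  min_samples <- min(min_samples, n - 1)
  D <- as.matrix(stats::dist(points))
  core <- apply(D, 1, function(r) sort(r)[min_samples + 1])  # self excluded
  MR <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(MR) <- 0

  # Prim MST on the dense mutual-reachability graph
  in_tree <- rep(FALSE, n); in_tree[1] <- TRUE
  best_w <- MR[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & MR[j, ] < best_w
    best_from[upd] <- j; best_w[upd] <- MR[j, upd]
  }
  edges <- edges[order(edges[, 3]), , drop = FALSE]

  # single-linkage hierarchy (union-find); internal nodes n+1 .. 2n-1
  parent <- integer(2 * n - 1)
  uf <- seq_len(2 * n - 1)
  find <- function(i) { while (uf[i] != i) { uf[i] <<- uf[uf[i]]; i <- uf[i] }; i }
  node_dist <- numeric(2 * n - 1)
  node_size <- c(rep(1L, n), integer(n - 1))
  children <- vector("list", 2 * n - 1)
  nxt <- n
  for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    nxt <- nxt + 1L
    parent[ra] <- nxt; parent[rb] <- nxt
    uf[ra] <- nxt; uf[rb] <- nxt
    node_dist[nxt] <- edges[e, 3]
    node_size[nxt] <- node_size[ra] + node_size[rb]
    children[[nxt]] <- c(ra, rb)
  }
  root <- 2L * n - 1L
  lam <- function(d) 1 / max(d, 1e-12)

  # ---- condense the hierarchy at min_cluster_size ----
  cl_parent <- integer(0); cl_birth <- numeric(0); cl_stab <- numeric(0)
  cl_children <- list()
  point_cluster <- integer(n); point_lambda <- numeric(n)
  new_cluster <- function(parent_id, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent_id
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_children) + 1L]] <<- integer(0)
    id <- length(cl_parent)
    if (parent_id > 0) cl_children[[parent_id]] <<- c(cl_children[[parent_id]], id)
    id
  }
  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v) else stack <- c(stack, children[[v]])
    }
    out
  }
  root_cl <- new_cluster(0L, 0)
  stack <- list(c(root, root_cl))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1]; cid <- top[2]
    repeat {
      ch <- children[[node]]
      sz <- node_size[ch]
      lambda_here <- lam(node_dist[node])
      big <- ch[sz >= min_cluster_size]
      if (length(big) == 2) {
        # true split: all remaining points leave cid here
        cl_stab[cid] <- cl_stab[cid] + node_size[node] * (lambda_here - cl_birth[cid])
        for (b in seq_len(2))
          stack[[length(stack) + 1L]] <- c(ch[b], new_cluster(cid, lambda_here))
        break
      }
      small <- setdiff(ch, big)
      for (sn in small) {
        pts <- leaves_under(sn)
        point_cluster[pts] <- cid
        point_lambda[pts] <- lambda_here
        cl_stab[cid] <- cl_stab[cid] + length(pts) * (lambda_here - cl_birth[cid])
      }
      if (length(big) == 0) break
      node <- big  # single surviving child: same condensed cluster
    }
  }
  ncl <- length(cl_parent)

  # ---- excess-of-mass selection (root excluded) ----
  selected <- rep(FALSE, ncl)
  score <- cl_stab
  for (cid in rev(seq_len(ncl))) {   # children have larger ids than parents
    kids <- cl_children[[cid]]
    if (length(kids) == 0) { selected[cid] <- cid != 1L; next }
    kid_sum <- sum(score[kids])
    if (cl_stab[cid] >= kid_sum && cid != 1L) {
      selected[cid] <- TRUE
      # deselect all descendants
      st <- kids
      while (length(st)) {
        v <- st[length(st)]; st <- st[-length(st)]
        selected[v] <- FALSE
        st <- c(st, cl_children[[v]])
      }
    } else score[cid] <- max(score[cid], kid_sum)
  }

  # ---- labels: nearest selected ancestor of each point's record ----
  labels <- rep(-1L, n)
  sel_map <- integer(ncl)
  next_lab <- 0L
  for (p in seq_len(n)) {
    cid <- point_cluster[p]
    while (cid > 0 && !selected[cid]) cid <- cl_parent[cid]
    if (cid > 0) {
      if (sel_map[cid] == 0L) { next_lab <- next_lab + 1L; sel_map[cid] <- next_lab }
      labels[p] <- sel_map[cid] - 1L
    }
  }
  labels
}

#' Cluster a 2-D embedding with the 1-2% minimum-cluster-size rule
#'
#' HDBSCAN with `min cluster size = max(5, round(min_cluster_frac * n))`;
#' the default fraction 0.02 reflects the 2% rule-of-thumb for single-cell
#' embeddings.  Points outside every selected cluster get label `-1`.
#'
#' @param points numeric matrix `n x 2` (`n >= 10`).
#' @param min_cluster_frac fraction of `n` used as minimum cluster size,
#'   `0 < frac < 1` (default 0.02).
#' @return Integer label vector (`-1` = noise).
#' @export
cluster_embeddings <- function(points, min_cluster_frac = 0.02) {
  points <- as.matrix(points)
  stopifnot(min_cluster_frac > 0, min_cluster_frac < 1)
  if (nrow(points) < 10)
    stop("cluster_embeddings: need at least 10 points", call. = FALSE)
  mcs <- max(5L, as.integer(round(min_cluster_frac * nrow(points))))
  hdbscan_cluster(points, mcs)
}

#' Per-cluster morphology statistics
#'
#' For every non-noise cluster: number of cells, mean original mask area
#' (pixels, measured before the 128 x 128 resize), and the standard error of
#' the mean `sd / sqrt(n)` (sd with the `n - 1` denominator).  Optionally an
#' equal-size random subsample is drawn from every cluster first, so clusters
#' of different sizes are compared on equal footing.
#'
#' @param labels integer labels (`-1` = noise), one per crop.
#' @param crops list of `cell_crop` objects aligned with `labels`.
#' @param equal_n if `TRUE`, subsample every cluster to the smallest cluster
#'   size (seeded).
#' @param seed seed for the subsampling draw.
#' @return `data.frame` with columns `cluster`, `n`, `mean_area`, `sem_area`,
#'   noise excluded.
#' @export
cluster_area_stats <- function(labels, crops, equal_n = FALSE, seed = 0) {
  stopifnot(length(labels) == length(crops))
  areas <- vapply(crops, function(cr) as.numeric(cr$orig_area), numeric(1))
  keep <- labels >= 0
  labs <- sort(unique(labels[keep]))
  if (length(labs) == 0)
    return(data.frame(cluster = integer(0), n = integer(0),
                      mean_area = numeric(0), sem_area = numeric(0)))
  idx_by <- lapply(labs, function(l) which(labels == l))
  if (equal_n) {
    m <- min(lengths(idx_by))
    idx_by <- with_seed(seed, lapply(idx_by, function(ix) sort(sample(ix, m))))
  }
  data.frame(
    cluster = labs,
    n = lengths(idx_by),
    mean_area = vapply(idx_by, function(ix) mean(areas[ix]), numeric(1)),
    sem_area = vapply(idx_by, function(ix)
      if (length(ix) > 1) stats::sd(areas[ix]) / sqrt(length(ix)) else 0, numeric(1))
  )
}
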