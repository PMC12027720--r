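# Shared fixtures, built in code (no stored data).  Heavy objects are created
# once per test run and memoised here.

.fx <- new.env(parent = emptyenv())

fixture_scene_small <- function() {
  if (is.null(.fx$scene_small))
    .fx$scene_small <- generate_texture_scene(64, 64, 2, 2, 11)
  .fx$scene_small
}

fixture_covs_small <- function() {
  if (is.null(.fx$covs_small)) {
    sc <- fixture_scene_small()
    st <- feature_stack(sc$image)
    ex <- extract_patches(st, 16, 8)
    .fx$covs_small <- list(grid = ex$grid,
                           covs = lapply(ex$patches, patch_covariance),
                           scene = sc)
  }
  .fx$covs_small
}

fixture_crops <- function(n = 24, seed = 5) {
  key <- paste0("crops_", n, "_", seed)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_cell_crops(n, c(0.5, 0.5), seed)
  .fx[[key]]
}

# naive two-pass covariance (independent oracle for patch_covariance)
naive_covariance <- function(X, eps) {
  d <- nrow(X); n <- ncol(X)
  mu <- sapply(seq_len(d), function(i) mean(X[i, ]))
  C <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d))
    C[i, j] <- sum((X[i, ] - mu[i]) * (X[j, ] - mu[j])) / (n - 1)
  C + diag(eps, d)
}

# naive evaluation of the dictionary loss parts (independent oracle)
naive_dictionary_loss <- function(model, covs, field) {
  Om <- riemcell:::field_as_matrix(field)
  N <- length(covs)
  st <- 0
  for (i in seq_len(N)) {
    Y <- matrix(0, model$d, model$d)
    for (k in seq_len(model$K)) Y <- Y + Om[i, k] * model$atoms[[k]]
    Ahat <- spd_exp(Y)
    st <- st + stein_divergence(covs[[i]], Ahat)
  }
  st <- st / N
  l1 <- model$alpha * mean(apply(Om, 1, function(w) sum(abs(w))))
  dims <- field$grid$grid_dims
  sm <- 0; np <- 0
  for (r in seq_len(dims[1])) for (cc in seq_len(dims[2])) {
    i <- (r - 1) * dims[2] + cc
    if (cc < dims[2]) { sm <- sm + sum((Om[i, ] - Om[i + 1, ])^2); np <- np + 1 }
    if (r < dims[1]) { sm <- sm + sum((Om[i, ] - Om[i + dims[2], ])^2); np <- np + 1 }
  }
  sm <- if (np > 0) model$beta * sm / np else 0
  list(stein = st, l1 = l1, smooth = sm, total = st + l1 + sm)
}

# silhouette coefficient for a 2-class labeling of 2-D points
silhouette_mean <- function(points, labels) {
  D <- as.matrix(dist(points))
  s <- vapply(seq_len(nrow(points)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
options(riemcell.log_level = "quiet")
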