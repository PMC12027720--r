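# ---- Riemannian dictionary learning -----------------------------------------
#
# Model: each patch descriptor A_i is mapped to the tangent space at the
# identity, z_i = vec(log A_i); an amortized linear encoder produces weights
# omega_i = W z_i + b; the reconstruction is A_hat_i = exp(sum_k omega_ik Z_k)
# with K learnable symmetric atoms Z_k.  Training minimizes
#
#   L = mean_i S(A_i, A_hat_i) + alpha * mean_i ||omega_i||_1
#       + beta * mean_pairs ||omega_a - omega_b||^2
#
# where S is the Stein divergence and pairs are 4-neighbor patches on the
# grid (spatial smoothness of the weight field).  All gradients are analytic;
# the matrix-exponential backward pass uses the Daleckii-Krein formula.

# K-Means++ seeding using the current RNG state; returns a K x m center matrix.
.kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  if (K > 1) {
    d2 <- colSums((t(X) - centers[1, ])^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      i <- sample.int(n, 1, prob = p)
      centers[k, ] <- X[i, ]
      d2 <- pmin(d2, colSums((t(X) - centers[k, ])^2))
    }
  }
  centers
}

# Lloyd iterations from given centers; deterministic.  Returns centers,
# cluster (1-based, nearest center, lowest index on ties), inertia.
.lloyd <- function(X, centers, iter_max = 100) {
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
      2 * X %*% t(centers) + outer(rep(1, nrow(X)), rowSums(centers^2))
    cl <- max.col(-d2, ties.method = "first")
    new_c <- centers
    for (k in seq_len(nrow(centers)))
      if (any(cl == k)) new_c[k, ] <- colMeans(X[cl == k, , drop = FALSE])
    if (max(abs(new_c - centers)) < 1e-12) { centers <- new_c; break }
    centers <- new_c
  }
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) + outer(rep(1, nrow(X)), rowSums(centers^2))
  cl <- max.col(-d2, ties.method = "first")
  list(centers = centers, cluster = cl,
       inertia = sum(d2[cbind(seq_len(nrow(X)), cl)]))
}

#' Initialize a dictionary model from descriptors
#'
#' Atoms are the K-Means++ centroids of the tangent vectors
#' `vec(log A_i)` (unvectorized back to symmetric matrices); the encoder
#' `(W, b)` is initialized by ridge least squares mapping each tangent vector
#' to the one-hot encoding of its centroid assignment, so the untrained
#' encoder already produces roughly cluster-indicator weights.
#'
#' @param covs list of SPD matrices (equal dimension).
#' @param K number of atoms, `1 <= K <= length(covs)`.
#' @param seed integer seed (K-Means++ draws).
#' @param alpha,beta,eps loss hyperparameters stored on the model: L1
#'   coefficient, spatial-smoothness coefficient, SPD floor.
#' @return Object of class `riem_dictionary`: `atoms` (list of K symmetric
#'   matrices), `W` (K x d(d+1)/2), `bias` (K), `alpha`, `beta`, `eps`, `d`.
#' @export
init_dictionary <- function(covs, K, seed = 0, alpha = 1e-3, beta = 1e-3, eps = 1e-6) {
  stopifnot(length(covs) >= 1, K >= 1, K <= length(covs), alpha >= 0, beta >= 0)
  d <- nrow(covs[[1]])
  Zmat <- t(vapply(covs, function(A) tangent_vectorize(spd_log(A)),
                   numeric(d * (d + 1) / 2)))
  with_seed(seed, {
    km <- .lloyd(Zmat, .kmeanspp_centers(Zmat, K))
    atoms <- lapply(seq_len(K), function(k) tangent_unvectorize(km$centers[k, ], d))
    onehot <- matrix(0, nrow(Zmat), K)
    onehot[cbind(seq_len(nrow(Zmat)), km$cluster)] <- 1
    X <- cbind(1, Zmat)
    B <- solve(crossprod(X) + 1e-6 * diag(ncol(X)), crossprod(X, onehot))
    structure(list(atoms = atoms, W = t(B[-1, , drop = FALSE]),
                   bias = as.numeric(B[1, ]), alpha = alpha, beta = beta,
                   eps = eps, d = d, K = K),
              class = "riem_dictionary")
  })
}

#' Encode an SPD matrix to dictionary weights
#'
#' The amortized encoder: `omega = W vec(log A) + b`.  Weights are
#' unconstrained reals; probabilistic class interpretation happens downstream
#' via soft cluster assignment, not here.
#'
#' @param model a `riem_dictionary`.
#' @param A SPD matrix of the model's dimension.
#' @return Numeric K-vector.
#' @export
encode_weights <- function(model, A) {
  stopifnot(inherits(model, "riem_dictionary"))
  if (nrow(A) != model$d) stop("encode_weights: dimension mismatch", call. = FALSE)
  as.numeric(model$W %*% tangent_vectorize(spd_log(A)) + model$bias)
}

#' Reconstruct an SPD matrix from dictionary weights
#'
#' `A_hat = exp(sum_k omega_k Z_k)`: the linear combination lives in the
#' tangent space, the exponential map returns it to the manifold, so the
#' result is SPD by construction for any real weights.
#'
#' @param model a `riem_dictionary`.
#' @param omega numeric K-vector.
#' @return SPD matrix.
#' @export
reconstruct_spd <- function(model, omega) {
  stopifnot(inherits(model, "riem_dictionary"), length(omega) == model$K)
  Y <- Reduce(`+`, Map(`*`, model$atoms, as.list(omega)))
  spd_exp(Y)
}

# 4-neighbor patch pairs on an r x c row-major grid -> 2-column index matrix.
.grid_pairs <- function(grid_dims) {
  r <- grid_dims[1]; c_ <- grid_dims[2]
  idx <- function(i, j) (i - 1L) * c_ + j
  hp <- if (c_ > 1) cbind(idx(rep(1:r, each = c_ - 1), rep(1:(c_ - 1), r)),
                          idx(rep(1:r, each = c_ - 1), rep(2:c_, r))) else NULL
  vp <- if (r > 1) cbind(idx(rep(1:(r - 1), each = c_), rep(1:c_, r - 1)),
                         idx(rep(2:r, each = c_), rep(1:c_, r - 1))) else NULL
  rbind(hp, vp)
}

#' Encode a whole descriptor grid to a weight field
#'
#' @param model a `riem_dictionary`.
#' @param covs list of SPD descriptors in grid (row-major) order.
#' @param grid the `patch_grid` the descriptors came from.
#' @return Object of class `weight_field`: `weights` (rows x cols x K array),
#'   `grid`.
#' @export
encode_weight_field <- function(model, covs, grid) {
  stopifnot(length(covs) == prod(grid$grid_dims))
  m <- model$d * (model$d + 1) / 2
  Zmat <- t(vapply(covs, function(A) tangent_vectorize(spd_log(A)), numeric(m)))
  Om <- Zmat %*% t(model$W) + matrix(model$bias, nrow(Zmat), model$K, byrow = TRUE)
  weights <- array(0, c(grid$grid_dims, model$K))
  for (k in seq_len(model$K))
    weights[, , k] <- matrix(Om[, k], grid$grid_dims[1], grid$grid_dims[2], byrow = TRUE)
  structure(list(weights = weights, grid = grid), class = "weight_field")
}

# weight_field -> N x K matrix in row-major patch order
field_as_matrix <- function(field) {
  dm <- dim(field$weights)
  out <- matrix(0, dm[1] * dm[2], dm[3])
  for (k in seq_len(dm[3])) out[, k] <- as.numeric(t(field$weights[, , k]))
  out
}

#' Dictionary loss and its parts
#'
#' `total = stein + l1 + smooth` with
#' `stein` = mean Stein divergence between each descriptor and its
#' reconstruction, `l1` = `alpha` times the mean L1 norm of the weight
#' vectors, `smooth` = `beta` times the mean (over 4-neighbor patch pairs)
#' squared difference of weight vectors.
#'
#' @param model a `riem_dictionary`.
#' @param covs list of SPD descriptors in grid order.
#' @param field a `weight_field` with matching shape.
#' @return List `total`, `parts` (list `stein`, `l1`, `smooth`).
#' @export
dictionary_loss <- function(model, covs, field) {
  Om <- field_as_matrix(field)
  if (nrow(Om) != length(covs))
    stop("dictionary_loss: field shape does not match descriptor count", call. = FALSE)
  N <- length(covs)
  stein <- mean(vapply(seq_len(N), function(i)
    stein_divergence(covs[[i]], reconstruct_spd(model, Om[i, ])), numeric(1)))
  l1 <- model$alpha * mean(abs(Om)) * model$K  # alpha * mean_i ||omega_i||_1
  pairs <- .grid_pairs(field$grid$grid_dims)
  smooth <- if (is.null(pairs) || nrow(pairs) == 0) 0 else
    model$beta * sum((Om[pairs[, 1], , drop = FALSE] - Om[pairs[, 2], , drop = FALSE])^2) / nrow(pairs)
  list(total = stein + l1 + smooth,
       parts = list(stein = stein, l1 = l1, smooth = smooth))
}

# Daleckii-Krein backward pass of the matrix exponential: given symmetric Y
# with eigen pairs (gamma, V) and an upstream symmetric gradient G wrt exp(Y),
# return the gradient wrt Y.  Divided differences are evaluated in the stable
# form exp((gi+gj)/2) * sinh(delta/2)/(delta/2).
.expm_backward <- function(eigY, G) {
  gam <- eigY$values; V <- eigY$vectors
  D <- outer(gam, gam, function(a, b) {
    m <- (a + b) / 2; h <- (a - b) / 2
    ifelse(abs(h) < 1e-7, exp(m) * (1 + h^2 / 6), exp(m) * sinh(h) / h)
  })
  Gt <- t(V) %*% G %*% V
  out <- V %*% (Gt * D) %*% t(V)
  (out + t(out)) / 2
}

# Forward + gradient evaluation shared by fit_dictionary and the tests'
# finite-difference checks.  Returns loss parts and gradients wrt W, bias,
# atoms.  `which_parts` lets the gradient checker isolate the Stein term.
.dictionary_loss_grad <- function(model, covs, Zmat, pairs,
                                  which_parts = c("stein", "l1", "smooth"),
                                  logdetA = NULL) {
  N <- length(covs); K <- model$K; d <- model$d
  Om <- Zmat %*% t(model$W) + matrix(model$bias, N, K, byrow = TRUE)
  Zc <- t(vapply(model$atoms, as.numeric, numeric(d * d)))  # K x d^2
  Ymat <- Om %*% Zc                                          # N x d^2
  dOm <- matrix(0, N, K)
  dZc <- matrix(0, K, d * d)
  stein <- 0
  if ("stein" %in% which_parts) {
    if (is.null(logdetA))
      logdetA <- vapply(covs, .logdet_chol, numeric(1))
    for (i in seq_len(N)) {
      Y <- matrix(Ymat[i, ], d, d)
      Y <- (Y + t(Y)) / 2
      eY <- eigen(Y, symmetric = TRUE)
      ex <- exp(eY$values)
      if (!all(is.finite(ex)))
        stop("dictionary loss: overflow in exp (weights too large)", call. = FALSE)
      Ahat <- eY$vectors %*% (ex * t(eY$vectors))
      A <- covs[[i]]
      cholM <- chol((2 * A + Ahat + t(Ahat)) / 4)
      stein <- stein + 2 * sum(log(diag(cholM))) -
        0.5 * logdetA[i] - 0.5 * sum(eY$values)
      G <- 0.5 * chol2inv(cholM) -
        0.5 * eY$vectors %*% ((1 / ex) * t(eY$vectors))
      dY <- .expm_backward(eY, (G + t(G)) / 2) / N
      dOm[i, ] <- dOm[i, ] + as.numeric(Zc %*% as.numeric(dY))
      dZc <- dZc + outer(Om[i, ], as.numeric(dY))
    }
    stein <- stein / N
  }
  l1 <- 0; smooth <- 0
  if ("l1" %in% which_parts && model$alpha > 0) {
    l1 <- model$alpha * sum(abs(Om)) / N
    dOm <- dOm + model$alpha * sign(Om) / N
  }
  if ("smooth" %in% which_parts && model$beta > 0 && !is.null(pairs) && nrow(pairs) > 0) {
    Dif <- Om[pairs[, 1], , drop = FALSE] - Om[pairs[, 2], , drop = FALSE]
    smooth <- model$beta * sum(Dif^2) / nrow(pairs)
    g <- 2 * model$beta / nrow(pairs)
    for (r in seq_len(nrow(pairs))) {
      dOm[pairs[r, 1], ] <- dOm[pairs[r, 1], ] + g * Dif[r, ]
      dOm[pairs[r, 2], ] <- dOm[pairs[r, 2], ] - g * Dif[r, ]
    }
  }
  dW <- t(dOm) %*% Zmat
  dbias <- colSums(dOm)
  dAtoms <- lapply(seq_len(K), function(k) {
    M <- matrix(dZc[k, ], d, d); (M + t(M)) / 2
  })
  list(total = stein + l1 + smooth,
       parts = list(stein = stein, l1 = l1, smooth = smooth),
       dW = dW, dbias = dbias, dAtoms = dAtoms, omega = Om)
}

#' Fit the dictionary and encoder by full-batch gradient descent
#'
#' Minimizes the dictionary loss over `W`, `bias`, and the atoms `Z_k` with
#' deterministic full-batch gradient descent; atoms are re-symmetrized
#' `(Z + Z') / 2` after every step.  If a step would increase the loss the
#' step size for that epoch is halved (up to 20 times) — a deterministic
#' backtracking safeguard that keeps plain gradient descent stable on
#' ill-conditioned descriptors.
#'
#' @param model initialized `riem_dictionary` (see [init_dictionary()]).
#' @param covs list of SPD descriptors in grid order.
#' @param grid the `patch_grid` (supplies 4-neighbor pairs for the smoothness
#'   term); pass `NULL` to drop the spatial term.
#' @param epochs number of full-batch steps (`>= 1`).
#' @param lr learning rate.
#' @param seed kept for interface symmetry; the optimizer itself is
#'   deterministic.
#' @return List `model` (trained), `loss_history` (numeric, one total per
#'   epoch, measured before each step), `final_loss`.
#' @export
fit_dictionary <- function(model, covs, grid = NULL, epochs = 500, lr = 1e-2, seed = 0) {
  stopifnot(inherits(model, "riem_dictionary"), epochs >= 1, lr > 0)
  N <- length(covs)
  m <- model$d * (model$d + 1) / 2
  Zmat <- t(vapply(covs, function(A) tangent_vectorize(spd_log(A)), numeric(m)))
  pairs <- if (is.null(grid)) NULL else .grid_pairs(grid$grid_dims)
  logdetA <- vapply(covs, riemcell_logdet <- function(A) 2 * sum(log(diag(chol(A)))), numeric(1))
  loss_history <- numeric(epochs)
  cur <- .dictionary_loss_grad(model, covs, Zmat, pairs, logdetA = logdetA)
  for (ep in seq_len(epochs)) {
    loss_history[ep] <- cur$total
    if (!is.finite(cur$total))
      stop(sprintf("fit_dictionary: non-finite loss at epoch %d", ep), call. = FALSE)
    step <- lr
    accepted <- FALSE
    for (try in 1:21) {
      cand <- model
      cand$W <- model$W - step * cur$dW
      cand$bias <- model$bias - step * cur$dbias
      cand$atoms <- lapply(seq_len(model$K), function(k) {
        Z <- model$atoms[[k]] - step * cur$dAtoms[[k]]; (Z + t(Z)) / 2
      })
      nxt <- tryCatch(.dictionary_loss_grad(cand, covs, Zmat, pairs, logdetA = logdetA),
                      error = function(e) NULL)
      if (!is.null(nxt) && is.finite(nxt$total) && nxt$total <= cur$total + 1e-12) {
        model <- cand; cur <- nxt; accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) {  # stationary to machine precision: freeze remaining epochs
      if (ep < epochs) loss_history[(ep + 1):epochs] <- cur$total
      break
    }
  }
  list(model = model, loss_history = loss_history, final_loss = cur$total)
}

#' Serialize / restore a dictionary model (plain JSON)
#'
#' @param model a `riem_dictionary`.
#' @param path output file.
#' @param hash optional config hash embedded in the bundle.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(model, path, hash = NULL) {
  obj <- list(config_hash = hash, d = model$d, K = model$K,
              alpha = model$alpha, beta = model$beta, eps = model$eps,
              atoms = lapply(model$atoms, function(Z) as.numeric(Z)),
              W = as.numeric(model$W), bias = model$bias)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$d; K <- obj$K
  atoms <- if (is.matrix(obj$atoms)) {
    lapply(seq_len(K), function(k) matrix(obj$atoms[k, ], d, d))
  } else {
    lapply(obj$atoms, function(a) matrix(unlist(a), d, d))
  }
  structure(list(atoms = atoms,
                 W = matrix(obj$W, K, d * (d + 1) / 2),
                 bias = obj$bias, alpha = obj$alpha, beta = obj$beta,
                 eps = obj$eps, d = d, K = K),
            class = "riem_dictionary")
}
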