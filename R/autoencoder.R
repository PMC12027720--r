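# ---- convolutional autoencoder for single-cell morphology ------------------
#
# Encoder: 5 conv stages (kernel 4, stride 2, padding 1) doubling channels
# 1 -> 16 -> 32 -> 64 -> 128 -> 256, so a 128x128 crop becomes a 4x4x256 map.
# Bottleneck (variant MHAAE): a shape vector (bounding-box h, w scaled by 128)
# is embedded by a 2-layer ReLU MLP with layer normalization and injected as
# an additive query bias in multi-head cross-attention over the 16 spatial
# positions; letterboxed positions are excluded via the downsampled padding
# mask.  The bottleneck is reduced to a 256-d vector by a 1x1 projection +
# global average pooling; its L2 normalization is the cell embedding.  The
# decoder re-expands the (shape-conditioned) bottleneck vector to 4x4x256 and
# mirrors the encoder with 5 transposed convolutions.  Loss: MAE + (1 - SSIM)
# (+ kld_weight * KLD for the VAE variant).  All gradients are hand-derived;
# convolutions run through the compiled im2col kernels.

#' Autoencoder configuration
#'
#' @param variant one of `"AE"` (plain), `"MHAAE"` (shape cross-attention
#'   bottleneck, default), `"VAE"` (reparameterized latent + KLD penalty).
#' @param latent_dim embedding dimension (default 256).
#' @param feature_depth channels of the deepest encoder stage (default 256).
#' @param kernel,stride,padding conv hyperparameters (defaults 4 / 2 / 1).
#' @param loss_terms subset of `c("MAE", "SSIM")`.
#' @param kld_weight KLD coefficient for the VAE variant (default 0.001,
#'   applied as a positive penalty).
#' @param lr learning rate (default 1e-4, Adam).
#' @param batch batch size (default 128).
#' @param lr_decay exponential per-epoch decay factor (default 0.95).
#' @param epochs training epochs (default 50).
#' @param attn_heads attention heads for MHAAE (default 4).
#' @param augment apply random 90-degree rotations/flips and 3x3 Gaussian
#'   input blur during training (default TRUE).
#' @param seed integer seed controlling init, shuffling, augmentation, VAE
#'   noise.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(variant = c("MHAAE", "AE", "VAE"), latent_dim = 256,
                           feature_depth = 256, kernel = 4, stride = 2,
                           padding = 1, loss_terms = c("MAE", "SSIM"),
                           kld_weight = 0.001, lr = 1e-4, batch = 128,
                           lr_decay = 0.95, epochs = 50, attn_heads = 4,
                           augment = TRUE, seed = 0) {
  variant <- match.arg(variant)
  stopifnot(latent_dim >= 2, batch >= 1, epochs >= 1, lr > 0,
            all(loss_terms %in% c("MAE", "SSIM")), length(loss_terms) >= 1)
  structure(list(variant = variant, latent_dim = latent_dim,
                 feature_depth = feature_depth, kernel = kernel,
                 stride = stride, padding = padding, loss_terms = loss_terms,
                 kld_weight = abs(kld_weight), lr = lr, batch = batch,
                 lr_decay = lr_decay, epochs = epochs, attn_heads = attn_heads,
                 augment = isTRUE(augment), seed = seed),
            class = "encoder_config")
}

.enc_channels <- function(fd) c(1L, 16L, 32L, 64L, 128L, fd)

.he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

.init_params <- function(cfg) {
  ch <- .enc_channels(cfg$feature_depth)
  k <- cfg$kernel; C5 <- cfg$feature_depth; L <- cfg$latent_dim; A <- C5
  p <- list()
  for (l in 1:5) {
    p[[paste0("enc", l, "_w")]] <- .he_init(c(k, k, ch[l], ch[l + 1]), k * k * ch[l])
    p[[paste0("enc", l, "_b")]] <- numeric(ch[l + 1])
  }
  if (cfg$variant == "MHAAE") {
    p$mlp_W1 <- .he_init(c(2, 64), 2);    p$mlp_b1 <- numeric(64)
    p$mlp_W2 <- .he_init(c(64, A), 64);   p$mlp_b2 <- numeric(A)
    p$mlp_lng <- rep(1, A);               p$mlp_lnb <- numeric(A)
    for (nm in c("q", "k", "v", "o")) {
      p[[paste0("att_W", nm)]] <- .he_init(c(A, A), A)
      p[[paste0("att_b", nm)]] <- numeric(A)
    }
  }
  p$lat_W <- .he_init(c(C5, L), C5); p$lat_b <- numeric(L)
  if (cfg$variant == "VAE") {
    p$vae_Wmu <- .he_init(c(L, L), L); p$vae_bmu <- numeric(L)
    p$vae_Wlv <- .he_init(c(L, L), L) * 0.01; p$vae_blv <- numeric(L)
  }
  zdim <- L + if (cfg$variant == "MHAAE") C5 else 0L
  p$dec0_W <- .he_init(c(zdim, 16 * C5), zdim); p$dec0_b <- numeric(16 * C5)
  p$bn_g <- rep(1, C5); p$bn_b <- numeric(C5)
  dch <- rev(ch)  # C5, 128, 64, 32, 16, 1
  for (l in 1:5) {
    p[[paste0("dec", l, "_w")]] <- .he_init(c(k, k, dch[l + 1], dch[l]), k * k * dch[l] / 4)
    p[[paste0("dec", l, "_b")]] <- numeric(dch[l + 1])
  }
  p
}

# (4,4,C,N) array <-> (N*16 x C) position-feature matrix
.arr_to_pos <- function(a) {
  d <- dim(a)
  m <- aperm(a, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}
.pos_to_arr <- function(m, H, W, N) {
  C <- ncol(m)
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1, 2, 4, 3))
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# masked multi-head cross-attention for one sample.
# Fp: P x C image features; s: length-C shape embedding; valid: P logical.
.attn_fwd_one <- function(p, Fp, s, valid, heads) {
  C <- ncol(Fp); dh <- C / heads; P <- nrow(Fp)
  Qin <- Fp + matrix(s, P, C, byrow = TRUE)
  Q <- Qin %*% p$att_Wq + matrix(p$att_bq, P, C, byrow = TRUE)
  K <- Fp %*% p$att_Wk + matrix(p$att_bk, P, C, byrow = TRUE)
  V <- Fp %*% p$att_Wv + matrix(p$att_bv, P, C, byrow = TRUE)
  if (!any(valid)) valid <- rep(TRUE, P)
  Amats <- vector("list", heads); O <- matrix(0, P, C)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    S[, !valid] <- -Inf
    Am <- .softmax_rows(S)
    Amats[[h]] <- Am
    O[, idx] <- Am %*% V[, idx, drop = FALSE]
  }
  out <- O %*% p$att_Wo + matrix(p$att_bo, P, C, byrow = TRUE)
  list(out = out, Q = Q, K = K, V = V, O = O, A = Amats, Qin = Qin, valid = valid)
}

.attn_bwd_one <- function(p, cache, Fp, gout, heads, g) {
  C <- ncol(Fp); dh <- C / heads; P <- nrow(Fp)
  g$att_Wo <- g$att_Wo + t(cache$O) %*% gout
  g$att_bo <- g$att_bo + colSums(gout)
  gO <- gout %*% t(p$att_Wo)
  gQ <- matrix(0, P, C); gK <- matrix(0, P, C); gV <- matrix(0, P, C)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    Am <- cache$A[[h]]
    gOh <- gO[, idx, drop = FALSE]
    gV[, idx] <- t(Am) %*% gOh
    gA <- gOh %*% t(cache$V[, idx, drop = FALSE])
    # softmax backward (rows); masked columns have A == 0 so drop out naturally
    gS <- Am * (gA - rowSums(gA * Am))
    gS <- gS / sqrt(dh)
    gQ[, idx] <- gS %*% cache$K[, idx, drop = FALSE]
    gK[, idx] <- t(gS) %*% cache$Q[, idx, drop = FALSE]
  }
  g$att_Wq <- g$att_Wq + t(cache$Qin) %*% gQ
  g$att_bq <- g$att_bq + colSums(gQ)
  g$att_Wk <- g$att_Wk + t(Fp) %*% gK
  g$att_bk <- g$att_bk + colSums(gK)
  g$att_Wv <- g$att_Wv + t(Fp) %*% gV
  g$att_bv <- g$att_bv + colSums(gV)
  gFp <- gQ %*% t(p$att_Wq) + gK %*% t(p$att_Wk) + gV %*% t(p$att_Wv)
  gs <- colSums(gQ %*% t(p$att_Wq))
  list(gFp = gFp, gs = gs, g = g)
}

# shape MLP: (N x 2) -> (N x A); 2 linear layers, ReLU, layer normalization.
.mlp_fwd <- function(p, sh) {
  h1 <- sh %*% p$mlp_W1 + matrix(p$mlp_b1, nrow(sh), 64, byrow = TRUE)
  a1 <- pmax(h1, 0)
  h2 <- a1 %*% p$mlp_W2 + matrix(p$mlp_b2, nrow(sh), length(p$mlp_b2), byrow = TRUE)
  mu <- rowMeans(h2); v <- rowMeans((h2 - mu)^2)
  sg <- sqrt(v + 1e-5)
  xh <- (h2 - mu) / sg
  s <- xh * matrix(p$mlp_lng, nrow(sh), ncol(h2), byrow = TRUE) +
    matrix(p$mlp_lnb, nrow(sh), ncol(h2), byrow = TRUE)
  list(s = s, sh = sh, h1 = h1, a1 = a1, xh = xh, sg = sg)
}

.mlp_bwd <- function(p, cache, gs, g) {
  A <- ncol(cache$xh); n <- nrow(cache$xh)
  g$mlp_lng <- g$mlp_lng + colSums(gs * cache$xh)
  g$mlp_lnb <- g$mlp_lnb + colSums(gs)
  gxh <- gs * matrix(p$mlp_lng, n, A, byrow = TRUE)
  # layer-norm backward per row
  gh2 <- (gxh - rowMeans(gxh) - cache$xh * rowMeans(gxh * cache$xh)) / cache$sg
  g$mlp_W2 <- g$mlp_W2 + t(cache$a1) %*% gh2
  g$mlp_b2 <- g$mlp_b2 + colSums(gh2)
  ga1 <- gh2 %*% t(p$mlp_W2)
  gh1 <- ga1 * (cache$h1 > 0)
  g$mlp_W1 <- g$mlp_W1 + t(cache$sh) %*% gh1
  g$mlp_b1 <- g$mlp_b1 + colSums(gh1)
  g
}

# batch norm over (H, W, N) per channel on a (H,W,C,N) array
.bn_fwd <- function(a, gamma, beta, run, train, momentum = 0.1) {
  d <- dim(a)
  m <- .arr_to_pos(a)                 # (HWN x C)
  if (train) {
    mu <- colMeans(m); v <- colMeans(m^2) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else { mu <- run$mean; v <- run$var }
  sg <- sqrt(v + 1e-5)
  xh <- (m - matrix(mu, nrow(m), ncol(m), byrow = TRUE)) /
    matrix(sg, nrow(m), ncol(m), byrow = TRUE)
  y <- xh * matrix(gamma, nrow(m), ncol(m), byrow = TRUE) +
    matrix(beta, nrow(m), ncol(m), byrow = TRUE)
  list(y = .pos_to_arr(y, d[1], d[2], d[4]), xh = xh, sg = sg, run = run, dims = d)
}

.bn_bwd <- function(cache, gamma, gy_arr) {
  gy <- .arr_to_pos(gy_arr)
  n <- nrow(gy)
  ggamma <- colSums(gy * cache$xh)
  gbeta <- colSums(gy)
  gxh <- gy * matrix(gamma, n, ncol(gy), byrow = TRUE)
  gm <- (gxh - matrix(colMeans(gxh), n, ncol(gy), byrow = TRUE) -
           cache$xh * matrix(colMeans(gxh * cache$xh), n, ncol(gy), byrow = TRUE)) /
    matrix(cache$sg, n, ncol(gy), byrow = TRUE)
  d <- cache$dims
  list(gx = .pos_to_arr(gm, d[1], d[2], d[4]), ggamma = ggamma, gbeta = gbeta)
}

# SSIM over non-overlapping 16x16 windows on the normalized [-1, 1] scale.
# Returns mean SSIM and (optionally) its gradient wrt x.
.ssim_stat <- function(x, y, with_grad = TRUE, win = 16L) {
  C1 <- (0.01 * 2)^2; C2 <- (0.03 * 2)^2
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  nbh <- H %/% win; nbw <- W %/% win
  resh <- function(a) {
    dim(a) <- c(win, nbh, win, nbw, N)
    m <- aperm(a, c(1, 3, 2, 4, 5))
    dim(m) <- c(win * win, nbh * nbw * N)
    m
  }
  mx <- resh(x); my <- resh(y)
  n <- win * win
  ux <- colMeans(mx); uy <- colMeans(my)
  vx <- colMeans(mx^2) - ux^2; vy <- colMeans(my^2) - uy^2
  cxy <- colMeans(mx * my) - ux * uy
  A1 <- 2 * ux * uy + C1; A2 <- 2 * cxy + C2
  B1 <- ux^2 + uy^2 + C1; B2 <- vx + vy + C2
  S <- A1 * A2 / (B1 * B2)
  out <- list(ssim = mean(S))
  if (with_grad) {
    nw <- length(S)
    cm <- function(v) matrix(v, n, nw, byrow = TRUE)
    dS_dux <- (2 * uy * A2 - 2 * ux * S * B2) / (B1 * B2)
    dS_dvx <- -S / B2
    dS_dcxy <- 2 * A1 / (B1 * B2)
    gm <- cm(dS_dux) / n +
      cm(dS_dvx) * 2 * (mx - cm(ux)) / n +
      cm(dS_dcxy) * (my - cm(uy)) / n
    gm <- gm / nw                      # gradient of mean SSIM
    dim(gm) <- c(win, win, nbh, nbw, N)
    gm <- aperm(gm, c(1, 3, 2, 4, 5))
    dim(gm) <- d
    out$grad <- gm
  }
  out
}

# full forward pass on an assembled batch.
# x: (128,128,1,B) inputs; target same shape; sh: (B x 2); valid: (B x 16)
.ae_forward <- function(p, cfg, x, sh, valid, train = TRUE, run = NULL) {
  k <- cfg$kernel; s_ <- cfg$stride; pd <- cfg$padding
  B <- dim(x)[4]; C5 <- cfg$feature_depth; L <- cfg$latent_dim; P <- 16L
  cache <- list(x = x)
  a <- x
  for (l in 1:5) {
    z <- conv_fwd_cpp(a, p[[paste0("enc", l, "_w")]], p[[paste0("enc", l, "_b")]], s_, pd)
    cache[[paste0("enc_in", l)]] <- a
    cache[[paste0("enc_z", l)]] <- z
    a <- pmax(z, 0)
  }
  Fpos <- .arr_to_pos(a)              # (B*16 x C5)
  cache$Fmap <- a; cache$Fpos <- Fpos
  if (cfg$variant == "MHAAE") {
    mlp <- .mlp_fwd(p, sh)
    cache$mlp <- mlp
    att <- vector("list", B)
    G <- Fpos
    for (i in seq_len(B)) {
      rows <- ((i - 1) * P + 1):(i * P)
      att[[i]] <- .attn_fwd_one(p, Fpos[rows, , drop = FALSE], mlp$s[i, ],
                                valid[i, ], cfg$attn_heads)
      G[rows, ] <- Fpos[rows, , drop = FALSE] + att[[i]]$out
    }
    cache$att <- att
  } else G <- Fpos
  cache$G <- G
  latp <- G %*% p$lat_W + matrix(p$lat_b, nrow(G), L, byrow = TRUE)
  cache$latp <- latp
  # global average pooling over the 16 positions
  lat_pre <- matrix(0, B, L)
  for (i in seq_len(B)) lat_pre[i, ] <- colMeans(latp[((i - 1) * P + 1):(i * P), , drop = FALSE])
  cache$lat_pre <- lat_pre
  if (cfg$variant == "VAE") {
    mu <- lat_pre %*% p$vae_Wmu + matrix(p$vae_bmu, B, L, byrow = TRUE)
    lv <- lat_pre %*% p$vae_Wlv + matrix(p$vae_blv, B, L, byrow = TRUE)
    lv <- pmin(pmax(lv, -10), 10)
    epsn <- if (train) matrix(rnorm(B * L), B, L) else matrix(0, B, L)
    zlat <- mu + exp(0.5 * lv) * epsn
    cache$mu <- mu; cache$lv <- lv; cache$epsn <- epsn
    zdec <- zlat
  } else zdec <- lat_pre
  zc <- if (cfg$variant == "MHAAE") cbind(zdec, cache$mlp$s) else zdec
  cache$zc <- zc
  d0m <- zc %*% p$dec0_W + matrix(p$dec0_b, B, 16 * C5, byrow = TRUE)
  d0 <- array(t(d0m), c(4, 4, C5, B))
  cache$d0m <- d0m
  bn <- .bn_fwd(d0, p$bn_g, p$bn_b, run, train)
  cache$bn <- bn
  a <- pmax(bn$y, 0)
  cache$dec_a0 <- a
  for (l in 1:5) {
    z <- convt_fwd_cpp(a, p[[paste0("dec", l, "_w")]], p[[paste0("dec", l, "_b")]], s_, pd)
    cache[[paste0("dec_in", l)]] <- a
    cache[[paste0("dec_z", l)]] <- z
    a <- if (l < 5) pmax(z, 0) else z
  }
  cache$recon <- a
  cache$run <- bn$run
  cache
}

.zero_like <- function(p) lapply(p, function(a) array(0, dim(a) %||% length(a)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# backward from a gradient on the reconstruction (plus optional VAE KLD
# gradients); returns the named gradient list.
.ae_backward <- function(p, cfg, cache, grecon, sh, valid, kld_scale = 0) {
  k <- cfg$kernel; s_ <- cfg$stride; pd <- cfg$padding
  B <- dim(cache$x)[4]; C5 <- cfg$feature_depth; L <- cfg$latent_dim; P <- 16L
  g <- .zero_like(p)
  ga <- grecon
  for (l in 5:1) {
    gz <- if (l < 5) ga * (cache[[paste0("dec_z", l)]] > 0) else ga
    bw <- convt_bwd_cpp(cache[[paste0("dec_in", l)]], p[[paste0("dec", l, "_w")]], gz, s_, pd)
    g[[paste0("dec", l, "_w")]] <- bw$gw
    g[[paste0("dec", l, "_b")]] <- bw$gb
    ga <- bw$gx
  }
  ga <- ga * (cache$bn$y > 0)
  bb <- .bn_bwd(cache$bn, p$bn_g, ga)
  g$bn_g <- bb$ggamma; g$bn_b <- bb$gbeta
  gd0m <- t(matrix(bb$gx, 16 * C5, B))
  g$dec0_W <- t(cache$zc) %*% gd0m
  g$dec0_b <- colSums(gd0m)
  gzc <- gd0m %*% t(p$dec0_W)
  gs_extra <- NULL
  if (cfg$variant == "MHAAE") {
    gzdec <- gzc[, 1:L, drop = FALSE]
    gs_extra <- gzc[, (L + 1):(L + C5), drop = FALSE]
  } else gzdec <- gzc
  if (cfg$variant == "VAE") {
    gmu <- gzdec + kld_scale * cache$mu
    glv <- gzdec * 0.5 * exp(0.5 * cache$lv) * cache$epsn -
      kld_scale * 0.5 * (1 - exp(cache$lv))
    glv[cache$lv <= -10 | cache$lv >= 10] <- 0
    g$vae_Wmu <- t(cache$lat_pre) %*% gmu; g$vae_bmu <- colSums(gmu)
    g$vae_Wlv <- t(cache$lat_pre) %*% glv; g$vae_blv <- colSums(glv)
    glat_pre <- gmu %*% t(p$vae_Wmu) + glv %*% t(p$vae_Wlv)
  } else glat_pre <- gzdec
  # GAP backward: spread over the 16 positions
  glatp <- matrix(0, B * P, L)
  for (i in seq_len(B))
    glatp[((i - 1) * P + 1):(i * P), ] <- matrix(glat_pre[i, ] / P, P, L, byrow = TRUE)
  g$lat_W <- t(cache$G) %*% glatp
  g$lat_b <- colSums(glatp)
  gG <- glatp %*% t(p$lat_W)
  if (cfg$variant == "MHAAE") {
    gFpos <- gG                        # residual path
    gsm <- matrix(0, B, C5)
    for (i in seq_len(B)) {
      rows <- ((i - 1) * P + 1):(i * P)
      ab <- .attn_bwd_one(p, cache$att[[i]], cache$Fpos[rows, , drop = FALSE],
                          gG[rows, , drop = FALSE], cfg$attn_heads, g)
      g <- ab$g
      gFpos[rows, ] <- gFpos[rows, ] + ab$gFp
      gsm[i, ] <- ab$gs
    }
    if (!is.null(gs_extra)) gsm <- gsm + gs_extra
    g <- .mlp_bwd(p, cache$mlp, gsm, g)
  } else gFpos <- gG
  ga <- .pos_to_arr(gFpos, 4L, 4L, B)
  for (l in 5:1) {
    gz <- ga * (cache[[paste0("enc_z", l)]] > 0)
    bw <- conv_bwd_cpp(cache[[paste0("enc_in", l)]], p[[paste0("enc", l, "_w")]], gz, s_, pd)
    g[[paste0("enc", l, "_w")]] <- bw$gw
    g[[paste0("enc", l, "_b")]] <- bw$gb
    ga <- bw$gx
  }
  g
}

# reconstruction loss and gradient on the recon array
.recon_loss_grad <- function(recon, target, loss_terms, with_grad = TRUE) {
  nel <- length(recon)
  mae <- 0; ssim_term <- 0
  grad <- if (with_grad) array(0, dim(recon)) else NULL
  if ("MAE" %in% loss_terms) {
    mae <- mean(abs(recon - target))
    if (with_grad) grad <- grad + sign(recon - target) / nel
  }
  if ("SSIM" %in% loss_terms) {
    ss <- .ssim_stat(recon, target, with_grad = with_grad)
    ssim_term <- 1 - ss$ssim
    if (with_grad) grad <- grad - ss$grad
  }
  list(mae = mae, ssim_term = ssim_term, grad = grad)
}

.rot90k <- function(m, kturns) {
  kturns <- kturns %% 4
  if (kturns == 0) return(m)
  for (i in seq_len(kturns)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

# assemble crops into batch tensors; optional per-sample augmentation draws
# must already be made (aug: list of k90, flip per sample or NULL)
.assemble_batch <- function(crops, idx, aug = NULL, blur = FALSE) {
  B <- length(idx)
  x <- array(0, c(128, 128, 1, B)); tg <- array(0, c(128, 128, 1, B))
  sh <- matrix(0, B, 2); valid <- matrix(FALSE, B, 16)
  for (j in seq_len(B)) {
    cr <- crops[[idx[j]]]
    px <- cr$pixels; pm <- cr$padding_mask; os <- cr$orig_size
    if (!is.null(aug)) {
      kturns <- aug$k90[j]
      px <- .rot90k(px, kturns); pm <- .rot90k(pm, kturns)
      if (kturns %% 2 == 1) os <- rev(os)
      if (aug$flip[j]) { px <- px[, ncol(px):1]; pm <- pm[, ncol(pm):1] }
    }
    tg[, , 1, j] <- px
    x[, , 1, j] <- if (blur) blur3(px) else px
    sh[j, ] <- os / 128
    blk <- matrix(FALSE, 4, 4)
    for (bi in 1:4) for (bj in 1:4)
      blk[bi, bj] <- any(pm[((bi - 1) * 32 + 1):(bi * 32), ((bj - 1) * 32 + 1):(bj * 32)])
    valid[j, ] <- as.logical(blk)     # column-major: matches position order
  }
  list(x = x, target = tg, sh = sh, valid = valid)
}

#' Train the single-cell autoencoder
#'
#' Adam (lr from the config, exponential per-epoch decay), shuffled
#' mini-batches, optional rotation/flip augmentation and 3x3 Gaussian input
#' blur (reconstruction target stays unblurred).  Fully deterministic for a
#' fixed seed.
#'
#' @param crops list of `cell_crop` objects.
#' @param config an [encoder_config()].
#' @return List `model` (class `cell_autoencoder`: `params`, `config`,
#'   `bn_run` running statistics), `loss_history` (total per epoch),
#'   `parts_history` (data.frame with `mae`, `ssim`, `kld` per epoch).
#' @export
train_autoencoder <- function(crops, config = encoder_config()) {
  stopifnot(length(crops) >= 1, inherits(config, "encoder_config"))
  n <- length(crops)
  with_seed(config$seed, {
    p <- .init_params(config)
    run <- list(mean = numeric(config$feature_depth),
                var = rep(1, config$feature_depth))
    mstate <- .zero_like(p); vstate <- .zero_like(p)
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tstep <- 0
    loss_history <- numeric(config$epochs)
    parts <- data.frame(mae = numeric(config$epochs),
                        ssim = numeric(config$epochs),
                        kld = numeric(config$epochs))
    for (ep in seq_len(config$epochs)) {
      lr_t <- config$lr * config$lr_decay^(ep - 1)
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch))
      ep_loss <- 0; ep_mae <- 0; ep_ssim <- 0; ep_kld <- 0; nseen <- 0
      for (bidx in batches) {
        aug <- if (config$augment)
          list(k90 = sample(0:3, length(bidx), replace = TRUE),
               flip = sample(c(FALSE, TRUE), length(bidx), replace = TRUE)) else NULL
        bt <- .assemble_batch(crops, bidx, aug, blur = config$augment)
        cache <- .ae_forward(p, config, bt$x, bt$sh, bt$valid, train = TRUE, run = run)
        run <- cache$run
        rl <- .recon_loss_grad(cache$recon, bt$target, config$loss_terms)
        kld <- 0; kld_scale <- 0
        if (config$variant == "VAE") {
          B <- length(bidx)
          kld_raw <- sum(-0.5 * (1 + cache$lv - cache$mu^2 - exp(cache$lv))) / B
          kld <- config$kld_weight * kld_raw
          kld_scale <- config$kld_weight / B
        }
        total <- rl$mae + rl$ssim_term + kld
        if (!is.finite(total))
          stop(sprintf("train_autoencoder: non-finite loss at epoch %d", ep), call. = FALSE)
        g <- .ae_backward(p, config, cache, rl$grad, bt$sh, bt$valid, kld_scale)
        tstep <- tstep + 1
        for (nm in names(p)) {
          mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
          vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- mstate[[nm]] / (1 - b1^tstep)
          vhat <- vstate[[nm]] / (1 - b2^tstep)
          p[[nm]] <- p[[nm]] - lr_t * mhat / (sqrt(vhat) + epsA)
        }
        w <- length(bidx)
        ep_loss <- ep_loss + total * w; ep_mae <- ep_mae + rl$mae * w
        ep_ssim <- ep_ssim + rl$ssim_term * w; ep_kld <- ep_kld + kld * w
        nseen <- nseen + w
      }
      loss_history[ep] <- ep_loss / nseen
      parts$mae[ep] <- ep_mae / nseen
      parts$ssim[ep] <- ep_ssim / nseen
      parts$kld[ep] <- ep_kld / nseen
    }
    model <- structure(list(params = p, config = config, bn_run = run),
                       class = "cell_autoencoder")
    list(model = model, loss_history = loss_history, parts_history = parts)
  })
}

#' Embed crops as L2-normalized latent vectors
#'
#' Deterministic eval-mode forward pass: encoder (+ shape cross-attention for
#' MHAAE), 1x1 latent projection, global average pooling, L2 normalization.
#' The VAE variant embeds the posterior mean.
#'
#' @param model a trained `cell_autoencoder`.
#' @param crops list of `cell_crop` objects.
#' @return Numeric matrix `n x latent_dim`; every row has unit Euclidean
#'   norm.
#' @export
embed_cells <- function(model, crops) {
  stopifnot(inherits(model, "cell_autoencoder"))
  cfg <- model$config; p <- model$params
  n <- length(crops)
  out <- matrix(0, n, cfg$latent_dim)
  bs <- min(cfg$batch, n)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    bt <- .assemble_batch(crops, idx, aug = NULL, blur = FALSE)
    cache <- .ae_forward(p, cfg, bt$x, bt$sh, bt$valid, train = FALSE,
                         run = model$bn_run)
    lat <- if (cfg$variant == "VAE") cache$mu else cache$lat_pre
    nrm <- sqrt(rowSums(lat^2)); nrm[nrm < 1e-12] <- 1
    out[idx, ] <- lat / nrm
  }
  out
}

#' Reconstruct crops through the trained autoencoder
#'
#' Eval-mode forward pass (batch-norm running statistics, no augmentation,
#' VAE decodes the posterior mean).  Used for reconstruction-quality checks.
#'
#' @inheritParams embed_cells
#' @return Array `(128, 128, 1, n)` of reconstructions on the normalized
#'   `[-1, 1]` scale.
#' @export
reconstruct_cells <- function(model, crops) {
  stopifnot(inherits(model, "cell_autoencoder"))
  cfg <- model$config; p <- model$params
  n <- length(crops)
  out <- array(0, c(128, 128, 1, n))
  bs <- min(cfg$batch, n)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    bt <- .assemble_batch(crops, idx, aug = NULL, blur = FALSE)
    cache <- .ae_forward(p, cfg, bt$x, bt$sh, bt$valid, train = FALSE,
                         run = model$bn_run)
    out[, , , idx] <- cache$recon
  }
  out
}
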