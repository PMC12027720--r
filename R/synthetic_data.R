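# ---- synthetic scenes, cell-crop populations, random SPD fixtures -----------
#
# The original single-cell phase-contrast data behind this package's design is
# not redistributable, so everything downstream is exercised on synthetic
# stand-ins: textured elliptical "cells" on a noisy background with exact
# instance masks and class labels, and crop populations with controlled shape
# classes.  No attempt is made at phase-contrast optics (halo / shade-off).

# Texture palette.  Amplitude 0.3 (peak-to-peak contrast 0.6) and a cell
# base level close to the background keep the class signal in the local
# second-order statistics rather than in mean-intensity steps at cell
# borders: covariance descriptors are blind to the patch mean but are badly
# contaminated by intensity edges inside a patch.  These values were set
# from a one-off separability analysis (supervised nearest-class-mean
# recovery on descriptor space must be near-perfect for the unsupervised
# recovery task to be well-posed); see the methods vignette.
.texture_params <- list(
  list(freq = 0.25, theta = 0),            # class 1: vertical stripes
  list(freq = NA,   theta = NA),           # class 2: isotropic speckle
  list(freq = 0.25, theta = pi / 2),       # class 3: stripes rotated 90 deg
  list(freq = 0.40, theta = pi / 4)        # class 4: finer 45-deg stripes
)
.cell_level <- 0.5
.bg_level <- 0.4

.render_texture <- function(class_id, h, w, phase = 0) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (class_id == 2) {
    z <- matrix(rnorm(h * w), h, w)
    z <- blur3(z)
    z <- z / max(sd(as.numeric(z)), 1e-12)
    .cell_level + 0.3 * pmax(pmin(z, 1.5), -1.5) / 1.5
  } else {
    p <- .texture_params[[class_id]]
    u <- cos(p$theta) * xx + sin(p$theta) * yy
    .cell_level + 0.3 * sin(2 * pi * p$freq * u + phase)
  }
}

#' Generate a synthetic textured scene with ground truth
#'
#' Places `n_cells` elliptical cells with class-specific textures (oriented
#' sinusoidal stripes or isotropic speckle) on a background of low-amplitude
#' Gaussian noise (sd 0.05 around level 0.4).  Classes are assigned
#' round-robin so every class is represented.  Overlaps are resolved by
#' placement priority: a later cell is clipped by all earlier masks, and a
#' candidate keeping less than half of its pixels is rejected and re-sampled
#' (at most 1000 attempts per cell).
#'
#' @param width,height scene size in pixels (`>= 32`).
#' @param n_cells number of cells to place (0 allowed).
#' @param n_classes number of texture classes, 1..4.
#' @param seed integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `synthetic_scene`: list with `image` (h x w in
#'   `[0,1]`), `label_map` (h x w integer, 0 = background), `instance_masks`
#'   (list of logical matrices, pairwise disjoint), `cell_specs` (list of
#'   `center`, `semi_axes`, `angle`, `class`).
#' @export
generate_texture_scene <- function(width, height, n_cells, n_classes, seed) {
  stopifnot(width >= 32, height >= 32, n_cells >= 0,
            n_classes >= 1, n_classes <= 4)
  with_seed(seed, {
    image <- clamp01(.bg_level + 0.05 * matrix(rnorm(height * width), height, width))
    label_map <- matrix(0L, height, width)
    occupied <- matrix(FALSE, height, width)
    masks <- list()
    specs <- list()
    for (i in seq_len(n_cells)) {
      cls <- (i - 1L) %% n_classes + 1L
      placed <- FALSE
      for (attempt in seq_len(1000)) {
        a <- runif(1, 12, max(14, min(width, height) / 4))
        b <- a * runif(1, 0.55, 1)
        th <- runif(1, 0, pi)
        cy <- runif(1, a + 1, height - a)
        cx <- runif(1, a + 1, width - a)
        m <- ellipse_mask(height, width, cy, cx, a, b, th)
        kept <- m & !occupied
        if (sum(kept) >= 0.5 * sum(m) && sum(kept) >= 40) {
          phase <- runif(1, 0, 2 * pi)
          tex <- .render_texture(cls, height, width, phase)
          image[kept] <- clamp01(tex[kept] + 0.02 * rnorm(sum(kept)))
          label_map[kept] <- cls
          occupied <- occupied | kept
          masks[[length(masks) + 1L]] <- kept
          specs[[length(specs) + 1L]] <- list(center = c(cy, cx),
                                              semi_axes = c(a, b),
                                              angle = th, class = cls)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf("generate_texture_scene: could not place cell %d after 1000 attempts", i),
             call. = FALSE)
    }
    structure(list(image = image, label_map = label_map,
                   instance_masks = masks, cell_specs = specs),
              class = "synthetic_scene")
  })
}

#' Generate a population of synthetic single-cell crops
#'
#' Emulates masked single-cell crops: class 0 cells are round (axis ratio
#' close to 1), class 1 cells are elongated (axis ratio >= 3), an optional
#' class 2 is intermediate.  Each cell is drawn at its natural size with a
#' smooth interior texture plus speckle, then passed through the same crop
#' pipeline as real data ([crop_cells()] machinery): tight bounding box,
#' aspect-preserving resize to 128 x 128, mean/std 0.5 normalization, padding
#' mask.
#'
#' @param n number of crops (`>= 1`).
#' @param class_fractions numeric vector summing to 1; length = number of
#'   shape classes (1..3).
#' @param seed integer seed.
#' @return List of `n` samples, each a list with `crop` (a `cell_crop`, see
#'   [crop_cells()]) and `true_class` (0-based integer).
#' @export
generate_cell_crops <- function(n, class_fractions, seed) {
  stopifnot(n >= 1, length(class_fractions) >= 1, length(class_fractions) <= 3,
            abs(sum(class_fractions) - 1) < 1e-8, all(class_fractions >= 0))
  ratio_band <- list(c(1.0, 1.2), c(3.0, 4.0), c(1.8, 2.2))
  # largest-remainder apportionment of n over the classes
  raw <- n * class_fractions
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  classes <- rep.int(seq_along(cnt) - 1L, cnt)
  with_seed(seed, {
    classes <- sample(classes)
    lapply(seq_len(n), function(i) {
      cls <- classes[i]
      band <- ratio_band[[cls + 1L]]
      ratio <- runif(1, band[1], band[2])
      # natural semi-minor axis with size jitter; elongated cells keep a
      # comparable area so area alone does not separate the classes
      b <- runif(1, 14, 22) / sqrt(ratio)
      a <- b * ratio
      th <- runif(1, 0, pi)
      half <- ceiling(a) + 3
      hw <- 2L * as.integer(half) + 1L
      cy <- half + 1 + runif(1, -1, 1)
      cx <- half + 1 + runif(1, -1, 1)
      m <- ellipse_mask(hw, hw, cy, cx, a, b, th)
      img <- matrix(0, hw, hw)
      tex <- matrix(rnorm(hw * hw), hw, hw)
      tex <- blur3(tex)
      tex <- tex / max(sd(as.numeric(tex)), 1e-12)
      img[m] <- clamp01(0.65 + 0.12 * tex[m])
      # tight bounding box, as crop_cells() would produce from a label image
      ys <- range(which(rowSums(m) > 0)); xs <- range(which(colSums(m) > 0))
      crop <- .make_cell_crop(img[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE],
                              m[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE],
                              c(ys[1], ys[2] + 1L, xs[1], xs[2] + 1L))
      list(crop = crop, true_class = cls)
    })
  })
}

#' Random SPD matrix fixture
#'
#' Draws a random orthogonal basis (QR of a Gaussian matrix), eigenvalues
#' spanning exactly `[1/cond_max, 1]`, and a random overall scale in
#' `[0.5, 2]`.  With `cond_max = 1` the result is a positive multiple of the
#' identity.
#'
#' @param d dimension (`>= 1`).
#' @param cond_max maximal condition number (`>= 1`).
#' @param seed integer seed.
#' @return `d x d` SPD matrix.
#' @export
random_spd <- function(d, cond_max, seed) {
  stopifnot(d >= 1, cond_max >= 1)
  with_seed(seed, {
    scale <- runif(1, 0.5, 2)
    if (d == 1) return(matrix(scale, 1, 1))
    lam <- c(1, 1 / cond_max, if (d > 2) runif(d - 2, 1 / cond_max, 1))
    Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
    A <- Q %*% (scale * lam * t(Q))
    (A + t(A)) / 2
  })
}

#' Write a synthetic scene to disk
#'
#' The image goes out as an 8-bit grayscale PNG plus a full-precision CSV,
#' instance labels as an integer CSV, and `cell_specs` as a JSON sidecar.
#' (Plain-text CSV stands in for multi-bit TIFF so artifacts stay text-only.)
#'
#' @param scene a `synthetic_scene`.
#' @param out_prefix path prefix; files `<prefix>_image.png`,
#'   `<prefix>_image.csv`, `<prefix>_labels.csv`, `<prefix>_specs.json`.
#' @param hash optional config hash embedded in every artifact.
#' @return Invisibly, the vector of file paths written.
#' @export
write_scene <- function(scene, out_prefix, hash = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  paths <- paste0(out_prefix, c("_image.png", "_image.csv", "_labels.csv", "_specs.json"))
  png::writePNG(scene$image, paths[1])
  write_matrix_csv(scene$image, paths[2], hash = hash)
  write_matrix_csv(scene$label_map, paths[3], hash = hash)
  inst <- lapply(scene$cell_specs, function(s)
    list(center = s$center, semi_axes = s$semi_axes, angle = s$angle, class = s$class))
  jsonlite::write_json(list(config_hash = hash, cell_specs = inst),
                       paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
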