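# ---- single-cell crops ------------------------------------------------------

# Bilinear resize of a numeric matrix to (out_h, out_w), sampling at pixel
# centers (align-corners = FALSE convention).
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  sy <- h / out_h; sx <- w / out_w
  yc <- (seq_len(out_h) - 0.5) * sy + 0.5
  xc <- (seq_len(out_w) - 0.5) * sx + 0.5
  iy <- pmin(pmax(floor(yc), 1), h); iy2 <- pmin(iy + 1, h)
  ix <- pmin(pmax(floor(xc), 1), w); ix2 <- pmin(ix + 1, w)
  fy <- pmin(pmax(yc - iy, 0), 1)
  fx <- pmin(pmax(xc - ix, 0), 1)
  A <- img[iy, ix, drop = FALSE]; B <- img[iy, ix2, drop = FALSE]
  C <- img[iy2, ix, drop = FALSE]; D <- img[iy2, ix2, drop = FALSE]
  Fy <- matrix(fy, out_h, out_w); Fx <- matrix(fx, out_h, out_w, byrow = TRUE)
  (1 - Fy) * ((1 - Fx) * A + Fx * B) + Fy * ((1 - Fx) * C + Fx * D)
}

# Nearest-neighbor resize for boolean masks.
nearest_resize <- function(mask, out_h, out_w) {
  h <- nrow(mask); w <- ncol(mask)
  iy <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * h / out_h), 1), h)
  ix <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * w / out_w), 1), w)
  mask[iy, ix, drop = FALSE]
}

# Build a cell_crop from a masked source image patch: zero the background,
# aspect-preserving resize so the longer side becomes 128, symmetric zero
# letterboxing, then normalize (x - 0.5) / 0.5.
.crop_size <- 128L

.make_cell_crop <- function(img, mask, bbox = c(1L, nrow(img) + 1L, 1L, ncol(img) + 1L)) {
  stopifnot(any(mask))
  orig_h <- nrow(img); orig_w <- ncol(img)
  orig_area <- sum(mask)
  img <- img * mask  # background to 0 before normalization
  s <- .crop_size / max(orig_h, orig_w)
  new_h <- max(1L, as.integer(round(orig_h * s)))
  new_w <- max(1L, as.integer(round(orig_w * s)))
  ri <- bilinear_resize(img, new_h, new_w)
  rm_ <- nearest_resize(mask, new_h, new_w)
  pix <- matrix(0, .crop_size, .crop_size)
  pm <- matrix(FALSE, .crop_size, .crop_size)
  y0 <- (.crop_size - new_h) %/% 2L
  x0 <- (.crop_size - new_w) %/% 2L
  pix[y0 + seq_len(new_h), x0 + seq_len(new_w)] <- ri
  pm[y0 + seq_len(new_h), x0 + seq_len(new_w)] <- rm_
  if (!any(pm)) pm[y0 + 1L, x0 + 1L] <- TRUE  # degenerate tiny masks
  structure(list(pixels = (clamp01(pix) - 0.5) / 0.5,
                 padding_mask = pm,
                 orig_size = c(orig_h, orig_w),
                 orig_area = orig_area,
                 bbox = as.integer(bbox)),
            class = "cell_crop")
}

#' Cut masked, normalized single-cell crops out of an image
#'
#' For every instance label `>= 1` in `instance_labels`: take the tight
#' bounding box, zero all pixels outside the instance mask, resize
#' aspect-preserving so the longer side is 128 (bilinear for intensities,
#' nearest-neighbor for the mask), letterbox symmetrically with zeros to
#' 128 x 128, and normalize intensities as `(x - 0.5) / 0.5`.  The original
#' bounding-box size and mask pixel count are kept for downstream shape
#' conditioning and morphology statistics.
#'
#' @param image 2-D numeric array, intensities in `[0, 1]`.
#' @param instance_labels integer matrix of the same shape; 0 = background.
#' @return List of `cell_crop` objects in ascending label order.  Each has
#'   `pixels` (128 x 128, normalized), `padding_mask` (TRUE on real cell
#'   pixels), `orig_size` = (h, w) of the bounding box, `orig_area` = instance
#'   pixel count, `bbox` = half-open `(y0, y1, x0, x1)` (1-based start).
#' @export
crop_cells <- function(image, instance_labels) {
  stopifnot(is.matrix(image), all(dim(image) == dim(instance_labels)))
  ids <- sort(unique(instance_labels[instance_labels >= 1]))
  crops <- list()
  for (id in ids) {
    m <- instance_labels == id
    if (!any(m)) { warning(sprintf("instance %d has an empty mask; skipped", id)); next }
    ys <- range(which(rowSums(m) > 0)); xs <- range(which(colSums(m) > 0))
    bbox <- c(ys[1], ys[2] + 1L, xs[1], xs[2] + 1L)
    sub_i <- image[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
    sub_m <- m[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE]
    crops[[length(crops) + 1L]] <- .make_cell_crop(sub_i, sub_m, bbox)
  }
  crops
}
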