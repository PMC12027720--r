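# riemcell

Unsupervised analysis of grayscale microscopy images of cultured cells, in
two arms:

1. **Texture segmentation on the SPD manifold.**  Local image structure is
   summarized by *region covariance descriptors* — covariance matrices of
   per-pixel feature vectors over patches, which are symmetric positive
   definite (SPD) and live on a Riemannian manifold.  A dictionary of
   tangent-space atoms `Z_k` and an amortized linear encoder `(W, b)` are
   learned by minimizing the Stein-divergence reconstruction loss

   ```
   L = (1/N) Σᵢ S(Aᵢ, exp(Σₖ ωᵢₖ Zₖ)) + α (1/N) Σᵢ ‖ωᵢ‖₁ + β mean₍₄₋ₙₑᵢgₕᵦₒᵣ₎ ‖ωₐ − ω_b‖²,
   ωᵢ = W vec(log Aᵢ) + b,
   S(A, B) = log det((A+B)/2) − ½ log det A − ½ log det B.
   ```

   K-Means on the weight field, Gaussian soft assignments, and fold-with-
   averaging rendering yield per-pixel, per-class probability maps and an
   argmax label map — unsupervised segmentation.

2. **Single-cell latent morphology.**  Masked cell crops (tight bounding
   box, background zeroed, aspect-preserving resize to 128×128, mean/std 0.5
   normalization) are embedded by a convolutional autoencoder (5 stride-2
   conv stages to a 4×4×256 map; kernel 4, padding 1) whose bottleneck can
   attend over spatial positions with queries conditioned on the cell's
   bounding-box shape (multi-head cross-attention with the letterbox masked
   out).  The 1×1-projected, globally pooled, **L2-normalized 256-d latent**
   is the cell embedding.  Latents go through Barnes–Hut t-SNE under a
   cosine metric to 2-D, HDBSCAN with the 1–2 % minimum-cluster-size rule
   (noise = −1), and per-cluster morphology statistics
   (n, mean mask area, SEM = sd/√n).

Because the kind of data this targets (phase-contrast time-lapse of
myoblast-like cultures) is typically not redistributable, a first-class
synthetic module generates textured elliptical cells with exact instance
masks, shape-class crop populations, and random SPD fixtures; the entire
test battery runs without any download.

## Worked example

```r
library(riemcell)

## segmentation arm: plant two textures, recover them without labels
scene <- generate_texture_scene(width = 128, height = 128, n_cells = 5,
                                n_classes = 2, seed = 0)
stack  <- feature_stack(scene$image)                   # 6 derivative planes
ex     <- extract_patches(stack, patch_size = 16, stride = 8)
covs   <- lapply(ex$patches, patch_covariance)         # 225 SPD descriptors
model  <- init_dictionary(covs, K = 4, seed = 1)
fit    <- fit_dictionary(model, covs, ex$grid, epochs = 100, lr = 1e-2)
field  <- encode_weight_field(fit$model, covs, ex$grid)
km     <- cluster_patch_weights(field, C = 3, seed = 0)
maps   <- render_probability_map(ex$grid, soft_assignments(field, km$centers))

## morphology arm: round vs elongated cells
samples <- generate_cell_crops(200, c(0.5, 0.5), seed = 7)
crops   <- lapply(samples, `[[`, "crop")
truth   <- vapply(samples, `[[`, numeric(1), "true_class")
cfg     <- encoder_config(variant = "MHAAE", epochs = 4, batch = 64, seed = 1)
ae      <- train_autoencoder(crops, cfg)
lat     <- embed_cells(ae$model, crops)                # 200 x 256, unit rows
emb     <- tsne_project(lat, perplexity = 20, seed = 2)
labels  <- cluster_embeddings(emb, min_cluster_frac = 0.02)
cluster_area_stats(labels, crops)
```

Output of this exact script (fixed seeds):

```
dictionary loss: 0.0881 -> 0.0862
patch-majority ARI vs ground truth: 0.434
autoencoder loss: 1.765 -> 1.615
clusters found: 2 (noise: 0)  ARI vs shape classes: 1.000
  cluster   n mean_area sem_area
1       0 100   1033.05 27.24100
2       1 100   1047.44 27.13314
```

Reading it: 100 epochs of dictionary descent lower the Stein+penalty loss;
clustering the learned patch weights recovers the planted texture layout at
patch-majority adjusted Rand index 0.43 at this training depth (≈0.6 at the
500-epoch default — boundary patches cap it; see the methods vignette).  The
morphology arm separates the two planted shape classes perfectly (ARI 1.0)
after only 4 epochs, because the shape-conditioned bottleneck makes
round-versus-elongated linearly visible in the latent space; the per-cluster
mean mask areas are statistically indistinguishable (the two classes were
generated area-matched, so area alone could not have produced the split).

## Command line

```sh
./exec/riemcell simulate-scene --width 128 --height 128 --cells 5 --classes 2 \
                               --seed 0 --out-prefix scene
./exec/riemcell fit-dictionary --image scene_image.csv --config cfg.yaml \
                               --out-model dict.json
./exec/riemcell segment --image scene_image.csv --model dict.json \
                        --classes 3 --out-prefix seg
./exec/riemcell crop | train-ae | embed | tsne | cluster ...   # morphology arm
```

One `--seed`/`seed:` key drives every stage through a documented splitting
rule; rerunning any stage with the same config reproduces its CSV artifacts
byte for byte, and every artifact embeds the SHA-256 hash of the resolved
configuration.

## Documentation

The methods vignette (`vignettes/riemcell-methods.Rmd`) documents the model,
parameter defaults with units, the synthetic world and what green tests do
and do not establish, numerical choices, and known limitations — including
the one deliberately red acceptance expectation (patch-level segmentation
ARI ≥ 0.7, which exceeds what single-patch covariance descriptors support on
the reference scene).
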