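# lodgeseg

Compact attention-augmented semantic segmentation for mapping crop
lodging in aerial field imagery.

Rice lodging — stems flattened by wind, rain or excess nitrogen — is
surveyed today by flying an RGB camera over the paddy and segmenting the
orthomosaic into background / healthy canopy / lodged canopy. The two
vegetation classes share very similar colours, and the models that do the
segmentation must stay small enough to deploy near the field. This
package implements, in R, the two training-time techniques that make
small segmentation networks competitive at this task, plus everything
needed to exercise them end-to-end on a desktop CPU:

* **A global attention block** (`gattn_*`): a single-head query–key–value
  unit for convolutional feature maps. The input `H × W × C` map is
  projected to a low-dimensional embedding `C′` (default 64), split into
  query/key/value matrices, and every pair of spatial positions is
  compared through the global affinity `M_I = M₁ M₂ᵀ` (an
  `(HW) × (HW)` matrix, so each output position sees the whole image).
  After aggregation and a two-layer MLP recalibration, the map is
  average-pooled over channels and applied residually,
  `X̃ = (A_R + 1) ⊗ X` — a zero-initialised block is an exact identity.
* **Channel-wise knowledge distillation** (`kd_loss`, `distill_step`,
  `train_segmodel(..., teacher=)`): a student is trained on
  `L = L_CE + α·L_KD`, where `L_KD` compares teacher and student
  *per-channel spatial distributions* under a temperature softmax
  `θ(Y_c)_i = exp(Y_{c,i}/T) / Σ_j exp(Y_{c,j}/T)` with a `T²/C`
  prefactor (defaults `T = 4`, `α = 3`).
* **Compact encoder–decoder models** (`build_segmodel`): residual, plain
  or bottleneck backbones with stride-2 stages, an ASPP decoder (three
  atrous convolutions at distinct rates plus a pointwise branch), and
  bilinear upsampling of logits to label resolution. Attention blocks
  insert at any (stage, block); parameter and GFLOP profilers and an
  analytic receptive-field calculator (`receptive_field`) are included.
* **A synthetic lodged-field generator** (`generate_field`): a textured
  mosaic with exact index-mask ground truth, 42% lodging cover by
  default, visually similar vegetation classes, and the full orthomosaic
  tiling protocol — disjoint 60/20/20 train/val/test bands,
  non-overlapping evaluation crops, overlapping training crops
  (`make_tileset`), PNG/CSV tile-set I/O.
* **Evaluation** (`accumulate_confusion`, `miou`): confusion-matrix
  accumulation and mean intersection over union with per-class
  reporting.

All numerics (convolution via im2col, bilinear resampling and their
adjoints) are implemented in the package with RcppArmadillo kernels, and
every gradient path is verified against finite differences in the test
suite.

## A worked example

```r
library(lodgeseg)

# a 1536x1536 synthetic paddy with 42% lodging, and its tile set
mosaic  <- generate_field(field_config(seed = 3))
mean(mosaic$mask == 2L)
#> [1] 0.4199999

tiles <- make_tileset(mosaic, split_config(crop_size = 64,
                                           n_eval_crops = 100,
                                           n_train_crops = 200,
                                           seed = 103))

# a small residual model with a global attention block in its final
# encoder block, started as an exact identity
spec <- segmodel_spec(
  backbone_spec("resnet", stages = c(1, 1), base_width = 8,
                attn_insertions = list(c(2, 1)),
                attn_config = gattn_config(embed_dim = 16,
                                           affinity_scaling = TRUE,
                                           init = "identity_start")),
  aspp_rates = c(2, 4, 6), num_classes = 3, decoder_channels = 16)

fit <- train_segmodel(spec, tiles,
                      train_config(total_epochs = 10, freeze_epochs = 0,
                                   batch_unfrozen = 8, lr0 = 2e-3,
                                   seed = 3, attn_lr_scale = 0.3),
                      augment = FALSE, class_weights = "balanced")
max(fit$metrics$val_miou)
#> [1] 0.7319066

ev <- evaluate_tiles(fit$model, tiles$tiles[tiles$manifest$split == "test"])
ev$miou
#> [1] 0.7128255
round(ev$per_class_iou, 4)
#> [1] 0.3001 0.9689 0.8694
```

`val_miou` is the mean over classes of intersection-over-union between
predicted and true masks on the 50 held-out validation tiles. This
17,739-parameter attention-augmented model reaches 0.73 validation /
0.71 test mIoU after ten epochs of CPU training (about a minute); the
same model without the attention block (16,107 parameters) plateaus
around 0.63 on this dataset because it never learns the rare background
class (compare the per-class IoU above: the attention model gets 0.30 on
background, plain students get ~0). Gains at this desk scale are
seed-dependent — see the vignette's benchmark section for the honest
picture.

The receptive-field calculus that motivates the atrous decoder:

```r
receptive_field(list(layer_spec(3), layer_spec(3)))          # 5
receptive_field(list(layer_spec(3), layer_spec(3, rate = 2))) # 7
```

A command-line front end wrapping these functions (verbs `synth`,
`tile`, `train`, `eval`, `profile`) is installed at
`system.file("cli", "lodgeseg", package = "lodgeseg")`.

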