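# anisoseg

Instance segmentation of **anisotropic 3D electron-microscopy volumes**
with a selective state-space (Mamba-style) encoder–decoder, in R.

Serial-section EM volumes have voxels that are 5–10× coarser along the
cutting axis (z) than in-plane (x–y). `anisoseg` implements a network that
respects this asymmetry: at full resolution, features are scanned as 1D
sequences along the four planar directions (within each slice) and
bidirectionally along z; after in-plane down-sampling makes the features
approximately isotropic, full-volume scans take over. The package is a
complete, tested pipeline for this model class:

* **SSM core** — zero-order-hold discretization
  (`A_bar = exp(ΔA)`, `B_bar = (ΔA)⁻¹(exp(ΔA) − I)ΔB`), the sequential
  recurrence `h_t = A_bar h_{t−1} + B_bar x_t`, `y_t = C h_t`, its
  global-convolution dual, and the selective (input-dependent) variant.
* **Scanning orders** — exact permutation unfold/fold for planar,
  volumetric and bidirectional-depth traversals.
* **Blocks & network** — residual visual state-space modules with channel
  attention, anisotropic (SAA) and isotropic (SIA) adaptation modules,
  and a U-shaped network with the stride schedule
  `[1,2,2],[1,2,2],[1,1,1],[2,2,2]`.
* **Losses** — Dice + foreground-proportion-weighted BCE, for affinity
  (3-channel) or mask+boundary (2-channel) heads.
* **Training** — a built-in tape-based reverse-mode autodiff engine with
  compiled kernels (conv3d, fused selective scan, layer norm) and AdamW.
* **Inference** — Gaussian-blended sliding-window prediction
  (patch 8×256×256, stride 4×128×128 by default).
* **Post-processing** — marker-controlled watershed and union-find
  affinity agglomeration.
* **Metrics** — split/merge variation of information, adapted Rand error,
  size-stratified AP-75.
* **Synthetic data** — anisotropic neurite-like and mitochondria-like
  labeled volumes plus the standard eight augmentations, so everything is
  testable without external datasets.

## Worked example

```r
library(anisoseg)

# 1. a synthetic anisotropic volume with dense neurite-like tubes
gen <- generate_neuron_like(synth_spec(shape = c(8L, 64L, 64L),
                                       n_instances = 10L, seed = 7L))
aff <- labels_to_affinities(gen$labels)   # (3, D, H, W) z/y/x affinities

# 2. a small network + a few AdamW steps on this one patch
cfg   <- network_config(stage_widths = c(4L, 8L, 12L, 16L), N = 4L,
                        patch_size = c(8L, 64L, 64L))
model <- build_network(cfg, seed = 1)
opt   <- adamw_state(model, lr = 1e-3)
patch  <- array(gen$image, c(1, 1, 8, 64, 64))
target <- array(aff,       c(1, 3, 8, 64, 64))
for (i in 1:20) {
  st <- train_step(model, patch, target, loss_spec(scheme = "affinity"), opt)
  model <- st$model; opt <- st$opt
  if (i %% 10 == 0) cat("iter", i, "loss", round(st$loss, 4), "\n")
}
#> iter 10 loss 1.2787
#> iter 20 loss 1.1901

# 3. blended prediction and instance recovery
prob <- blended_predict(model, gen$image,
                        plan_tiling(dim(gen$image), c(8, 64, 64), c(4, 32, 32)))
seg  <- affinities_to_instances(prob, merge_threshold = 0.5, min_size = 64L)

# 4. ideal-probability round trip scores perfectly
ideal <- affinities_to_instances(aff, merge_threshold = 0.5)
metric_report(ideal, gen$labels)[c("voi_total", "arand")]
#> $voi_total
#> [1] 0
#> $arand
#> [1] 0
```

The loss values printed above are from the first 20 optimization steps on
one patch (the test suite carries the full 200-step run, which cuts the
composite loss by well over half). `voi_total = 0`, `arand = 0` confirm
that converting labels to affinities and agglomerating them back recovers
the original instances exactly, up to relabeling.

A command-line wrapper with `generate`, `train`, `predict` and `evaluate`
subcommands lives at `inst/cli/anisoseg`; volumes travel as multipage TIFF
stacks and configurations as YAML.

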