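---
title: "Anisotropy-aware state-space segmentation of 3D EM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropy-aware state-space segmentation of 3D EM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisoseg)
```

## The problem

Serial-section electron microscopy produces 3D volumes whose voxels are
strongly anisotropic: the in-plane (x-y) resolution is set by the imaging
optics (~6-8 nm), while the z resolution is set by the physical section
thickness (~30 nm), 5-10x coarser.  Neurites and organelles therefore look
crisp within a slice and jump abruptly between slices.  Instance
segmentation of such volumes — assigning each neurite or mitochondrion its
own integer label — needs long-range context within slices, careful
modelling along the cutting axis, and post-processing that turns dense
per-voxel predictions into instances.

`anisoseg` implements a selective state-space (Mamba-style) encoder-decoder
for this setting, together with everything needed to exercise it end to end
on synthetic data: directional scanning orders, the anisotropic/isotropic
adaptation blocks, Dice + weighted-BCE losses, Gaussian-blended
sliding-window inference, watershed and affinity-agglomeration
post-processing, and split/merge VOI, adapted Rand error and size-stratified
AP-75 metrics.

## The state-space model

The continuous model is $h'(t) = A\,h(t) + B\,x(t)$, $y(t) = C\,h(t)$ with a
diagonal state transition over $N$ hidden states per channel.  A positive
step size $\Delta$ converts it to a discrete recurrence by zero-order hold:

$$\bar A = \exp(\Delta A), \qquad
  \bar B = (\Delta A)^{-1}(\exp(\Delta A) - I)\,\Delta B ,$$

applied elementwise over the diagonal.  When $|\Delta A| < 10^{-8}$ the
analytic limit $\bar B \to \Delta B$ replaces the quotient, which would
otherwise cancel catastrophically.  The recurrence
$h_t = \bar A h_{t-1} + \bar B x_t$, $y_t = C h_t$ is equivalent, for
time-invariant parameters, to a causal convolution with the structured
kernel $\bar K = (C\bar B, C\bar A\bar B, \dots, C\bar A^{M-1}\bar B)$;
`ssm_scan()` and `kernel_convolve()` implement the two routes and the test
suite checks their agreement to $10^{-5}$ over random parameter draws.

The *selective* variant makes $\Delta$, $B$ and $C$ functions of the input
at each step.  Here $B_t$ and $C_t$ are dense channel-to-state maps
($x_t W_B + b_B$), as in the selective-scan designs this block follows,
while $\Delta_{t,c} = \mathrm{softplus}(w_c x_{t,c} + b_c)$ is a
*per-channel affine* map rather than a dense one: a diagonal map keeps the
naive sequential scan affordable while retaining input-dependent step
sizes.  All recurrences run as explicit sequential loops (compiled, but no
parallel prefix scan): correctness and portability over speed.

```{r}
p <- ssm_params(A = -1, B = 1, C_out = 1, delta = log(2))
discretize_zoh(p)           # A_bar = B_bar = 0.5
```

## Scanning orders

Feature volumes are 5-axis arrays `(batch, channel, depth, height, width)`.
A scanning direction is a permutation that unfolds the volume into 1D
sequences:

* **Planar four-direction scanning** (`scan_2d_expanded`): each depth slice
  independently, along `row-forward`/`row-backward` (x innermost) and
  `col-forward`/`col-backward` (y innermost).  The four outputs are merged
  by arithmetic mean, which keeps the activation scale independent of the
  direction count.  No information crosses slices — the right behaviour at
  full resolution where z is physically coarse.
* **Bidirectional depth scanning** (`scan_bidirectional`): the
  depth-outermost unfolding traversed forwards and backwards, outputs
  summed ($y_t = C(s^\rightarrow_t + s^\leftarrow_t)$); forward and
  backward recursions carry independent parameters but share the output
  projection.
* **Volumetric scanning** (`scan_3d_expanded`): the whole block as one
  sequence.  Two fixed axis orders are used where two different volumetric
  scans are required: depth-outermost (`"dhw"`) and width-outermost
  (`"whd"`).  The orders are a free choice — the architecture only requires
  that the two cascaded units traverse the volume differently.

Indexing is 0-based row-major in spirit: `row-forward` increases x within a
row, `col-forward` increases y within a column; depth is always the axis of
anisotropy.  Every unfold is an exact permutation (`fold(unfold(v, d), d)`
is bitwise identity), which the tests check for all eight directions.

## Blocks and architecture

The **RVSSM** (residual visual state-space module) is transformer-shaped:
layer-normalize, apply the gated selective-scan VSSM, add a skip; then
layer-normalize, apply channel attention, add a skip.  The VSSM follows the
usual visual-state-space design: a pointwise expansion (factor 2), a
depthwise 1x3x3 convolution, SiLU, the directional scan, layer norm, a
multiplicative SiLU gate, and a pointwise projection back.  Channel
attention is squeeze-excite-shaped with reduction ratio 4 (small, because
stage widths are small); normalization is layer normalization over
channels throughout, and the smooth gated unit (SiLU) is the single
activation used repo-wide.

The **SAA** (anisotropic adaptation) module runs two branches over its
input: a planar-scanned RVSSM followed by a 1x3x3 convolution block and a
1x3x3 residual block, and a bidirectionally-scanned RVSSM followed by their
3x1x1 counterparts.  The branches are concatenated to `2C` channels and a
bare 1x1x1 convolution (no norm or activation — the fusion is linear)
restores `C`.  The **SIA** (isotropic adaptation) module cascades two units
of RVSSM + 3x3x3 convolution block + 3x3x3 residual block, with the two
different volumetric scan orders.

The network is U-shaped: a stem convolution, three SAA stages with a skip
at each resolution, and down-sampling by strided convolution with the
schedule `[1,2,2], [1,2,2], [1,1,1], [2,2,2]` — in-plane-only reduction
early (to equalize the physical voxel), a stride-1 third stage implemented
exactly as scheduled (a stride-1 convolution stage that changes channels
but not resolution), and an isotropic reduction into the bottleneck.  The
bottleneck holds two SIA modules, an up-sample and an isotropic
convolution module; the decoder mirrors with trilinear up-sampling
(end-aligned, exact on affine ramps), skip concatenation and anisotropic
convolution modules, ending in a head convolution.  Two heads are
supported: 3 sigmoid channels of nearest-neighbour affinities (z, y, x),
or 2 sigmoid channels of semantic mask + instance boundary.

Default stage widths are `c(16, 32, 64, 96)` with state dimension
`N = 16`, which lands the model near the few-million-parameter scale; both
are configuration, not architecture.

## Losses

The composite loss is $\alpha L_{Dice} + \beta L_{WBCE}$ with
$\alpha = \beta = 1$ by default (the weights are genuinely free
parameters).  Dice is the smoothed region overlap
$1 - (2\sum pt + \epsilon)/(\sum t + \sum p + \epsilon)$ with
$\epsilon = 10^{-6}$; its per-voxel gradient at $\epsilon = 0$ reduces to
$-2t^2/(t+p)^2$ in the two-element reduction, which a finite-difference
test pins.  The weighted BCE uses the foreground proportion
$W_f = \sum G / DHW$ and the two-branch weight map: for $W_f > 0.5$,
background voxels get weight $W_f/(1-W_f)$ and foreground 1; for
$W_f \le 0.5$, foreground gets $W_f/(1-W_f)$ and background 1.  The two
branches agree (all ones) at $W_f = 1/2$.  This is the published form,
implemented as printed and pinned by a unit test; note that in the
$W_f > 0.5$ branch it *up*-weights the minority background class.  $W_f$
is computed from the ground truth rather than the predictions — a
prediction-based "foreground proportion" would make the weights
non-stationary during training — with the literal prediction-based variant
available via `weights_from = "prediction"`.

The affinity head trains with one composite loss over the three stacked
channels; the mask+boundary head sums the composite losses of the two
channels.

## Training

Training runs on a small tape-based reverse-mode autodiff engine written
for this package: every array operation either computes plainly (inference)
or records a node whose analytic adjoint is applied on the backward sweep.
The heavy kernels — im2col convolution, the fused selective scan
(projections + recurrence + adjoint in one pass), layer normalization and
the scan permutations — are compiled.  The optimizer is AdamW with
$\beta_1 = 0.9$, $\beta_2 = 0.999$ and learning rate $10^{-4}$ by default,
matching the benchmark protocol of the underlying method.

Two deliberate scale choices keep the built-in demonstrations desk-sized:

* The **overfit demonstration** (200 steps on one fixed 8x64x64 synthetic
  patch) uses reduced stage widths `c(4, 8, 12, 16)`, `N = 4`, and a
  learning rate of $10^{-3}$.  A 200-step single-patch overfit needs a step
  size matched to its horizon; $10^{-4}$ belongs to a 200,000-iteration
  schedule.  The run reduces the composite loss by well over half.
* The **architecture contract** is exercised at the full benchmark patch
  size (1,1,8,256,256) with the default configuration.

## Inference and post-processing

`blended_predict()` slides a patch (default 8x256x256) with stride
(default 4x128x128) over the volume, accumulating
$\sum w\,\sigma(\text{logits}) / \sum w$ with a separable Gaussian weight
($\sigma$ = patch extent / 8 per axis, peak-normalized to 1).  Windows
clamp to the volume edge; volumes smaller than one patch are padded
reflectively.  Because the weights normalize out, a constant-logit model
yields an exactly constant probability volume — the key identity the tests
check.

Two post-processors convert probabilities to instances.  The
marker-controlled watershed (for the mask+boundary head) seeds 6-connected
components of `mask > 0.9 & boundary < 0.1`, floods the elevation
`boundary - mask` inside `mask > 0.8`, and drops instances below 128
voxels; the thresholds are exposed configuration, chosen as sensible
defaults rather than published values.  The affinity head uses a greedy
union-find agglomerator over nearest-neighbour affinity edges, strongest
first with lexicographic tie-breaks — a simple, deterministic in-package
stand-in for the heavier external agglomerators used in benchmark
pipelines; externally produced segmentations can be fed straight to the
metric functions instead.

## Metrics

All instance metrics are built on a sparse contingency table.  VOI is
reported as the two conditional entropies — $H(\text{seg}|\text{gt})$
(split / over-segmentation, under the conventional reading) and
$H(\text{gt}|\text{seg})$ (merge) — in bits by default; the literature is
not consistent about which component carries which name, so the
implementation names the entropies explicitly.  The adapted Rand error is
one minus the pairwise Rand F-score, ignoring ground-truth background.
AP-75 greedily matches each ground-truth instance to the prediction of
maximal IoU (one-to-one, decreasing IoU); matches at IoU >= 0.75 are TP,
the rest FN/FP.  Predictions are ranked by voxel count as a confidence
proxy (a watershed emits no scores) and AP is the un-interpolated area
under the precision-recall curve, stratified by instance size at 5,000 and
30,000 voxels.  Empty strata are reported as absent, not zero.  Both VOI
and ARAND are verified against $O(n^2)$ brute-force pair/entropy oracles.

## Synthetic data

The generator exists so every stage is testable without external
downloads.  `generate_neuron_like()` lays densely packed random-walk tubes
over a jittered grid (neuropil is space-filling, so tube radii are drawn
as 0.45-0.7 of the grid cell), carves later tubes around earlier ones,
keeps each label's largest 6-connected component, and renders dark
membranes at in-plane label transitions plus smooth texture and Gaussian
noise.  `generate_mito_like()` places anisotropically squashed ellipsoids
whose in-plane radii cycle through a small / medium / large law so all
three AP-75 strata are populated when the volume permits.  Default voxel
size is (30, 6, 6) nm.  The images are procedural models, not EM
simulations: passing tests demonstrates that the pipeline is wired
correctly and can fit structured signal, not that the network reaches
benchmark accuracy on real tissue.

Augmentation covers the standard eight operations: rotation (in-plane
multiples of 90 degrees — free 3D rotation is meaningless under 5x
anisotropy), scaling, flipping, elastic deformation (in-plane only), and
the image-only degradations missing parts (zeroed in-plane rectangles),
missing slices, motion blur and dislocation (one slice translated
in-plane).  The last two are interpretations of their names, documented as
such.  Geometric operations use nearest-neighbour sampling for labels.

## Numerical choices and limitations

* Diagonal state transition (standard structured-SSM practice); full
  matrices would make both the ZOH closed form and the naive scan
  needlessly costly.
* Small-argument threshold $10^{-8}$ for the $\bar B$ limit; softplus and
  BCE computed in overflow-stable forms; probabilities clamped at
  $10^{-7}$ in the BCE.
* Determinism: one seed fans out to parameter initialization, data
  generation, augmentation and window order; all compute is
  single-threaded apart from BLAS, and repeated runs are bitwise
  reproducible on one machine.
* The engine keeps whole activation tensors on an R-level tape; memory,
  not time, bounds the trainable patch size (a 8x64x64 patch at the
  reduced widths uses well under 2 GB).
* No GPU path, no parallel prefix scan, no mixed precision; the package
  targets correctness, testability and desk-scale experiments, not
  benchmark training runs.
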