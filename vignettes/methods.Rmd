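---
title: "Methods: model, phantom and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, phantom and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spineseg)
```

This vignette documents the scientific and numerical decisions behind
`spineseg`: what each block computes, which parameters matter and why they
default as they do, what the synthetic phantom does and does not emulate,
and where the design was genuinely open.

## The segmentation problem

Sagittal lumbar MR studies acquire paired T1- and T2-weighted stacks of the
same anatomy. The two sequences carry complementary contrast: fatty bone
marrow in the vertebral bodies is bright on T1 while discs are dark; the
water-rich nucleus pulposus makes discs bright on T2 while vertebrae are
darker. The segmentation target is a three-class voxel labelling
(background / vertebral body / intervertebral disc); a finer ten-class
scheme (L1..L5 and the four intervening discs) indexes the anatomical
graph. Stacks are thin along the slice (depth) axis — clinically ~11
slices at 4.0 mm thickness + 0.5 mm gap — and are resampled to 48 slices
at 256×256 in-plane during preprocessing. Throughout the package, arrays
are `(depth, height, width)` with depth the sagittal slice axis, and
feature maps are `(batch, channel, D, H, W)`.

## Blocks

**Frequency dynamic convolution.** `X_mod = X * sigmoid(Conv_dw(X))`
(depthwise, one filter per channel) modulates each voxel of each channel
into a data-dependent gain in (0,1); a global-pooling attention branch
produces a softmax distribution over N parallel kernel banks, and the
output is the attention-mixed convolution of `X_mod` plus a shared bias.
Because the mixture weights are per sample (not per voxel), the banks are
mixed in weight space and a single convolution is run. N is not fixed by
the architecture description; the default is N = 4 (2 in the reduced test
profile), exposed for ablation. The attention bottleneck uses a *leaky*
rectifier (slope 0.01): at test-profile widths the bottleneck can be a
single unit, and a hard rectifier can kill the entire branch at
initialization, which would contradict the intended "no dead branch"
property of the encoder.

**Three-directional state-space block.** The volume is flattened into
independent sequences along each of depth (inter-vertebral continuity),
height (bilateral symmetry) and width (anteroposterior relationships).
Each direction applies: a depthwise 1D convolution of width `d_conv` along
the sequence, a SiLU, then the discretized state-space recurrence with
per-channel diagonal state of size `d_state`, zero-order-hold state factor
`exp(Δ·A)`, Euler input path `Δ·B·u`, and input-dependent projections for
Δ (softplus), B and C — the "selective" parameterization. `h_0 = 0` at
every sequence start; scans run in ascending index order (an optional
reversed flag exists but defaults off, since nothing in the architecture
description asks for bidirectionality). A pure linear-time-invariant mode
(`ssm_params`/`ssm_recurrence`/`selective_scan`) exposes the literal
recurrence `h_t = A h_{t-1} + B x_t, y_t = C h_t` for oracle testing; the
test suite drives the O(T) evaluation against the sequential reference on
random instances. Defaults `d_state = (8, 8, 16, 16)` and
`d_conv = (3, 3, 5, 5)` across encoder stages encode monotone capacity
growth with depth; the description says these adapt with feature hierarchy
but gives no numbers.

**Encoder stage.** Stem convolution (to the stage width), the two branches
in parallel on the stem output, channel-concat + pointwise fusion, a
residual connection around the fusion, then strided (×2) convolution
downsampling. Skip features are taken pre-downsampling, so skip *s* lives
at 1/2^(s−1) resolution with the stage width. Stage widths default to
(32, 64, 128, 256); four stages are fixed so that four decoder upsamplings
restore full resolution.

**Position-aware attention fusion.** Each modality's bottleneck is
globally enhanced as `LayerNorm(F_rot) * sigmoid(W_g F_rot)`, with `F_rot`
the fused three-directional scan of the bottleneck (the "rotational" scan
is implemented as the same three-directional block with independent
weights — nothing distinguishes them structurally) and `W_g` a channel map
applied per voxel; LayerNorm normalizes over channels per voxel. The two
enhanced maps are compressed channel-pair-by-channel-pair (a per-channel
1×1×1 convolution: `out_c = w1_c F1_c + w2_c F2_c + b_c`), and an enhanced
position attention rescales the fused map: the map is mean-pooled along
each axis into positional descriptor sequences, each position is scored
linearly, the three axis scores combine additively and pass through a
sigmoid. The additive combination is the minimal-assumption reading of
"spatially adaptive weights from global positional dependencies"; it is
replaceable behind the operation contract. A constant input provably
yields a constant attention map (no baked-in positional preference).

**Anatomy graph.** Ten nodes — background (0), L1..L5 (1–5), discs
L1/L2..L4/L5 (6–9) — with an edge exactly between each vertebra and each
adjacent disc: 8 undirected edges; the background is isolated and
participates only through the self-loop added by symmetric normalization
`D^{-1/2}(A+I)D^{-1/2}`. Pooled bottleneck features project linearly to
(10, 128) node embeddings; three GCN layers `G <- ReLU(Ã G W)` propagate
context. Global pooling destroys the spatial index needed for
back-projection, so the module also produces a voxel→node soft assignment
(pointwise convolution + softmax over nodes) used to scatter the updated
node features back, added residually: with zero node features the module
is exactly the identity. The assignment map is an extension beyond the
literal projection equations and is documented as such.

**Depth-aware decoder stage.** Slice descriptors `F_depth` (mean over H, W
per channel and slice) feed a channel bottleneck
`A_d = sigmoid(W2 ReLU(W1 F_depth + b1) + b2)` — the ReLU here is part of
the stated formula and stays exact — broadcast over H and W. A boundary
branch runs dilated 3×3×3 convolutions at rates (1, 2, 4) (standard
multi-scale receptive fields; unstated in the architecture description) at
the *input* resolution and is interpolated up. Upsampling is trilinear ×2
followed by convolution ("progressive", artifact-free); fusion with the
skip is concatenation + pointwise convolution; a structure-preserving
convolution with a residual closes the stage.

**Normalization.** The architecture description is silent on
normalization layers. Without any, CPU-scale training converges an order
of magnitude more slowly; the package inserts instance normalization
(per-(batch, channel) spatial standardization with learnable gain/shift)
after the stem, fusion and decoder convolutions — the standard choice in
3D segmentation networks, where batch statistics are unusable at batch
size 1.

## Loss family

`L_HFD = λ·L_Tversky + (1−λ)·(L_Tversky^vert + ω·L_freq)` with
`L_Tversky = (Σ_c w_c (1 − TI_c)) / Σ_c w_c` and
`TI_c = (TP+ε)/(TP + α_c·FP + β_c·FN + ε)` using the soft counts
`TP = Σ p g`, `FP = Σ p(1−g)`, `FN = Σ (1−p)g`. The printed layout of the
weighted sum is read as `w_c·(1 − TI_c)` inside the normalized sum — the
only reading that is bounded and zero at perfection. Defaults are the
tuned configuration: α = 0.25, β = 0.75 with the disc β raised
*multiplicatively* by 20% ("increased by 20%" read as relative) to 0.9,
class weights (0.2, 1.2, 1.6), ε = 1e−6, ω = 0.07, λ = 0.55. `L_freq`
compares per-voxel gradient magnitudes of the vertebra maps, each the
average over the three axes of |central difference| (one-sided at
borders); the stencil is configurable in principle but the symmetric
interior stencil is the default because it matches "average of gradients
in the three directions" with second-order accuracy. All losses are built
on the package's autodiff tape, so `loss_gradient()` returns exact
derivatives; the suite checks them against central finite differences.

## Metrics

DSC and IoU keep the +1 smoothing of their printed definitions (making the
empty-vs-empty case equal 1); a strict flag removes it. Surfaces are
6-connected boundary voxels with the volume border counting as background.
HD95 takes the maximum over both directed 95th-percentile
nearest-surface-distance distributions — computing both directions makes
the naming ambiguity in the prose moot — using the linear-interpolation
percentile (R type 7), pinned for reproducibility. ASSD is the
standard symmetric mean. Distances are exact nearest-neighbour Euclidean
distances over surface voxel centres in physical mm (O(n²) pairwise; fine
at desk scale, and required to match the brute-force oracle to 1e−9).
Empty masks raise an error and are reported as missing (NA), never as 0.

## The phantom: what a green test establishes

`generate_phantom()` builds five superellipsoidal vertebral bodies stacked
along the height axis, separated by four thinner disc slabs (~0.35× the
vertebral height, the approximate clinical ratio), centred in-plane,
occupying ~80% of the height extent. Base intensities are piecewise
constant per structure and modality: T1 vertebra 0.8 / disc 0.35, T2
vertebra 0.4 / disc 0.9, background 0.1 — encoding the contrast inversion.
Both modalities share one multiplicative bias field (smooth low-order
cosine mixture scaled to ±`bias_strength`, default 0.2) and receive
independent Rician noise (magnitude of a complex Gaussian, σ =
`noise_sigma`·contrast-range, default 0.05) — the MR magnitude noise
model. Spacing defaults to (4.5, 1, 1) mm: 4.0 mm slices plus 0.5 mm gap;
in-plane spacing is unstated clinically and set to 1 mm. The same
configuration and seed always reproduce bit-identical volumes.

The phantom emulates: dual-modality contrast inversion, slab-like
anisotropic geometry, the vertebra–disc–vertebra topology that the graph
module encodes, bias-field shading and Rician noise. It does **not**
emulate: pathological deformation, soft-tissue clutter, partial-volume
boundaries, inter-patient shape variability, or misregistration (the
clinical acquisition is inherently aligned). A passing overfit test
therefore establishes that the architecture, loss and optimizer are wired
correctly and can fit spine-shaped structure — not that the model reaches
clinical accuracy, which requires the original private dataset and
GPU-scale training and is explicitly out of scope.

## Training protocol and the overfit check

Defaults follow the stated protocol exactly: Adam at 1e−3 with the rate
multiplied by 0.8 every 30 epochs; deep supervision on decoder stages 2
and 3 (placement unstated; two mid-decoder heads are the common choice)
with weight 0.4 decayed by 0.8 every 30 epochs; early stopping monitors
the mean validation Dice of vertebra and disc with patience 20 (patience
unstated). Batch size defaults to 1 (3D memory).

The acceptance trainability check overfits one 32×64×64 phantom with the
reduced test profile. Two deliberate departures from the clinical
defaults, made for the 1-CPU budget and recorded here: the test profile
uses stage widths (3, 6, 12, 24) with `d_state = 3`, N = 2 kernels and
graph width 24 (a heavier profile was originally envisaged for CI but does
not fit a pure-R training stack on one CPU within the budget); and the
overfit runs at lr = 3e−3, since 1e−3 was tuned for 190-case training and
converges ~3× slower on a single case. The step-decay schedules themselves
are never altered and are asserted exactly (criterion 8).

## Numerical choices

* Convolutions: same-padding, stride 1 inside blocks; downsampling only by
  the encoder's strided convolutions; batch-1 fast paths via im2col + BLAS.
* Upsampling and resampling: trilinear with the half-pixel convention;
  nearest neighbour for labels (no label invention).
* Scan discretization: zero-order hold on the state factor, Euler on the
  input path; Δ kept positive through softplus with init ≈ 0.1; A = −exp(A_log)
  initialized to −(1..d_state) per channel for a spread of time scales.
* Initialization: Glorot-uniform, seeded per module; instance-norm gains 1,
  biases 0; attention bottleneck bias +0.1 (alive at init).
* Degenerate inputs: empty masks error in distance metrics; spatial dims
  < 2 error before downsampling; non-divisible-by-16 volumes are rejected
  with the constraint named; non-finite losses abort training with
  diagnostics.
* Ties: argmax labelling takes the first maximal class; percentiles use
  R's type-7 interpolation.

## Known limitations

Training is CPU-bound R: practical for phantoms and method development,
not for clinical-scale data. Distance metrics are O(n²) in surface voxels.
The graph module assumes batch size 1 (the training default). The NIfTI
reader covers the little-endian single-file subset the package writes
(plus common datatypes), not the full standard. The ten-class head exists
as a configuration but the default protocol, matching the stated one-hot
scheme, is three-class; the tension between the ten-node graph and the
three-class head in the source description is resolved by keeping the
graph internal (soft assignments) and the head three-class.
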