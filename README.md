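# spineseg

Volumetric segmentation of lumbar vertebral bodies and intervertebral discs
from paired T1/T2-weighted sagittal MR stacks, in pure R (+ Rcpp kernels).

Lumbar MRI segmentation has to reconcile three things: tissue contrast that
inverts between sequences (fatty vertebral marrow is bright on T1, the
water-rich disc nucleus on T2), long-range inter-vertebral structure that a
local convolution cannot see, and a known anatomical topology — five
vertebrae sandwiching four discs. `spineseg` implements a network built
around exactly those observations, together with everything needed to
exercise it offline: a synthetic dual-modality spine phantom with
ground-truth masks, a NIfTI-1 reader/writer, surface-distance evaluation
metrics, a small reverse-mode autodiff tape so the model trains on a CPU,
and a command-line interface.

## The model

Per modality, a four-stage **spatial enhancement encoder** combines two
branches at each stage:

* **Frequency dynamic convolution** — input `X` is gated voxelwise by
  `X_mod = X ⊙ σ(Conv_dw(X))`, then convolved with an attention-weighted
  mixture of N kernel banks, `Y = Σᵢ αᵢ (Wᵢ ∗ X_mod) + b`, where
  `α = softmax(MLP(GAP(X)))` is one probability vector per sample.
* **Three-directional state-space (Mamba-style) block** — the volume is
  flattened into sequences along depth, height and width; each direction
  runs an independent selective scan of the discrete recurrence
  `h_t = Ā h_{t−1} + B̄ x_t`, `y_t = C h_t` with input-dependent Δ, B, C and
  per-channel diagonal state; outputs are concatenated and fused 1×1×1.

The two bottlenecks are fused by **position-aware attention fusion**
(per-modality enhancement `LayerNorm(F_rot) ⊙ σ(W_g F_rot)` with a
rotational three-directional scan, channel-wise cross-modal compression,
and a sigmoid position-attention map), then passed through an
**anatomy-graph module**: a fixed 10-node graph (background, L1–L5, four
discs; each vertebra adjacent to its neighbouring discs), symmetric
normalization `Ã = D^{−1/2}(A+I)D^{−1/2}`, linear projection of pooled
features to node embeddings, a three-layer GCN `G ← ReLU(Ã G W)`, and a
soft-assignment back-projection with a residual.

The decoder is four **depth-aware progressive upsampling** stages: slice
attention `A_d = σ(W₂ ReLU(W₁ F_depth + b₁) + b₂)` on in-plane-pooled
descriptors broadcast over H and W, a multi-scale dilated boundary branch
(rates 1, 2, 4), trilinear ×2 upsampling, skip fusion, and a
structure-preserving convolution.

Training minimizes the **hybrid frequency-domain-aware Tversky loss**

```
L = λ·L_Tversky + (1−λ)·(L_Tversky^vert + ω·L_freq)
```

with per-class Tversky indices `TI_c = (TP+ε)/(TP + α_c FP + β_c FN + ε)`,
class weights (0.2, 1.2, 1.6), α = 0.25, β = 0.75 with the disc β raised
20% to 0.9, ω = 0.07, λ = 0.55, and `L_freq` the mean absolute difference
of the vertebra maps' 3D gradient magnitudes. Evaluation uses DSC and IoU
with +1 smoothing, plus HD95 and ASSD in millimetres.

## Worked example

```r
library(spineseg)

# a 32x64x64 dual-modality phantom with ten-class ground truth
ph <- generate_phantom(phantom_config(shape = c(32, 64, 64), seed = 42))
mask <- to_three_class(ph$labels)

# reduced-width model, CPU training on the single phantom
model <- build_model(model_config(profile = "test", seed = 1))
zs <- function(v) (v - mean(v)) / sd(v)
x <- array(0, c(1, 2, 32, 64, 64))
x[1, 1, , , ] <- zs(ph$volume$t1); x[1, 2, , , ] <- zs(ph$volume$t2)
fit <- train_model(model, list(as_case(x, mask$labels)),
                   train_config(lr = 3e-3, max_epochs = 180, patience = 0))
tail(fit$logs, 1)
#  epoch         lr ds_alpha     loss val_dice
#    179 0.00098304 0.131072 0.193517       NA

pred <- predict_volume(model, ph$volume)
evaluate_case(mask, pred)
# Segmentation metrics (DSC/IoU fractions, distances in mm):
#             dsc    iou   hd95   assd
# vertebra 0.9875 0.9752 1.0000 0.0708
# disc     0.8056 0.6745 2.2361 0.3290
# mean     0.8965 0.8248 1.6180 0.1999
```

That is the verbatim output of one run of the block above. The vertebral
bodies are essentially solved (Dice 0.99, sub-voxel mean surface error);
the 2-voxel-thin discs converge last — Tversky-family losses typically
plateau on the thinnest class before snapping up, and seeds differ by tens
of steps in when that happens. `fit$logs` records the exact step-decay
schedules: learning rate `lr0 · 0.8^⌊epoch/30⌋` (here from 3e-3) and
deep-supervision weight `0.4 · 0.8^⌊epoch/30⌋`.

## Command line

```sh
inst/cli/spineseg generate-phantom --out-dir data/case1 --shape 48,256,256 --seed 1
inst/cli/spineseg train    --data data/ --out runs/exp1 --profile test --seed 1
inst/cli/spineseg predict  --model runs/exp1/checkpoint.rds --data data/ --out preds/
inst/cli/spineseg evaluate --pred preds/ --gt data/ --out metrics.csv
```

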