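---
title: "Methods: gated wavelet-diffusion and state-space segmentation of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gated wavelet-diffusion and state-space segmentation of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Delineating the left ventricle (LV) in 2-D echocardiograms is the gateway to
every downstream functional index (ejection fraction, systolic/diastolic
volumes). Ultrasound is a hostile imaging modality for segmentation:
multiplicative speckle noise, low tissue contrast, fuzzy endocardial borders,
and dark background regions (vessels, other chambers, shadowing) that look
locally like the ventricular cavity. Pediatric studies add large anatomical
variability and lower image quality. A useful model therefore needs two
complementary abilities: *local* noise suppression that does not destroy the
boundary, and *global* context so that a dark blob far from the heart is not
mistaken for the cavity.

`pmamba` implements the P-Mamba architecture, which assigns those two jobs to
two expert branches fused by a learned mixture-of-experts gate.

# The model

## The wavelet-domain Perona–Malik diffusion expert

Perona–Malik diffusion evolves a feature map $u$ by
$\partial_t u = \mathrm{div}(g(|\nabla u|)\,\nabla u)$ with the rational
diffusivity $g(m) = 1/(1+(m/k)^2)$: strong smoothing where gradients are
small (noise), nearly none across strong edges. The discrete block works in
the Haar wavelet domain. A single-level orthonormal Haar analysis splits the
map into four half-resolution subbands (`ll`, `lh`, `hl`, `hh`); the `lh`
and `hl` bands are scaled two-point differences and serve as the horizontal
and vertical derivative proxies. One update computes
$m = \sqrt{u_{LH}^2 + u_{HL}^2}$, scales both detail bands by $g(m, k)$,
synthesizes them back to full resolution with the `ll` and `hh` slots zeroed,
and adds the result to the input. Constant regions are exact fixed points.
The block then feeds a residual two-convolution stack
(conv–BN–ReLU–conv–BN plus identity skip).

Choices a user should know about:

* **Wavelet family.** Orthonormal Haar. Its high-pass is exactly a scaled
  finite difference — the reading of the subbands as derivatives is then
  literal — and orthonormality makes synthesis both the inverse and the
  adjoint, which keeps the backward pass exact.
* **Update sign** (`update_sign`). The discrete update as usually printed
  *adds* the $g$-scaled detail, which preserves (and where $g \approx 1$,
  amplifies) high-frequency content rather than removing it; a strictly
  diffusive reading would subtract it. Both are implemented; `"additive"`
  is the default, `"subtractive"` is one flag away. We do not guess intent.
* **Contrast constant** `k = 1` by default; one diffusion step per block
  (`n_steps = 1`, step size fixed to 1) — depth of the network, not inner
  iteration, supplies repeated diffusion.
* **Odd map sizes.** A 96-pixel input makes the deepest stage 3×3; subband
  analysis needs even sizes, so odd maps are replicate-padded by one
  row/column and cropped back after synthesis (the gradient folds the
  padded entries back).
* `finite_difference_pmd()` is a classical explicit four-neighbour scheme
  (replicate boundaries, `dt <= 0.25`) kept as a behavioural reference: it
  conserves mean intensity exactly and is used in tests to demonstrate
  variance decay with edge preservation.

## The selective state-space (ViM) expert

Feature maps are flattened to token sequences (row-major over the spatial
grid) and mixed by a bidirectional selective state-space block. The
continuous model $h'(t) = A h(t) + B x(t)$, $y = C h(t)$ is discretized
per token with zero-order hold for the diagonal transition
($\bar A = e^{\Delta A}$) and the simplified Euler rule for the input
($\bar B = \Delta B$); $\Delta$, $B$ and $C$ are input-dependent
(selective). The block is: pre-layer-norm, linear expansion (ratio 2) into a
signal path and a SiLU gate path, causal depthwise convolution (width 4) +
SiLU, scans run left-to-right and (with separate parameters) over the
reversed sequence, both modulated by the gate, averaged, and projected back
with a residual connection.

Choices: diagonal $A$ initialized as $-(1,\dots,N)$ per channel;
log-uniform step-size bias in $[10^{-3}, 10^{-1}]$; direction merge is the
arithmetic mean (symmetric and parameter-free); token order is fixed
row-major for reproducibility; state dimension defaults to 16 (8 in the
tiny preset). The explicit-loop recurrence (`selective_scan()`) is the
reference; the compiled kernel must match it within $10^{-5}$ and is tested
against it.

## Mixture-of-experts fusion and the pyramid

Per block, a gate $w = \sigma(\mathrm{linear}(\mathrm{GAP}(H)))$ (global
average pooling, one scalar per sample) convexly combines the experts:
$H_t = \mathrm{DropPath}(w\,\mathrm{PMD}(H_{t-1}) + (1-w)\,\mathrm{ViM}(H_{t-1}))$.
The gate linear layer starts at zero, i.e. an equal 0.5/0.5 mixture. A
channel-wise gate (`gate_scope = "channel"`) and a plain unweighted sum
(`fusion_mode = "add"`) are available as configuration, which also expresses
the no-diffusion and Sobel-edge ablations (`pmd_mode`). DropPath drops a
whole block per sample during training (rate scaled linearly with depth,
identity at inference, and the residual path then passes the input through).

The encoder has four stages at 1/4, 1/8, 1/16, 1/32 of the input
resolution (strided overlapping convolution embeddings: 7×7 stride 4, then
3×3 stride 2), each with a learned position embedding and `depths[i]`
blocks; default depths `[2,2,2,2]`. Stage widths are not dictated by the
architecture description; the default is the conventional `[64,128,256,512]`
pyramid and no attempt is made to reproduce any specific parameter count.
The decoder projects each level to a common width (1×1 conv + BN + ReLU),
bilinearly interpolates everything to the 1/4 grid (half-pixel convention),
concatenates, fuses with 1×1 and 3×3 conv + BN + ReLU stacks, and a final
1×1 convolution produces a single logit map upsampled ×4 to input
resolution. Segmentation is logistic with a 0.5 threshold; the classifier
bias starts at the background prior log-odds (≈ −1.9) so early training is
calibrated.

# Training protocol

The default `train_config()` mirrors the full protocol: AdamW (decoupled
weight decay on weight matrices only), learning rate `1e-4`, weight decay
`0.01`, batch 24, 256×256 inputs, 50 epochs, validation Dice every 5
epochs, early stopping after 10 evaluations without improvement (a
`patience_unit = "epochs"` reading is available; with 50 epochs and
5-epoch cadence the evaluation reading is the binding one). The loss is not
prescribed by the architecture; the default is the standard equal-weight
sum of pixelwise binary cross-entropy and per-sample soft Dice (additive
smoothing 1.0). Inputs are scaled to [0,1] and standardized by train-split
mean/sd. No augmentation by default (`augment` adds flips and intensity
jitter). Training is deterministic given the seed; the best-validation
weights are kept.

The **tiny preset** (`pmamba_tiny_config()`: widths `[16,32,64,96]`, one
block per stage, state dim 8, decoder width 64, no DropPath, 64×64 inputs)
exists so the full pipeline can be exercised on one CPU core in minutes.
Studies with it use learning rate `1e-3`: at a few hundred optimizer steps
the full-protocol `1e-4` barely moves a freshly initialized network, and
`1e-3` is the customary rate at this model scale.

# The synthetic phantom generator

The package cannot ship clinical echo data, so `render_phantom()` emulates
the statistical challenges instead: a sector-shaped field of view; mid-gray
tissue; a dark elliptical cavity (the LV) with a brighter myocardial rim;
dark distractor blobs outside the LV — the background regions that naive
segmenters latch onto; Gaussian blur; and L-look multiplicative gamma
speckle (mean 1, variance 1/L) applied after blur, then clipping and 8-bit
quantization. The ground-truth mask is the exact pre-blur, pre-noise
cavity raster, so labels are noise-independent. Dataset generation draws
per-sample pose/shape/noise from fixed documented ranges (semi-axes
0.13–0.20 × 0.20–0.30 of the edge, rotation ±25°, rim contrast 0.5–0.9,
looks 2–8, blur 0.5–1.5 px, 2–5 distractors) with split-disjoint RNG
streams, so resizing one split never changes another.

What the phantoms do *not* emulate: scan-line/beamforming physics, tissue
texture correlation, temporal coherence, anatomical variability beyond an
ellipse, probe-dependent artifacts. Passing the desk-scale studies
therefore shows the implementation trains and that the architecture behaves
as specified — it is *not* evidence of clinical-grade accuracy. Notably,
at 64 px the phantom LV is a large, high-contrast target: in our scaled-down
ablation study both the gated two-expert model and the add/no-diffusion
ablation can saturate validation Dice, in which case their difference is at
seed-noise level; the phantom family is kept fixed rather than redesigned
around the comparison.

# Numerical choices and degenerate inputs

* Bilinear resampling uses half-pixel centers (corner alignment disabled)
  everywhere, via explicit separable interpolation matrices whose
  transposes implement the exact adjoint in the backward pass.
* Probabilities are clamped to `[1e-6, 1-1e-6]` inside the cross-entropy;
  the soft-Dice smoothing keeps empty masks finite.
* Metric conventions: a fully empty prediction/reference pair scores 1 on
  precision/recall/Dice; any other 0/0 ratio scores 0. Hausdorff distance
  is boundary-to-boundary Euclidean in pixels, symmetric
  `max(directed percentiles)`, default 95th percentile (HD95, the
  segmentation-community norm; percentile 100 is the classical maximum).
  Images with an empty mask are excluded from the HD mean and counted.
  Dataset aggregation is the unweighted per-image mean, not a pooled
  confusion matrix.
* Tracing rasterization sorts chords along the principal axis of their
  midpoints and assigns endpoints to sides by the sign of the cross
  product, making the polygon invariant to chord order; pixel centers sit
  at integer coordinates (x = column, y = row) and boundary pixels are
  included.
* All gradients are hand-derived per layer and verified against central
  finite differences in the test suite.

# Problem sizes used by tests and the acceptance script

The suite exercises micro configurations (stage widths 4–8) for gradient
and contract checks, and the tiny preset for two studies: overfitting 8
phantoms for 300 steps, and a 200/50-sample, 10-epoch comparison of the
gated model against the add/no-diffusion ablation across 3 seeds. The
acceptance script trains the tiny preset for 8 epochs on 120/30 phantoms
and reports held-out Dice, precision, recall and HD95 on 30 test phantoms,
alongside wavelet round-trip error, scan-vs-reference error, and the
speckle moment ratio. These sizes are the package's chosen desk-scale
study; the full-protocol defaults above remain available for real data.

# Known limitations

* Training is CPU-oriented and single-device; no mixed precision, no
  learning-rate schedules, no distributed training.
* The additive default of the discrete diffusion update enhances rather
  than attenuates detail where $g \approx 1$ (see above); users wanting
  strict smoothing should set `update_sign = "subtractive"`.
* Stage widths of the full preset are conventional, not a replication of
  any specific parameter budget; no latency/FLOPs accounting is provided.
* Binary (LV vs background) segmentation only; no volumetric indices
  (ejection fraction etc.) are computed.
* Video decoding is out of scope: EchoNet-style inputs enter as PNG
  frames plus tracing tables.
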