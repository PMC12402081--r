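# pmamba

Left-ventricle segmentation in echocardiograms with the **P-Mamba**
architecture: a mixture-of-experts network whose two branches attack the two
failure modes of ultrasound segmentation. A **DWT-based Perona–Malik
diffusion (PMD) expert** suppresses speckle noise while preserving the
endocardial boundary; a **bidirectional selective state-space (Vision Mamba)
expert** models global context at linear cost, so dark background blobs are
not mistaken for the ventricular cavity. A learned gate fuses the experts in
every block of a four-stage pyramid encoder; a multi-scale interpolation
decoder emits a logistic foreground map.

The network, its training pipeline (AdamW, soft-Dice + cross-entropy loss,
early stopping), segmentation metrics (precision, recall, Dice, Hausdorff
distance), a synthetic echo phantom generator with exact ground-truth masks,
an EchoNet-style tracing rasterizer, and a CLI are all implemented in this
package; the numeric hot paths (convolution, selective scan) are compiled
via RcppArmadillo and every layer carries a hand-derived, finite-difference-
verified backward pass.

## The model in brief

Per feature map $u$, the diffusion expert applies the discrete wavelet-domain
update

$$u_k = u_{k-1} + \left[g(m)\,u_{LH}\right]_{LH} + \left[g(m)\,u_{HL}\right]_{HL},
\qquad m = \sqrt{u_{LH}^2 + u_{HL}^2},\qquad g(m) = \frac{1}{1 + (m/k)^2},$$

where $u_{LH}, u_{HL}$ are the horizontal/vertical detail bands of a
single-level orthonormal Haar transform (derivative proxies) and the bracket
notation re-embeds the scaled bands into an otherwise-zero subband set before
synthesis; a residual conv–BN–ReLU block follows. The state-space expert
flattens the map to tokens and runs the selective recurrence
$h_t = e^{\Delta_t A} h_{t-1} + \Delta_t B_t x_t$, $y_t = C_t h_t$
forward and backward over the sequence. Each block outputs

$$H_t = \mathrm{DropPath}\big(w \cdot \mathrm{PMD}(H_{t-1}) + (1-w)\cdot \mathrm{ViM}(H_{t-1})\big),$$

with $w \in (0,1)$ a sigmoid gate computed from globally average-pooled
features. See `vignettes/pmamba-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

Generate a synthetic phantom dataset, train the CPU-scale tiny preset, and
evaluate on held-out phantoms:

```r
library(pmamba)

dir <- tempfile("echo")
generate_echo_dataset(24, 8, 8, echo_phantom_params(image_size = 64),
                      seed = 1, out_dir = dir)

data <- list(train = load_image_mask_dir(dir, split = "train"),
             val   = load_image_mask_dir(dir, split = "val"))
fit <- train_pmamba(pmamba_tiny_config(64), data,
                    train_config(epochs = 20, learning_rate = 1e-3,
                                 batch_size = 8, input_size = 64,
                                 eval_every_epochs = 5, seed = 1))
cat(sprintf("best validation Dice: %.3f\n", fit$history$best_val_dice))

test  <- load_image_mask_dir(dir, split = "test")
masks <- predict_pmamba(fit$model, array(test$x, c(64, 64, 8)))
report <- evaluate_dataset(lapply(1:8, function(i) masks[, , i] > 0.5),
                           lapply(1:8, function(i) test$y[, , 1, i] > 0.5))
print(report)
```

which prints (about a minute on one CPU core):

```
best validation Dice: 0.905
metrics over 8 images: precision 0.9325  recall 0.9320  dice 0.9313  HD95 2.033 px (8 images)
```

`precision`/`recall`/`dice` are per-image means of the pixel-overlap
measures (1 = perfect); `HD95` is the 95th-percentile symmetric
boundary-to-boundary distance in pixels (0 = perfect), averaged over the
images where it is defined. `fit$model` carries the best-validation weights
and can be saved/restored bitwise with `save_checkpoint()` /
`load_checkpoint()`.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/pmamba.R synth --n-train 24 --n-val 8 --n-test 8 --seed 1 \
        --image-size 64 --out data/
Rscript inst/cli/pmamba.R evaluate --pred preds/ --ref data/masks --out report
```

(`train`, `predict` and `rasterize` subcommands are also available; run
without arguments for usage.)

Real data enters through the same `load_image_mask_dir()` manifest format
(8-bit PNG image/mask pairs), and EchoNet-style `VolumeTracings` chord
tables are converted to masks with `rasterize_tracing()`.

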