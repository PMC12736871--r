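# femseg

Frequency-domain feature enhancement for breast-ultrasound lesion
segmentation, in pure R.

Breast ultrasound is a first-line imaging modality for lesion assessment,
but B-mode scans are hard to segment automatically: multiplicative speckle
noise, low lesion-to-tissue contrast and poorly defined boundaries defeat
purely spatial convolutional features. `femseg` implements a
**frequency-domain feature enhancement module (FEM)** that addresses this,
together with everything needed to train and evaluate it at desk scale on a
single CPU: baseline encoder–decoder segmenters, the full metric and loss
suite, a synthetic speckle-phantom generator, and a class-imbalance-aware
training pipeline. It is aimed at medical-image-analysis researchers who
want a transparent, dependency-light reference implementation of the method.

## The method

Given a deep encoder feature map `X ∈ R^{B×C×H×W}`, the FEM

1. transforms each channel with the real-input 2-D FFT to the half
   spectrum `x̂ ∈ C^{B×C×H×W_f}`, `W_f = ⌊W/2⌋ + 1`;
2. partitions the spectrum with binary radial masks into low/mid/high
   bands, `x̂_k = x̂ ⊙ M_k` (normalised radial cutoffs `(1/3, 2/3)` by
   default, DC in the low band);
3. reconstructs each band in the spatial domain, `X_k = irFFT2(x̂_k)`;
4. refines each band: `F_k = Dropout(GN(Conv1×1(X_k)))`, reducing `C` to
   `C/ρ` channels;
5. fuses across bands with a two-layer 1×1 bottleneck
   `F = Conv1×1(ReLU(Conv1×1([F_low ∥ F_mid ∥ F_high])))`; and
6. injects the result residually: `Y = X + Dropout(F)`.

The final fusion layer is zero-initialised, so the module starts as an
exact identity residual — it refines rather than replaces features.
**FADeepLabV3** applies the FEM to the deepest (fourth) encoder stage
before the atrous-spatial-pyramid-pooling (ASPP) decoder of DeepLabV3;
U-Net and U-Net++ (accurate/fast deep-supervision modes) are provided as
baselines. Because no deep-learning framework is available on a plain R
stack, the networks run on a small reverse-mode automatic-differentiation
engine over `(B, C, H, W)` arrays included in the package (BLAS-backed
convolutions, group normalisation, bilinear resizing, FFT band projection).

Segmentation trains with the Dice loss `DL = 1 − DSC`; classification with
the focal loss `FL = −Σ_c α_c (1−p_c)^γ y_c log p_c`. Evaluation covers
per-image Dice, IoU, pixel accuracy, pooled pixel-level ROC AUC, and
per-class/macro precision–recall–F1 with labelled confusion matrices.

## Worked example

Train the tiny-encoder FADeepLabV3 on 64 synthetic phantoms (40 benign,
24 malignant, 64×64 pixels, stratified 48/8/8):

```r
library(femseg)
res <- smoke_train_segmentation(seed = 1, max_epochs = 30)
res$init_dice
#> [1] 0.2081202
res$val_metrics
#> Segmentation metrics over 8 images:
#>   pixel accuracy 0.9746   Dice 0.8719   IoU 0.7818   AUC 0.9836
```

An untrained network thresholds to a near-random mask (validation mean
Dice 0.21); after at most 30 epochs of Dice-loss training on one CPU the
validation mean Dice rises to 0.87 and the pooled pixel AUC to 0.98 —
i.e. the model has genuinely learned the hypoechoic lesions of the
phantoms rather than a trivial all-background answer.

The building blocks compose directly:

```r
masks <- make_band_masks(32, 32, cutoffs = c(1/3, 2/3))
x     <- array(rnorm(1 * 16 * 32 * 32), c(1, 16, 32, 32))
bands <- band_split(x, masks)          # low + mid + high == x
p     <- fem_params(C = 16, rho = 4)
y     <- fem_forward(x, p, masks)      # == x at zero-initialised fusion

net <- build_segmenter(seg_config("fadeeplabv3", encoder_kind = "tiny"))
dim(forward_network(net, array(rnorm(3 * 64 * 64), c(1, 3, 64, 64))))
#> [1]  1  1 64 64
```

A BUSI-style dataset (per-class folders, `<class> (i).png` +
`<class> (i)_mask.png`) can be written and read back with
`generate_dataset()` / `read_busi_dataset()`; `stratified_split()`,
`make_class_weights()`, the augmentation policies, `train_model()`,
`evaluate_model()`, `hpo_search()` and `ablate_fem()` cover the rest of
the workflow. A thin command-line wrapper lives at `inst/cli/femseg.R`.

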