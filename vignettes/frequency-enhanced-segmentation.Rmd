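---
title: "Frequency-enhanced lesion segmentation: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-enhanced lesion segmentation: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femseg)
```

## The problem and the model

Breast-ultrasound lesion segmentation is difficult for purely spatial
convolutional features: speckle is a multiplicative, broadband interference
pattern, lesions are hypoechoic with low contrast against surrounding
tissue, and their boundaries are often diffuse. The premise of the
frequency-domain feature enhancement module (FEM) in this package is that
these properties separate naturally in the frequency domain of *deep
feature maps*: global lesion morphology lives in low spatial frequencies,
anatomical transitions in mid frequencies, and boundary detail in high
frequencies.

For a feature map $X \in \mathbb{R}^{B\times C\times H\times W}$ the FEM
computes the real-input 2-D Fourier transform of each channel (unnormalised
forward; the inverse carries the $1/(HW)$ factor), keeping the
non-redundant half spectrum of width $\lfloor W/2\rfloor + 1$. Three binary
masks partition the half-spectrum grid by normalised radial frequency
$r=\sqrt{(\lvert f_y\rvert/0.5)^2+(f_x/0.5)^2}/\sqrt{2}$ into
low ($r<c_1$), mid ($c_1\le r<c_2$) and high ($r\ge c_2$) bands. Each
band-limited reconstruction is refined by a $1{\times}1$ convolution
reducing $C$ to $C/\rho$ channels, group normalisation and dropout; the
three refined bands are concatenated and fused by a two-layer
$1{\times}1$ bottleneck ($3C/\rho \to C/2 \to C$, rectifier in between);
the fused tensor is added back to $X$ through a final dropout. FADeepLabV3
applies this module to the deepest (fourth) stage of a staged encoder
before the ASPP decoder of DeepLabV3.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `cutoffs` | (1/3, 2/3) | normalised radial band boundaries |
| `rho` | 4 | per-band channel reduction `C -> C/rho` |
| `groups` | min(8, C/rho) | group-norm group count (largest divisor ≤ 8) |
| `p_band`, `p_residual` | 0.1 | dropout after refinement / before residual |
| `zero_init_fusion` | TRUE | start as an exact identity residual |
| `aspp_rates` | (6, 12, 18) | atrous rates of the five-branch ASPP |
| `output_stride` | 16 | input:deepest-feature resolution ratio |

The band cutoffs, reduction ratio, group count, dropout rates and the
nonlinearity between the fusion layers are genuinely open design points of
the method; the values above are this package's choices. Radial
(isotropic) masks were chosen because lesion boundaries have no preferred
orientation; equal thirds of the normalised radius are the least-informative
prior on where the useful bands sit, and the cutoffs are configurable for
anyone who wants to study them. $\rho = 4$ keeps the module lightweight
(for $C = 512$: 235,136 parameters, about 2% of a ResNet18-scale encoder);
the closed form is checked by `fem_param_count()`. Zero-initialising the
final fusion layer makes the module an exact identity at initialisation,
which both stabilises early training and gives a sharp, testable contract:
FADeepLabV3 and DeepLabV3 with shared remaining weights produce
bit-identical logits until the fusion layer moves away from zero. The DC
bin is assigned to the low band ($r = 0 < c_1$). Whether the two dropout
sites share one rate is unspecified in the method's description; they are
independent parameters here with a common default.

Two further conventions matter for correctness on odd sizes: the inverse
transform is always given the explicit output size $(H, W)$, so odd widths
round-trip exactly, and the half-spectrum masks are expanded to the full
grid by Hermitian symmetry before masking, which keeps every band-limited
reconstruction real. Because the masks are symmetric under frequency
negation, each band projection is an orthogonal projection and therefore
self-adjoint — its backward pass is the same projection applied to the
incoming gradient (verified against finite differences in the tests).

## Architectural choices

The four segmenters share a *staged encoder* contract: four feature stages
with declared channel counts. Two encoders ship: a ResNet18-style encoder
(64/128/256/512, two basic blocks per stage) and a tiny 8/16/32/64 encoder
for CPU-scale work; both use group instead of batch normalisation because
the package targets small-batch CPU training where batch statistics are
degenerate, and no pretrained weights are shipped (requesting them raises
an error rather than silently training from scratch "pretrained"). U-Net
upsamples with 2×2 transposed convolutions and concatenates exactly one
skip per level; U-Net++ builds the nested dense grid with deep-supervision
heads on every top-level node, averaging them in accurate mode and
returning the deepest-supervision branch in fast mode (which branch "fast"
selects is another open point; the deepest uses all pyramid levels and is
the conventional choice). DeepLabV3 uses the canonical output stride 16
and bilinear decoder upsampling; stride 8 is available and used by the
desk-scale harness so that 64×64 inputs still give an 8×8 grid at the FEM.
The binary task uses a single logit channel with a sigmoid rather than
two-channel softmax.

Since no neural-network framework exists on a plain R stack, the networks
run on a small reverse-mode autodiff engine over dense `(B, C, H, W)`
arrays written for this package: convolutions as kernel-offset GEMMs on
BLAS, transposed convolution, 2×2 max pooling, group normalisation,
separable bilinear resizing, global average pooling, dropout, the FFT band
projection, and Dice/focal losses with analytic gradients. Every operator's
gradient is checked against central finite differences in the test suite.

## Training pipeline

Stratified splitting uses floor rounding on the validation and test
fractions with the remainder to training — the only simple rule that
reproduces the published 80:10:10 table for class counts 436/210/132
(350/43/43, 168/21/21, 106/13/13; validation and test totals of 77).
Weighted replacement sampling uses inverse-class-frequency weights on the
*training* split only; resampling the validation split would distort the
early-stopping signal, so validation keeps its natural distribution.
Augmentation follows the stated policies (flips and brightness/contrast at
p = 0.4 for segmentation with zero-padding to minimum 32×256 and ImageNet
normalisation; flips/rotations/jitter at p = 0.5 with mean-0.5/sd-0.5
normalisation for classification), with one guard: padding minima are
capped at the model input side so that small synthetic inputs are not
padded up merely to be shrunk again. Masks receive only geometric
transforms and stay binary (nearest-neighbour resize).

The schedule controller reduces the learning rate by a factor of 0.1
(the conventional plateau factor; only the patience of 25 is prescribed)
after 25 epochs without validation improvement, stops after 25 such epochs,
and checkpoints the minimum-validation-loss state. The hyperparameter
search is a seeded random search over the documented spaces (log-uniform on
rates) with within-trial pruning after 10 epochs without improvement; the
search contracts (budget, argmin, pruning, locating a smooth optimum) are
what the package tests. All randomness flows from one run seed through
named sub-streams (`sub_seed()`), so identical seeds give bit-identical
runs.

## What the phantom generator emulates — and what it does not

`generate_phantom()` emulates the qualitative character of B-mode
ultrasound: a smooth low-frequency background field, hypoechoic lesions
(subtractive contrast drop of 0.35 by default), multiplicative
Rayleigh-like speckle (a squared, lightly smoothed Gaussian field with
unit mean), and blur-softened boundaries; benign lesions are smooth
ellipses, malignant ones star-convex shapes with low-order harmonic
boundary perturbations, and the default dataset imbalance quarter-scales
the 436/210/132 clinical class ratio. The masks are the pre-blur lesion
support, and normal-class images get all-zero mask files so the reader and
pipeline treat all classes uniformly.

It is *not* an acoustic simulation: there is no depth-dependent
attenuation, no shadowing or posterior enhancement, no probe geometry, and
single lesions only. Passing the desk-scale training check therefore shows
that the whole stack — data loading, augmentation, forward/backward pass,
optimisation, scheduling, checkpointing, evaluation — learns a genuinely
non-trivial segmentation task end to end; it does not certify clinical
performance on real ultrasound, which additionally requires the real
dataset and pretrained encoders at full resolution.

## Numerical choices and degenerate inputs

Soft Dice uses smoothing $\varepsilon = 10^{-6}$; two empty masks score
Dice = IoU = 1 by convention; probabilities are binarised at 0.5; AUC is
the normalised Mann–Whitney statistic with ties counted ½ and raises an
error on single-class truth; zero-denominator precision/recall cells
report 0 with a warning; focal loss floors the true-class probability at
$10^{-12}$. Dataset-level Dice/IoU/pixel accuracy are per-image means
(AUC is pooled over pixels) — per-image versus pooled aggregation is
unspecified in the method's description, and per-image means are the
common reporting convention. Group-norm uses $\varepsilon = 10^{-5}$.
Non-finite losses abort training with a diagnostic rather than continuing.

## Desk-scale problem sizes

The shipped harness (`smoke_train_segmentation()`) trains the tiny-encoder
FADeepLabV3 at output stride 8 on 64 lesion-bearing phantoms of 64×64
pixels (40 benign, 24 malignant; stratified 48/8/8), batch 8, Adam at
$3\times10^{-3}$, at most 30 epochs — sizes chosen so a laptop CPU core
completes the run in about a minute while the learning signal is still
unambiguous (validation mean Dice rises from ≈0.21 at initialisation to
≈0.87). Only lesion-bearing classes are included so per-image Dice is
informative rather than saturated by empty-vs-empty scores. The test suite
and the reproduction script use the same scale.

## Known limitations

- Learnable (soft) frequency masks and attention inside the FEM are out of
  scope, as is applying the FEM at multiple encoder depths.
- Opaque classification backbones (Inception, DenseNet, MobileNet,
  GoogleNet) are registry slots for user-supplied constructors, not
  re-implementations; the shipped backbones are the tiny and
  ResNet18-style encoders, randomly initialised.
- The autodiff engine is written for clarity and desk-scale sizes, not for
  GPU-scale throughput; full-resolution (256–320 px) ResNet18 training is
  possible but slow.
- The class-count table of the underlying corpus is reported as read from
  disk; the reader never hard-codes a total (published per-class counts
  sum to 778 although the corpus is described as 780 images).
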