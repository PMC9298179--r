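---
title: "Adversarial enhancement of blurred cell micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial enhancement of blurred cell micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellsharp)
```

# The problem

Long-term live-cell imaging trades image quality for throughput and
gentleness: label-free brightfield acquisition at low light produces
low-contrast frames, and focus drift, thermal expansion of the culture
chamber, multilayer cell growth and floating debris all blur individual
frames. Many of the blurred frames capture moments that cannot be
re-acquired. `cellsharp` restores such frames with a conditional
generative adversarial network (GAN) trained on paired blurred/sharp
images of the same field of view, and ships everything needed to study
that restoration quantitatively: a synthetic data generator, a classical
enhancement baseline, the full loss stack, tiled inference, and an image
quality metric suite.

# Model

The generator $G$ maps a blurred image $z$ to an enhanced image
$\hat{x} = G(z)$; the discriminator $D$ maps an image to the probability
that it is a real sharp image rather than a generator output. They play
the usual min–max game

$$\min_G \max_D \; \mathbb{E}_x[\log D(x)] + \mathbb{E}_z[\log(1 - D(G(z)))],$$

with the conditional twist that $z$ is a degraded observation of $x$
rather than noise.

## Objectives

The discriminator minimises
$L_D = -\mathrm{mean}[\log D(x) + \log(1 - D(\hat{x}))]$. The printed
minimisation objective for the generator's adversarial part,
$\min_G \log D(\hat x)$, decreases as the generator gets *worse*; we use
the standard non-saturating form $L_{advG} = -\mathrm{mean}\log D(\hat{x})$,
which has the same optimum and stable gradients. Discriminator outputs are
clamped to $[10^{-7}, 1-10^{-7}]$ before logs.

The full generator objective is

$$L_G = \lambda_{rec} L_{rec} + \lambda_{feat} L_{feat}
      + \lambda_{style} L_{style} + \lambda_{tv} L_{tv}
      + \lambda_{advG} L_{advG},$$

with, for batches of shape $B \times C \times H \times W$:

* **Reconstruction** $L_{rec} = \frac{1}{BCHW}\lVert x - \hat{x}\rVert_2^2$ —
  pixel fidelity.
* **Feature perceptual** $L_{feat} = \sum_i \frac{1}{BC_iH_iW_i}
  \lVert \Phi_i(x) - \Phi_i(\hat{x}) \rVert_2^2$ over the taps $\Phi_i$ of a
  frozen convolutional feature extractor — texture and structure beyond
  per-pixel error.
* **Style perceptual** $L_{style} = \sum_i \frac{1}{BC_iH_iW_i}
  \lVert \mathrm{Gram}_i(x) - \mathrm{Gram}_i(\hat{x}) \rVert_F^2$ with
  $\mathrm{Gram} = AA^\top$ of the $C_i \times H_iW_i$ channel unfolding,
  computed per batch item — feature co-occurrence statistics, blind to
  spatial arrangement. Note the Gram matrices themselves are *not*
  normalised; the $1/(BCHW)$ factor sits outside the Frobenius norm. A
  `normalize_gram` flag provides the conventional $1/(CHW)$ Gram scaling.
* **Total variation** $L_{tv} = \frac{1}{BCHW}\sum_{i,j}
  (\hat{x}_{i+1,j}-\hat{x}_{ij})^2 + (\hat{x}_{i,j+1}-\hat{x}_{ij})^2$ —
  suppresses spikey artifacts.

## The feature extractor

The reference choice for $\Phi$ is a VGG network pretrained on ImageNet.
Pretrained weights are a large binary artifact that cannot be assumed
present, so the default extractor is a *frozen, seed-fixed random
convolutional network* with one relu tap per stage (three stages by
default, widths 8/16/16, stride 1/2/2), He-initialised so feature
magnitudes are $O(1)$. Random frozen convolutional features are an
established stand-in for trained features in perceptual objectives; the
extractor's provenance is recorded in its `descriptor`
(`"random-cnn-seed17"`). An identity extractor is also provided; with it
the feature loss reduces *exactly* to the reconstruction loss and the
style loss to a directly checkable Gram computation, which the test suite
exploits. Gray images are replicated to the extractor's channel count.

## Loss weights

No weights are prescribed for $L_G$, so the defaults are the package's
own calibration, done once on the synthetic benchmark at initialisation:
each auxiliary term's weighted *gradient* is kept subdominant to the
reconstruction gradient so that pixel fidelity anchors training while the
perceptual and adversarial terms shape texture. This matters at the
residual generator's identity starting point: with heavier perceptual
weights the warm-up phase optimises texture statistics instead of
fidelity and the reconstruction loss stalls completely, which is how the
calibration experiment on the synthetic benchmark chose the defaults.
With O(1)-scale random-CNN features the *unnormalised* Gram matrices
also make the raw style term about $10^4 \times$ larger relative to the
feature term than with VGG-scale magnitudes, hence the very small
$\lambda_{style}$: $\lambda_{rec}=1$, $\lambda_{feat}=0.01$,
$\lambda_{style}=10^{-5}$, $\lambda_{tv}=10^{-4}$,
$\lambda_{advG}=10^{-3}$.

## Architecture

No layer-level architecture is published for this model family beyond
"encoder–decoder generator, convolutional discriminator, no fully
connected layers", so the concrete networks are this package's design and
are deliberately small enough to train on one CPU:

* **Generator**: 3×3 conv stem → `n_down` stride-2 3×3 convs (encoder,
  widths doubling) → `n_residual` residual blocks
  ($x + \mathrm{conv}(\mathrm{relu}(\mathrm{conv}(x)))$) on the latent
  representation → `n_down` [nearest-neighbour upsample + 3×3 conv]
  stages (decoder, no U-net skips) → a 1×1 linear head predicting a
  *correction* that is added to the input and clamped to $[0,1]$
  (`global_residual = TRUE`, head zero-initialised: the untrained
  generator is exactly the identity). Output is bounded and
  shape-preserving; inputs must be divisible by $2^{n\_down}$.
  Upsample+conv replaces transposed convolution (no checkerboard
  artifacts, simpler adjoint). The global residual exists because the
  skip-free alternative (1×1 conv + sigmoid head reconstructing the
  image from the decoder alone, available as `global_residual = FALSE`)
  measurably cannot reach pixel fidelity at CPU-scale widths: its
  reconstruction floor sits *above* the blurred input's own error
  against the sharp target, so enhancement in PSNR terms is impossible
  for it at this scale. Predicting a residual makes the identity free
  and spends all capacity on sharpening, as super-resolution generators
  do.
* **Discriminator**: `n_down` stride-2 3×3 convs with leaky-ReLU (0.2),
  widths doubling and capped at 4×, then a global mean pool and a 1×1
  conv + sigmoid head — one probability per image, and no dense layers
  anywhere.

Weights are initialised with He-scaled normals (`init = "he"`). The
familiar GAN convention of $\mathcal{N}(0, 0.02)$ remains available
(`init = "dcgan"`), but at the narrow widths used here it starves early
layers of signal: in controlled identity-learning experiments the 0.02
init plateaued an order of magnitude above the He-init loss at equal
step counts, so He is the default.

## Training schedule

Training runs in three phases (the "multistep" schedule): (1) the
generator alone on the non-adversarial terms, so it produces
primary-quality images before the game starts; (2) the discriminator
alone against frozen-generator fakes; (3) the alternating adversarial
game under the full objectives (one D step per G step by default). The
optimiser is Adam with learning rate $2\times10^{-4}$ and
$\beta = (0.5, 0.999)$; a separate `lr_game` may lower the step size for
phase 3 — warm-up tolerates a much larger rate than the adversarial
game, which diverges if driven hard (the scaled-down benchmark warms up
at $10^{-3}$ and plays the game at $2\times10^{-4}$). Full-scale regimes pair input size and batch
size as (128, 32), (256, 20), (512, 4), with 256/20 the canonical
default. Runs are bit-reproducible from the seed; checkpoints carry both
networks, optimiser moments, the step counter and the RNG state, so a
resumed run is bit-identical to an uninterrupted one. The CIEGANP
variant is not a separate trainer: it is the same `train()` on a dataset
whose targets were passed through the classical enhancer
(`target_mode = "EGT"`).

# Synthetic data

The imaging study this package models worked on human iPSC-derived
cardiomyocyte cultures; those images are not publicly deposited, so the
`synthetic_cells` module generates stand-ins capturing the features that
matter for enhancement: soft-edged elliptical cells with dark membrane
rims and interior texture, optional clustering, small dark dead-cell
dots, a linear illumination gradient, and fine background texture.
Degradation mirrors a defocused acquisition: Gaussian blur, then
contrast/brightness attenuation about the mean, then additive Gaussian
noise, then clamping — optics before sensor. Simulated Z-stacks blur
each layer in proportion to its axial distance from the focal plane
(`sigma_px = 0.15 |dz| / pixel_size`, a slope chosen so the 1.5–18 µm
interval regimes of real stacks produce visibly distinct layers at
0.65 µm/px).

What the generator does *not* model: physically rigorous point-spread
functions, fluorescence photophysics and photobleaching, motion blur
from beating cardiomyocytes, and correlated (structured) sensor noise.
Passing tests on synthetic data therefore demonstrate that the training
machinery and metrics behave as designed, not that the trained toy
network transfers to real micrographs.

# Metrics

* **NRMSE** — RMSE divided by the reference intensity range.
* **PSNR** — $10\log_{10}(1/\mathrm{MSE})$ on the $[0,1]$ scale; the
  identity case is reported as a 100 dB cap so summaries stay finite.
* **MS-SSIM** — Wang et al. multi-scale SSIM, 11×11 Gaussian window
  ($\sigma = 1.5$), five dyadic scales with the standard weights; images
  too small for five scales use fewer with renormalised weights, and the
  scale count is recorded.
* **Entropy / mutual information** — computed in bits on 8-bit
  requantised gray levels (0–255, 256-bin histograms), matching the
  standard 8-bit convention; MI uses the joint 256×256 histogram.
* **Decorrelation resolution** — the image spectrum $I(k)$ is compared
  with its phase-normalised, low-pass-masked version $I_n(k)M(k,r)$
  through the normalised cross-correlation $d(r)$; the curve is computed
  for 50 mask radii and repeated after 10 geometrically spaced Gaussian
  high-pass filters; the cutoff $k_c$ is the highest local-maximum
  frequency over all curves and the resolution is $2p/k_c$ for pixel
  size $p$ (smaller = sharper). As printed, the correlation lacks the
  square root over the two spectral energies; we normalise by
  $\sqrt{\smash{\int |I|^2 \int |I_n M|^2}}$ as a correlation
  coefficient requires, which is also what the cited decorrelation
  method does. The mean is removed and a cosine edge apodisation (outer
  10%) applied before the FFT to suppress boundary ringing; images whose
  curves have no interior local maximum fall back to the global-maximum
  radius and are flagged. On noise fixtures ideally band-limited at half
  Nyquist the estimator recovers $k_c = 0.5$ within $\pm 0.02$.

# Inference on large images

A trained generator accepts inputs of one divisibility class; arbitrary
images are enhanced tile-by-tile (default 256 px tiles, 32 px overlap)
and re-assembled either by linear feathering across overlaps (default)
or a centre-crop mosaic. Undersized images are reflect-padded and
cropped back — reflect rather than zero padding so no dark border leaks
into the no-reference metrics. With an identity generator the
tile/stitch path reproduces the input exactly, which the test suite
asserts for both blend modes.

# The scaled-down benchmark

Full-scale training (thousands of 256 px frames, $10^4$ game steps) is
not feasible on one CPU, so the package fixes one scaled-down benchmark
(`toy_benchmark_dataset()`, `toy_training_config()`): 64 px scenes with
~6 cells, blur $\sigma = 2$ px degradation (no noise — the benchmark
isolates deblurring), 200 training and 20 held-out pairs (master seed
7), generator width 8 with 2 downsamplings and 2 residual blocks, batch
8, phases 300/300/1500. Success is measured on the held-out pairs as
the mean PSNR gain over the blurred inputs and the reduction in mean
decorrelation resolution. These problem sizes are the package's chosen
study conditions for CPU-scale validation; `scripts/acceptance.R` reruns
the whole pipeline from scratch.

# Numerical and design notes

* All intensities live in float $[0,1]$; files are normalised on read by
  $2^{\mathrm{bits}}-1$ and RGB collapses to Rec. 601 luminance. PSNR,
  entropy and MI use the 8-bit convention above.
* The degradation order blur → contrast → noise mimics optics-then-sensor
  physics; each degraded image records its provenance.
* CLAHE stands on the Graphics Gems IV implementation; the clip limit is
  expressed as a fraction of tile pixels per bin (0.01 ≈ the familiar
  bin-relative limit 2.56 at 256 bins). The classical baseline sharpens
  first (unsharp masking) and equalises second, matching the
  sharpness-then-contrast division of labour; both steps are
  deterministic.
* The backpropagation through every layer and loss path is hand-derived
  and verified against central finite differences in the test suite
  (relative error $\le 10^{-4}$ on all sampled coordinates).
* Losses logged per step satisfy, at every step, total = weighted sum of
  components to $10^{-6}$ relative; phase 1 logs no adversarial term
  (it is not evaluated there).
* Even-layer Z-stacks take the lower-middle layer as focal. Degenerate
  inputs: constant images pass CLAHE unchanged, entropy 0; TV of a
  constant batch is 0; MS-SSIM reduces scales below 176 px with a
  warning.

# Known limitations

* The architecture is a faithful-genre stand-in, not a reproduction of
  the (unpublished) original layer stack; widths and depths here are
  sized for CPU training.
* The random-CNN perceptual extractor preserves the structure of the
  perceptual objective but not ImageNet-trained feature semantics;
  swapping in real VGG weights would only require a `feature_extractor`
  with the same tap interface.
* The dataset-average metric panels of the original full-scale study
  (e.g. mean decorrelation resolutions near 1.4–4.3 µm across methods)
  are not reproducible without the original data and weights; the
  package's quantitative claims are confined to its synthetic benchmark.
* Entropy/MI are histogram estimators; they inherit the usual bias at
  small image sizes.
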