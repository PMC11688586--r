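---
title: "Methods: cycle-consistent adversarial enhancement of B-mode ultrasound"
author: "echoGAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cycle-consistent adversarial enhancement of B-mode ultrasound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Portable ultrasound probes produce B-mode images that are blurrier, noisier
and flatter in contrast than those of high-end carts. Supervision for an
enhancement model is available only as *anatomically paired* images — the
same anatomy scanned with both devices — which are **not pixel-registered**:
the probe moves between acquisitions, so a pixel-wise loss alone would
penalize geometry rather than quality.

`echoGAN` treats enhancement as translation between two imaging domains,
low quality $L$ and high quality $H$. Two UNet generators $G_H: L \to H$
and $G_L: H \to L$ are trained against two patch discriminators $D_H, D_L$,
one per domain. The aggregate generator objective is

$$\mathcal{L} = \lambda_{adv} L_{adv} + \lambda_{cycle} L_{cycle}
  + \lambda_{L1} L_{L1} + \lambda_{per} L_{per},$$

with defaults $\lambda_{adv}=1$, $\lambda_{cycle}=10$, $\lambda_{L1}=2$,
$\lambda_{per}=10$:

* $L_{adv} = \mathrm{MSE}(1, D_H(G_H(L))) + \mathrm{MSE}(1, D_L(G_L(H)))$ —
  least-squares adversarial loss; the all-ones target is materialized at
  the discriminator's score-map shape, never at image shape.
* $L_{cycle} = \lVert G_L(G_H(L)) - L\rVert_1 + \lVert G_H(G_L(H)) - H\rVert_1$ —
  translating to the other domain and back must reproduce the input; this
  is the main guard against hallucinated anatomy.
* $L_{L1} = \lVert G_H(L) - H\rVert_1 + \lVert G_L(H) - L\rVert_1$ — the
  pairs, though misaligned, still carry low-frequency supervision. Whether
  the second direction belongs in this term is genuinely open; the package
  defaults to both directions (symmetric with every other term) and exposes
  `l1BothDirections = FALSE` for the enhancement-only reading.
* $L_{per} = d(H, G_H(L)) + d(L, G_L(H))$ — a perceptual feature distance
  (below), robust to misregistration because deep features pool spatially.

All reductions are means over batch, channels and space, which keeps the
$\lambda$ weights scale-free in batch and image size.

### Perceptual distance

$d(X, Y) = \sum_i \frac{w_i}{S_i}\sum_{s}
  \lVert \hat F_i(X)_s - \hat F_i(Y)_s \rVert_2^2$, where $\hat F_i$ is the
stage-$i$ feature map with its channel vector unit-normalized at every
spatial location $s$, $S_i$ the number of locations, and $w_i \ge 0$ stage
weights (default 1). The backbone is pluggable
(`FeatureExtractor`); the default is a **seeded random convolutional
stack** — five stride-2 3×3 convolution + ReLU stages with He-scaled
Gaussian weights under a fixed seed. Random convolutional features are not
a trained perceptual model, but they preserve multi-scale structure and
give a deterministic, download-free distance with the same invariances
(zero at identity, symmetric, misregistration-tolerant); a pretrained
backbone can be dropped in by constructing a `FeatureExtractor` with its
weights. The extractor is frozen: its parameters are never updated, and the
test suite asserts they are bit-identical across training steps.

### Discriminators, spectral normalization, label smoothing

Discriminators are PatchGAN critics: stacks of 4×4 convolutions (strides
2,2,2,1,1 at defaults, widths 1×,2×,4×,8× the base width, then one scoring
channel) that emit a spatial score map — 30×30 on a 256×256 input — so
realism is judged per region rather than per image. Every kernel is
spectrally normalized (divided by a power-iteration estimate of its largest
singular value) to keep each layer 1-Lipschitz; during training one power
iteration per step is run with persistent vectors, while the standalone
`spectralNormalize()` iterates to convergence so its output's singular value
can be checked against exact SVD. No instance normalization is used in the
discriminator — spectral normalization is its only conditioning.

Discriminator training uses MSE against a real-image target chosen by a
conditional label-smoothing rule: while the batch means of both the real
and the fake score maps stay **strictly below 0.9** the hard target 1.0 is
used; once either mean reaches 0.9 the target drops to 0.9, tempering
overconfidence exactly when the discriminator starts winning. The rule as
written in its source applies to the high-quality domain; the package
applies it per discriminator from that discriminator's own batch means,
which is the symmetric reading (both discriminators share one architecture
and training protocol; a domain-asymmetric rule would be arbitrary).

### Generators

UNets with stride-2 4×4 convolutions: encoder stages use instance
normalization (omitted on the first stage, and wherever the spatial extent
collapses to a single pixel, where per-instance moments are degenerate) and
leaky ReLU (slope 0.2); decoder stages are transposed convolutions with
instance normalization and ReLU, each concatenated with its mirrored
encoder stage; dropout (rate 0.5) sits on the three innermost decoder
stages; the head is tanh, so generator outputs live in $[-1,1]$ and images
are mapped $[0,1] \leftrightarrow [-1,1]$ at the boundary. Widths double
from `baseChannels` (default 64) and are capped at 8× the base. Depth is
configurable — 8 for 256-pixel inputs, 6 for the 64-pixel desk scale used
in the tests. Dropout is placed in the decoder, following the UNet lineage
this generator derives from; an encoder-dropout variant would be a
one-line change but is not exposed, since the decoder placement is the
established one.

Initialization is zero-mean Gaussian with standard deviation 0.02,
seedable, for all four networks.

## Training procedure

Adam (learning rate $3\times10^{-4}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$)
for all networks; the rate halves every 100 epochs
(`lrAtEpoch`). Reference settings are 300 epochs at batch size 4. Each step
updates the two generators jointly on the aggregate loss, then each
discriminator once on its own term, scoring the current fakes *detached*
(no gradient back into the generator, no regeneration). Generators first,
one update each — the convention of the cycle-consistent lineage. The
label rule is evaluated from the score means of the same step. A
`lossScaling` flag multiplies the objective before backpropagation and
rescales gradients before the update (the mixed-precision "gradient
scaling" practice); in this implementation all arithmetic is double
precision, so the flag is numerically neutral and exists for configuration
fidelity.

Datasets are split 70/10/20 into train/validation/test by seeded shuffle,
sizes `floor(fraction * n)` for validation and test with the remainder to
training (1050 pairs → 735/105/210). Validation metrics are computed each
epoch; the best checkpoint (by validation PSNR, configurable) and the
latest checkpoint are archived with specs, optimizer state, epoch counter
and seeds.

## The differentiation engine

No deep-learning framework is used: the package carries a small
reverse-mode tape (`R/autograd.R`) whose operations — convolution,
transposed convolution, instance normalization, leaky ReLU/ReLU/tanh,
dropout, channel concatenation, channel normalization and the scalar
reductions — are exactly those the model needs. Convolutions are
im2col/col2im (compiled, `src/conv_ops.cpp`) plus BLAS matrix products;
transposed convolution is implemented as the exact adjoint of convolution,
and Adam runs in place in compiled code. Every operation's gradient was
verified against central finite differences (relative error $\sim 10^{-7}$)
during development; the test suite retains behavioral checks (a step moves
all four networks, zero weights move nothing, frozen modules stay frozen,
fixed seeds reproduce steps bit-for-bit).

## Synthetic phantoms

The paired data generator emulates the *structure* of a paired two-device
corpus, not any specific anatomy. The high-quality member is a
piecewise-elliptical echogenicity map (background plus uniformly drawn
elliptical inclusions) multiplied by unit-mean gamma speckle with shape
`speckleLooksHigh` — the fully developed speckle model, variance
$1/\text{looks}$. The low-quality member applies, in order: a smooth random
warp (Gaussian offsets on a coarse grid, bilinearly upsampled, peak
displacement `warpAmplitude` — a scene change, hence first), Gaussian blur
(`psfSigma`), resolution loss (block down/up-sampling by
`downsampleFactor`), gamma contrast compression, and re-speckling at fewer
looks (`speckleLooksLow` — sensor-level, hence last). Out-of-range values
are clipped, not rescaled, so echogenicity stays comparable across pairs.
`warpAmplitude = 0` makes a pair pixel-registered, and the pair is flagged
as such.

Defaults (64-pixel side, 3 inclusions, background 0.35, inclusion
echogenicity 0.55–0.9, 4 looks high / 2 looks low, blur σ = 2 px, factor-2
resolution loss, γ = 1.5, 1-px warp) were chosen once as a plausible
first-order rendering of the gap between a portable probe and a high-end
cart: visible blur and contrast compression, roughly doubled speckle
variance, and misregistration of about a pixel. No published noise
statistics exist for the source devices, so these are stated assumptions,
not calibrated values. What the phantoms deliberately lack: anatomy-shaped
structures, depth-dependent attenuation and focusing, scan-conversion
geometry, and correlated speckle between the two members (each member's
speckle is drawn independently, which is why absolute SSI/LNCC values on
phantom pairs are much smaller than on real registered data — conclusions
should rest on *comparisons* between enhancers, not on absolute metric
levels). Passing tests on phantoms show the optimization and evaluation
machinery behaves as specified; they do not certify clinical image quality.

## Evaluation metrics

All metrics operate on $[0,1]$ intensities with $MAX_I = 1$ internally;
PSNR is invariant to this convention. Bit depth read from files is recorded
so the convention is reproducible.

* **SSI** — default is the field-standard windowed form: an 11×11 Gaussian
  window (σ = 1.5) slides over all valid positions and the local values
  $\frac{(2\mu_H\mu_{H'}+C_1)(2\sigma_{HH'}+C_2)}
  {(\mu_H^2+\mu_{H'}^2+C_1)(\sigma_H^2+\sigma_{H'}^2+C_2)}$ are averaged;
  a `global` mode evaluates the same formula once with whole-image moments
  (the literal single-window equation). $C_1=(0.01\,MAX_I)^2$,
  $C_2=(0.03\,MAX_I)^2$, the conventional stabilizers. Both modes agree
  exactly on constant images.
* **LNCC** — mean over all patch centers (9×9 window, stride 1, symmetric
  boundary padding) of the local Pearson correlation, with $10^{-8}$ added
  to the product of local standard deviations; clipped to $[-1,1]$.
* **PSNR** — $10\log_{10}(MAX_I^2/\mathrm{MSE})$; infinite for identical
  images, reported as such per pair and capped at 100 dB in aggregate
  means with a flag.
* **Perceptual metric** — the training feature distance on a single pair,
  with intensities mapped to the network range $[-1,1]$.

`evaluateDataset` with the identity enhancer is the *reference-low
baseline*: low-quality images scored directly against their high-quality
counterparts. Two evaluations are compared metric-by-metric with a paired
one-sided Wilcoxon signed-rank test (exact for small samples without ties,
normal approximation otherwise), oriented higher-better for SSI/LNCC/PSNR
and lower-better for the perceptual metric; all-zero differences make the
test undefined and are reported as `NA` with a warning.

## Numerical and degenerate-input choices

* Instance normalization adds $10^{-5}$ inside the square root; channel
  normalization adds $10^{-10}$ under its norm.
* Spectral normalization of an all-zero kernel is undefined; the weight is
  returned unchanged with a warning. The power iteration starts from a
  fixed-seed Gaussian vector so results are deterministic.
* Leaky ReLU's subgradient at 0 takes the negative-side slope; L1 terms use
  sign() (subgradient 0 at exact zero).
* A non-finite loss component aborts the step naming the offending term.
* Image writing errors on out-of-range intensities unless clipping is
  requested explicitly; reading infers the intensity scale from the
  container's declared bit depth, not from observed maxima.
* The optimizer updates parameters in place (compiled kernel); moment
  buffers are allocated on first use per parameter, and checkpoint
  restoration copies parameter arrays so an archived checkpoint can never
  be mutated by later training.

## Problem sizes used in the tests

The automated suite exercises the full loop at sizes a single CPU handles
comfortably: 64×64 phantoms, depth-6 generators and discriminators at base
width 16 (the architecture is identical in shape to the 256-pixel, width-64
reference configuration; width and depth are capacity knobs, not structural
changes), 200 pairs split 140/20/40, 10 epochs at batch size 4, and the
seeded random perceptual backbone. Under these conditions the trained
enhancer must beat the reference-low baseline on the held-out split in
PSNR, SSI and the perceptual metric with one-sided Wilcoxon p < 0.05 — the
directional counterpart, at desk scale, of the full-scale claim that
enhancement improves on unprocessed low-quality images. Reference-scale
training (300 epochs, width 64, 256-pixel images, ~1000 pairs) uses the
same code paths unchanged but GPU-scale time; nothing in the package
assumes the desk scale.

## Known limitations

* The default perceptual backbone is untrained; with pretrained weights
  the perceptual term would align better with human judgment. The stage
  weights $w_i$ default to 1 rather than to any fitted values.
* Phantom realism is first-order only (see above); organ-specific
  validation requires real paired data.
* The engine is CPU-only and single-threaded apart from BLAS; it is meant
  for method study and desk-scale experiments, not production training.
* No identity/self-regularization loss and no historical fake pool are
  implemented — the objective contains exactly the four terms listed.
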