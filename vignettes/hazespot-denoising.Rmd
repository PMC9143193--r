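---
title: "Attention-guided adversarial removal of haze-spot noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-guided adversarial removal of haze-spot noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hazegan)
```

## The problem

Infrared cameras used for continuous livestock monitoring emit their own
IR illumination. Insect secretions deposited on the lens reflect that
illumination back into the sensor and appear as bright, localized "haze
spots" that occlude the animals beneath them and break downstream
detection. Because animals move constantly, a real noisy frame never has a
clean counterpart of the same scene, so a denoiser cannot be trained on
real pairs. hazegan takes the simulation route: clean frames are corrupted
with a physically motivated haze-spot model, and an attention-guided
generator is trained adversarially on the simulated pairs, then applied to
frames with real noise.

## The haze-spot model

A spot is modelled with the atmospheric scattering law

$$I(x) = J(x)\,t(x) + A\,(1 - t(x)),$$

where $J$ is the clean scene, $t \in (0,1]$ the per-pixel transmission and
$A \in [0,1]$ the light of the occluding veil. Outside every spot $t = 1$
and the image is untouched. Three radial profiles cover the variety seen
in real spots (`d` is distance to the spot center, normalized by the
radius and clamped at 1):

* **uniform** — constant $t \in [0.1, 0.4]$, $A \in [0.6, 1]$ across the
  disc;
* **linear** — $t = 0.4d + 0.1(1-d)$; $A$ interpolates from 1 to 0.6 but
  is clamped to 1 above a per-spot plateau threshold drawn from
  $(0.75, 0.85)$ (real spots stay saturated near their center), then the
  $A$ map is smoothed with a normalized $5\times5$ Gaussian kernel
  ($\sigma = 1$ px, replicate padding);
* **exponential** — $t = e^{\min\{(d-0.5)\cdot4,\,0\}}$ (opaque core,
  clear beyond half the radius) and $A = e^{-\theta d}$ with
  $\theta \in (0.3, 0.7)$.

A frame receives 3–8 spots with form probabilities 0.2/0.4/0.4, centers
uniform over the frame and radii uniform in $[0.05, 0.25]\cdot\min(H,W)$
(the paper-scale visual range; configurable). Overlapping spots are
combined *before* the scattering law is applied once: the combined
transmission is the minimum over spots and $A$ follows the winning spot
(exact ties resolve to the brighter light), which makes composition
deterministic and order-invariant. The plateau threshold is drawn once
per spot, not per pixel — per-pixel draws would speckle a plateau that is
smooth in real frames. Only the linear form's light map is blurred; that
is where the plateau creates a hard edge, and the other two forms are
already smooth.

The $t(x) = e^{-\beta d(x)}$ depth parameterization of the homogeneous
atmosphere is deliberately absent: the simulator sets $t$ directly from
the radial profiles, so $\beta$ and scene depth have no role here.

## Target attention maps

Supervision for the attention modules is the element-wise *absolute*
difference $|{\rm noisy} - {\rm clean}|$ (absolute, because the predicted
maps are sigmoid-valued and non-negative), which is nonzero exactly on
the corrupted support. Deeper levels are $2\times2$ average-pooled
halvings — average pooling preserves the proportional "noise mass" of a
cell and keeps the target smooth; max pooling is available behind the
`pool` argument.

## Networks

**Generator.** A five-level U-Net: each encoder level applies two groups
of 3×3 convolution → ReLU → batch normalization (the order as described;
channel width doubles per level from `base_channels`), with 2×2
max-pooling between levels. A single spatial-attention module gates every
encoder output before it enters the decoder: channel-wise max- and
average-pooling give two single-channel maps whose concatenation passes a
shared, bias-free 7×7 convolution and a sigmoid. Sharing one convolution
across all five levels — the positions and strengths of spots survive
downsampling — means the whole mechanism adds exactly $7\cdot7\cdot2 = 98$
trainable parameters; the absence of a bias term is what makes that count
exact. The decoder mirrors the encoder with bilinear upsampling followed
by a 3×3 convolution halving channels, concatenation with the attended
skip features, and two convolution groups; a final linear 1×1 convolution
produces the image. Outputs are clipped to $[0,1]$ only at the image
boundary, never inside the losses.

**Discriminator.** Conditional: it scores the channel concatenation of
the noisy input with a candidate (real clean or generated) image, 6
channels in. The body is a plain CNN — four stride-2 4×4 convolutions
(widths base×1/2/4/8, LeakyReLU 0.2, batch norm except the first block),
a 3×3 convolution to one channel, global average, sigmoid. The reference
description fixes only "an ordinary CNN producing a number"; this
layer recipe is our documented convention.

**Weight initialization** is zero-mean Gaussian with standard deviation
0.02, the conditional-GAN lineage's reading of "normal initialization".

## The four-term objective

The generator minimizes
$\lambda_1 L_{adv} + \lambda_2 L_{con} + \lambda_3 L_{per} + \lambda_4 L_{att}$
with published weights $(1, 100, 1000, 1)$:

* $L_{adv} = \mathbb{E}[\log(1 - D(x, G(x)))]$ — the saturating form as
  printed; a non-saturating $-\log D$ variant sits behind
  `adv_saturating = FALSE` because the printed form can stall early
  training, but the default follows the reference.
* $L_{con}$ — mean absolute error over all channels and pixels.
* $L_{per}$ — squared distance between frozen VGG19-layout features,
  normalized by the feature map's spatial extent only (the printed outer
  sum bounds are read as the feature map's own extent; summing image-sized
  indices over a smaller map cannot be meant literally). The tap point
  \{5, 4\} is read as the fourth convolution of the fifth block, the
  established convention for that index pair — read literally ("5th
  convolution before pooling 4") the layer does not exist in the
  19-layer layout.
* $L_{att} = \sum_{l=1}^{5}\lVert A_l - M_l\rVert_2^2$ — implemented as
  printed, i.e. an *unnormalized* sum whose scale grows with resolution;
  `att_normalize = TRUE` divides each level by its cell count. Adam's
  per-parameter step normalization makes training robust to this scale in
  practice, so the printed form is also the training default.

The discriminator minimizes the negation of
$\mathbb{E}[\log D(x,y)] + \mathbb{E}[\log(1 - D(x, G(x)))]$. The two
networks alternate every iteration, one update each, the generator first,
with the discriminator's fake sample taken from the generator output of
the same iteration before its update. Both optimizers are Adam with betas
$(0.5, 0.999)$ and share one learning-rate schedule: constant for the
first half of training, then a linear ramp to zero (full scale: 2e-4 over
200 epochs, decay from epoch 100, batch size 5).

### The perceptual extractor without pretrained weights

The reference describes the extractor as an *untrained* (and untrainable)
VGG19. This package ships no pretrained weights; constructing
`feature_extractor("pretrained")` stops with an explicit error pointing
to `"random_seeded"`, which builds the same layout with He-initialized
random weights under a fixed seed and freezes it. He initialization is
deliberate: it preserves activation magnitude through the 16 convolutions
up to the tap, so the random features form a usable multi-scale basis
(a 0.02-std initialization would attenuate features by many orders of
magnitude and silently disable the term). Gradients pass through the
extractor to its input but its weights are never updated.

## The synthetic scene generator

Training scenes emulate night-time infrared pig-pen frames: bright
rotated ellipses (mean intensity ~0.7, Gaussian-softened edges) on a
darker low-frequency textured floor (mean ~0.25), composited by per-pixel
maximum so overlapping animals remain individually boxed — group-housed
animals overlap constantly and the detector is still expected to box each
one. Boxes are the bounding rectangles of the hard ellipse masks. Frame
$i$ of a dataset uses seed $\textrm{master} + i - 1$, so fixtures are
stable across platforms and any subsequence can be regenerated.

What the simulator does *not* reproduce: animal texture and posture,
occlusion by pen furniture, temporal coherence between frames, sensor
noise, and the exact radiometry of a real IR camera. Passing tests on
these scenes therefore demonstrate that the method's machinery — the
scattering compositor, attention supervision, adversarial training and
evaluation — behaves as specified, not that the trained weights transfer
to any particular farm.

## Scaled-down study conditions (the "desk" profile)

All tests and the acceptance script run on one CPU, so the package defines
a first-class scaled-down profile: 64×64 scenes, generator base width 8,
discriminator base width 16, extractor width 1/8, 300 paired samples
split 250 train / 50 held-out, 20 epochs, batch 5 (1000 optimization
steps; roughly five minutes of single-core time). Two schedule constants
are rescaled with the shorter run, and both deserve a note because the
choice was genuinely open:

* **Learning rate 2e-3** (published shape kept: constant for the first
  half, linear decay to zero over the second). Adam moves each parameter
  by at most roughly one learning rate per step, so 1000 steps at the
  full-scale 2e-4 bound total parameter motion by ~0.2 — structurally too
  little to grow 0.02-std weights to image scale. At 2e-3 the same run
  converges comfortably.
* **Perceptual weight 10** instead of 1000. With a magnitude-preserving
  random extractor the perceptual gradient at weight 1000 exceeds the
  pixel-loss gradients by about three orders of magnitude and prevents
  convergence within 1000 steps; 10 keeps the term active without letting
  it dominate. The published 1000 remains the paper-profile default.

Under these conditions the held-out PSNR rises by several dB over the
noisy input and the predicted attention maps correlate with their targets
above 0.5 on average across levels, for the majority of fixed seeds — the
two properties the acceptance suite asserts.

## Numerical choices

* Convolutions run as single-precision im2col/GEMM (the standard
  arithmetic for convolutional networks); everything else is double.
  Gradient correctness is guarded by adjoint identities (exact up to
  float rounding) and central-difference checks at tolerances chosen
  above the float32 forward noise.
* Batch normalization uses batch statistics in training and running
  statistics (momentum 0.1, $\epsilon$ = 1e-5) at inference.
* Bilinear resampling uses the half-pixel convention with clamped
  borders; its backward pass is the exact adjoint.
* Discriminator scores are clamped to $[10^{-7}, 1 - 10^{-7}]$ inside the
  log losses to avoid infinities; the losses' domain checks reject
  scores outside $(0,1)$ at the API surface.
* Detection matching processes detections in descending score with ties
  broken by input order; "overlap ratio to the summation area" is read as
  intersection over union, since intersection over the sum of areas could
  never exceed 1/2 and would make the 0.5 criterion unsatisfiable.
  Average precision uses the all-points precision envelope by default,
  with the 11-point variant behind a flag; neither the interpolation nor
  the tie-break is fixed by the reference, so both choices are recorded
  in the report metadata.
* PSNR is computed on the 8-bit scale by mapping internal $[0,1]$ images
  through ×255 without rounding (a rounding flag exists); identical
  images report an infinite-PSNR sentinel rather than an error.

## Known limitations

* The full-resolution 512×512 training run of the reference is out of
  scope for CPU execution; the paper profile exists and its forward pass
  is exercised in the tests, but headline farm-imagery numbers are not
  reproducible without the proprietary data and a GPU.
* The discriminator's internal layout and the decoder's convolution
  kernel size are documented conventions, not prescriptions from the
  reference.
* With the published saturating adversarial loss the discriminator can
  win early on hard problems; the non-saturating flag exists for that
  case but is off by default.
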