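---
title: "A frequency-domain structure loss for unpaired 3D CBCT-to-CT translation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A frequency-domain structure loss for unpaired 3D CBCT-to-CT translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqgan)
```

## The problem

Cone-beam CT (CBCT) scans acquired on-board during radiotherapy are fast and
low-dose but suffer from Hounsfield-unit miscalibration, scatter- and
motion-induced streaks, blur, and noise relative to fan-beam planning CT. If
CBCT intensities could be restored to CT-like quality, the daily CBCT could
substitute for a rescanned CT in adaptive treatment planning. The catch is
that paired, voxel-aligned CBCT/CT training data essentially never exist: the
two scans are acquired at different times, with different set-up, and with
real anatomical change in between.

CycleGAN-style unpaired translation addresses the missing pairing: a
generator $G$ maps domain $X$ (CBCT) into domain $Y$ (CT), an inverse
generator $F$ maps back, discriminators $D_Y$ and $D_X$ judge realism, and a
cycle-consistency penalty $\lVert F(G(x)) - x\rVert_1$ ties the round trip to
the input. Cycle consistency alone, however, under-constrains *structure*: a
mapping can relocate or invent anatomy as long as the inverse mapping undoes
it. Structure losses add a direct penalty between a generator's input and
its translation. Penalizing voxelwise differences would be wrong here — input
and output belong to different intensity distributions and are not aligned —
so the penalty must be insensitive to where structures sit while still
responding to what they are.

## The generalized frequency loss

The loss this package is built around compares volumes in the frequency
domain. For a volume $I$ of size $L \times M \times N$:

1. $F = \mathrm{DFT}_{3}(I)$, the full complex 3D discrete Fourier
   transform, orthonormalized as $F' = F / \sqrt{LMN}$ (under which
   Parseval's identity holds, so total spectral energy equals image energy);
2. the spectrum is cyclically shifted so zero frequency sits at the centre
   index $(\lfloor L/2\rfloor, \lfloor M/2\rfloor, \lfloor N/2\rfloor)$;
3. only the magnitude is kept, $F_{\mathrm{mag}} = |F'|$, discarding all
   phase;
4. a tanh compresses the result into $[0, 1)$:
   $F_{\mathrm{rep}} = \tanh(F_{\mathrm{mag}})$.

The structure loss between a generator input $x$ and its translation $G(x)$
is the elementwise distance between the two representations,

$$ d\bigl(G(x), x\bigr) \;=\; \sum_{u,v,w}
   \bigl\lVert F_{\mathrm{rep}}(x) - F_{\mathrm{rep}}(G(x)) \bigr\rVert_1 ,$$

with an L2 variant obtained by squaring instead of taking absolute values.
Two properties make this suitable for unpaired data:

* **Translation insensitivity.** The magnitude spectrum is invariant to
  circular spatial shifts (the shift theorem moves phase only), so the loss
  does not punish set-up differences or displacement — only changes in
  spatial frequency content. `frequency_distance(x, circshift(x))` is zero
  to machine precision, and the test suite verifies this over random
  volumes and offsets.
* **Scale robustness.** The tanh bounds every spectral bin to $[0,1)$, so no
  single dominant frequency (in CT volumes, typically DC and low
  frequencies) can dominate the loss; what matters is the distribution of
  spectral content. This is also what makes a single weight transferable
  across datasets without per-dataset spectral normalization.

The full training objective adds the frequency term on both mappings to the
usual CycleGAN objective:

$$ \mathcal{L} = \mathcal{L}_{\mathrm{adv}}(G, D_Y) +
   \mathcal{L}_{\mathrm{adv}}(F, D_X) +
   \lambda_A \, \mathbb{E}\lVert F(G(x)) - x \rVert_1 +
   \lambda_B \, \mathbb{E}\lVert G(F(y)) - y \rVert_1 +
   \lambda_{fA} \, \mathbb{E}\, d(G(x), x) +
   \lambda_{fB} \, \mathbb{E}\, d(F(y), y). $$

Setting $\lambda_{fA} = \lambda_{fB} = 0$ recovers the plain CycleGAN
objective exactly (`total_objective()` reduces bitwise; this is tested).

### Numerical choices

* **Orthonormal scaling.** The DFT normalization is $1/\sqrt{LMN}$ by
  default: it is the convention under which "ortho-normalization" means what
  it says (energy conservation), and it is what keeps spectral magnitudes in
  a range where the tanh has usable slope. The alternative $1/(LMN)$ scaling
  appears in some write-ups and is selectable via `convention = "strict"`.
* **Even-length centering.** For even axes, zero frequency is placed at
  index $\lfloor n/2 \rfloor + 1$ (1-based), the dominant convention; this
  is pinned so tests are deterministic.
* **Full complex spectrum.** The full (not half/real) spectrum is used so
  the representation has exactly the input's shape and the shift-invariance
  statement is exact.
* **Reduction.** `frequency_distance()` defaults to the summed form above.
  The *trainer* (`train_config()`) defaults to the mean over voxels instead:
  a summed loss grows with patch size, and at the nominal
  $16 \times 320 \times 320$ patch the weighted sum term would exceed the
  cycle terms by about six orders of magnitude, which contradicts the role
  of $\lambda_f$ as a balance weight (all weights default to 5, the
  published operating point). Both reductions are selectable.
* **Loss scale.** The loss is computed on the network intensity scale: HU
  windowed to $[-1, 1]$ (window `[-1000, 2000]` HU by default, matching the
  tanh-bounded generator output). On raw HU arrays, spectral magnitudes are
  $O(10^3)$ and the tanh saturates to 1.0 in double precision for nearly
  every bin, which would make the loss blind.
* **Gradient.** The loss is differentiable in both arguments; the gradient
  through the modulus is $\partial |z| / \partial z = z / |z|$ with a
  subgradient of 0 at $z = 0$, propagated through the DFT by its adjoint
  (the inverse transform at the same scaling). Analytic gradients are
  verified against central finite differences in the test suite.

## The translation stack

### Networks

The generator is a 3D VNet: an input block (kernel-5 convolution, instance
norm, PReLU), four down-sampling stages with 1, 2, 3, 2 convolution blocks,
four up-sampling stages with 2, 2, 1, 1 blocks, U-Net-style skip
connections joining matching resolutions, and an output block of two
convolutions ending in tanh. Details the architecture description leaves
open were fixed as follows: every down stage ends in a stride-2 convolution
doubling the channel count; z-striding is disabled in the last two stages so
a 16-slice patch stays valid (z shrinks $16 \to 8 \to 4$ while the in-plane
dims shrink by 16); up-sampling is nearest-neighbour followed by
convolution; kernel size is 3 everywhere outside the input block; weights
are initialized $\mathcal{N}(0, 0.02^2)$ under a configurable seed. The
discriminator is a 3D PatchGAN — strided convolutions with instance norm and
LeakyReLU(0.2) emitting a grid of raw patch scores — with 3 strided layers
and 64 base filters by default.

Because no deep-learning framework is available to R in this toolchain, the
package carries its own small convolution engine: im2col gathers plus BLAS
matrix multiplies forward, hand-derived backward passes, and per-network
Adam optimizers. Every layer's backward pass is finite-difference-checked in
the tests. This keeps the full training loop in plain R at speeds adequate
for patch-scale experiments; it is a CPU engine and does not pretend to
GPU-scale throughput.

### Training recipe

`train_config()` defaults reproduce the published recipe key for key:
discriminator learning rate 0.0002, generator 0.0004, batch size 1, Adam
with $\beta = (0.5, 0.999)$, 30,000 iterations, patch size (16, 320, 320)
in (z, x, y), instance normalization, $\lambda_A = \lambda_B = 5$,
$\lambda_{fA} = \lambda_{fB} = 5$, and a learning rate fixed for the first
half of training then decayed linearly to zero (exactly half the base rate
three quarters of the way through). Each training step samples one CBCT and
one CT scan uniformly and independently (so same-patient and cross-patient
pairings both occur), applies the online preprocessing chain — body
masking, truncation of the CT field of view to the CBCT's, patch extraction
with the patch centre constrained to the body mask — and performs one joint
generator update followed by updates of both discriminators against pooled
historical fakes (pool size 50; a standard stabilization, disabled by
setting the size to 0). Runs are deterministic given the seed, checkpointed
periodically, and resumable.

Decisions the recipe leaves open, fixed here: generators update before
discriminators; the adversarial loss defaults to least squares (the
implementation lineage of CycleGAN frameworks), with the log-form variant
selectable; no identity loss is included.

### Preprocessing conventions

Arrays are indexed (z, y, x) while header metadata stays (x, y, z) mm, the
convention of the supported formats (NIfTI via RNifti; NRRD and MetaImage
via small readers/writers included in the package, as no installed R package
handles them). Body masks are derived by thresholding at −300 HU, keeping
the largest 26-connected component, and filling holes per axial slice;
masked-out voxels are set to −1000 HU (air). Intensity volumes resample
trilinearly, masks nearest-neighbour. Network inputs are windowed to
`[-1000, 2000]` HU onto $[-1, 1]$; evaluation instead clips to `[0, 3000]`
HU, the published metric convention. Whole-volume inference tiles the
volume with overlapping patches blended by smooth weights normalized to sum
to one at every voxel.

## Evaluation suite

`evaluate_pair()` computes MAE, MSE, NMSE (numerator not divided by N, so a
zero prediction scores exactly 1), PSNR, and SSIM under one recorded
convention (clip range, masking). Choices the metric definitions leave
open: PSNR uses the per-image reference maximum exactly as defined rather
than a fixed range; SSIM defaults to a windowed form (7×7×7 uniform window,
the common volumetric IQA practice) with the literal single-window global
form selectable; the SSIM data range defaults to 3000, the evaluation clip
width. PSNR of a perfect prediction is reported as `Inf` rather than an
error, while NMSE of an all-zero reference is an error — distinguishing
"perfect" from "undefined". Dice on user-supplied masks, soft-tissue HU
histograms (default range (−500, 500)), and bilinear line profiles across
an axial slice complete the suite.

## The synthetic phantom

The real training cohort behind this method is private, so the package
generates its own study material. `make_phantom_ct()` builds an
anthropomorphic thorax analogue: an ellipsoidal body (soft tissue ≈ 40 HU)
containing two lungs (≈ −750 HU), a heart (≈ 50 HU), rib-like bone arcs and
a spine column (≈ 700 HU), and an optional lung tumor (≈ 30 HU, present by
default — tumors are the structure most at risk of being "translated away"),
plus ~10 HU Gaussian texture. `degrade_to_cbct()` then applies, in order:
affine HU miscalibration (scale 1.05, shift +80 HU), an angular streak
pattern in the axial plane (24 spokes, 60 HU amplitude — a statistical
stand-in for scatter/motion streaks, not reconstruction physics), Gaussian
blur (1.5 mm), additive noise (40 HU), and optionally a smooth random
deformation emulating set-up differences. All defaults were chosen once as
representative of clinical CBCT degradation and are not tuned to any test.
`make_dataset()` writes a multi-patient cohort with acquisition dates
arranged so the weak-pairing rule (closest same-patient CT/CBCT pair, at
most one day apart) sees both qualifying and non-qualifying cases, plus one
held-out phantom pair for out-of-distribution evaluation.

What the phantom does *not* emulate: real anatomical variation between
patients (geometry is jittered, not resampled from a population),
respiratory motion, metal artifacts, or scanner-specific scatter kernels.
Tests passing on this material demonstrate that the algorithms are
implemented correctly and that the training signal behaves as designed; they
are not evidence of clinical-grade translation quality.

## Problem sizes used in tests

The test suite and the acceptance script exercise training at deliberately
small scale so the full stack runs in minutes on one CPU: 50 steps at patch
(8, 32, 32) with a 4-filter generator and an 8-filter discriminator, on
patches cut from a 16×48×48 phantom at 5×5×6 mm spacing. At this scale the
documented checks hold: all losses stay finite, cycle losses fall from step
1 to step 50, and the generator trained with the frequency loss ends with a
lower `frequency_distance(input, translation)` than a baseline trained
identically with $\lambda_f = 0$. DFT correctness is established against a
naive triple-sum oracle on volumes with axes 1–6, where the quadratic-cost
oracle is exact and cheap.

## Known limitations

* The engine trains with batch size 1 (as the recipe specifies); there is no
  GPU path, no mixed precision, no distributed training.
* Instance normalization is degenerate when a feature map collapses to a
  single spatial voxel; the smallest recommended patch is (8, 32, 32), which
  keeps the bottleneck at 2×2×2.
* Deformable registration of weak pairs is out of scope: `select_weak_pairs()`
  emits the manifest and users register with dedicated tooling.
* Direction matrices in volume headers are not interpreted (axis-aligned
  grids assumed); DICOM series reading is out of scope.
* tanh(|F|) saturates in double precision for magnitudes above ~19, so
  frequency distances between raw HU-scale volumes are uninformative —
  window first (the trainer does this automatically).

## A worked example

```{r example, eval = FALSE}
td <- tempfile(); dir.create(td)
meta <- make_dataset(td, n_patients = 2, shape = c(16, 48, 48),
                     spacing = c(5, 5, 6), seed = 1)

cfg <- train_config(patch_size = c(8, 32, 32),
                    generator = generator_spec(base_filters = 4),
                    discriminator = discriminator_spec(base_filters = 8),
                    total_iterations = 50, seed = 11)
fit <- train_cyclegan(cfg, meta, out_dir = td)
summary(fit)
plot(fit)

cbct <- read_volume(file.path(td, "phantom_CBCT.nii.gz"))
ct <- read_volume(file.path(td, "phantom_CT.nii.gz"))
sct <- predict(fit, cbct)
evaluate_pair(ct, sct, mask = compute_body_mask(ct))
```
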