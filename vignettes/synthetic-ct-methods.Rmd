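---
title: "Multi-planar adversarial MR-to-CT synthesis: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-planar adversarial MR-to-CT synthesis: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthCT)
```

## The problem

MRI-guided adaptive radiotherapy replans each treatment fraction on the
day's MR anatomy, but dose calculation needs electron/mass density, which MR
does not measure. The clinical workaround — deformably registering the
simulation CT onto the daily MR — is slow and adds registration error. This
package implements the alternative: a conditional generative adversarial
network (cGAN) that translates low-field MR volumes directly into synthetic
CT (sCT) in Hounsfield units, trained on 2D planes sampled in all three
orthogonal orientations and fused at inference time, together with the full
image-quality and dosimetric evaluation suite used to judge such a model.

Because real paired MR/CT patient volumes cannot ship with a package, a
procedural paired pelvis phantom generator (`phantomSpec()`,
`generatePairedCase()`) provides the study conditions: every stage of the
pipeline is exercisable, end to end, on a desk machine.

## Model and objective

The generator G is a U-Net with skip connections mapping a normalized MR
plane to a CT plane in [-1, 1]; the discriminator D is a PatchGAN that
scores overlapping patches of a conditioned (MR, CT) pair as a 2D score map
rather than a single scalar. Training minimizes

$$L_T = L_{cGAN}(G,D) + \lambda_1 L_{L1}(G) + \lambda_2 L_{MI}(G),
\qquad \lambda_1 = 100,\ \lambda_2 = 5,$$

where

* $L_{cGAN}$ is the least-squares adversarial loss. We use the standard
  least-squares-GAN label convention — real pairs target 1, generated pairs
  target 0, and the generator is rewarded by
  $\mathbb{E}[(D(x, G(x)) - 1)^2]$. The opposite label assignment makes the
  min–max objective degenerate, so the standard convention is the only
  self-consistent reading (`discriminatorLoss()`,
  `generatorAdversarialLoss()`).
* $L_{L1}$ is the voxelwise mean absolute error between real and generated
  CT planes (`l1Loss()`); it anchors the translation where adversarial
  gradients alone would drift.
* $L_{MI} = 1 - \mathrm{nMI}(y, G(x))$ penalizes statistical independence
  between the real and generated planes, which makes the objective robust
  to small residual MR–CT misalignment. Mutual information is normalized as
  $\mathrm{nMI} = I(a,b)/\sqrt{H(a)H(b)}$ over a $64 \times 64$ equal-width
  joint histogram on [-1, 1] — the unique common normalization that equals
  1 for identical images and tends to 0 for independent ones
  (`normalizedMutualInformation()`). The hard histogram is the reference
  value; during training the gradient flows through a triangular-kernel
  (linear-interpolation) soft binning whose analytic gradient is verified
  against finite differences in the test suite.

Optimization is Adam with $\beta = (0.5, 0.999)$, initial learning rates
$2\times10^{-4}$ (generator) and $5\times10^{-5}$ (discriminator), decayed
1% per epoch. We read "decreased by 1% per epoch" multiplicatively
($0.99^{epoch}$): a linear 1%-of-initial decrement reaches zero at epoch
100 and then goes negative, so the multiplicative reading is the only one
consistent with a 100-epoch schedule (`lrAtEpoch()`).

## Multi-planar sampling and fusion

Each training iteration draws one axial, one sagittal and one coronal MR/CT
plane pair from one case, uniformly from that epoch's *unused* slice
indices; an epoch visits at most `slices × cases` iterations and never
reuses a slice for a given case and orientation (`epochPlan()`,
`sampleMultiplanarBatch()`). A batch in which any extracted plane contains
no anatomy (every voxel at the -1 background) is disregarded — the drawn
indices stay consumed, but no optimizer step is taken. We read "any
extracted planes" as *any one empty plane skips the batch*; the alternative
(all three empty) almost never occurs for body-centred anatomy, and the
stricter reading errs on the side of clean gradients. One generator and one
discriminator step per kept batch (the pix2pix default). The discriminator
sees generated planes through a history buffer (capacity 50, swap
probability 0.5, values from the technique this trick originates from):
once full, each fresh plane replaces a random stored one with probability
0.5 and the stored plane is scored instead, damping oscillation.

At inference the trained generator translates every slice along each of the
three orientations independently; the three restacked volumes are
denormalized to HU and averaged voxelwise into the final synthetic CT
(`synthesizeCT()`). Averaging after denormalization equals denormalizing
the average because the HU map is affine — asserted by test. The fused
volume's mean absolute error is bounded above by the mean of the three
single-orientation errors (triangle inequality, also asserted), and in the
desk-scale study the fusion typically improves on the mean single-orientation
MAE while suppressing across-slice discontinuities
(`sliceDiscontinuity()`).

## Preprocessing

* **Exterior masking** — outside the body contour CT is forced to
  -1000 HU and MR to 0 (`maskExterior()`); all synthetic outputs have their
  exterior forced to -1000 HU.
* **CT normalization** — the affine map pinned by -1000 HU → -1 and
  3095 HU → 1, i.e. `(HU + 1000)/2047.5 - 1`, exactly invertible
  (`normalizeCT()`, `denormalizeCT()`). A "divide by the 4095 range"
  formulation circulates for this map, but it is inconsistent with the two
  endpoint anchors as literal sequential steps; the endpoints are the
  ground truth and uniquely pin the affine map.
* **MR normalization** — z-score with exclusion: the mean and SD are
  computed only over voxels ≥ 40 (the clinical air/gas threshold on
  balanced-SSFP images), then `z/3` clipped to [-1, 1], so ±3σ truncates to
  ±1 and air lands at -1 (`normalizeMR()`). Scaling by 1/3 is the unique
  continuous linear map consistent with the ±3σ truncation endpoints. The
  threshold is applied to bias-corrected intensities: correction rescales
  to preserve the mean, so the threshold's meaning is unchanged, and
  correcting first is the order the artifacts demand.
* **Bias-field correction** — a homomorphic corrector: the smooth
  multiplicative field is estimated by large-kernel Gaussian smoothing of
  the log-intensity restricted to the body (normalized convolution), then
  divided out, preserving the mean in-body intensity
  (`correctBiasField()`). The kernel SD defaults to 1/8 of the grid extent
  — wide enough to pass anatomy through to the corrected image, narrow
  enough to track a low-order field; on a flat phantom with a 20% synthetic
  field it removes well over half the intensity variation. The
  widely used N4 parameter set (B-spline order 3, shrink factor 4, 50/40/30
  iterations, convergence 1e-4) is recorded in `defaultN4Params()` so an
  external N4 implementation can be configured identically and swapped in.
* **Body mask derivation** (for inputs without a contour) — CT threshold
  above -400 HU, largest 6-connected component, interior hole fill
  (`bodyMaskFromCT()`). Gas pockets become part of the body, as a skin
  contour should behave.

## The phantom generator

`generatePairedCase()` emulates, deterministically per seed: an elliptical
body with a fat rim; an elliptical pelvic bone ring plus femoral-head
spheres; an MR-bright bladder sphere with modest filling; a rectal tube
with an optional gas pocket; a prostate/PTV sphere between bladder and
rectum; and a thin urethra. Default CT class means (air -1000, gas -800,
fat -90, muscle 45, bladder 15, prostate 40, bone 700 HU) respect the
-200/200 HU segmentation thresholds; MR means (gas/bone near 0–20, muscle
300, fat 450, bladder 800) follow balanced-SSFP contrast ordering, with
bone and gas both MR-dark — deliberately preserving the hardest ambiguity
of real MR-to-CT translation. Corruption: a seeded low-order-polynomial
multiplicative bias field (exponentiated, amplitude-limited to ±20%) and
Rician noise (magnitude of a complex Gaussian) on MR; additive Gaussian
noise (SD 20 HU) and partial-volume smoothing on CT. The partial-volume
scale is physical (2 mm), not a voxel count, so coarse desk grids are not
artificially blurred; this keeps the phantom's learnability guarantee — a
per-class HU lookup reproduces the CT to within twice the noise SD — true
at every grid scale.

The phantom emulates class geometry, modality-typical corruption and the
exterior conventions. It does **not** emulate continuous soft-tissue
texture, anatomical variability beyond mild seeded jitter, inter-scan
deformation, or dose physics: the analytic pseudo-dose
(`generateDose()`) is a Gaussian falloff anchored at the PTV centroid,
supporting exact DVH/gamma arithmetic but standing in no relation to a
treatment planning system. Passing tests on phantoms therefore demonstrates
the pipeline's correctness and trainability, not clinical image quality;
headline clinical numbers require a patient cohort and full-scale training.

## Numerical and scale choices

* **Grid convention** — axis 1 left–right (sagittal slicing), axis 2
  anterior–posterior (coronal), axis 3 superior–inferior (axial);
  physical mapping is corner-of-first-voxel anchored with half-open voxel
  extents. One fixed convention, documented, so geometry is testable.
* **Resampling** — trilinear for images and dose, nearest for masks
  (keeps them binary). The full-scale working grid is 256³ at
  1.5×1.5×1 mm³; the desk-scale default is 64³ at 6×6×4 mm³.
* **Network scale** — desk-scale generator: depth 3, 16 base channels at
  64×64 planes; discriminator: downsampling factor 16 (the 256→16
  PatchGAN ratio), so a 64-pixel plane yields a 4×4 score map. This compact
  model trains in minutes on one CPU core while exercising every
  architectural property (skip connections, bounded tanh output, patch
  scoring); both specs scale up configurably (depth ≥ 6 at 256×256 for the
  full-size model). Weights initialize from N(0, 0.02); instance
  normalization everywhere except the first encoder/discriminator block.
* **Study sizes** — the packaged experiments (tests and the acceptance
  script) use 8 training phantoms plus a held-out case at 64³, a few
  epochs, chosen as the smallest cohort on which held-out improvement,
  fusion benefit and dosimetric agreement are all measurable in minutes.
* **SSIM** — the single global statistic (means, population variances and
  cross-covariance of the whole volume) with c₁ = (0.01·4095)²,
  c₂ = (0.03·4095)², exactly as the printed formula; windowed mean-SSIM
  implementations differ and are available behind `windowed = TRUE`.
* **PSNR** — `10·log10(MAX²/MSE)`, log base 10, MAX taken as the maximum
  reference-CT voxel value; a perfect match reports the sentinel `Inf`
  rather than a number.
* **Tissue segments** — thresholds on the reference CT only; -200 HU and
  +200 HU belong to soft tissue (the inclusive residual class); no
  morphology.
* **DVH** — exact survival curve of the sorted in-structure voxel doses;
  Dx% by linear interpolation between order statistics (type-7 quantile at
  1 - x/100), no histogram binning.
* **Gamma** — global normalization: the dose criterion is a percentage of
  the maximum *reference* dose, matching the convention in which the 10%
  low-dose threshold is also defined on the reference maximum. The search
  uses a sphere of radius 2×DTA sampled at DTA/10 steps with trilinear
  interpolation, offsets sorted by distance with early exit; tests compare
  against an exhaustive search at the same lattice. Local-normalization
  gamma is a different (stricter) convention and is out of scope.
* **Degenerate inputs** — empty ROIs, all-zero reference doses, constant
  MR included regions, and sub-minimum phantom shapes raise errors rather
  than returning silent zeros.

## Reproducibility

Training is a pure function of (cases, seed): all initialization and
sampling flows through R's RNG seeded from `trainConfig(seed=)`, so two
runs produce bitwise-identical loss histories and weights. Checkpoints
(`writeCheckpoint()`) store the architecture spec, weights and RNG state in
one file. The CLI (`runPipeline()`) writes every output atomically and
dumps an effective-config file per run; identical inputs and seed produce
byte-identical reports.

## Known limitations

* The desk-scale model under-fits bone after a few epochs — bone and gas
  share the MR-dark ambiguity and need more capacity/epochs than the
  packaged smoke studies run; whole-body MAE on phantoms lands near
  ~80 HU rather than the tens-of-HU regime a full-scale trained model
  reaches on real cohorts.
* The nMI term's soft-binning gradient is exact for the soft histogram but
  the reported loss uses the hard histogram; the two differ by the binning
  kernel (tested to track within 0.2).
* NRRD support covers the attached-header raw little-endian subset the
  pipeline writes, not the full format zoo; DICOM and DICOM-RT are out of
  scope.
* Orientation handling assumes volumes already share the fixed axis
  convention; no rotation matrices are interpreted.
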