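# synthCT

Adversarial MR-to-CT synthesis with multi-planar fusion, plus the
image-quality and dosimetric evaluation suite to judge it — for medical
physicists and imaging researchers working on MRI-guided adaptive
radiotherapy (MRgART), and for anyone who needs a fully reproducible,
CPU-scale testbed for MR→CT translation pipelines.

## The problem

MRgART replans each treatment fraction on the day's MR anatomy, but dose
calculation needs electron/mass density, which MR does not provide. The
usual workaround — deforming the simulation CT onto the daily MR — is slow
and adds registration uncertainty. The alternative implemented here is a
conditional GAN that translates low-field MR volumes directly into
synthetic CT (sCT) in Hounsfield units.

## The method

A U-Net generator G (MR plane → CT plane, tanh-bounded to [-1, 1]) and a
PatchGAN discriminator D (conditioned (MR, CT) pair → 2D patch score map)
are trained with the composite objective

    L_T = L_cGAN(G, D) + λ1 · L_L1(G) + λ2 · L_MI(G),   λ1 = 100, λ2 = 5

where `L_cGAN` is the least-squares adversarial loss, `L_L1` the voxelwise
mean absolute error, and `L_MI = E[1 − nMI(y, G(x))]` a normalized
mutual-information term (nMI = I/√(H·H) ∈ [0, 1]) that tolerates small
MR–CT misalignment. Training batches contain one axial, one sagittal and
one coronal plane pair drawn without slice reuse per epoch; empty planes
are skipped; the discriminator is fed through a history buffer of past
generated planes; Adam learning rates (2e-4 / 5e-5) decay 1% per epoch. At
inference the generator is run slice-wise along all three orientations and
the three volumes are averaged voxelwise into `sCT_ave`.

Evaluation: MAE/ME/PSNR within the body contour, MAE/ME per HU-threshold
tissue segment (air < -200 HU < soft ≤ 200 HU < bone), global SSIM, exact
cumulative DVHs with D95%/D2%, and 3D gamma analysis (1%/1 mm and 2%/2 mm,
global normalization, 10%-of-maximum dose threshold).

Everything runs on procedurally generated paired pelvis phantoms
(deterministic per seed), so the whole pipeline — including adversarial
training — is exercisable end to end on one CPU core. See the methods
vignette (`vignettes/synthetic-ct-methods.Rmd`) for the model, the design
decisions and the limits of phantom-based evidence.

## Worked example

```r
library(synthCT)

# one seeded phantom case: paired MR/CT + masks on a 48^3 grid
spec <- phantomSpec(seed = 7, shape = c(48, 48, 48), spacing = c(8, 8, 6))
case <- generatePairedCase(spec)
case
#> PairedCase 48 x 48 x 48, body voxels 32286, structures: PTV, rectum,
#>   bladder, urethra, no dose

# short adversarial training on two other phantoms
cases <- lapply(1:2, function(s)
  preprocessCase(generatePairedCase(
    phantomSpec(seed = s, shape = c(48, 48, 48), spacing = c(8, 8, 6)))))
fit <- trainTranslator(cases, trainConfig(epochs = 2, seed = 7),
                       generatorSpec(depth = 3, baseChannels = 8),
                       discriminatorSpec(downsampleFactor = 8, baseChannels = 8))
fit$history[, c("epoch", "lrG", "meanL1", "meanD", "kept", "skipped")]
#>   epoch      lrG    meanL1     meanD kept skipped
#> 1     0 0.000200 0.6925337 0.8248820   55      41
#> 2     1 0.000198 0.4261952 0.5334355   56      40

# multi-planar synthesis on the held-out case, then image quality
sct <- synthesizeCT(fit$generator, case@mr, case@bodyMask)
report <- evaluateQuality(sct@sctAve, case@ct, case@bodyMask)
report
#> Image-quality report (synthetic vs reference CT)
#>   MAE [HU]  whole 209.3 | air 967.5 | soft 183.2 | bone 405.0
#>   ME  [HU]  whole +115.3 | air +967.5 | soft +179.4 | bone -405.0
#>   PSNR 9.99 dB, SSIM 0.9692
#>   voxels: body 32286 (air 54, soft 28618, bone 3614)

# dosimetry on the analytic pseudo-dose
dose <- generateDose(case)                     # 36.25 Gy at the PTV centroid
curve <- computeDVH(dose, case@structures$PTV, "PTV")
dvhMetric(curve, 95); dvhMetric(curve, 2)
#> [1] 34.08  ...  36.07                          # PTV D95% / D2% in Gy
pert <- perturbDose(dose, scale = 1.005, shiftMM = c(0, 0, 1), interpolate = TRUE)
gammaPassRate(dose, pert, gammaCriteria(1, 1))  # 100 (% of ROI voxels passing)
```

Reading the numbers: after only two epochs on two tiny phantoms, the mean
training L1 (in normalized units) drops from 0.69 to 0.43 and the
synthesized volume already tracks soft tissue, while bone — MR-dark, like
gas — is still poorly resolved (bone MAE 405 HU); more cases and epochs
close that gap (the acceptance run below reaches ~80 HU whole-body MAE).
The DVH and gamma numbers show the dosimetry tools on a controlled pair: a
0.5% dose scaling plus 1 mm shift stays within 1%/1 mm everywhere.

A command-line wrapper over the same functions is installed with the
package (`system.file("cli", "synthct", package = "synthCT")`) with
subcommands `phantom`, `preprocess`, `train`, `synthesize`, `evaluate`,
`dvh`, `gamma`.

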