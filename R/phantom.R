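#' Specification of a procedural paired pelvis phantom
#'
#' Defines the geometry, tissue-class intensities and corruption model of a
#' synthetic paired MR/CT pelvis case. Default CT class means respect the
#' Hounsfield segmentation thresholds (gas/air below -200 HU, soft tissue
#' within [-200, 200] HU, bone above 200 HU); default MR means follow the
#' balanced-SSFP contrast ordering of low-field pelvic imaging (fluid
#' brightest, fat bright, muscle intermediate, bone and gas near zero).
#'
#' @param seed RNG seed making the phantom fully deterministic.
#' @param shape integer(3) grid dimensions (at least 32 per axis).
#' @param spacing numeric(3) voxel size in mm.
#' @param classCTMeans named HU means for classes
#'   `air, gas, fat, muscle, bladder, prostate, bone`.
#' @param classMRMeans named MR means (arbitrary units) for the same classes.
#' @param noiseSdCT additive Gaussian noise SD on CT (HU).
#' @param noiseSdMR Rician noise scale on MR (arbitrary units).
#' @param biasAmplitude fractional amplitude of the smooth multiplicative MR
#'   bias field (0.2 = +/-20%).
#' @param gasPocket logical; carve a gas pocket into the rectal tube.
#' @param pvSigmaMM physical scale (mm) of the partial-volume smoothing
#'   applied to both modalities at tissue-class boundaries.
#' @return A list of class `"PhantomSpec"`.
#' @examples
#' spec <- phantomSpec(seed = 1, shape = c(48, 48, 48))
#' case <- generatePairedCase(spec)
#' @export
phantomSpec <- function(seed = 1L,
                        shape = c(64L, 64L, 64L),
                        spacing = c(6, 6, 4),
                        classCTMeans = c(air = -1000, gas = -800, fat = -90,
                                         muscle = 45, bladder = 15,
                                         prostate = 40, bone = 700),
                        classMRMeans = c(air = 0, gas = 10, fat = 450,
                                         muscle = 300, bladder = 800,
                                         prostate = 330, bone = 20),
                        noiseSdCT = 20,
                        noiseSdMR = 15,
                        biasAmplitude = 0.2,
                        gasPocket = TRUE,
                        pvSigmaMM = 2) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (any(shape < 32L))
    stop("shape too small to place all organs (need >= 32 voxels per axis)")
  cls <- c("air", "gas", "fat", "muscle", "bladder", "prostate", "bone")
  stopifnot(all(cls %in% names(classCTMeans)),
            all(cls %in% names(classMRMeans)))
  if (any(classCTMeans[c("air", "gas")] >= -200))
    stop("air/gas CT means must be below -200 HU")
  if (any(classCTMeans[c("fat", "muscle", "bladder", "prostate")] < -200) ||
      any(classCTMeans[c("fat", "muscle", "bladder", "prostate")] > 200))
    stop("soft-tissue CT means must lie in [-200, 200] HU")
  if (classCTMeans[["bone"]] <= 200) stop("bone CT mean must exceed 200 HU")
  if (max(classMRMeans) != classMRMeans[["bladder"]])
    stop("bladder must be the brightest MR class")
  structure(list(seed = as.integer(seed), shape = shape,
                 spacing = as.numeric(spacing),
                 classCTMeans = classCTMeans[cls],
                 classMRMeans = classMRMeans[cls],
                 noiseSdCT = noiseSdCT, noiseSdMR = noiseSdMR,
                 biasAmplitude = biasAmplitude, gasPocket = isTRUE(gasPocket),
                 pvSigmaMM = pvSigmaMM),
            class = "PhantomSpec")
}

# Tissue-class integer codes shared with truthLabels.
PHANTOM_CLASSES <- c(air = 0L, gas = 1L, fat = 2L, muscle = 3L,
                     bladder = 4L, prostate = 5L, bone = 6L)

#' Generate one paired MR/CT phantom case
#'
#' Builds, deterministically for a fixed seed, an elliptical body with a fat
#' rim, an elliptical bone ring with femoral-head spheres, an MR-bright
#' bladder sphere, a rectal tube (with optional gas pocket), and a
#' prostate/PTV sphere between bladder and rectum, plus a thin urethra.
#' The CT volume is the class-mean lookup, partial-volume smoothed at class
#' boundaries, with additive Gaussian noise; the MR volume carries a smooth
#' multiplicative bias field and Rician noise (magnitude of a complex
#' Gaussian). Outside the body contour CT = -1000 HU and MR = 0 exactly.
#'
#' @param spec a [phantomSpec()].
#' @return A [PairedCase-class] with structures PTV, rectum, bladder,
#'   urethra, ground-truth `truthLabels`, and no dose (see [generateDose()]).
#' @export
generatePairedCase <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  withSeed(spec$seed, generatePairedCaseImpl(spec))
}

generatePairedCaseImpl <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  # normalized coordinates in [-1, 1] per axis
  cx <- coordGrid(d, 1L); cy <- coordGrid(d, 2L); cz <- coordGrid(d, 3L)

  # mild seeded anatomy jitter so cases differ
  j <- stats::runif(6, -0.04, 0.04)

  inEllipsoid <- function(c0, r) {
    ((cx - c0[1]) / r[1])^2 + ((cy - c0[2]) / r[2])^2 +
      ((cz - c0[3]) / r[3])^2 <= 1
  }
  body <- inEllipsoid(c(j[1], j[2], 0), c(0.86, 0.72, 0.96))
  fatRimOuter <- body
  fatRimInner <- inEllipsoid(c(j[1], j[2], 0), c(0.74, 0.60, 0.90))

  labels <- array(PHANTOM_CLASSES[["air"]], d)
  labels[fatRimOuter & !fatRimInner] <- PHANTOM_CLASSES[["fat"]]
  labels[fatRimInner] <- PHANTOM_CLASSES[["muscle"]]

  # elliptical bone ring (pelvic girdle) over the central axial band
  ringR <- sqrt(((cx - j[1]) / 0.58)^2 + ((cy - j[2]) / 0.46)^2)
  ring <- ringR >= 0.82 & ringR <= 1.0 & abs(cz) <= 0.45 & fatRimInner
  labels[ring] <- PHANTOM_CLASSES[["bone"]]
  # femoral heads
  fh1 <- inEllipsoid(c(-0.52 + j[3], 0.05, 0), c(0.14, 0.14, 0.17))
  fh2 <- inEllipsoid(c(0.52 + j[3], 0.05, 0), c(0.14, 0.14, 0.17))
  labels[(fh1 | fh2) & fatRimInner] <- PHANTOM_CLASSES[["bone"]]

  inside <- labels == PHANTOM_CLASSES[["muscle"]]
  # bladder: anterior sphere, modest filling
  bladder <- inEllipsoid(c(j[4], -0.22 + j[5], 0.05), c(0.16, 0.15, 0.16)) & inside
  labels[bladder] <- PHANTOM_CLASSES[["bladder"]]
  # rectal tube: posterior cylinder along superior-inferior axis
  rectR <- sqrt(((cx - j[4]) / 0.10)^2 + ((cy - (0.30 + j[6])) / 0.10)^2)
  rectum <- rectR <= 1 & abs(cz) <= 0.5 & inside
  labels[rectum] <- PHANTOM_CLASSES[["muscle"]]  # rectal wall/content ~ soft
  if (spec$gasPocket) {
    gas <- rectR <= 0.75 & abs(cz - 0.12) <= 0.14 & rectum
    labels[gas] <- PHANTOM_CLASSES[["gas"]]
  }
  # prostate between bladder and rectum
  prostate <- inEllipsoid(c(j[4], 0.04 + j[5], 0.0), c(0.11, 0.11, 0.12)) &
    inside & labels == PHANTOM_CLASSES[["muscle"]]
  labels[prostate] <- PHANTOM_CLASSES[["prostate"]]
  # urethra: thin tube through the prostate
  urethra <- sqrt(((cx - j[4]) / 0.035)^2 + ((cy - (0.04 + j[5])) / 0.035)^2) <= 1 &
    abs(cz) <= 0.18

  bodyMask <- array(as.numeric(labels != PHANTOM_CLASSES[["air"]]), d)

  ctMeanVol <- array(spec$classCTMeans[match(labels, PHANTOM_CLASSES)], d)
  mrMeanVol <- array(spec$classMRMeans[match(labels, PHANTOM_CLASSES)], d)

  # partial-volume effect: light smoothing of the class-mean CT at boundaries
  pvSigmaVox <- spec$pvSigmaMM / sp
  ct <- gaussianSmooth3D(ctMeanVol, sigmaVox = pvSigmaVox)
  ct <- ct + stats::rnorm(length(ct), 0, spec$noiseSdCT)
  ct <- pmin(pmax(ct, -1000), 3095)

  # MR: smooth multiplicative bias field + Rician noise
  bias <- biasField(d, amplitude = spec$biasAmplitude)
  mrClean <- gaussianSmooth3D(mrMeanVol, sigmaVox = pvSigmaVox) * bias
  n1 <- stats::rnorm(length(mrClean), 0, spec$noiseSdMR)
  n2 <- stats::rnorm(length(mrClean), 0, spec$noiseSdMR)
  mr <- sqrt((mrClean + n1)^2 + n2^2)

  out <- bodyMask == 0
  ct[out] <- -1000
  mr[out] <- 0

  mk <- function(a, modality) Volume(array(a, d), spacing = sp,
                                     modality = modality)
  asMask <- function(logic) mk(as.numeric(logic & bodyMask == 1), "MASK")
  PairedCase(
    mr = mk(mr, "MR"), ct = mk(ct, "CT"), bodyMask = mk(bodyMask, "MASK"),
    structures = list(PTV = asMask(prostate),
                      rectum = asMask(rectum),
                      bladder = asMask(bladder),
                      urethra = asMask(urethra & inside)),
    dose = NULL,
    truthLabels = array(labels, d)
  )
}

#' Analytic pseudo-dose for a phantom case
#'
#' A stand-in for a treatment-planning dose engine: an isotropic Gaussian
#' falloff centred on the PTV centroid, equal to the prescription at the
#' centroid and strictly non-increasing along every ray from it.
#'
#' @param case a [PairedCase-class] with a nonempty PTV structure.
#' @param prescription prescription dose in Gy (default 36.25, a typical
#'   5-fraction prostate SBRT prescription).
#' @param falloffMM Gaussian width parameter in mm (default 60).
#' @return A DOSE [Volume-class] on the case grid.
#' @export
generateDose <- function(case, prescription = 36.25, falloffMM = 60) {
  stopifnot(is(case, "PairedCase"))
  ptv <- case@structures$PTV
  if (is.null(ptv) || sum(ptv@values) == 0) stop("empty PTV")
  d <- dim(ptv@values); sp <- ptv@spacing
  idx <- which(ptv@values == 1, arr.ind = TRUE)
  centroid <- round(colMeans(idx))  # snap to the nearest voxel centre
  ax <- (seq_len(d[1]) - centroid[1]) * sp[1]
  ay <- (seq_len(d[2]) - centroid[2]) * sp[2]
  az <- (seq_len(d[3]) - centroid[3]) * sp[3]
  r2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  dose <- prescription * exp(-r2 / (2 * falloffMM^2))
  Volume(dose, spacing = sp, origin = ptv@origin, modality = "DOSE")
}

#' Perturb a dose grid for gamma-analysis testing
#'
#' Returns a scaled and/or spatially shifted copy of a dose volume, used to
#' construct controlled gamma-index test pairs. Without interpolation the
#' shift must be an integer number of voxels per axis; voxels shifted in
#' from outside the grid are zero-filled.
#'
#' @param dose a DOSE [Volume-class].
#' @param scale multiplicative factor.
#' @param shiftMM numeric(3) spatial shift in mm.
#' @param interpolate allow non-integer voxel shifts via linear resampling.
#' @return A perturbed DOSE [Volume-class] on the same grid.
#' @export
perturbDose <- function(dose, scale = 1, shiftMM = c(0, 0, 0),
                        interpolate = FALSE) {
  stopifnot(is(dose, "Volume"))
  if (!all(is.finite(dose@values))) stop("dose contains non-finite values")
  v <- dose@values * scale
  shiftVox <- shiftMM / dose@spacing
  if (any(shiftMM != 0)) {
    if (!interpolate) {
      if (max(abs(shiftVox - round(shiftVox))) > 1e-9)
        stop("shift must be a multiple of the voxel size unless interpolate=TRUE")
      v <- integerShift(v, as.integer(round(shiftVox)))
    } else {
      d <- dim(v)
      xi <- seq_len(d[1]) - 1 - shiftVox[1]
      yi <- seq_len(d[2]) - 1 - shiftVox[2]
      zi <- seq_len(d[3]) - 1 - shiftVox[3]
      v <- interp3(v, xi, yi, zi)
    }
  }
  Volume(v, spacing = dose@spacing, origin = dose@origin, modality = "DOSE")
}

integerShift <- function(a, s) {
  d <- dim(a)
  out <- array(0, d)
  srcFrom <- pmax(1, 1 - s); srcTo <- pmin(d, d - s)
  if (any(srcTo < srcFrom)) return(out)
  dstFrom <- srcFrom + s; dstTo <- srcTo + s
  out[dstFrom[1]:dstTo[1], dstFrom[2]:dstTo[2], dstFrom[3]:dstTo[3]] <-
    a[srcFrom[1]:srcTo[1], srcFrom[2]:srcTo[2], srcFrom[3]:srcTo[3]]
  out
}

# ---- shared numeric helpers ----

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(expr)
}

coordGrid <- function(d, axis) {
  g <- seq(-1, 1, length.out = d[axis])
  switch(axis,
         array(g, d),
         array(rep(g, each = d[1]), d),
         array(rep(g, each = d[1] * d[2]), d))
}

# Separable Gaussian smoothing with a truncated discrete kernel (sigma in
# voxels). Edge handling: renormalized (kernel mass inside the grid).
gaussianSmooth3D <- function(a, sigmaVox) {
  if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
  for (ax in 1:3) {
    s <- sigmaVox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- convolveAxis(a, k, ax)
  }
  a
}

# 1D convolution along one axis with edge renormalization, via matrix products
convolveAxis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  # banded n x n matrix, rows renormalized at the edges
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n)
    j <- idx + off
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- k[off + r + 1]
  }
  K <- K / rowSums(K)
  m <- aperm(a, c(axis, setdiff(1:3, axis)))
  dm <- dim(m)
  m <- K %*% matrix(m, nrow = n)
  dim(m) <- dm
  aperm(m, order(c(axis, setdiff(1:3, axis))))
}

# Smooth multiplicative bias field: exp of a seeded low-order polynomial in
# normalized coordinates, rescaled to [1-amplitude, 1+amplitude].
biasField <- function(d, amplitude) {
  if (amplitude <= 0) return(array(1, d))
  cx <- coordGrid(d, 1L); cy <- coordGrid(d, 2L); cz <- coordGrid(d, 3L)
  co <- stats::runif(9, -1, 1)
  p <- co[1] * cx + co[2] * cy + co[3] * cz +
    co[4] * cx * cy + co[5] * cy * cz + co[6] * cx * cz +
    co[7] * cx^2 + co[8] * cy^2 + co[9] * cz^2
  p <- p - mean(p)
  if (max(abs(p)) > 0) p <- p / max(abs(p)) * log1p(amplitude)
  exp(p)
}
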