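HU_MIN <- -1000
HU_MAX <- 3095
HU_RANGE <- HU_MAX - HU_MIN  # 4095

#' Set the volume exterior to its modality background value
#'
#' Voxels outside the body contour are set to -1000 HU for CT/SCT and 0 for
#' MR; voxels inside are untouched. Idempotent.
#'
#' @param v an MR, CT or SCT [Volume-class].
#' @param body a MASK [Volume-class] on the same grid.
#' @return The masked [Volume-class].
#' @export
maskExterior <- function(v, body) {
  stopifnot(is(v, "Volume"), is(body, "Volume"))
  if (v@modality == "MASK") stop("mask_exterior expects an image, not a MASK")
  if (!v@modality %in% c("MR", "CT", "SCT"))
    stop("maskExterior applies to MR, CT or SCT volumes")
  if (body@modality != "MASK") stop("body must be a MASK volume")
  if (!identical(dim(v@values), dim(body@values)))
    stop("grid mismatch between volume and body mask")
  bg <- if (v@modality == "MR") 0 else -1000
  out <- v@values
  out[body@values == 0] <- bg
  Volume(out, spacing = v@spacing, origin = v@origin, modality = v@modality)
}

#' CT intensity normalization to [-1, 1]
#'
#' Affine map pinned by the Hounsfield range endpoints: -1000 HU maps to -1
#' and 3095 HU maps to 1, i.e. `norm = (HU + 1000) / 2047.5 - 1`. Values
#' outside [-1000, 3095] are clipped first. Exactly invertible on the range
#' by [denormalizeCT()].
#'
#' @param hu HU scalar, array, or CT/SCT [Volume-class].
#' @return Same shape as the input, in [-1, 1] (a Volume stays a Volume).
#' @examples
#' normalizeCT(c(-1000, 1047.5, 3095))  # -1 0 1
#' @export
normalizeCT <- function(hu) {
  if (is(hu, "Volume")) {
    v <- hu
    v@values <- normalizeCT(v@values)
    return(v)
  }
  if (any(!is.finite(hu))) stop("non-finite HU input")
  hu <- pmin(pmax(hu, HU_MIN), HU_MAX)
  (hu - HU_MIN) / (HU_RANGE / 2) - 1
}

#' Inverse of the CT normalization
#'
#' @param x normalized intensity in [-1, 1] (small tolerance allowed),
#'   scalar, array, or Volume.
#' @return HU values; `denormalizeCT(normalizeCT(h)) == h` on [-1000, 3095].
#' @export
denormalizeCT <- function(x) {
  if (is(x, "Volume")) {
    v <- x
    v@values <- denormalizeCT(v@values)
    return(v)
  }
  if (any(!is.finite(x))) stop("non-finite input")
  if (any(x < -1 - 1e-6) || any(x > 1 + 1e-6))
    stop("normalized intensity outside [-1, 1]")
  x <- pmin(pmax(x, -1), 1)
  (x + 1) * (HU_RANGE / 2) + HU_MIN
}

#' MR z-score normalization to [-1, 1]
#'
#' The mean and standard deviation are computed only over voxels whose
#' intensity is at least `airThreshold` (default 40, the clinical air/gas
#' cutoff on balanced-SSFP images); air voxels do not influence them. The
#' z-score is then scaled by `1/truncationSigmas` and clipped, so values at
#' or beyond +/- `truncationSigmas` standard deviations from the mean are
#' truncated to +/-1; air lands at -1.
#'
#' @param v an MR [Volume-class] (or bare numeric array).
#' @param airThreshold intensity below which voxels are excluded from the
#'   mean/SD (default 40).
#' @param truncationSigmas number of SDs mapped to the unit interval
#'   (default 3).
#' @return A list with `volume` (normalized, in [-1, 1]) and `params`
#'   (list: `mean`, `sd`, `airThreshold`, `truncationSigmas`).
#' @export
normalizeMR <- function(v, airThreshold = 40, truncationSigmas = 3) {
  isVol <- is(v, "Volume")
  a <- if (isVol) v@values else v
  stopifnot(airThreshold >= 0, truncationSigmas > 0)
  inc <- a >= airThreshold
  if (sum(inc) < 2L) stop("fewer than 2 voxels at or above the air threshold")
  mu <- mean(a[inc])
  sd <- stats::sd(a[inc])
  if (sd == 0) stop("included region is constant; z-score undefined")
  z <- (a - mu) / sd
  out <- pmin(pmax(z / truncationSigmas, -1), 1)
  params <- list(mean = mu, sd = sd, airThreshold = airThreshold,
                 truncationSigmas = truncationSigmas)
  vol <- if (isVol)
    Volume(out, spacing = v@spacing, origin = v@origin, modality = "MR")
  else out
  list(volume = vol, params = params)
}

#' Homomorphic bias-field correction
#'
#' Estimates a smooth multiplicative intensity non-uniformity field inside
#' the body contour by large-kernel Gaussian smoothing of the log-intensity
#' (normalized convolution, so only in-body voxels contribute), divides it
#' out, and rescales so the mean in-body intensity is preserved. Voxels
#' outside the body are returned unchanged.
#'
#' The reference N4 parameter set used clinically (BSpline order 3, grid
#' (1,1,1), shrink factor 4, 50/40/30 iterations, convergence 1e-4) is
#' recorded in [defaultN4Params()] for documentation and for plugging in an
#' external N4 implementation; this function is the package's own
#' log-domain smoothing corrector.
#'
#' @param v an MR [Volume-class].
#' @param body a MASK [Volume-class] on the same grid; must be nonempty.
#' @param sigmaMM Gaussian kernel SD in mm (default: 1/8 of the largest
#'   grid extent, a scale well above anatomy but below the field's
#'   variation).
#' @return A list with `volume` (corrected MR) and `field` (estimated
#'   multiplicative field, 1 outside the body).
#' @export
correctBiasField <- function(v, body, sigmaMM = NULL) {
  stopifnot(is(v, "Volume"), is(body, "Volume"))
  if (body@modality != "MASK") stop("body must be a MASK volume")
  if (!identical(dim(v@values), dim(body@values))) stop("grid mismatch")
  b <- body@values
  if (sum(b) == 0) stop("empty body mask")
  if (is.null(sigmaMM)) {
    ext <- dim(v@values) * v@spacing
    sigmaMM <- max(ext) / 8
  }
  sigmaVox <- sigmaMM / v@spacing
  eps <- 1e-6
  logv <- log(pmax(v@values, eps)) * b
  num <- gaussianSmooth3D(logv, sigmaVox)
  den <- gaussianSmooth3D(b, sigmaVox)
  logfield <- ifelse(den > 1e-12, num / den, 0)
  # zero-mean the log field inside the body so the field is pure shape
  logfield <- logfield - sum(logfield * b) / sum(b)
  field <- exp(logfield)
  corrected <- v@values
  inB <- b == 1
  corrected[inB] <- v@values[inB] / field[inB]
  # preserve mean in-body intensity
  ratio <- mean(v@values[inB]) / mean(corrected[inB])
  corrected[inB] <- corrected[inB] * ratio
  fieldOut <- array(1, dim(v@values))
  fieldOut[inB] <- field[inB]
  list(volume = Volume(corrected, spacing = v@spacing, origin = v@origin,
                       modality = v@modality),
       field = fieldOut)
}

#' Reference N4 bias-correction parameters
#'
#' The externally validated N4 configuration recorded for documentation and
#' for use when an external N4 implementation is plugged into the pipeline;
#' [correctBiasField()] itself uses homomorphic log-domain smoothing.
#'
#' @return A named list of N4 settings.
#' @export
defaultN4Params <- function() {
  list(bsplineOrder = 3L, bsplineGridResolution = c(1L, 1L, 1L),
       shrinkFactor = 4L, maxIterations = c(50L, 40L, 30L),
       convergenceThreshold = 1e-4)
}

#' Derive a body mask from a CT volume
#'
#' For inputs that arrive without a skin contour: threshold HU > -400, keep
#' the largest 6-connected component, and fill interior holes (background
#' components not reachable from the grid border).
#'
#' @param ct a CT [Volume-class] in HU.
#' @param thresholdHU threshold above which voxels are candidate body
#'   (default -400).
#' @return A MASK [Volume-class].
#' @export
bodyMaskFromCT <- function(ct, thresholdHU = -400) {
  stopifnot(is(ct, "Volume"))
  fg <- ct@values > thresholdHU
  lab <- largestComponent(fg)
  filled <- fillHoles(lab)
  Volume(array(as.numeric(filled), dim(fg)), spacing = ct@spacing,
         origin = ct@origin, modality = "MASK")
}

# Largest 6-connected foreground component by iterative geodesic dilation
# from the strongest seed.
largestComponent <- function(fg) {
  remaining <- fg
  best <- NULL; bestN <- 0L
  while (any(remaining)) {
    seedIdx <- which(remaining)[1]
    comp <- array(FALSE, dim(fg))
    comp[seedIdx] <- TRUE
    comp <- floodGrow(comp, remaining)
    n <- sum(comp)
    if (n > bestN) { best <- comp; bestN <- n }
    remaining <- remaining & !comp
    if (bestN >= sum(remaining)) break  # no larger component possible
  }
  best
}

floodGrow <- function(comp, mask) {
  repeat {
    grown <- comp
    grown <- grown | shiftLogical(comp, 1, 1) | shiftLogical(comp, -1, 1) |
      shiftLogical(comp, 1, 2) | shiftLogical(comp, -1, 2) |
      shiftLogical(comp, 1, 3) | shiftLogical(comp, -1, 3)
    grown <- grown & mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

shiftLogical <- function(a, by, axis) {
  s <- c(0L, 0L, 0L); s[axis] <- by
  integerShift(array(as.numeric(a), dim(a)), s) > 0
}

fillHoles <- function(fg) {
  d <- dim(fg)
  bg <- !fg
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- floodGrow(border & bg, bg)
  fg | (bg & !outside)
}

#' Preprocess a paired case for training
#'
#' Full preprocessing chain: bias-correct the MR inside the body, mask
#' exteriors, normalize CT by the Hounsfield affine map and MR by the
#' thresholded z-score, both to [-1, 1].
#'
#' @param case a [PairedCase-class].
#' @param biasCorrect run [correctBiasField()] on the MR first.
#' @return A list with `mr`, `ct` (normalized volumes), `bodyMask`, and
#'   `mrParams` (the [normalizeMR()] parameters).
#' @export
preprocessCase <- function(case, biasCorrect = TRUE) {
  stopifnot(is(case, "PairedCase"))
  mr <- case@mr
  if (biasCorrect) mr <- correctBiasField(mr, case@bodyMask)$volume
  mr <- maskExterior(mr, case@bodyMask)
  ct <- maskExterior(case@ct, case@bodyMask)
  nm <- normalizeMR(mr)
  list(mr = nm$volume, ct = normalizeCT(ct), bodyMask = case@bodyMask,
       mrParams = nm$params)
}
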