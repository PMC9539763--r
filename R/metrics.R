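#' Hounsfield-threshold tissue segmentation
#'
#' Splits the body ROI of the reference CT into three segments by voxelwise
#' intensity thresholds, with no morphological post-processing: air below
#' -200 HU, bone above 200 HU, soft tissue the inclusive residual
#' [-200, 200] HU. The segments partition the body mask exactly.
#'
#' @param ct reference CT [Volume-class] in HU.
#' @param body MASK [Volume-class].
#' @return A list of class `"TissueSegments"` with logical arrays `air`,
#'   `soft`, `bone`.
#' @export
segmentTissues <- function(ct, body) {
  stopifnot(is(ct, "Volume"), is(body, "Volume"))
  if (!identical(dim(ct@values), dim(body@values))) stop("grid mismatch")
  b <- body@values == 1
  if (!any(b)) stop("empty body mask")
  a <- ct@values
  structure(list(air = b & a < -200,
                 soft = b & a >= -200 & a <= 200,
                 bone = b & a > 200),
            class = "TissueSegments")
}

#' Mean absolute error in CT numbers over an ROI
#'
#' @param sct synthetic CT [Volume-class] (HU).
#' @param ct reference CT [Volume-class] (HU).
#' @param roi logical array or MASK [Volume-class]; must be nonempty.
#' @return MAE in HU.
#' @export
maeHU <- function(sct, ct, roi) {
  r <- roiIndex(sct, ct, roi)
  mean(abs(sct@values[r] - ct@values[r]))
}

#' Mean (signed) error in CT numbers over an ROI
#'
#' Sign convention: synthetic minus reference, so a positive ME means the
#' synthetic CT overestimates.
#'
#' @inheritParams maeHU
#' @return ME in HU.
#' @export
meHU <- function(sct, ct, roi) {
  r <- roiIndex(sct, ct, roi)
  mean(sct@values[r] - ct@values[r])
}

roiIndex <- function(sct, ct, roi) {
  if (is(roi, "Volume")) roi <- roi@values == 1
  if (!identical(dim(sct@values), dim(ct@values)) ||
      !identical(dim(sct@values), dim(roi)))
    stop("grid mismatch")
  if (!any(roi)) stop("empty ROI")
  roi
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX_CT^2 / MSE)` where MSE is taken over the ROI and MAX_CT
#' is the maximum reference-CT voxel value over the whole volume. A perfect
#' match (MSE = 0) is reported as the sentinel `Inf`.
#'
#' @inheritParams maeHU
#' @return PSNR in dB (`Inf` when sct == ct on the ROI).
#' @export
psnrHU <- function(sct, ct, roi) {
  r <- roiIndex(sct, ct, roi)
  mse <- mean((sct@values[r] - ct@values[r])^2)
  maxCT <- max(ct@values)
  if (mse == 0) return(Inf)
  10 * log10(maxCT^2 / mse)
}

#' Global structural similarity index
#'
#' The single global SSIM statistic computed from whole-volume means,
#' variances (population, 1/n) and cross-covariance:
#' `(2 mu_s mu_c + c1)(2 cov + c2) / ((mu_s^2 + mu_c^2 + c1)(var_s + var_c + c2))`
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and dynamic range L = 4095 HU.
#' A windowed mean-SSIM variant (8^3-voxel non-overlapping windows) is
#' available behind `windowed = TRUE`.
#'
#' @param sct,ct volumes on the full evaluation grid (HU).
#' @param L dynamic range (default 4095).
#' @param windowed compute the mean of per-window SSIM instead of the
#'   single global statistic.
#' @param windowSize window side in voxels for the windowed variant.
#' @return SSIM in [-1, 1].
#' @export
ssimGlobal <- function(sct, ct, L = 4095, windowed = FALSE, windowSize = 8L) {
  stopifnot(is(sct, "Volume"), is(ct, "Volume"))
  if (!identical(dim(sct@values), dim(ct@values))) stop("grid mismatch")
  if (!windowed) return(ssimStat(sct@values, ct@values, L))
  d <- dim(ct@values)
  starts <- lapply(d, function(n) seq(1L, n, by = windowSize))
  vals <- c()
  for (i in starts[[1]]) for (j in starts[[2]]) for (k in starts[[3]]) {
    ii <- i:min(i + windowSize - 1L, d[1])
    jj <- j:min(j + windowSize - 1L, d[2])
    kk <- k:min(k + windowSize - 1L, d[3])
    vals <- c(vals, ssimStat(sct@values[ii, jj, kk], ct@values[ii, jj, kk], L))
  }
  mean(vals)
}

ssimStat <- function(x, y, L) {
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Assemble the full image-quality report
#'
#' Whole-body MAE/ME/PSNR (ROI = voxels within the body contour),
#' per-segment MAE/ME on the threshold tissue segments of the reference CT,
#' and whole-grid global SSIM.
#'
#' @param sct synthetic CT [Volume-class] (HU).
#' @param ct reference CT [Volume-class] (HU).
#' @param body MASK [Volume-class].
#' @return A list of class `"QualityReport"`; see [segmentTissues()],
#'   [maeHU()], [psnrHU()], [ssimGlobal()].
#' @export
evaluateQuality <- function(sct, ct, body) {
  seg <- segmentTissues(ct, body)
  b <- body@values == 1
  segMetric <- function(f, m) if (any(m)) f(sct, ct, m) else NA_real_
  rep <- list(
    maeWhole = maeHU(sct, ct, b),
    maeAir = segMetric(maeHU, seg$air),
    maeSoft = segMetric(maeHU, seg$soft),
    maeBone = segMetric(maeHU, seg$bone),
    meWhole = meHU(sct, ct, b),
    meAir = segMetric(meHU, seg$air),
    meSoft = segMetric(meHU, seg$soft),
    meBone = segMetric(meHU, seg$bone),
    psnr = psnrHU(sct, ct, b),
    ssim = ssimGlobal(sct, ct),
    nVoxels = c(body = sum(b), air = sum(seg$air), soft = sum(seg$soft),
                bone = sum(seg$bone))
  )
  structure(rep, class = "QualityReport")
}

#' @export
print.QualityReport <- function(x, ...) {
  cat("Image-quality report (synthetic vs reference CT)\n")
  cat(sprintf("  MAE [HU]  whole %.1f | air %s | soft %s | bone %s\n",
              x$maeWhole, fmtNA(x$maeAir), fmtNA(x$maeSoft), fmtNA(x$maeBone)))
  cat(sprintf("  ME  [HU]  whole %+.1f | air %s | soft %s | bone %s\n",
              x$meWhole, fmtNA(x$meAir, TRUE), fmtNA(x$meSoft, TRUE),
              fmtNA(x$meBone, TRUE)))
  cat(sprintf("  PSNR %.2f dB, SSIM %.4f\n", x$psnr, x$ssim))
  cat(sprintf("  voxels: body %d (air %d, soft %d, bone %d)\n",
              x$nVoxels[["body"]], x$nVoxels[["air"]], x$nVoxels[["soft"]],
              x$nVoxels[["bone"]]))
  invisible(x)
}

fmtNA <- function(v, signed = FALSE) {
  if (is.na(v)) "n/a" else sprintf(if (signed) "%+.1f" else "%.1f", v)
}
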