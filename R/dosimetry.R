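#' Cumulative dose-volume histogram of a structure
#'
#' Exact cumulative DVH from the sorted in-structure voxel doses (no
#' binning loss): the curve value at dose d is `count(dose >= d) / n`. The
#' stored axis runs from 0 to just above the maximum voxel dose so the
#' curve starts at 1 and ends at 0.
#'
#' @param dose DOSE [Volume-class] in Gy.
#' @param structure MASK [Volume-class] or logical array; nonempty.
#' @param structureName label stored on the curve.
#' @return A [DVHCurve-class].
#' @export
computeDVH <- function(dose, structure, structureName = "structure") {
  stopifnot(is(dose, "Volume"))
  m <- if (is(structure, "Volume")) structure@values == 1 else structure
  if (!identical(dim(m), dim(dose@values))) stop("grid mismatch")
  n <- sum(m)
  if (n == 0) stop("empty structure")
  d <- sort(dose@values[m])
  ax <- unique(c(0, d, d[n] * (1 + 1e-9) + 1e-12))
  frac <- vapply(ax, function(t) sum(d >= t) / n, 1.0)
  new("DVHCurve", doses = d, doseAxis = ax, cumulativeFraction = frac,
      structureName = structureName, voxelCount = as.integer(n))
}

#' DVH dose metric Dx%
#'
#' The greatest dose received by at least x% of the structure volume,
#' evaluated by linear interpolation between the sorted voxel doses
#' (`quantile` type 7 at probability 1 - x/100), with no histogram binning.
#' D95% (x = 95) and D2% (x = 2) are the planning metrics of interest for
#' target coverage and near-maximum dose.
#'
#' @param curve a [DVHCurve-class].
#' @param x percent volume in (0, 100); or the strings `"D95%"`, `"D2%"`.
#' @return Dose in Gy.
#' @examples
#' # uniform ramp over [0, 100] Gy: D95% = 5 Gy, D2% = 98 Gy
#' @export
dvhMetric <- function(curve, x) {
  stopifnot(is(curve, "DVHCurve"))
  if (is.character(x)) x <- as.numeric(sub("^D", "", sub("%$", "", x)))
  if (!is.finite(x) || x <= 0 || x >= 100)
    stop("x must lie strictly between 0 and 100")
  unname(stats::quantile(curve@doses, probs = 1 - x / 100, type = 7))
}

#' Dose-metric difference report
#'
#' Tabulates evaluated minus reference per metric, in Gy and as percent of
#' the prescription dose.
#'
#' @param referenceMetrics,evaluatedMetrics named numeric vectors (Gy) with
#'   identical names (e.g. `c("PTV D95%" = 36.1, ...)`).
#' @param prescription prescription dose in Gy used for the relative
#'   difference.
#' @return data.frame with columns metric, reference, evaluated, diffGy,
#'   diffPct.
#' @export
doseDifferenceReport <- function(referenceMetrics, evaluatedMetrics,
                                 prescription = 36.25) {
  if (!identical(sort(names(referenceMetrics)),
                 sort(names(evaluatedMetrics))))
    stop("metric name mismatch between reference and evaluated tables")
  nm <- names(referenceMetrics)
  ev <- evaluatedMetrics[nm]
  dGy <- as.numeric(ev - referenceMetrics)
  data.frame(metric = nm,
             reference = as.numeric(referenceMetrics),
             evaluated = as.numeric(ev),
             diffGy = dGy,
             diffPct = 100 * dGy / prescription,
             row.names = NULL)
}

#' Gamma-analysis criteria
#'
#' @param dosePercent dose-difference criterion as percent of the global
#'   normalization dose (the maximum of the reference distribution).
#' @param dtaMM distance-to-agreement criterion in mm.
#' @param lowDoseThreshold fraction of the maximum reference dose below
#'   which voxels are excluded from the analysis (default 0.10).
#' @return A list of class `"GammaCriteria"`.
#' @export
gammaCriteria <- function(dosePercent = 1, dtaMM = 1, lowDoseThreshold = 0.10) {
  stopifnot(dosePercent > 0, dtaMM > 0, lowDoseThreshold > 0)
  structure(list(dosePercent = dosePercent, dtaMM = dtaMM,
                 lowDoseThreshold = lowDoseThreshold),
            class = "GammaCriteria")
}

#' 3D gamma-index pass rate
#'
#' For every reference voxel whose dose exceeds the low-dose threshold
#' (fraction of the reference maximum), the gamma index is the minimum over
#' evaluated-dose sample points of
#' `sqrt((dose difference / deltaD)^2 + (distance / dta)^2)`,
#' with global normalization `deltaD = dosePercent% of max(reference)`. The
#' evaluated dose is sampled by trilinear interpolation on a sub-voxel
#' lattice of step `dta/10` within a search sphere of radius `2 * dta`
#' (offsets sorted by distance with early exit). A voxel passes when
#' gamma <= 1; the pass rate is `100 * passed / evaluated`.
#'
#' @param reference,evaluated DOSE volumes on one grid (resample first
#'   otherwise).
#' @param criteria a [gammaCriteria()].
#' @param searchRadiusFactor search radius as a multiple of dta.
#' @param stepFraction sample step as a fraction of dta.
#' @return Pass rate in percent, with attributes `evaluated` and `passed`.
#' @export
gammaPassRate <- function(reference, evaluated, criteria = gammaCriteria(),
                          searchRadiusFactor = 2, stepFraction = 0.1) {
  stopifnot(is(reference, "Volume"), is(evaluated, "Volume"),
            inherits(criteria, "GammaCriteria"))
  if (!identical(dim(reference@values), dim(evaluated@values)))
    stop("grid mismatch: resample the evaluated dose first")
  maxRef <- max(reference@values)
  if (maxRef <= 0) stop("all-zero reference dose")
  if (!any(reference@values > criteria$lowDoseThreshold * maxRef))
    stop("empty ROI after low-dose thresholding")
  deltaD <- criteria$dosePercent / 100 * maxRef
  r <- cpp_gamma_pass(reference@values, evaluated@values,
                      reference@spacing, deltaD, criteria$dtaMM,
                      criteria$lowDoseThreshold,
                      searchRadiusFactor * criteria$dtaMM,
                      stepFraction * criteria$dtaMM)
  structure(100 * r$passed / r$evaluated,
            evaluated = r$evaluated, passed = r$passed)
}
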