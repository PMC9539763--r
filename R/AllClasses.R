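#' @useDynLib synthCT, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

VOLUME_MODALITIES <- c("MR", "CT", "SCT", "DOSE", "MASK")

#' Volume: a 3D scalar grid with physical geometry
#'
#' The universal data currency of the pipeline: a 3D array of scalar voxel
#' values (Hounsfield units for CT/SCT, arbitrary units for MR, Gy for DOSE,
#' 0/1 for MASK) together with per-axis voxel spacing in mm, the physical
#' position of the corner of voxel (1,1,1) in mm, and a modality tag.
#'
#' Grid axis convention (fixed, used everywhere): axis 1 runs left-right
#' (sagittal slicing), axis 2 anterior-posterior (coronal slicing), axis 3
#' superior-inferior (axial slicing). Physical-space mapping is anchored at
#' the corner of the first voxel with half-open voxel extents, so the centre
#' of 1-based voxel i lies at `origin + (i - 0.5) * spacing`.
#'
#' @slot values 3D numeric array of voxel values.
#' @slot spacing numeric(3), per-axis voxel size in mm; all > 0.
#' @slot origin numeric(3), physical position (mm) of the corner of the first
#'   voxel.
#' @slot modality one of `"MR"`, `"CT"`, `"SCT"`, `"DOSE"`, `"MASK"`.
#' @export
setClass("Volume", representation(
  values = "array",
  spacing = "numeric",
  origin = "numeric",
  modality = "character"
))

setValidity("Volume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers (mm)")
  if (length(object@modality) != 1L ||
      !(object@modality %in% VOLUME_MODALITIES))
    msg <- c(msg, paste("modality must be one of",
                        paste(VOLUME_MODALITIES, collapse = ", ")))
  if (length(msg) == 0L && object@modality == "MASK") {
    v <- object@values
    if (any(v != 0 & v != 1))
      msg <- c(msg, "MASK values must be exactly 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Volume
#'
#' @param values 3D numeric array.
#' @param spacing per-axis voxel size in mm (length 3, recycled if length 1).
#' @param origin physical corner of the first voxel in mm (length 3).
#' @param modality `"MR"`, `"CT"`, `"SCT"`, `"DOSE"` or `"MASK"`.
#' @return A [Volume-class] object.
#' @examples
#' v <- Volume(array(0, c(8, 8, 8)), spacing = c(1.5, 1.5, 1), modality = "CT")
#' dim(v)
#' @export
Volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   modality = "CT") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  values <- array(as.double(values), dim(values))  # strip foreign classes
  new("Volume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' PairedCase: one co-registered MR/CT case with masks and optional dose
#'
#' The unit of training and evaluation: MR and CT volumes on one grid, a
#' binary body mask (outside which CT = -1000 HU and MR = 0 by convention),
#' named structure masks (PTV, rectum, bladder, urethra), an optional dose
#' grid, and — for phantom cases — the per-voxel ground-truth tissue class.
#'
#' @slot mr MR [Volume-class].
#' @slot ct CT [Volume-class].
#' @slot bodyMask MASK [Volume-class]; 1 inside the body contour.
#' @slot structures named list of MASK volumes, each a subset of the body.
#' @slot dose optional DOSE [Volume-class] (or NULL).
#' @slot truthLabels integer 3D array of tissue-class codes (or 0-length
#'   array when unknown, e.g. patient data).
#' @export
setClass("PairedCase", representation(
  mr = "Volume",
  ct = "Volume",
  bodyMask = "Volume",
  structures = "list",
  dose = "ANY",
  truthLabels = "array"
))

setValidity("PairedCase", function(object) {
  msg <- character()
  d <- dim(object@ct@values)
  sameGrid <- function(v) identical(dim(v@values), d) &&
    isTRUE(all.equal(v@spacing, object@ct@spacing)) &&
    isTRUE(all.equal(v@origin, object@ct@origin))
  if (!sameGrid(object@mr)) msg <- c(msg, "mr and ct must share one grid")
  if (!sameGrid(object@bodyMask))
    msg <- c(msg, "bodyMask must share the ct grid")
  if (object@bodyMask@modality != "MASK")
    msg <- c(msg, "bodyMask must have modality MASK")
  for (nm in names(object@structures)) {
    s <- object@structures[[nm]]
    if (!is(s, "Volume") || s@modality != "MASK" || !sameGrid(s)) {
      msg <- c(msg, sprintf("structure '%s' must be a MASK on the ct grid", nm))
    } else if (any(s@values > object@bodyMask@values)) {
      msg <- c(msg, sprintf("structure '%s' must be a subset of bodyMask", nm))
    }
  }
  if (!is.null(object@dose)) {
    if (!is(object@dose, "Volume") || object@dose@modality != "DOSE" ||
        !sameGrid(object@dose))
      msg <- c(msg, "dose must be a DOSE Volume on the ct grid")
  }
  out <- object@bodyMask@values == 0
  if (any(object@ct@values[out] != -1000))
    msg <- c(msg, "ct must equal -1000 outside the body mask")
  if (any(object@mr@values[out] != 0))
    msg <- c(msg, "mr must equal 0 outside the body mask")
  if (length(msg)) msg else TRUE
})

#' Construct a PairedCase
#'
#' @param mr,ct,bodyMask volumes on one grid; see [PairedCase-class].
#' @param structures named list of MASK volumes.
#' @param dose optional DOSE volume.
#' @param truthLabels optional integer array of tissue classes.
#' @return A [PairedCase-class] object.
#' @export
PairedCase <- function(mr, ct, bodyMask, structures = list(), dose = NULL,
                       truthLabels = array(integer(0), c(0, 0, 0))) {
  new("PairedCase", mr = mr, ct = ct, bodyMask = bodyMask,
      structures = structures, dose = dose, truthLabels = truthLabels)
}

#' SyntheticCTSet: the three single-orientation predictions and their fusion
#'
#' Holds the synthetic CT volumes predicted slice-by-slice along the axial,
#' sagittal and coronal axes, plus their voxelwise mean, all in HU on the
#' input MR grid.
#'
#' @slot sctAx,sctSag,sctCor single-orientation SCT volumes.
#' @slot sctAve voxelwise mean of the three.
#' @export
setClass("SyntheticCTSet", representation(
  sctAx = "Volume", sctSag = "Volume", sctCor = "Volume", sctAve = "Volume"
))

setValidity("SyntheticCTSet", function(object) {
  d <- dim(object@sctAve@values)
  for (s in c("sctAx", "sctSag", "sctCor"))
    if (!identical(dim(slot(object, s)@values), d))
      return("all four volumes must share one grid")
  ave <- (object@sctAx@values + object@sctSag@values + object@sctCor@values) / 3
  if (max(abs(ave - object@sctAve@values)) > 1e-6)
    return("sctAve must be the voxelwise mean of the three orientations")
  TRUE
})

#' DVHCurve: cumulative dose-volume histogram of one structure
#'
#' Exact cumulative curve built from the sorted in-structure voxel doses (no
#' binning): `cumulativeFraction[i]` is the fraction of the structure volume
#' receiving at least `doseAxis[i]` Gy. The curve starts at 1 (dose 0) and
#' ends at 0 just above the maximum voxel dose.
#'
#' @slot doses sorted in-structure voxel doses (Gy), kept for exact Dx%
#'   evaluation.
#' @slot doseAxis dose grid (Gy) of the cumulative curve.
#' @slot cumulativeFraction fraction of volume receiving >= each axis dose.
#' @slot structureName character label.
#' @slot voxelCount number of in-structure voxels.
#' @export
setClass("DVHCurve", representation(
  doses = "numeric",
  doseAxis = "numeric",
  cumulativeFraction = "numeric",
  structureName = "character",
  voxelCount = "integer"
))

setValidity("DVHCurve", function(object) {
  f <- object@cumulativeFraction
  if (length(f) != length(object@doseAxis))
    return("doseAxis and cumulativeFraction lengths differ")
  if (any(diff(f) > 1e-12)) return("cumulativeFraction must be non-increasing")
  if (abs(f[1] - 1) > 1e-12 || abs(f[length(f)]) > 1e-12)
    return("cumulativeFraction must start at 1 and end at 0")
  if (is.unsorted(object@doses)) return("doses must be sorted ascending")
  TRUE
})
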