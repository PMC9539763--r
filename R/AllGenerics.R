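#' Accessors for Volume geometry and values
#'
#' `voxelValues` returns the raw 3D array, `voxelSpacing` the per-axis voxel
#' size in mm, `volumeOrigin` the physical corner of the first voxel in mm,
#' and `modality` the modality tag.
#'
#' @param x a [Volume-class].
#' @param value replacement value.
#' @return The corresponding slot (or the modified object for setters).
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelValues<-", function(x, value) standardGeneric("voxelValues<-"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname volume-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname volume-accessors
#' @export
setGeneric("modality<-", function(x, value) standardGeneric("modality<-"))

#' @rdname volume-accessors
#' @export
setMethod("voxelValues", "Volume", function(x) x@values)

#' @rdname volume-accessors
#' @export
setMethod("voxelValues<-", "Volume", function(x, value) {
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "Volume", function(x) x@spacing)

#' @rdname volume-accessors
#' @export
setMethod("volumeOrigin", "Volume", function(x) x@origin)

#' @rdname volume-accessors
#' @export
setMethod("modality", "Volume", function(x) x@modality)

#' @rdname volume-accessors
#' @export
setMethod("modality<-", "Volume", function(x, value) {
  x@modality <- value
  validObject(x)
  x
})

#' @describeIn Volume-class grid dimensions.
#' @param x a Volume.
#' @export
setMethod("dim", "Volume", function(x) dim(x@values))

setMethod("show", "Volume", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume [%s] %d x %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm, value range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "PairedCase", function(object) {
  d <- dim(object@ct@values)
  cat(sprintf("PairedCase %d x %d x %d", d[1], d[2], d[3]))
  cat(sprintf(", body voxels %d", as.integer(sum(object@bodyMask@values))))
  if (length(object@structures))
    cat(", structures: ", paste(names(object@structures), collapse = ", "),
        sep = "")
  cat(if (is.null(object@dose)) ", no dose\n" else ", with dose\n")
})

setMethod("show", "SyntheticCTSet", function(object) {
  d <- dim(object@sctAve@values)
  cat(sprintf("SyntheticCTSet %d x %d x %d (sctAx, sctSag, sctCor, sctAve)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  sctAve HU range [%.1f, %.1f]\n",
              min(object@sctAve@values), max(object@sctAve@values)))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf("DVHCurve '%s': %d voxels, dose range [%.3g, %.3g] Gy\n",
              object@structureName, object@voxelCount,
              min(object@doses), max(object@doses)))
})

#' Orientation axes of the fixed grid convention
#'
#' Maps the three anatomical slicing orientations onto grid axes: sagittal
#' planes are extracted along axis 1 (left-right), coronal along axis 2
#' (anterior-posterior) and axial along axis 3 (superior-inferior).
#'
#' @param label `"axial"`, `"sagittal"` or `"coronal"`.
#' @return A list with `label` and `sliceAxis` (grid axis index 1-3).
#' @examples
#' orientationAxis("axial")$sliceAxis  # 3
#' @export
orientationAxis <- function(label = c("axial", "sagittal", "coronal")) {
  label <- match.arg(label)
  axis <- c(axial = 3L, sagittal = 1L, coronal = 2L)[[label]]
  list(label = label, sliceAxis = axis)
}

ORIENTATIONS <- c("axial", "sagittal", "coronal")
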