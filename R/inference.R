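#' Predict a synthetic CT volume along one orientation
#'
#' Translates every 2D slice perpendicular to the orientation's grid axis
#' independently through the generator, restacks, and converts the bounded
#' [-1, 1] output back to HU with [denormalizeCT()].
#'
#' @param gen trained generator ([buildGenerator()] object), or any plain
#'   function mapping a normalized MR plane to a CT plane in [-1, 1] (e.g.
#'   an oracle translator in tests).
#' @param mr normalized MR [Volume-class] in [-1, 1].
#' @param orientation `"axial"`, `"sagittal"` or `"coronal"`.
#' @return An SCT [Volume-class] in HU on the MR grid.
#' @export
predictVolume <- function(gen, mr, orientation = c("axial", "sagittal",
                                                   "coronal")) {
  stopifnot(is(mr, "Volume"))
  orientation <- match.arg(orientation)
  translate <- if (is.function(gen)) gen else
    function(p) generatorForward(gen, p)$y
  a <- mr@values
  ax <- orientationAxis(orientation)$sliceAxis
  out <- array(0, dim(a))
  for (i in seq_len(dim(a)[ax])) {
    plane <- extractPlane(a, orientation, i)
    pred <- translate(plane)
    out <- insertPlane(out, orientation, i, pred)
  }
  Volume(denormalizeCT(out), spacing = mr@spacing, origin = mr@origin,
         modality = "SCT")
}

#' Fuse three single-orientation synthetic CTs
#'
#' Voxelwise arithmetic mean of the axial, sagittal and coronal
#' predictions; the fusion step that suppresses across-slice
#' discontinuities of any single 2D-planar direction.
#'
#' @param ax,sag,cor SCT volumes on one grid.
#' @return The fused SCT [Volume-class].
#' @export
fuseVolumes <- function(ax, sag, cor) {
  for (v in list(sag, cor))
    if (!identical(dim(v@values), dim(ax@values)) ||
        !isTRUE(all.equal(v@spacing, ax@spacing)))
      stop("grid mismatch between orientation volumes")
  Volume((ax@values + sag@values + cor@values) / 3, spacing = ax@spacing,
         origin = ax@origin, modality = "SCT")
}

#' Synthesize CT from raw MR: the full inference chain
#'
#' Bias-corrects the MR inside the body, masks the exterior, applies the
#' z-score normalization, predicts a synthetic CT along each of the three
#' orientations, fuses them by voxelwise averaging, and forces all
#' exterior voxels of every output to -1000 HU.
#'
#' @param gen trained generator.
#' @param mrRaw raw MR [Volume-class].
#' @param body MASK [Volume-class] on the same grid.
#' @param biasCorrect run the bias-field correction first (default TRUE).
#' @return A [SyntheticCTSet-class].
#' @export
synthesizeCT <- function(gen, mrRaw, body, biasCorrect = TRUE) {
  stopifnot(is(mrRaw, "Volume"), is(body, "Volume"))
  mr <- mrRaw
  if (biasCorrect) mr <- correctBiasField(mr, body)$volume
  mr <- maskExterior(mr, body)
  mrN <- normalizeMR(mr)$volume
  clampExt <- function(v) {
    out <- v@values
    out[body@values == 0] <- -1000
    Volume(out, spacing = v@spacing, origin = v@origin, modality = "SCT")
  }
  ax <- clampExt(predictVolume(gen, mrN, "axial"))
  sag <- clampExt(predictVolume(gen, mrN, "sagittal"))
  cor <- clampExt(predictVolume(gen, mrN, "coronal"))
  new("SyntheticCTSet", sctAx = ax, sctSag = sag, sctCor = cor,
      sctAve = fuseVolumes(ax, sag, cor))
}

#' Across-slice discontinuity statistic
#'
#' Mean absolute difference between adjacent slices along one axis;
#' used to quantify the slice-stacking artifacts that multi-planar fusion
#' suppresses.
#'
#' @param v a [Volume-class].
#' @param axis grid axis (1-3).
#' @return Mean |adjacent-slice difference| (same units as the volume).
#' @export
sliceDiscontinuity <- function(v, axis = 3L) {
  a <- v@values
  d <- dim(a)
  n <- d[axis]
  idxA <- idxB <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idxA[[axis]] <- seq_len(n - 1L)
  idxB[[axis]] <- 2:n
  mean(abs(a[idxA[[1]], idxA[[2]], idxA[[3]]] -
             a[idxB[[1]], idxB[[2]], idxB[[3]]]))
}
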