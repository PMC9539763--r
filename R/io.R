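#' Read a 3D volume from NIfTI or NRRD
#'
#' Reads a scalar 3D image with its voxel spacing and origin. The format is
#' inferred from the file extension (`.nii`, `.nii.gz` or `.nrrd`) unless
#' given explicitly. Spacing is taken from the header; the origin is the
#' translation column of the stored transform (NIfTI) or the `space origin`
#' field (NRRD). Axis order is the fixed grid convention of [Volume-class];
#' no reorientation beyond that is attempted.
#'
#' @param path file to read.
#' @param format `"nifti"`, `"nrrd"`, or `"auto"` (default, by extension).
#' @param modality modality tag for the returned volume.
#' @return A [Volume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(Volume(array(1:27, c(3, 3, 3)), spacing = c(1.5, 1.5, 1)), f)
#' readVolume(f)
#' @seealso [writeVolume()], [resampleVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "nrrd"),
                       modality = "CT") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- formatFromPath(path)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L]
    if (length(dim(a)) != 3L)
      stop("expected a 3D scalar image, got ", length(dim(a)), "D")
    sp <- RNifti::pixdim(img)[1:3]
    xf <- RNifti::xform(img)
    org <- as.numeric(xf[1:3, 4])
    Volume(a, spacing = sp, origin = org, modality = modality)
  } else {
    readNrrd(path, modality = modality)
  }
}

#' Write a 3D volume to NIfTI or NRRD
#'
#' Values are stored as 64-bit floats so the round trip through
#' [readVolume()] is bit-exact. Spacing and origin are written into the
#' header (NIfTI qform/sform, NRRD `space directions`/`space origin`).
#'
#' @param v a [Volume-class] with finite values.
#' @param path destination file (`.nii`, `.nii.gz` or `.nrrd`).
#' @param format `"nifti"`, `"nrrd"`, or `"auto"` (by extension).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(v, path, format = c("auto", "nifti", "nrrd")) {
  stopifnot(is(v, "Volume"))
  format <- match.arg(format)
  if (!all(is.finite(v@values))) stop("volume contains non-finite values")
  if (format == "auto") format <- formatFromPath(path)
  if (format == "nifti") {
    img <- RNifti::asNifti(v@values)
    RNifti::pixdim(img) <- v@spacing
    m <- diag(4)
    diag(m)[1:3] <- v@spacing
    m[1:3, 4] <- v@origin
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path)
  } else {
    writeNrrd(v, path)
  }
  invisible(path)
}

formatFromPath <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", low)) "nifti"
  else stop("cannot infer format from extension: ", path)
}

# Minimal NRRD: attached header, raw little-endian double, 3D only.
writeNrrd <- function(v, path) {
  d <- dim(v@values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# synthCT volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            v@spacing[1], v@spacing[2], v@spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            v@origin[1], v@origin[2], v@origin[3]),
    sprintf("synthct-modality:=%s", v@modality),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(v@values), con, size = 8, endian = "little")
}

readNrrd <- function(path, modality = "CT") {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("truncated NRRD header: ", path)
    if (ln == "") break
    lines <- c(lines, ln)
  }
  if (!grepl("^NRRD", lines[1])) stop("not an NRRD file: ", path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(hit)) NA_character_ else sub(paste0("^", key, ": "), "", hit[1])
  }
  if (!identical(field("dimension"), "3"))
    stop("expected a 3D scalar image in ", path)
  type <- field("type")
  if (!type %in% c("double", "float64")) stop("unsupported NRRD type: ", type)
  if (!identical(field("encoding"), "raw"))
    stop("unsupported NRRD encoding: ", field("encoding"))
  d <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
  nums <- function(s) as.numeric(regmatches(s, gregexpr(
    "[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?", s))[[1]])
  dirs <- nums(field("space directions"))
  sp <- c(dirs[1], dirs[5], dirs[9])
  orgF <- field("space origin")
  org <- if (is.na(orgF)) c(0, 0, 0) else nums(orgF)
  modLine <- grep("^synthct-modality:=", lines, value = TRUE)
  if (length(modLine)) modality <- sub("^synthct-modality:=", "", modLine[1])
  n <- prod(d)
  raw <- readBin(con, "double", n = n, size = 8, endian = "little")
  if (length(raw) != n) stop("truncated NRRD data: ", path)
  Volume(array(raw, d), spacing = sp, origin = org, modality = modality)
}

#' Resample a volume onto a new grid
#'
#' Maps each target voxel centre to physical space (corner-anchored,
#' half-open convention), converts to a continuous source index and
#' interpolates. Linear (trilinear) interpolation is the default for
#' MR/CT/dose; `"nearest"` keeps masks binary. Target voxel centres falling
#' outside the source grid take the nearest edge value (clamped).
#'
#' @param v a [Volume-class].
#' @param targetShape integer(3) target grid dimensions.
#' @param targetSpacing numeric(3) target spacing in mm (default: keep the
#'   physical extent of `v`, i.e. `dim(v) * spacing / targetShape`).
#' @param method `"linear"` or `"nearest"`; masks default to `"nearest"`.
#' @param targetOrigin origin of the target grid (default: same as `v`).
#' @return A [Volume-class] on the target grid.
#' @export
resampleVolume <- function(v, targetShape, targetSpacing = NULL,
                           method = NULL, targetOrigin = NULL) {
  stopifnot(is(v, "Volume"))
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 3L || any(targetShape <= 0L))
    stop("targetShape must be 3 positive integers")
  if (is.null(targetSpacing))
    targetSpacing <- dim(v@values) * v@spacing / targetShape
  if (any(targetSpacing <= 0)) stop("targetSpacing must be positive")
  if (is.null(method)) method <- if (v@modality == "MASK") "nearest" else "linear"
  method <- match.arg(method, c("linear", "nearest"))
  if (is.null(targetOrigin)) targetOrigin <- v@origin

  # continuous source index (0-based voxel-centre coordinates) per target axis
  srcIdx <- lapply(1:3, function(ax) {
    phys <- targetOrigin[ax] + (seq_len(targetShape[ax]) - 0.5) * targetSpacing[ax]
    (phys - v@origin[ax]) / v@spacing[ax] - 0.5
  })
  out <- interp3(v@values, srcIdx[[1]], srcIdx[[2]], srcIdx[[3]],
                 nearest = (method == "nearest"))
  Volume(out, spacing = targetSpacing, origin = targetOrigin,
         modality = v@modality)
}

# Separable grid interpolation: xi, yi, zi are 0-based continuous indices per
# axis; returns the full tensor-product grid. Clamped at edges.
interp3 <- function(a, xi, yi, zi, nearest = FALSE) {
  d <- dim(a)
  if (nearest) {
    ix <- pmin(pmax(round(xi), 0), d[1] - 1) + 1
    iy <- pmin(pmax(round(yi), 0), d[2] - 1) + 1
    iz <- pmin(pmax(round(zi), 0), d[3] - 1) + 1
    return(a[ix, iy, iz, drop = FALSE])
  }
  lowWeight <- function(ci, n) {
    lo <- floor(ci)
    w <- 1 - (ci - lo)
    lo <- pmin(pmax(lo, 0), n - 1)
    hi <- pmin(lo + 1, n - 1)
    w[ci <= 0] <- 1
    w[ci >= n - 1] <- 1
    list(lo = lo + 1, hi = hi + 1, w = w)
  }
  X <- lowWeight(xi, d[1]); Y <- lowWeight(yi, d[2]); Z <- lowWeight(zi, d[3])
  wx <- X$w; wy <- Y$w; wz <- Z$w
  g <- function(ix, iy, iz) a[ix, iy, iz, drop = FALSE]
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  WX <- array(wx, c(nx, ny, nz))
  WY <- array(rep(wy, each = nx), c(nx, ny, nz))
  WZ <- array(rep(wz, each = nx * ny), c(nx, ny, nz))
  g(X$lo, Y$lo, Z$lo) * WX * WY * WZ +
    g(X$hi, Y$lo, Z$lo) * (1 - WX) * WY * WZ +
    g(X$lo, Y$hi, Z$lo) * WX * (1 - WY) * WZ +
    g(X$hi, Y$hi, Z$lo) * (1 - WX) * (1 - WY) * WZ +
    g(X$lo, Y$lo, Z$hi) * WX * WY * (1 - WZ) +
    g(X$hi, Y$lo, Z$hi) * (1 - WX) * WY * (1 - WZ) +
    g(X$lo, Y$hi, Z$hi) * WX * (1 - WY) * (1 - WZ) +
    g(X$hi, Y$hi, Z$hi) * (1 - WX) * (1 - WY) * (1 - WZ)
}

#' Extract / insert a 2D plane along an orientation axis
#'
#' `extractPlane` pulls the i-th slice perpendicular to the orientation's
#' grid axis; `insertPlane` writes one back. Used by the multi-planar
#' sampler and by slice-wise volume prediction.
#'
#' @param a 3D array.
#' @param orientation `"axial"`, `"sagittal"` or `"coronal"`.
#' @param i slice index (1-based).
#' @param plane 2D matrix to insert.
#' @return `extractPlane`: a 2D matrix; `insertPlane`: the modified array.
#' @keywords internal
extractPlane <- function(a, orientation, i) {
  switch(orientation,
         sagittal = a[i, , ],
         coronal  = a[, i, ],
         axial    = a[, , i])
}

insertPlane <- function(a, orientation, i, plane) {
  switch(orientation,
         sagittal = { a[i, , ] <- plane; a },
         coronal  = { a[, i, ] <- plane; a },
         axial    = { a[, , i] <- plane; a })
}
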