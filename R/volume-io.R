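## Reading and writing volumes and masks.
##
## NIfTI-1 (.nii, .nii.gz) is handled through RNifti. MetaImage (.mha and
## .mhd + raw) is handled by a small reader/writer below (uncompressed
## only), since no installed R package speaks the format. Intensities are
## stored losslessly (float64 for volumes, integer for masks); spacing is
## never silently defaulted: a missing ElementSpacing is an error.

.ioFormat <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.mha$", lp)) "mha"
  else if (grepl("\\.mhd$", lp)) "mhd"
  else stop(sprintf(
    "unknown volume format for '%s' (expected .nii, .nii.gz, .mha or .mhd)",
    basename(path)))
}

#' Read a CT volume from NIfTI or MetaImage
#'
#' @param path path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @return A [VoxelVolume-class] with spacing and origin taken from the
#'   file header; intensities are returned unmodified.
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  fmt <- .ioFormat(path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(sp)) || any(sp <= 0))
      stop(sprintf("NIfTI file '%s' has no valid voxel spacing", path))
    xf <- try(RNifti::xform(img), silent = TRUE)
    org <- if (!inherits(xf, "try-error")) xf[1:3, 4] else c(0, 0, 0)
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    VoxelVolume(arr, spacing = sp, origin = org)
  } else {
    mi <- .readMetaImage(path)
    VoxelVolume(mi$data, spacing = mi$spacing, origin = mi$origin)
  }
}

#' Write a CT volume to NIfTI or MetaImage
#'
#' The format follows the file extension. Round trips are lossless:
#' volumes are stored as float64, spacing and origin go into the header
#' (NIfTI qform / MetaImage ElementSpacing + Offset).
#'
#' @param volume a [VoxelVolume-class].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  fmt <- .ioFormat(path)
  if (fmt == "nifti") {
    .writeNifti(voxelData(volume), voxelSpacing(volume),
                voxelOrigin(volume), path, datatype = "double")
  } else {
    .writeMetaImage(voxelData(volume), voxelSpacing(volume),
                    voxelOrigin(volume), path, type = "MET_DOUBLE")
  }
  invisible(path)
}

#' Write a segmentation mask
#'
#' Masks and label maps are written as unsigned 8- or 16-bit integers
#' (depending on the largest label), losslessly.
#'
#' @param mask a [BinaryMask-class].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @return The path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  bits <- voxelData(mask)
  if (is.logical(bits)) bits <- array(as.integer(bits), dim = dim(bits))
  mx <- max(bits)
  if (mx > 65535L) stop("label values exceed 16-bit range")
  fmt <- .ioFormat(path)
  if (fmt == "nifti") {
    dt <- if (mx > 255L) "uint16" else "uint8"
    .writeNifti(bits, voxelSpacing(mask), voxelOrigin(mask), path,
                datatype = dt)
  } else {
    tp <- if (mx > 255L) "MET_USHORT" else "MET_UCHAR"
    .writeMetaImage(bits, voxelSpacing(mask), voxelOrigin(mask), path,
                    type = tp)
  }
  invisible(path)
}

#' Read a segmentation mask
#'
#' @param path path to a mask file written by [writeMask()] (or any
#'   integer-valued volume).
#' @param template optional parent [VoxelVolume-class]; the mask grid must
#'   match it exactly (shape and spacing), otherwise an error is raised.
#' @return A [BinaryMask-class] with integer labels.
#' @export
readMask <- function(path, template = NULL) {
  v <- readVolume(path)
  bits <- voxelData(v)
  if (max(abs(bits - round(bits))) > 1e-6)
    stop("mask file contains non-integer values")
  bits <- array(as.integer(round(bits)), dim = dim(bits))
  if (!is.null(template)) {
    if (!identical(dim(bits), gridDim(template)))
      stop("mask shape does not match its parent volume's grid")
    if (max(abs(voxelSpacing(v) - voxelSpacing(template))) > 1e-6)
      stop("mask spacing does not match its parent volume's grid")
  }
  BinaryMask(bits, spacing = voxelSpacing(v), origin = voxelOrigin(v))
}

.writeNifti <- function(arr, spacing, origin, path, datatype) {
  img <- RNifti::asNifti(arr)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
}

## ---- MetaImage (.mha local, .mhd + external raw), uncompressed ----

.metTypes <- list(
  MET_UCHAR = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT = list(what = "integer", size = 2L, signed = TRUE),
  MET_INT = list(what = "integer", size = 4L, signed = TRUE),
  MET_UINT = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

.writeMetaImage <- function(arr, spacing, origin, path, type) {
  d <- dim(arr)
  local <- grepl("\\.mha$", tolower(path))
  datafile <- if (local) "LOCAL" else paste0(
    sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("TransformMatrix = %s",
            paste(c(1, 0, 0, 0, 1, 0, 0, 0, 1), collapse = " ")),
    sprintf("Offset = %.10g %.10g %.10g", origin[1], origin[2], origin[3]),
    sprintf("ElementSpacing = %.10g %.10g %.10g",
            spacing[1], spacing[2], spacing[3]),
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementType = %s", type),
    sprintf("ElementDataFile = %s", datafile))
  tp <- .metTypes[[type]]
  vals <- as.vector(arr)
  if (tp$what == "integer") vals <- as.integer(round(vals))
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(vals, con, size = tp$size, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(vals, rcon, size = tp$size, endian = "little")
  }
  invisible(path)
}

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("MetaImage '%s': header ended before ElementDataFile",
                   path))
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (is.null(hdr$DimSize)) stop("MetaImage header lacks DimSize")
  if (is.null(hdr$ElementSpacing))
    stop("MetaImage header lacks ElementSpacing; refusing to default it")
  if (!is.null(hdr$CompressedData) &&
      tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage is not supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(d))
  tp <- .metTypes[[hdr$ElementType]]
  if (is.null(tp))
    stop(sprintf("unsupported MetaImage ElementType '%s'", hdr$ElementType))
  endian <- if (!is.null(hdr$BinaryDataByteOrderMSB) &&
                tolower(hdr$BinaryDataByteOrderMSB) == "true")
    "big" else "little"
  nvox <- prod(d)
  if (hdr$ElementDataFile == "LOCAL") {
    vals <- readBin(con, what = tp$what, n = nvox, size = tp$size,
                    signed = tp$signed, endian = endian)
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath))
      stop(sprintf("raw data file '%s' not found", rawpath))
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, what = tp$what, n = nvox, size = tp$size,
                    signed = tp$signed, endian = endian)
  }
  if (length(vals) < nvox)
    stop(sprintf("MetaImage '%s' is truncated: expected %d voxels, got %d",
                 path, nvox, length(vals)))
  list(data = array(as.numeric(vals), dim = d), spacing = spacing,
       origin = origin)
}

#' Write a phantom ground-truth record as JSON
#'
#' Sidecar for a generated phantom volume: the analytic truth in a plain
#' JSON document.
#'
#' @param truth a [PhantomTruth-class].
#' @param path output `.json` path.
#' @return The path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "PhantomTruth"))
  jsonlite::write_json(list(
    true_cavity_volume_ml = truth@volumeMl,
    true_axis_unit_vector = truth@axis,
    true_tilt_deg = truth@tiltDeg,
    fragment_centers_mm = truth@fragmentCentersMm,
    fragment_radii_mm = truth@fragmentRadiiMm,
    true_max_sphere_radius_mm = truth@sphereRadiusMm,
    true_max_sphere_depth_mm = truth@sphereDepthMm,
    entry_z_mm = truth@entryZMm
  ), path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
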