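#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) via RNifti and MetaImage
#' (`.mhd` + raw payload). The header's voxel spacing and origin are honoured;
#' intensities are returned unmodified. Volumes whose NIfTI transform encodes a
#' rotation (non-axis-aligned geometry) are rejected: this package works in an
#' unrotated index-times-spacing coordinate frame.
#'
#' @param path File path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @param slice_axis Axis perpendicular to the acquisition slices (not stored
#'   in either format; see [vb_volume]).
#' @param labels If `TRUE`, return a [vb_labels] (integer masks) instead of a
#'   plain [vb_volume].
#' @param vb_names Optional anatomical names when `labels = TRUE`.
#' @return A [vb_volume] (or [vb_labels]).
#' @export
read_volume <- function(path, slice_axis = 1L, labels = FALSE, vb_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("expected a 3D image, got ", length(d), " dimensions in ", path)
    spacing <- abs(RNifti::pixdim(img))[1:3]
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- c(0, 0, 0)
    if (!inherits(xf, "try-error") && is.matrix(xf)) {
      rot <- xf[1:3, 1:3]
      off <- abs(rot - diag(diag(rot)))
      if (any(off > 1e-4 * max(abs(diag(rot)), 1)))
        stop("volume has a rotated/oblique orientation, which is unsupported: ", path)
      if (any(diag(rot) < 0))
        stop("volume has a flipped axis orientation, which is unsupported: ", path)
      origin <- xf[1:3, 4]
    }
    arr <- array(as.numeric(img), dim = d)
  } else if (grepl("\\.mhd$", lower)) {
    mi <- read_mhd(path)
    arr <- mi$data
    spacing <- mi$spacing
    origin <- mi$origin
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .mhd): ", path)
  }
  if (labels) vb_labels(arr, spacing, origin, slice_axis, vb_names)
  else vb_volume(arr, spacing, origin, slice_axis)
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The format is chosen from the file extension. Label volumes are written
#' with an integer element type, intensity volumes as double precision, so a
#' write/read round trip is bit-exact.
#'
#' @param vol A [vb_volume] or [vb_labels].
#' @param path Output path ending in `.nii`, `.nii.gz` or `.mhd` (a sibling
#'   `.raw` file is written for MetaImage).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vb_volume"))
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- vol$spacing
    m <- diag(c(vol$spacing, 1))
    m[1:3, 4] <- vol$origin
    RNifti::sform(img) <- structure(m, code = 2L)
    RNifti::qform(img) <- structure(m, code = 2L)
    RNifti::writeNifti(img, path,
                       datatype = if (inherits(vol, "vb_labels")) "int32" else "double")
  } else if (grepl("\\.mhd$", lower)) {
    write_mhd(vol, path, integer_type = inherits(vol, "vb_labels"))
  } else {
    stop("unsupported volume format (expected .nii, .nii.gz or .mhd): ", path)
  }
  invisible(path)
}

# --- MetaImage (.mhd + .raw): plain-text header, little-endian raw payload ---

mhd_types <- list(MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
                  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
                  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
                  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
                  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
                  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
                  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
                  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    as.numeric(strsplit(kv[[key]], "\\s+")[[1]])
  }
  ndims <- num("NDims")
  if (is.null(ndims) || ndims != 3)
    stop("expected a 3D MetaImage, got NDims = ",
         if (is.null(ndims)) "missing" else ndims, " in ", path)
  dims <- as.integer(num("DimSize"))
  if (length(dims) != 3L) stop("malformed DimSize in ", path)
  spacing <- num("ElementSpacing", num("ElementSize", c(1, 1, 1)))
  origin <- num("Offset", num("Position", c(0, 0, 0)))
  if (!is.null(kv$CompressedData) && toupper(kv$CompressedData) == "TRUE")
    stop("compressed MetaImage data is unsupported: ", path)
  type <- kv$ElementType
  if (is.null(type) || is.null(mhd_types[[type]]))
    stop("unsupported MetaImage ElementType: ", type %||% "missing")
  tinfo <- mhd_types[[type]]
  datafile <- kv$ElementDataFile
  if (is.null(datafile)) stop("missing ElementDataFile in ", path)
  if (identical(datafile, "LOCAL"))
    stop("inline (LOCAL) MetaImage payloads are unsupported: ", path)
  rawpath <- file.path(dirname(path), datafile)
  msb <- !is.null(kv$BinaryDataByteOrderMSB) && toupper(kv$BinaryDataByteOrderMSB) == "TRUE"
  n <- prod(dims)
  con <- file(rawpath, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = tinfo$what, n = n, size = tinfo$size,
                  signed = tinfo$signed, endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop("raw payload shorter than DimSize implies: ", rawpath)
  list(data = array(as.numeric(vals), dim = dims), spacing = spacing, origin = origin)
}

write_mhd <- function(vol, path, integer_type = FALSE) {
  type <- if (integer_type) "MET_INT" else "MET_DOUBLE"
  rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  header <- c("ObjectType = Image",
              "NDims = 3",
              "BinaryData = True",
              "BinaryDataByteOrderMSB = False",
              "CompressedData = False",
              paste("DimSize =", paste(dim(vol$data), collapse = " ")),
              paste("ElementSpacing =", paste(format(vol$spacing, digits = 17), collapse = " ")),
              paste("Offset =", paste(format(vol$origin, digits = 17), collapse = " ")),
              paste("ElementType =", type),
              paste("ElementDataFile =", rawname))
  writeLines(header, path)
  con <- file(file.path(dirname(path), rawname), "wb")
  on.exit(close(con))
  if (integer_type)
    writeBin(as.integer(vol$data), con, size = 4L, endian = "little")
  else
    writeBin(as.numeric(vol$data), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
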