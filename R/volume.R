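#' 3D scalar volume with physical geometry
#'
#' Container for a 3D image: a scalar array plus the voxel spacing (mm per
#' voxel along each array axis), the physical position of the first voxel
#' (`origin`, mm) and the index of the axis perpendicular to the acquisition
#' slices (`slice_axis`). Voxel indices are 1-based; the physical position of
#' voxel `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`. Oriented
#' (rotated/oblique) geometries are not supported.
#'
#' The slice-axis convention follows the sagittal-MR / axial-CT acquisition
#' layouts: for sagittal MR volumes slices are parallel to the YZ plane
#' (`slice_axis = 1`), for axial CT volumes slices are parallel to the XY
#' plane (`slice_axis = 3`).
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3, mm per voxel along each axis; all `> 0`.
#' @param origin Numeric length-3, physical position (mm) of voxel `(1,1,1)`.
#' @param slice_axis Integer in `1:3`, axis perpendicular to the slices.
#' @return An object of class `vb_volume`.
#' @export
vb_volume <- function(data, spacing, origin = c(0, 0, 0), slice_axis = 1L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3")
  structure(list(data = data, spacing = spacing, origin = origin,
                 slice_axis = slice_axis),
            class = "vb_volume")
}

#' Integer-labeled volume of vertebral-body masks
#'
#' A [vb_volume] whose voxel values are integer labels: 0 is background and
#' `i` marks the i-th vertebral body, ordered cranio-caudally as in
#' `vb_names`.
#'
#' @inheritParams vb_volume
#' @param vb_names Character vector of anatomical names (e.g. `"T11"..."L5"`),
#'   one per positive label. Defaults to `L1, L2, ...`.
#' @return An object of class `vb_labels` (also a `vb_volume`).
#' @export
vb_labels <- function(data, spacing, origin = c(0, 0, 0), slice_axis = 1L,
                      vb_names = NULL) {
  vol <- vb_volume(data, spacing, origin, slice_axis)
  vals <- unique(as.vector(data))
  if (any(vals %% 1 != 0) || any(vals < 0))
    stop("label values must be non-negative integers")
  m <- max(0L, as.integer(max(vals)))
  if (is.null(vb_names)) vb_names <- if (m > 0L) paste0("L", seq_len(m)) else character(0)
  if (length(vb_names) < m)
    stop("need at least ", m, " vb_names for the labels present")
  vol$vb_names <- as.character(vb_names)
  class(vol) <- c("vb_labels", "vb_volume")
  vol
}

#' @export
print.vb_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin %s mm, slice axis %d\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", "), x$slice_axis))
  invisible(x)
}

#' @export
dim.vb_volume <- function(x) dim(x$data)

#' Convert voxel indices to physical coordinates
#'
#' @param vol A [vb_volume] (or anything with `spacing` and `origin`).
#' @param idx Numeric n x 3 matrix (or length-3 vector) of 1-based voxel
#'   indices; fractional indices are allowed.
#' @return n x 3 matrix of physical positions (mm).
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- rbind3(idx)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Convert physical coordinates to (fractional) voxel indices
#'
#' @param vol A [vb_volume].
#' @param pts Numeric n x 3 matrix (or length-3 vector) of positions in mm.
#' @return n x 3 matrix of 1-based, possibly fractional, voxel indices.
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind3(pts)
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

# coerce a length-3 vector or n x 3 matrix to n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("expected a 3-vector or an n x 3 matrix")
    matrix(as.numeric(x), 1L, 3L)
  } else {
    if (ncol(x) != 3L) stop("expected an n x 3 matrix")
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

# in-plane axes = the two axes that are not the slice axis
inplane_axes <- function(vol) setdiff(1:3, vol$slice_axis)
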