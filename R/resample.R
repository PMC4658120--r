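#' Resample a volume to a target voxel spacing
#'
#' Standardizes voxel spacing before any training or testing (all images in a
#' study are resampled to a common spacing, e.g. 0.5 x 0.5 x 1.0 mm for CT).
#' The output grid preserves the physical origin and covers the same physical
#' extent to within one voxel. Intensities are interpolated trilinearly;
#' label volumes use nearest-neighbor interpolation.
#'
#' @param vol A [vb_volume] or [vb_labels].
#' @param target_spacing Length-3 positive numeric, mm per voxel.
#' @param interpolation `"linear"` or `"nearest"`; label volumes always use
#'   nearest-neighbor.
#' @return A resampled volume of the same class.
#' @export
resample_volume <- function(vol, target_spacing,
                            interpolation = c("linear", "nearest")) {
  stopifnot(inherits(vol, "vb_volume"))
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0))
    stop("`target_spacing` must be 3 positive numbers")
  interpolation <- match.arg(interpolation)
  if (inherits(vol, "vb_labels")) interpolation <- "nearest"
  if (isTRUE(all(target_spacing == vol$spacing))) return(vol)

  d <- dim(vol$data)
  out_dim <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  # sample positions of the output voxel centers, in input fractional indices
  ax_idx <- lapply(1:3, function(a) {
    pos <- vol$origin[a] + (seq_len(out_dim[a]) - 1) * target_spacing[a]
    (pos - vol$origin[a]) / vol$spacing[a] + 1
  })
  out <- interp3(vol$data, ax_idx[[1]], ax_idx[[2]], ax_idx[[3]], interpolation)
  res <- vb_volume(out, target_spacing, vol$origin, vol$slice_axis)
  if (inherits(vol, "vb_labels")) {
    res$vb_names <- vol$vb_names
    class(res) <- class(vol)
  }
  res
}

# Separable grid interpolation at the tensor grid xi x yi x zi of fractional
# 1-based indices (clamped to the volume). Returns an array
# length(xi) x length(yi) x length(zi).
interp3 <- function(arr, xi, yi, zi, interpolation) {
  d <- dim(arr)
  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(xi), 1), d[1])
    iy <- pmin(pmax(round(yi), 1), d[2])
    iz <- pmin(pmax(round(zi), 1), d[3])
    return(arr[ix, iy, iz, drop = FALSE])
  }
  clamp <- function(v, hi) pmin(pmax(v, 1), hi)
  x0 <- clamp(floor(xi), d[1]); x1 <- clamp(x0 + 1, d[1]); fx <- clamp(xi, d[1]) - x0
  y0 <- clamp(floor(yi), d[2]); y1 <- clamp(y0 + 1, d[2]); fy <- clamp(yi, d[2]) - y0
  z0 <- clamp(floor(zi), d[3]); z1 <- clamp(z0 + 1, d[3]); fz <- clamp(zi, d[3]) - z0
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  out <- array(0, c(nx, ny, nz))
  wx <- cbind(1 - fx, fx); wy <- cbind(1 - fy, fy); wz <- cbind(1 - fz, fz)
  xs <- cbind(x0, x1); ys <- cbind(y0, y1); zs <- cbind(z0, z1)
  for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
    w <- outer(outer(wx[, cx], wy[, cy]), wz[, cz])
    out <- out + w * arr[xs[, cx], ys[, cy], zs[, cz], drop = FALSE]
  }
  out
}

#' In-plane downsampling for the coarse localization step
#'
#' Reduces the two in-plane axes (those different from `slice_axis`) by an
#' integer factor while keeping the inter-slice axis untouched, emulating the
#' coarse-resolution detection pass (scale factor 1/4 in-plane by default in
#' the pipeline). Downsampling is by block averaging, which anti-aliases the
#' coarse-step features; in-plane spacing is multiplied by the factor and the
#' origin is shifted to the block centers. Trailing voxels that do not fill a
#' complete block are dropped.
#'
#' @param vol A [vb_volume].
#' @param factor Integer `>= 1`.
#' @return The downsampled [vb_volume].
#' @export
downsample_inplane <- function(vol, factor) {
  stopifnot(inherits(vol, "vb_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(vol)
  ax <- inplane_axes(vol)
  arr <- vol$data
  for (a in ax) {
    d <- dim(arr)
    nb <- d[a] %/% factor
    if (nb < 1L) stop("volume too small to downsample by ", factor, " along axis ", a)
    # move axis `a` first, average consecutive blocks of `factor`, move back
    perm <- c(a, setdiff(1:3, a))
    x <- aperm(arr, perm)
    dp <- dim(x)
    x <- x[seq_len(nb * factor), , , drop = FALSE]
    dim(x) <- c(factor, nb, dp[2], dp[3])
    x <- colMeans(x)                       # nb x dp2 x dp3
    arr <- aperm(x, order(perm))
  }
  spacing <- vol$spacing
  origin <- vol$origin
  spacing[ax] <- spacing[ax] * factor
  # new voxel center = mean of the block's voxel centers
  origin[ax] <- origin[ax] + (factor - 1) / 2 * vol$spacing[ax]
  vb_volume(arr, spacing, origin, vol$slice_axis)
}
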