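#' Data-driven ROI half-extent for one vertebral body
#'
#' The region of interest around a detected center must cover the vertebral
#' body with margin. Its half-extent is learned from the training data: the
#' per-axis maximum absolute offset of the body's mask voxels from its
#' center, over all training subjects, dilated by a safety fraction.
#'
#' @param masks List of [vb_labels] training masks.
#' @param centers_list List of matching [vb_centers] (ground truth).
#' @param vb_index Which vertebral body.
#' @param dilate Fractional dilation of the learned box (default 25%).
#' @return Length-3 numeric half-extent (mm).
#' @export
roi_half_extent <- function(masks, centers_list, vb_index, dilate = 0.25) {
  stopifnot(length(masks) == length(centers_list), length(masks) >= 1L)
  hw <- c(0, 0, 0)
  for (s in seq_along(masks)) {
    w <- which(masks[[s]]$data == vb_index)
    if (length(w) == 0L) next
    off <- abs(sweep(voxel_to_world(masks[[s]], arrayInd(w, dim(masks[[s]]$data))),
                     2, centers_list[[s]]$centers[vb_index, ]))
    hw <- pmax(hw, apply(off, 2, max))
  }
  if (all(hw == 0)) stop("label ", vb_index, " is absent from every training mask")
  hw * (1 + dilate)
}

#' Parzen-window spatial prior of one vertebral body
#'
#' Estimates the probability that a voxel at a given offset from the
#' vertebral-body center is foreground. Each training mask is aligned so its
#' ground-truth center sits at the ROI center and sampled (nearest-neighbor)
#' on the ROI grid; the aligned binary indicators are averaged and smoothed
#' with an isotropic Gaussian Parzen kernel (bandwidth in ROI voxels),
#' clamped to `[0, 1]`. A bandwidth of 0 skips the smoothing.
#'
#' @inheritParams roi_half_extent
#' @param half_extent Length-3 ROI half-extent in mm (e.g. from
#'   [roi_half_extent]).
#' @param bandwidth Parzen kernel SD, in ROI voxels (default 2).
#' @return An object of class `spatial_prior`: `data` (ROI-grid array,
#'   odd dimensions, center voxel at the body center), `half_n` (voxels per
#'   side), `spacing`, `bandwidth`.
#' @export
learn_spatial_prior <- function(masks, centers_list, vb_index, half_extent,
                                bandwidth = 2) {
  stopifnot(length(masks) == length(centers_list), length(masks) >= 1L)
  spacing <- masks[[1]]$spacing
  half_n <- pmax(1L, as.integer(ceiling(half_extent / spacing)))
  dims <- 2L * half_n + 1L
  offs <- lapply(1:3, function(a) (seq_len(dims[a]) - half_n[a] - 1L) * spacing[a])
  acc <- array(0, dims)
  used <- 0L
  for (s in seq_along(masks)) {
    if (!any(masks[[s]]$data == vb_index)) next
    ctr <- centers_list[[s]]$centers[vb_index, ]
    idx <- lapply(1:3, function(a)
      as.integer(round((ctr[a] + offs[[a]] - masks[[s]]$origin[a]) /
                         masks[[s]]$spacing[a] + 1)))
    d <- dim(masks[[s]]$data)
    ok <- lapply(1:3, function(a) idx[[a]] >= 1L & idx[[a]] <= d[a])
    cl <- lapply(1:3, function(a) pmin(pmax(idx[[a]], 1L), d[a]))
    ind <- (masks[[s]]$data[cl[[1]], cl[[2]], cl[[3]], drop = FALSE] == vb_index) &
      outer(outer(ok[[1]], ok[[2]], "&"), ok[[3]], "&")
    acc <- acc + ind
    used <- used + 1L
  }
  if (used == 0L) stop("label ", vb_index, " is absent from every training mask")
  prior <- acc / used
  if (bandwidth > 0) prior <- gaussian_smooth3(prior, bandwidth)
  prior <- pmin(pmax(prior, 0), 1)
  structure(list(data = prior, half_n = half_n, spacing = spacing,
                 bandwidth = bandwidth, vb_index = vb_index),
            class = "spatial_prior")
}

# Separable truncated-Gaussian smoothing (sigma in voxels). Kernel rows are
# renormalized at the array boundary so a constant array stays constant.
gaussian_smooth3 <- function(arr, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  smooth_axis <- function(x, axis) {
    d <- dim(x)
    K <- matrix(0, d[axis], d[axis])
    for (i in seq_len(d[axis])) {
      j <- pmax(1L, i - r):pmin(d[axis], i + r)
      K[i, j] <- w[j - i + r + 1L]
      K[i, j] <- K[i, j] / sum(K[i, j])
    }
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    res <- K %*% matrix(xp, d[axis])
    dim(res) <- dp
    aperm(res, order(perm))
  }
  for (a in 1:3) arr <- smooth_axis(arr, a)
  arr
}

# Place a spatial prior at a detected center on the image grid.
# Returns the clipped voxel box and the prior values over that box.
place_prior <- function(prior, vol, center_mm) {
  ctr_idx <- as.integer(round(world_to_voxel(vol, center_mm)))
  lo <- ctr_idx - prior$half_n
  hi <- ctr_idx + prior$half_n
  d <- dim(vol$data)
  clo <- pmax(lo, 1L)
  chi <- pmin(hi, as.integer(d))
  if (any(chi < clo)) stop("ROI around the center lies outside the volume")
  ps <- prior$data[(clo[1] - lo[1] + 1L):(chi[1] - lo[1] + 1L),
                   (clo[2] - lo[2] + 1L):(chi[2] - lo[2] + 1L),
                   (clo[3] - lo[3] + 1L):(chi[3] - lo[3] + 1L), drop = FALSE]
  list(box = list(lo = clo, hi = chi), ps = ps)
}
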