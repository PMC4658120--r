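#' Localization distance of one center
#'
#' Euclidean distance `R = sqrt(dx^2 + dy^2 + dz^2)` between a detected and a
#' ground-truth center, in mm.
#'
#' @param pred,gt Length-3 positions (mm).
#' @return Distance in mm.
#' @export
localization_error <- function(pred, gt) {
  pred <- as.numeric(pred); gt <- as.numeric(gt)
  if (any(!is.finite(pred)) || any(!is.finite(gt))) stop("non-finite center")
  sqrt(sum((pred - gt)^2))
}

#' Mean localization distance and its standard deviation
#'
#' `MLD` is the mean of the per-center distances over all images and
#' vertebrae; `SD` is the population standard deviation (divisor `N_c`, the
#' total number of centers, not `N_c - 1`).
#'
#' @param errors Numeric vector of distances (mm), pooled over images and
#'   vertebrae.
#' @return Named vector `c(mld = ..., sd = ...)` (mm).
#' @export
mld_sd <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("empty error list")
  mld <- mean(errors)
  c(mld = mld, sd = sqrt(mean((errors - mld)^2)))
}

#' Successful detection rate at accuracy t
#'
#' Percentage of centers localized within `t` mm of the ground truth
#' (distance no greater than `t` counts as a success).
#'
#' @param errors Numeric vector of distances (mm).
#' @param t Accuracy threshold (mm).
#' @return Percentage in `[0, 100]`.
#' @export
detection_rate <- function(errors, t) {
  errors <- as.numeric(errors)
  if (length(errors) == 0L) stop("empty error list")
  if (t <= 0) stop("`t` must be positive")
  100 * sum(errors <= t) / length(errors)
}

as_mask <- function(x) {
  arr <- if (inherits(x, "vb_volume")) x$data else x
  if (!is.array(arr)) stop("expected a 3D mask array or vb_volume")
  arr != 0
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`, in percent. Two empty masks are defined
#' to agree perfectly (100%).
#'
#' @param a,b Binary masks (logical/0-1 arrays or [vb_volume]s) on the same
#'   grid.
#' @return Percentage in `[0, 100]`.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks are on different grids")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(100)
  200 * sum(a & b) / denom
}

# Surface vertex set of a binary mask: centers (in mm) of foreground voxels
# that have at least one background 6-neighbour inside the volume. Works for
# 3D arrays and, with `axes`, for 2D slices.
surface_points <- function(mask, spacing, origin = rep(0, length(dim(mask)))) {
  d <- dim(mask)
  nd <- length(d)
  boundary <- array(FALSE, d)
  for (a in seq_len(nd)) {
    shift <- function(dir) {
      idx <- lapply(seq_len(nd), function(i) seq_len(d[i]))
      out <- array(FALSE, d)  # out-of-volume neighbours do not count as background
      src <- idx; dst <- idx
      if (d[a] < 2L) return(out)
      if (dir > 0) { dst[[a]] <- 2:d[a]; src[[a]] <- 1:(d[a] - 1L) }
      else { dst[[a]] <- 1:(d[a] - 1L); src[[a]] <- 2:d[a] }
      out <- do.call(`[<-`, c(list(out), dst, list(!do.call(`[`, c(list(mask), src, list(drop = FALSE))))))
      out
    }
    boundary <- boundary | (mask & (shift(1) | shift(-1)))
  }
  w <- which(boundary)
  if (length(w) == 0L) w <- which(mask)   # degenerate: mask fills the volume
  idx <- arrayInd(w, d)
  sweep(sweep(idx - 1, 2, spacing[seq_len(nd)], "*"), 2, origin[seq_len(nd)], "+")
}

#' Surface distances between two masks
#'
#' Surfaces are represented by their boundary voxel centers (foreground
#' voxels with a background 6-neighbour), in physical coordinates. `AAD` is
#' the mean distance from each automatic-surface vertex to its nearest
#' ground-truth vertex (one-directional by convention; `symmetric = TRUE`
#' averages both directions). `HSD` is the symmetric Hausdorff distance
#' between the two vertex sets.
#'
#' @param auto,gt Binary masks on the same grid (arrays or [vb_volume]s);
#'   both non-empty.
#' @param spacing Voxel spacing (mm); taken from `auto` if it is a
#'   [vb_volume].
#' @param symmetric Average the AAD over both directions.
#' @return Named vector `c(aad = ..., hsd = ...)` (mm).
#' @export
surface_distances <- function(auto, gt, spacing = NULL, symmetric = FALSE) {
  if (is.null(spacing)) {
    if (inherits(auto, "vb_volume")) spacing <- auto$spacing
    else stop("`spacing` required for bare arrays")
  }
  a <- as_mask(auto); g <- as_mask(gt)
  if (!all(dim(a) == dim(g))) stop("masks are on different grids")
  if (!any(a) || !any(g)) stop("surface distances are undefined for an empty mask")
  pa <- surface_points(a, spacing)
  pg <- surface_points(g, spacing)
  d_ag <- cpp_nn_dist(pa, pg)
  d_ga <- cpp_nn_dist(pg, pa)
  aad <- if (symmetric) (mean(d_ag) + mean(d_ga)) / 2 else mean(d_ag)
  c(aad = aad, hsd = max(max(d_ag), max(d_ga)))
}

#' Mid-sagittal 2D segmentation metrics
#'
#' Extracts the slice through the (rounded) vertebral-body center
#' perpendicular to the left-right axis and computes Dice, AAD and HSD on
#' that 2D slice, with contours represented by boundary pixel centers
#' (4-connectivity), matching several 2D-only methods in the literature.
#'
#' @param auto,gt Binary masks on the same grid (arrays or [vb_volume]s).
#' @param center Length-3 vertebral-body center (mm) selecting the slice.
#' @param sagittal_axis Axis index perpendicular to the sagittal plane.
#' @param spacing,origin Geometry; taken from `auto` if it is a [vb_volume].
#' @return List with `dice` (%), `aad` (mm), `hsd` (mm) and `slice` (index).
#' @export
midsagittal_metrics <- function(auto, gt, center, sagittal_axis,
                                spacing = NULL, origin = NULL) {
  if (inherits(auto, "vb_volume")) {
    if (is.null(spacing)) spacing <- auto$spacing
    if (is.null(origin)) origin <- auto$origin
  }
  if (is.null(spacing)) stop("`spacing` required for bare arrays")
  if (is.null(origin)) origin <- c(0, 0, 0)
  a <- as_mask(auto); g <- as_mask(gt)
  if (!all(dim(a) == dim(g))) stop("masks are on different grids")
  d <- dim(a)
  s <- as.integer(round((as.numeric(center)[sagittal_axis] - origin[sagittal_axis]) /
                          spacing[sagittal_axis] + 1))
  if (s < 1L || s > d[sagittal_axis]) stop("center slice lies outside the volume")
  keep <- setdiff(1:3, sagittal_axis)
  slice_of <- function(m) {
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx[[sagittal_axis]] <- s
    out <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
    array(out, dim(out)[keep])
  }
  a2 <- slice_of(a); g2 <- slice_of(g)
  dc <- dice(a2, g2)
  if (!any(a2) || !any(g2))
    return(list(dice = dc, aad = NA_real_, hsd = NA_real_, slice = s))
  pa <- surface_points(a2, spacing[keep], origin[keep])
  pg <- surface_points(g2, spacing[keep], origin[keep])
  d_ag <- cpp_nn_dist(pa, pg)
  d_ga <- cpp_nn_dist(pg, pa)
  list(dice = dc, aad = mean(d_ag), hsd = max(max(d_ag), max(d_ga)), slice = s)
}

#' Localization report over a cohort
#'
#' Pools per-vertebra localization distances over images, and reports the
#' mean (MLD), population SD, median and the detection rates at the given
#' accuracy thresholds.
#'
#' @param pred_list,gt_list Lists of [vb_centers] (predicted / ground
#'   truth), matched by position.
#' @param thresholds Accuracy thresholds t (mm) for the detection rates.
#' @return List with `errors` (per image x vertebra matrix), `mld`, `sd`,
#'   `median` and `rates` (named by threshold, in %).
#' @export
localization_report <- function(pred_list, gt_list, thresholds = c(2, 4, 6)) {
  stopifnot(length(pred_list) == length(gt_list), length(pred_list) >= 1L)
  errs <- do.call(rbind, lapply(seq_along(pred_list), function(s) {
    p <- pred_list[[s]]$centers; g <- gt_list[[s]]$centers
    vapply(seq_len(nrow(p)), function(i) localization_error(p[i, ], g[i, ]),
           numeric(1))
  }))
  pooled <- as.numeric(errs)
  ms <- mld_sd(pooled)
  rates <- vapply(thresholds, function(t) detection_rate(pooled, t), numeric(1))
  names(rates) <- paste0("t", thresholds)
  list(errors = errs, mld = unname(ms["mld"]), sd = unname(ms["sd"]),
       median = stats::median(pooled), rates = rates)
}

#' Segmentation report for one image
#'
#' Per-vertebra Dice, AAD and HSD between predicted and ground-truth label
#' volumes, in 3D and optionally on the mid-sagittal slice.
#'
#' @param pred,gt [vb_labels] on the same grid.
#' @param centers [vb_centers] used to pick the mid-sagittal slices
#'   (typically the ground truth); `NULL` skips the 2D metrics.
#' @param sagittal_axis Axis perpendicular to the sagittal plane; defaults
#'   to the volume's slice axis (sagittal MR convention).
#' @return Data frame with one row per vertebra.
#' @export
segmentation_report <- function(pred, gt, centers = NULL, sagittal_axis = NULL) {
  stopifnot(inherits(pred, "vb_labels"), inherits(gt, "vb_labels"))
  if (is.null(sagittal_axis)) sagittal_axis <- gt$slice_axis
  m <- max(gt$data)
  rows <- lapply(seq_len(m), function(i) {
    a <- pred$data == i
    g <- gt$data == i
    dc <- dice(a, g)
    sd3 <- if (any(a) && any(g)) surface_distances(a, g, spacing = gt$spacing)
           else c(aad = NA_real_, hsd = NA_real_)
    row <- data.frame(vb = gt$vb_names[i], dice = dc,
                      aad = unname(sd3["aad"]), hsd = unname(sd3["hsd"]))
    if (!is.null(centers)) {
      m2 <- midsagittal_metrics(a, g, centers$centers[i, ], sagittal_axis,
                                gt$spacing, gt$origin)
      row$dice2d <- m2$dice; row$aad2d <- m2$aad; row$hsd2d <- m2$hsd
    }
    row
  })
  do.call(rbind, rows)
}
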