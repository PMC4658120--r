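#' Segmentation pipeline parameters
#'
#' @param modality `"MR"` or `"CT"`.
#' @param m_train Training patches per vertebra (`M`), pooled over images.
#' @param patch_size Patch size for the classification features (default
#'   8 x 8 x 8 voxels).
#' @param k Feature blocks per axis.
#' @param alpha,beta Fusion weights of the spatial prior and the appearance
#'   likelihood in the posterior `L = alpha * P_s + beta * L_a` (defaults
#'   0.4 / 0.6).
#' @param prefilter Spatial-prior gate: voxels with `P_s <= prefilter` are
#'   hard-assigned background and never sent to the forest (default 0.1).
#' @param threshold Posterior binarization threshold (voxels with
#'   `L >= threshold` are foreground; default 0.5).
#' @param connectivity 26 (default) or 6, for the largest-component step.
#' @param bandwidth Parzen bandwidth of the spatial prior, in voxels.
#' @param dilate ROI dilation fraction.
#' @param forest A [forest_config] for the classification forest.
#' @param seed Integer seed.
#' @return An object of class `segment_params`.
#' @export
segment_params <- function(modality = c("MR", "CT"), m_train = 12000L,
                           patch_size = c(8L, 8L, 8L), k = 4L,
                           alpha = 0.4, beta = 0.6, prefilter = 0.1,
                           threshold = 0.5, connectivity = 26L,
                           bandwidth = 2, dilate = 0.25,
                           forest = forest_config(), seed = 1L) {
  modality <- match.arg(modality)
  if (alpha < 0 || beta < 0) stop("fusion weights must be non-negative")
  if (!connectivity %in% c(6L, 26L)) stop("`connectivity` must be 6 or 26")
  structure(list(modality = modality, m_train = as.integer(m_train),
                 patch_size = as.integer(patch_size), k = as.integer(k),
                 alpha = alpha, beta = beta, prefilter = prefilter,
                 threshold = threshold, connectivity = as.integer(connectivity),
                 bandwidth = bandwidth, dilate = dilate, forest = forest,
                 seed = as.integer(seed)),
            class = "segment_params")
}

#' Classification-forest appearance likelihood in an ROI
#'
#' Evaluates `L_a(v) = (1/T_s) sum_t p_t(l_v = 1 | f_v)` for every voxel of
#' the ROI box whose spatial prior exceeds the prefilter threshold; all other
#' voxels get `L_a = 0` and are never sent to the forest (the prior acts as a
#' gate). Voxels whose feature patch would leave the volume are likewise
#' skipped.
#'
#' @param forest A [train_voxel_classifier()] result.
#' @param vol A [vb_volume] or its [build_integral_volumes()].
#' @param box Voxel box `list(lo=, hi=)` of the ROI on the image grid.
#' @param ps Spatial-prior array over `box` (same dimensions).
#' @param cfg A [feature_config].
#' @param prefilter Gate threshold on `ps` (default 0.1).
#' @return Array of likelihoods over `box`, with attribute `n_evaluated`
#'   giving the number of voxels actually classified.
#' @export
appearance_likelihood <- function(forest, vol, box, ps, cfg, prefilter = 0.1) {
  iv <- as_integral(vol)
  bdim <- box$hi - box$lo + 1L
  if (!all(dim(ps) == bdim)) stop("`ps` does not match the ROI box")
  la <- array(0, bdim)
  rng <- valid_center_range(iv$dim, cfg$patch_size)
  sel <- which(ps > prefilter)
  if (length(sel) > 0L) {
    idx <- sweep(arrayInd(sel, bdim), 2, box$lo - 1L, "+")
    fits <- idx[, 1] >= rng$lo[1] & idx[, 1] <= rng$hi[1] &
            idx[, 2] >= rng$lo[2] & idx[, 2] <= rng$hi[2] &
            idx[, 3] >= rng$lo[3] & idx[, 3] <= rng$hi[3]
    sel <- sel[fits]
    idx <- idx[fits, , drop = FALSE]
    if (nrow(idx) > 0L) {
      feats <- patch_features(iv, idx, cfg)
      la[sel] <- predict_foreground(forest, feats)
    }
  }
  attr(la, "n_evaluated") <- length(sel)
  la
}

#' Fuse spatial prior and appearance likelihood
#'
#' Elementwise convex combination `L(v) = alpha * P_s(v) + beta * L_a(v)`
#' (defaults 0.4 / 0.6). If `prefilter` is given, voxels with
#' `P_s <= prefilter` are hard-assigned `L = 0` (the gate semantics of the
#' prior).
#'
#' @param ps,la Arrays on the same ROI grid.
#' @param alpha,beta Non-negative fusion weights.
#' @param prefilter Optional gate threshold.
#' @return An object of class `posterior_map` with the fused array `data`.
#' @export
fuse_posterior <- function(ps, la, alpha = 0.4, beta = 0.6, prefilter = NULL) {
  if (!all(dim(ps) == dim(la))) stop("prior and likelihood grids differ")
  if (alpha < 0 || beta < 0) stop("fusion weights must be non-negative")
  L <- alpha * ps + beta * la
  if (!is.null(prefilter)) L[ps <= prefilter] <- 0
  structure(list(data = L, alpha = alpha, beta = beta, prefilter = prefilter),
            class = "posterior_map")
}

#' Binarize a posterior map
#'
#' Thresholds the posterior at `L >= threshold` (boundary included) and keeps
#' only the largest connected component (26-connectivity by default). An
#' all-background result is allowed.
#'
#' @param post A [fuse_posterior()] result (or a bare array).
#' @param threshold Binarization threshold (default 0.5).
#' @param connectivity 26 or 6.
#' @return Logical array of the same dimensions.
#' @export
binarize_posterior <- function(post, threshold = 0.5, connectivity = 26L) {
  arr <- if (inherits(post, "posterior_map")) post$data else post
  mask <- arr >= threshold
  if (!any(mask)) return(array(FALSE, dim(arr)))
  cpp_largest_component(mask, as.integer(dim(arr)), as.integer(connectivity))
}

#' Train the vertebral-body segmenter
#'
#' For every vertebral body: learns the ROI half-extent and the Parzen
#' spatial prior from the training masks, samples balanced foreground /
#' background patches inside the per-image ROIs, and trains the
#' classification forest.
#'
#' @param volumes List of training [vb_volume]s.
#' @param labelvols List of matching [vb_labels].
#' @param centers_list List of matching ground-truth [vb_centers].
#' @param params A [segment_params].
#' @return An object of class `vb_segmenter` with one model per vertebra.
#' @export
train_segmenter <- function(volumes, labelvols, centers_list,
                            params = segment_params()) {
  stopifnot(length(volumes) == length(labelvols),
            length(volumes) == length(centers_list), length(volumes) >= 1L)
  m <- nrow(centers_list[[1]]$centers)
  cfg <- feature_config(params$modality, params$patch_size, params$k)
  ivs <- lapply(volumes, build_integral_volumes)
  models <- vector("list", m)
  for (i in seq_len(m)) {
    hw <- roi_half_extent(labelvols, centers_list, i, params$dilate)
    prior <- learn_spatial_prior(labelvols, centers_list, i, hw, params$bandwidth)
    n_img <- length(volumes)
    per_img <- ceiling(params$m_train / n_img)
    samples <- lapply(seq_len(n_img), function(s) {
      roi <- world_box(ivs[[s]], centers_list[[s]]$centers[i, ], hw)
      sample_segmentation_patches(ivs[[s]], labelvols[[s]], i, roi, per_img,
                                  cfg, seed = sub_seed(params$seed, 5000L + s * 53L + i))
    })
    fc <- params$forest
    fc$seed <- sub_seed(params$seed, 6000L + i)
    models[[i]] <- list(prior = prior, half_extent = hw,
                        forest = train_voxel_classifier(samples, fc))
  }
  structure(list(models = models, params = params, cfg = cfg, m = m,
                 vb_names = centers_list[[1]]$vb_names),
            class = "vb_segmenter")
}

#' Segment one vertebral body around a detected center
#'
#' Composes the full per-vertebra segmentation: place the spatial prior at
#' the center, evaluate the gated appearance likelihood, fuse, threshold at
#' 0.5 and keep the largest connected component. The mask is returned
#' embedded in the full volume grid.
#'
#' @param vol A [vb_volume].
#' @param center Length-3 detected center (mm).
#' @param model One per-vertebra model from [train_segmenter()]
#'   (`segmenter$models[[i]]`).
#' @param params A [segment_params] (for the fusion/threshold settings).
#' @param iv Optional precomputed [build_integral_volumes()] of `vol`.
#' @return Logical array with the dimensions of `vol`.
#' @export
segment_vb <- function(vol, center, model, params = segment_params(), iv = NULL) {
  if (is.null(iv)) iv <- build_integral_volumes(vol)
  placed <- place_prior(model$prior, vol, center)
  cfg <- feature_config(params$modality, params$patch_size, params$k)
  la <- appearance_likelihood(model$forest, iv, placed$box, placed$ps, cfg,
                              params$prefilter)
  post <- fuse_posterior(placed$ps, la, params$alpha, params$beta,
                         prefilter = params$prefilter)
  sub <- binarize_posterior(post, params$threshold, params$connectivity)
  full <- array(FALSE, dim(vol$data))
  full[placed$box$lo[1]:placed$box$hi[1],
       placed$box$lo[2]:placed$box$hi[2],
       placed$box$lo[3]:placed$box$hi[3]] <- sub
  full
}

#' Segment all vertebral bodies of a volume
#'
#' Runs [segment_vb] for every vertebra at its detected center and combines
#' the masks into one label volume (label `i` for the i-th vertebra; on the
#' rare overlapping voxel the later vertebra wins).
#'
#' @param vol A [vb_volume].
#' @param centers A [vb_centers] of detected centers.
#' @param segmenter A [train_segmenter()] result.
#' @return A [vb_labels] with one label per vertebra.
#' @export
segment <- function(vol, centers, segmenter) {
  stopifnot(inherits(segmenter, "vb_segmenter"),
            nrow(centers$centers) == segmenter$m)
  iv <- build_integral_volumes(vol)
  out <- array(0L, dim(vol$data))
  for (i in seq_len(segmenter$m)) {
    mask <- segment_vb(vol, centers$centers[i, ], segmenter$models[[i]],
                       segmenter$params, iv)
    out[mask] <- i
  }
  vb_labels(out, vol$spacing, vol$origin, vol$slice_axis, segmenter$vb_names)
}
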