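#' Sample training patches for center regression
#'
#' Draws `n` patch centers uniformly at random inside `region` (clamped so
#' every patch fits in the volume), computes their block features and the
#' displacement from each patch center to the ground-truth vertebral-body
#' center (`gt_center - patch_center`, in mm).
#'
#' @param vol A [vb_volume], or a precomputed [build_integral_volumes()]
#'   result for it.
#' @param gt_center Length-3 ground-truth center (mm).
#' @param n Number of patches to sample.
#' @param region Optional voxel box `list(lo=, hi=)` restricting the patch
#'   centers; `NULL` means the whole volume.
#' @param cfg A [feature_config].
#' @param seed Integer seed.
#' @return An object of class `localization_samples` with `features`
#'   (`n x d_f`), `displacements` (`n x 3`, mm) and `patch_centers`
#'   (`n x 3`, voxel indices).
#' @export
sample_localization_patches <- function(vol, gt_center, n, region = NULL, cfg,
                                        seed = 1L) {
  iv <- as_integral(vol)
  centers <- draw_patch_centers(iv, n, region, cfg, seed)
  geom <- list(spacing = iv$spacing, origin = iv$origin)
  disp <- sweep(-voxel_to_world(geom, centers), 2, as.numeric(gt_center), "+")
  structure(list(features = patch_features(iv, centers, cfg),
                 displacements = disp,
                 patch_centers = centers),
            class = "localization_samples")
}

#' Cast per-tree center votes on an unseen image
#'
#' Samples `n_test` patches uniformly in `region`, predicts each patch's
#' displacement with every tree of the regression forest, and returns the
#' `n_test x T` predicted center positions `y = patch_center + displacement`
#' (mm), each with unit weight.
#'
#' @inheritParams sample_localization_patches
#' @param forest A [train_center_regressor()] result.
#' @param n_test Number of test patches.
#' @return An object of class `vote_set` with `votes` (`(n_test*T) x 3`, mm)
#'   and `weights`.
#' @export
cast_votes <- function(forest, vol, n_test, region = NULL, cfg, seed = 1L) {
  iv <- as_integral(vol)
  centers <- draw_patch_centers(iv, n_test, region, cfg, seed)
  feats <- patch_features(iv, centers, cfg)
  disp <- predict_displacements(forest, feats, per_tree = TRUE)   # n x 3 x T
  geom <- list(spacing = iv$spacing, origin = iv$origin)
  pos <- voxel_to_world(geom, centers)
  T_ <- forest$n_trees
  votes <- matrix(0, nrow(centers) * T_, 3L)
  for (t in seq_len(T_))
    votes[seq_len(nrow(centers)) + (t - 1L) * nrow(centers), ] <- pos + disp[, , t]
  structure(list(votes = votes, weights = rep(1, nrow(votes))), class = "vote_set")
}

#' Sample labeled training patches for voxel classification
#'
#' Draws `m` patch centers in the region of interest around one vertebral
#' body, balanced 50/50 between foreground (mask label equals `vb_index` at
#' the patch center) and background, and computes their block features. The
#' segmentation stage uses small patches (8 x 8 x 8 voxels by default in the
#' pipeline).
#'
#' @inheritParams sample_localization_patches
#' @param mask A [vb_labels] on the same grid as `vol`.
#' @param vb_index Which vertebral body is foreground.
#' @param roi Voxel box `list(lo=, hi=)` of the region of interest.
#' @param m Total number of patches.
#' @return An object of class `segmentation_samples` with `features`
#'   (`m x d_f`), `labels` (0/1) and `patch_centers`.
#' @export
sample_segmentation_patches <- function(vol, mask, vb_index, roi, m, cfg,
                                        seed = 1L) {
  iv <- as_integral(vol)
  rng <- valid_center_range(iv$dim, cfg$patch_size)
  box <- clip_box(list(lo = pmax(roi$lo, rng$lo), hi = pmin(roi$hi, rng$hi)), iv$dim)
  sub <- crop_array(mask$data, box) == vb_index
  fg_lin <- which(sub)
  bg_lin <- which(!sub)
  if (length(fg_lin) == 0L || length(bg_lin) == 0L)
    stop("ROI must contain both foreground and background voxels")
  n_fg <- m %/% 2L
  n_bg <- m - n_fg
  with_seed(seed, {
    pick_fg <- fg_lin[sample.int(length(fg_lin), n_fg, replace = TRUE)]
    pick_bg <- bg_lin[sample.int(length(bg_lin), n_bg, replace = TRUE)]
  })
  lin <- c(pick_fg, pick_bg)
  centers <- sweep(arrayInd(lin, dim(sub)), 2, box$lo - 1L, "+")
  labels <- c(rep(1L, n_fg), rep(0L, n_bg))
  structure(list(features = patch_features(iv, centers, cfg),
                 labels = labels,
                 patch_centers = centers),
            class = "segmentation_samples")
}

# accept a vb_volume or prebuilt integral volumes
as_integral <- function(vol) {
  if (inherits(vol, "integral_volumes")) vol
  else build_integral_volumes(vol)
}

# Uniform random patch centers in region ∩ valid area.
draw_patch_centers <- function(iv, n, region, cfg, seed) {
  rng <- valid_center_range(iv$dim, cfg$patch_size)
  lo <- rng$lo; hi <- rng$hi
  if (!is.null(region)) {
    lo <- pmax(lo, as.integer(region$lo))
    hi <- pmin(hi, as.integer(region$hi))
  }
  if (any(hi < lo))
    stop("sampling region does not intersect the valid patch-center area")
  with_seed(seed, {
    cbind(sample.int(hi[1] - lo[1] + 1L, n, replace = TRUE) + lo[1] - 1L,
          sample.int(hi[2] - lo[2] + 1L, n, replace = TRUE) + lo[2] - 1L,
          sample.int(hi[3] - lo[3] + 1L, n, replace = TRUE) + lo[3] - 1L)
  })
}
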