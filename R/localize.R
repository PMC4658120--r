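#' Localization pipeline parameters
#'
#' Bundles every setting of the two-step coarse-to-fine localization. Default
#' patch sizes follow the standard acquisition conventions: for MR (slices
#' parallel to YZ) 16 voxels along the slice axis x 20 x 20 in-plane at the
#' coarse step and 8 x 40 x 40 at the fine step; for CT (slices parallel to
#' XY) 20 x 20 in-plane x 12 along the slice axis coarse and 80 x 80 x 32
#' fine. The patch-size vectors are stored as (along-slice, in-plane,
#' in-plane) and oriented to the volume's `slice_axis` at run time.
#'
#' @param modality `"MR"` or `"CT"` (selects feature dimension and default
#'   patch sizes).
#' @param n_train Training patches per vertebra per image (`N`).
#' @param n_test Test patches per vertebra per step (`N'`).
#' @param coarse_factor In-plane downsampling factor of the coarse step.
#' @param coarse_patch,fine_patch Length-3 patch sizes as (along-slice,
#'   in-plane, in-plane); `NULL` for the modality default.
#' @param train_halfwidth_mm Half-width of the fine-step training sampling
#'   box around the ground-truth center.
#' @param fine_halfwidth_mm Half-width of the fine-step test region around
#'   the coarse center estimate.
#' @param k_candidates Response-volume candidates per vertebra for the chain
#'   decoding.
#' @param var_floor Chain-prior variance floor (mm^2).
#' @param forest A [forest_config].
#' @param agg An [aggregation_config].
#' @param k Feature blocks per axis.
#' @param seed Integer seed for all sampling.
#' @return An object of class `localize_params`.
#' @export
localize_params <- function(modality = c("MR", "CT"), n_train = 15000L,
                            n_test = 10000L, coarse_factor = 4L,
                            coarse_patch = NULL, fine_patch = NULL,
                            train_halfwidth_mm = 30, fine_halfwidth_mm = 30,
                            k_candidates = 50L, var_floor = 1,
                            forest = forest_config(), agg = aggregation_config(),
                            k = 4L, seed = 1L) {
  modality <- match.arg(modality)
  if (is.null(coarse_patch))
    coarse_patch <- if (modality == "MR") c(16L, 20L, 20L) else c(12L, 20L, 20L)
  if (is.null(fine_patch))
    fine_patch <- if (modality == "MR") c(8L, 40L, 40L) else c(32L, 80L, 80L)
  structure(list(modality = modality, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), coarse_factor = as.integer(coarse_factor),
                 coarse_patch = as.integer(coarse_patch),
                 fine_patch = as.integer(fine_patch),
                 train_halfwidth_mm = train_halfwidth_mm,
                 fine_halfwidth_mm = fine_halfwidth_mm,
                 k_candidates = k_candidates, var_floor = var_floor,
                 forest = forest, agg = agg, k = as.integer(k),
                 seed = as.integer(seed)),
            class = "localize_params")
}

# orient an (along-slice, in-plane, in-plane) size vector to the array axes
oriented_patch <- function(size3, slice_axis) {
  out <- integer(3)
  out[slice_axis] <- size3[1]
  out[setdiff(1:3, slice_axis)] <- size3[2:3]
  out
}

# voxel box of half-width `hw` mm around a physical point, clipped
world_box <- function(vol_or_grid, center_mm, hw_mm) {
  ctr <- world_to_voxel(vol_or_grid, center_mm)
  d <- if (!is.null(vol_or_grid$dim)) vol_or_grid$dim else dim(vol_or_grid$data)
  lo <- pmax(1L, as.integer(floor(ctr - hw_mm / vol_or_grid$spacing)))
  hi <- pmin(as.integer(d), as.integer(ceiling(ctr + hw_mm / vol_or_grid$spacing)))
  if (any(hi < lo)) stop("region around the center lies outside the volume")
  list(lo = lo, hi = as.integer(hi))
}

#' Train the coarse-to-fine vertebral-body localizer
#'
#' Trains, for every vertebral body, one displacement regression forest on
#' the in-plane-downsampled volumes (coarse step; training patches sampled
#' over the whole image) and one at full resolution (fine step; patches
#' sampled in a box around the ground-truth center), and learns the
#' inter-vertebra chain prior from the training annotations.
#'
#' @param volumes List of [vb_volume]s (training images, common spacing).
#' @param centers_list List of [vb_centers] ground-truth annotations, one per
#'   volume, same vertebra ordering.
#' @param params A [localize_params].
#' @return An object of class `vb_localizer`.
#' @export
train_localizer <- function(volumes, centers_list, params = localize_params()) {
  stopifnot(length(volumes) == length(centers_list), length(volumes) >= 2L)
  m <- nrow(centers_list[[1]]$centers)
  slice_axis <- volumes[[1]]$slice_axis
  cfg_coarse <- feature_config(params$modality,
                               oriented_patch(params$coarse_patch, slice_axis),
                               params$k)
  cfg_fine <- feature_config(params$modality,
                             oriented_patch(params$fine_patch, slice_axis),
                             params$k)
  coarse_ivs <- lapply(volumes, function(v)
    build_integral_volumes(downsample_inplane(v, params$coarse_factor)))
  fine_ivs <- lapply(volumes, build_integral_volumes)

  coarse_forests <- vector("list", m)
  fine_forests <- vector("list", m)
  for (i in seq_len(m)) {
    coarse_samples <- lapply(seq_along(volumes), function(s)
      sample_localization_patches(coarse_ivs[[s]],
                                  centers_list[[s]]$centers[i, ],
                                  params$n_train, NULL, cfg_coarse,
                                  seed = sub_seed(params$seed, 1000L + s * 37L + i)))
    fine_samples <- lapply(seq_along(volumes), function(s) {
      box <- world_box(fine_ivs[[s]], centers_list[[s]]$centers[i, ],
                       params$train_halfwidth_mm)
      sample_localization_patches(fine_ivs[[s]],
                                  centers_list[[s]]$centers[i, ],
                                  params$n_train, box, cfg_fine,
                                  seed = sub_seed(params$seed, 2000L + s * 37L + i))
    })
    fc <- params$forest
    fc$seed <- sub_seed(params$seed, 3000L + i)
    coarse_forests[[i]] <- train_center_regressor(coarse_samples, fc)
    fc$seed <- sub_seed(params$seed, 4000L + i)
    fine_forests[[i]] <- train_center_regressor(fine_samples, fc)
  }
  prior <- if (m >= 2L) learn_chain_prior(centers_list, params$var_floor) else NULL
  structure(list(coarse_forests = coarse_forests, fine_forests = fine_forests,
                 prior = prior, params = params,
                 cfg_coarse = cfg_coarse, cfg_fine = cfg_fine,
                 vb_names = centers_list[[1]]$vb_names, m = m,
                 slice_axis = slice_axis),
            class = "vb_localizer")
}

#' Localize all vertebral-body centers in a volume
#'
#' Two-step coarse-to-fine detection. Coarse step: votes are cast from
#' patches sampled all over the in-plane-downsampled volume, aggregated into
#' one response volume per vertebra (IFGT), and the chain of centers is
#' decoded jointly with the hidden Markov prior. Fine step: for each
#' vertebra, votes are cast only in a small region around its coarse center
#' at the original resolution, and the final center is the argmax of the
#' fine response.
#'
#' @param vol A [vb_volume] with the same spacing convention as the training
#'   images.
#' @param localizer A [train_localizer()] result.
#' @param seed Integer seed for the test-patch sampling.
#' @param keep_responses Keep the per-vertebra response volumes in the
#'   result (memory-heavy; mainly for inspection and testing).
#' @return List of class `vb_localization` with `centers` (final,
#'   [vb_centers]), `coarse_centers`, and optionally `coarse_responses` /
#'   `fine_responses`.
#' @export
localize <- function(vol, localizer, seed = 1L, keep_responses = FALSE) {
  stopifnot(inherits(localizer, "vb_localizer"))
  p <- localizer$params
  m <- localizer$m
  coarse_vol <- downsample_inplane(vol, p$coarse_factor)
  coarse_iv <- build_integral_volumes(coarse_vol)
  coarse_grid <- response_grid(coarse_vol)
  responses <- vector("list", m)
  for (i in seq_len(m)) {
    votes <- cast_votes(localizer$coarse_forests[[i]], coarse_iv, p$n_test,
                        NULL, localizer$cfg_coarse,
                        seed = sub_seed(seed, 100L + i))
    responses[[i]] <- aggregate_votes_ifgt(votes, coarse_grid, p$agg)
  }
  coarse_centers <- if (m >= 2L)
    decode_center_chain(responses, localizer$prior, p$k_candidates,
                        localizer$vb_names)
  else
    vb_centers(rbind3(response_argmax(responses[[1]])), localizer$vb_names)

  fine_iv <- build_integral_volumes(vol)
  fine_centers <- matrix(0, m, 3L)
  fine_responses <- if (keep_responses) vector("list", m) else NULL
  for (i in seq_len(m)) {
    box <- world_box(fine_iv, coarse_centers$centers[i, ], p$fine_halfwidth_mm)
    votes <- cast_votes(localizer$fine_forests[[i]], fine_iv, p$n_test,
                        box, localizer$cfg_fine,
                        seed = sub_seed(seed, 200L + i))
    grid <- response_grid(vol, box)
    resp <- aggregate_votes_ifgt(votes, grid, p$agg)
    fine_centers[i, ] <- response_argmax(resp)
    if (keep_responses) fine_responses[[i]] <- resp
  }
  structure(list(centers = vb_centers(fine_centers, localizer$vb_names),
                 coarse_centers = coarse_centers,
                 coarse_responses = if (keep_responses) responses else NULL,
                 fine_responses = fine_responses),
            class = "vb_localization")
}
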