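#' Leave-one-out localization + segmentation study on phantoms
#'
#' Runs the complete pipeline as a leave-one-out experiment over a phantom
#' cohort: for every subject, the localizer and segmenter are trained on all
#' remaining subjects, the left-out volume is localized and segmented, and
#' the localization distances and segmentation overlap metrics are collected.
#' This is the package's desk-scale analogue of a clinical leave-one-out
#' validation, with ground truth known by construction.
#'
#' @param cfg A [phantom_config] describing the cohort.
#' @param n_subjects Cohort size.
#' @param loc_params A [localize_params].
#' @param seg_params A [segment_params].
#' @param seed Master seed (cohort generation, training and testing all
#'   derive their seeds from it).
#' @param thresholds Detection-rate accuracy thresholds (mm).
#' @return List with `localization` (see [localization_report]),
#'   `coarse_errors` (matrix, subjects x vertebrae), `segmentation`
#'   (data frame of per-subject per-vertebra Dice/AAD/HSD, 3D and
#'   mid-sagittal 2D) and `summary` (named numeric vector of the headline
#'   quantities).
#' @export
phantom_loo <- function(cfg = phantom_config(),
                        n_subjects = 6L,
                        loc_params = localize_params("MR"),
                        seg_params = segment_params("MR"),
                        seed = 1L,
                        thresholds = c(2, 4, 6)) {
  cohort <- generate_cohort(cfg, n_subjects, seed = sub_seed(seed, 1L))
  pred <- vector("list", n_subjects)
  coarse <- vector("list", n_subjects)
  seg_rows <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    train_idx <- setdiff(seq_len(n_subjects), s)
    vols <- lapply(cohort[train_idx], `[[`, "volume")
    labs <- lapply(cohort[train_idx], `[[`, "labels")
    ctrs <- lapply(cohort[train_idx], `[[`, "centers")
    lp <- loc_params; lp$seed <- sub_seed(seed, 10L + s)
    sp <- seg_params; sp$seed <- sub_seed(seed, 20L + s)
    localizer <- train_localizer(vols, ctrs, lp)
    segmenter <- train_segmenter(vols, labs, ctrs, sp)
    res <- localize(cohort[[s]]$volume, localizer, seed = sub_seed(seed, 30L + s))
    pred[[s]] <- res$centers
    coarse[[s]] <- res$coarse_centers
    mask <- segment(cohort[[s]]$volume, res$centers, segmenter)
    rep <- segmentation_report(mask, cohort[[s]]$labels, cohort[[s]]$centers)
    rep$subject <- s
    seg_rows[[s]] <- rep
  }
  gt <- lapply(cohort, `[[`, "centers")
  loc_rep <- localization_report(pred, gt, thresholds)
  coarse_rep <- localization_report(coarse, gt, thresholds)
  seg <- do.call(rbind, seg_rows)
  summary <- c(mld = loc_rep$mld, sd = loc_rep$sd, median = loc_rep$median,
               coarse_mld = coarse_rep$mld,
               stats::setNames(loc_rep$rates, paste0("rate_", thresholds, "mm")),
               dice = mean(seg$dice), aad = mean(seg$aad, na.rm = TRUE),
               hsd = mean(seg$hsd, na.rm = TRUE),
               dice2d = mean(seg$dice2d), aad2d = mean(seg$aad2d, na.rm = TRUE),
               hsd2d = mean(seg$hsd2d, na.rm = TRUE))
  list(localization = loc_rep, coarse_errors = coarse_rep$errors,
       segmentation = seg, summary = summary)
}
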