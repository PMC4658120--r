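#' Random-forest settings
#'
#' Shared settings for the displacement regression forests and the voxel
#' classification forests. Defaults follow common regression-forest practice:
#' 20 trees, maximum depth 12, at least 5 samples per leaf and `sqrt(d_f)`
#' candidate features per split.
#'
#' @param n_trees Number of trees `T`.
#' @param max_depth Maximum tree depth (0 = unlimited).
#' @param min_leaf Minimum samples per leaf.
#' @param mtry Candidate features per split; `NULL` for `floor(sqrt(d_f))`.
#' @param bootstrap Grow each tree on a bootstrap resample (`TRUE`, the
#'   default) or on the full training set (`FALSE`).
#' @param seed Integer seed; identical seeds give identical forests.
#' @return An object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 20L, max_depth = 12L, min_leaf = 5L,
                          mtry = NULL, bootstrap = TRUE, seed = 1L) {
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), mtry = mtry,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "forest_config")
}

ranger_args <- function(cfg, d_f) {
  list(num.trees = cfg$n_trees,
       max.depth = cfg$max_depth,
       min.node.size = cfg$min_leaf,
       mtry = if (is.null(cfg$mtry)) max(1L, floor(sqrt(d_f))) else as.integer(cfg$mtry),
       replace = cfg$bootstrap,
       sample.fraction = if (cfg$bootstrap) 1 else 1,
       num.threads = 1L,
       seed = cfg$seed)
}

#' Train the per-vertebra displacement regression forest
#'
#' Learns the mapping from patch appearance to the 3D displacement from the
#' patch center to the vertebral-body center. Internally one forest is grown
#' per displacement axis (variance-reduction splits on bootstrap resamples);
#' the t-th trees of the three forests are paired, so each of the `T` trees
#' of the conceptual multi-output forest returns one 3D displacement and a
#' test patch contributes `T` votes.
#'
#' @param samples A `localization_samples` object (from
#'   [sample_localization_patches]) or a list of them, pooled.
#' @param cfg A [forest_config].
#' @return An object of class `vb_regression_forest`.
#' @export
train_center_regressor <- function(samples, cfg = forest_config()) {
  if (inherits(samples, "localization_samples")) samples <- list(samples)
  feats <- do.call(rbind, lapply(samples, `[[`, "features"))
  disp <- do.call(rbind, lapply(samples, `[[`, "displacements"))
  if (is.null(feats) || nrow(feats) == 0L) stop("empty training set")
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  args <- ranger_args(cfg, ncol(feats))
  fits <- lapply(1:3, function(a) {
    df <- data.frame(feats, .y = disp[, a], check.names = FALSE)
    do.call(ranger::ranger, c(list(dependent.variable.name = ".y", data = df,
                                   seed = sub_seed(cfg$seed, a)),
                              args[names(args) != "seed"]))
  })
  structure(list(fits = fits, n_trees = cfg$n_trees, d_f = ncol(feats), cfg = cfg),
            class = "vb_regression_forest")
}

#' Per-tree displacement predictions
#'
#' @param forest A [train_center_regressor()] result.
#' @param features `n x d_f` matrix.
#' @param per_tree If `TRUE` return an `n x 3 x T` array of per-tree
#'   displacements (mm); otherwise the `n x 3` forest mean.
#' @return See `per_tree`.
#' @export
predict_displacements <- function(forest, features, per_tree = TRUE) {
  stopifnot(inherits(forest, "vb_regression_forest"))
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  df <- as.data.frame(features)
  preds <- lapply(forest$fits, function(f)
    stats::predict(f, df, predict.all = per_tree, num.threads = 1L)$predictions)
  if (!per_tree) return(do.call(cbind, preds))
  out <- array(0, c(nrow(features), 3L, forest$n_trees))
  for (a in 1:3) out[, a, ] <- preds[[a]]
  out
}

#' Train the voxel classification forest
#'
#' Learns the mapping from patch appearance to the probability that the
#' central voxel is vertebral-body foreground. Trees use Gini splits on
#' bootstrap resamples; each leaf stores the foreground fraction of its
#' training samples, and the forest likelihood is the average of the
#' per-tree leaf probabilities.
#'
#' @param samples A `segmentation_samples` object (from
#'   [sample_segmentation_patches]) or a list of them, pooled.
#' @param cfg A [forest_config].
#' @return An object of class `vb_classification_forest`.
#' @export
train_voxel_classifier <- function(samples, cfg = forest_config()) {
  if (inherits(samples, "segmentation_samples")) samples <- list(samples)
  feats <- do.call(rbind, lapply(samples, `[[`, "features"))
  labels <- unlist(lapply(samples, `[[`, "labels"))
  if (is.null(feats) || nrow(feats) == 0L) stop("empty training set")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both foreground and background samples")
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  df <- data.frame(feats, .l = factor(labels, levels = c(0, 1)), check.names = FALSE)
  args <- ranger_args(cfg, ncol(feats))
  fit <- do.call(ranger::ranger,
                 c(list(dependent.variable.name = ".l", data = df, probability = TRUE),
                   args))
  structure(list(fit = fit, n_trees = cfg$n_trees, d_f = ncol(feats), cfg = cfg),
            class = "vb_classification_forest")
}

#' Foreground likelihood of patches
#'
#' @param forest A [train_voxel_classifier()] result.
#' @param features `n x d_f` matrix.
#' @param per_tree If `TRUE` return the `n x T` matrix of per-tree foreground
#'   probabilities; otherwise their mean (the forest likelihood).
#' @return See `per_tree`.
#' @export
predict_foreground <- function(forest, features, per_tree = FALSE) {
  stopifnot(inherits(forest, "vb_classification_forest"))
  features <- as.matrix(features)
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  df <- as.data.frame(features)
  p <- stats::predict(forest$fit, df, predict.all = per_tree, num.threads = 1L)$predictions
  if (per_tree) {
    fg <- which(dimnames(p)[[2]] == "1")
    matrix(p[, fg, ], nrow = dim(p)[1])
  } else {
    p[, "1"]
  }
}
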