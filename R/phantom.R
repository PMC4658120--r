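#' Synthetic spine phantom configuration
#'
#' Phantoms are chains of bright ellipsoidal bodies on a dark background with
#' additive Gaussian noise — the repetitive pattern that makes per-vertebra
#' center detection ambiguous and chain regularization necessary. Every
#' module of the pipeline can be trained and tested on phantoms without any
#' external data; ground-truth centers and masks are known by construction.
#'
#' Defaults mirror a reduced sagittal-MR convention: a 40 x 128 x 128 grid at
#' (2, 1.25, 1.25) mm with slices parallel to the YZ plane, five bodies of
#' radii (9, 13, 13) mm spaced 30 mm along the y axis, foreground/background
#' intensities 120/40 and noise SD 12.
#'
#' @param n_vbs Number of vertebral bodies.
#' @param grid_dim Length-3 integer grid size.
#' @param spacing Voxel spacing (mm).
#' @param slice_axis Axis perpendicular to the slices.
#' @param chain_axis Axis along which the body chain runs.
#' @param radii Mean ellipsoid semi-axes (mm).
#' @param radii_jitter Fractional SD of per-body radius jitter.
#' @param offset Mean offset between adjacent centers (mm).
#' @param offset_jitter Per-axis SD of the offset jitter (mm).
#' @param start_center Center of the first body (mm); `NULL` centers the
#'   chain in the grid.
#' @param fg,bg Foreground/background mean intensities.
#' @param noise_sd Additive Gaussian noise SD.
#' @param modality `"MR"` adds a smooth multiplicative intensity modulation
#'   (bias-field-like texture); `"CT"` keeps a flat intensity plateau.
#' @param texture_amp Amplitude of the MR modulation.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_vbs = 5L, grid_dim = c(40L, 128L, 128L),
                           spacing = c(2, 1.25, 1.25), slice_axis = 1L,
                           chain_axis = 2L, radii = c(9, 13, 13),
                           radii_jitter = 0.08, offset = c(0, 30, 0),
                           offset_jitter = c(1.5, 2, 1.5),
                           start_center = NULL, fg = 120, bg = 40,
                           noise_sd = 12, modality = c("MR", "CT"),
                           texture_amp = 0.15, seed = 1L) {
  modality <- match.arg(modality)
  if (n_vbs < 1L) stop("`n_vbs` must be >= 1")
  if (any(radii <= 0)) stop("`radii` must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(n_vbs = as.integer(n_vbs), grid_dim = as.integer(grid_dim),
                 spacing = as.numeric(spacing), slice_axis = as.integer(slice_axis),
                 chain_axis = as.integer(chain_axis), radii = as.numeric(radii),
                 radii_jitter = radii_jitter, offset = as.numeric(offset),
                 offset_jitter = as.numeric(offset_jitter),
                 start_center = start_center, fg = fg, bg = bg,
                 noise_sd = noise_sd, modality = modality,
                 texture_amp = texture_amp, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate one synthetic spine phantom
#'
#' Places `n_vbs` ellipsoids along a jittered chain, labels them `1..n_vbs`,
#' fills foreground/background intensities plus Gaussian noise, and returns
#' the image volume, the true centers and the label volume.
#'
#' @param cfg A [phantom_config].
#' @return List with elements `volume` ([vb_volume]), `centers`
#'   ([vb_centers]; the exact ellipsoid centers) and `labels` ([vb_labels]).
#' @export
generate_spine_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  d <- cfg$grid_dim
  sp <- cfg$spacing
  extent <- d * sp
  with_seed(cfg$seed, {
    # draw the chain shape first (jittered inter-body offsets and radii),
    # then place it: the field of view is centered on the anatomy, so the
    # chain is centered in the grid rather than accumulated from one end
    rel <- matrix(0, cfg$n_vbs, 3L)
    if (cfg$n_vbs > 1L)
      for (i in 2:cfg$n_vbs)
        rel[i, ] <- rel[i - 1, ] + cfg$offset + stats::rnorm(3, 0, cfg$offset_jitter)
    radii <- matrix(rep(cfg$radii, each = cfg$n_vbs), cfg$n_vbs, 3L) *
      (1 + matrix(stats::rnorm(3 * cfg$n_vbs, 0, cfg$radii_jitter), cfg$n_vbs, 3L))
    start <- cfg$start_center
    if (is.null(start)) {
      span_lo <- apply(rel - radii, 2, min)
      span_hi <- apply(rel + radii, 2, max)
      start <- (extent - (span_hi - span_lo)) / 2 - span_lo
    }
    centers <- sweep(rel, 2, start, "+")

    if (any(centers - radii < 0) || any(centers + radii > rep(extent, each = cfg$n_vbs)))
      stop("phantom chain exceeds the grid; enlarge the grid or shrink the chain")

    ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
    labels <- array(0L, d)
    for (i in seq_len(cfg$n_vbs)) {
      qx <- ((ax[[1]] - centers[i, 1]) / radii[i, 1])^2
      qy <- ((ax[[2]] - centers[i, 2]) / radii[i, 2])^2
      qz <- ((ax[[3]] - centers[i, 3]) / radii[i, 3])^2
      inside <- outer(outer(qx, qy, "+"), qz, "+") <= 1
      labels[inside] <- i
    }
    img <- array(cfg$bg, d)
    fgmask <- labels > 0L
    if (cfg$modality == "MR") {
      mod <- 1 + cfg$texture_amp *
        outer(outer(sin(2 * pi * ax[[1]] / 60), cos(2 * pi * ax[[2]] / 85), "+"),
              sin(2 * pi * ax[[3]] / 70), "+") / 3
      img[fgmask] <- (cfg$fg * mod)[fgmask]
    } else {
      img[fgmask] <- cfg$fg
    }
    if (cfg$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(d), 0, cfg$noise_sd), d)
  })
  vol <- vb_volume(img, sp, c(0, 0, 0), cfg$slice_axis)
  list(volume = vol,
       centers = vb_centers(centers, paste0("L", seq_len(cfg$n_vbs))),
       labels = vb_labels(labels, sp, c(0, 0, 0), cfg$slice_axis,
                          paste0("L", seq_len(cfg$n_vbs))))
}

#' Generate a phantom cohort
#'
#' Draws `n_subjects` phantoms with distinct per-subject seeds derived from
#' the master seed, so the chain-offset and radius jitter varies across
#' subjects the way inter-subject anatomy does. The cohort feeds
#' leave-one-out training/testing of the localization and segmentation
#' stages.
#'
#' @param cfg A [phantom_config] (its `seed` is ignored).
#' @param n_subjects Number of phantoms.
#' @param seed Master seed.
#' @return List of `n_subjects` phantom triples (see
#'   [generate_spine_phantom]).
#' @export
generate_cohort <- function(cfg, n_subjects, seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"), n_subjects >= 1L)
  lapply(seq_len(n_subjects), function(s) {
    ci <- cfg
    ci$seed <- sub_seed(seed, s)
    generate_spine_phantom(ci)
  })
}
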