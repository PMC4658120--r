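#' Block mean/variance feature configuration
#'
#' A sampled 3D patch is evenly divided into `k x k x k` blocks. For MR
#' patches the feature is the vector of block mean intensities, normalized to
#' unit L1 norm; CT patches additionally concatenate the block intensity
#' variances (to cope with the diffuse intensity values of CT), the variance
#' half L1-normalized separately. With the default `k = 4` this gives a
#' 64-dimensional feature for MR and a 128-dimensional feature for CT. The L1
#' normalization makes the feature invariant to global intensity scaling, so
#' no inter-scan intensity standardization is required.
#'
#' @param modality `"MR"` or `"CT"`.
#' @param patch_size Length-3 integer patch size in voxels; each component
#'   must be `>= k`.
#' @param k Blocks per axis (default 4).
#' @return An object of class `feature_config` with fields `modality`,
#'   `patch_size`, `k` and the feature dimension `d_f` (`k^3` for MR,
#'   `2 k^3` for CT).
#' @export
feature_config <- function(modality = c("MR", "CT"), patch_size, k = 4L) {
  modality <- match.arg(modality)
  patch_size <- as.integer(patch_size)
  k <- as.integer(k)
  if (length(patch_size) != 3L || any(patch_size < 1L))
    stop("`patch_size` must be 3 positive integers")
  if (k < 1L) stop("`k` must be >= 1")
  if (any(patch_size < k))
    stop("each patch dimension must be >= k (", k, ")")
  d_f <- if (modality == "CT") 2L * k^3 else k^3
  structure(list(modality = modality, patch_size = patch_size, k = k, d_f = d_f),
            class = "feature_config")
}

# Patch span for a center voxel c and size s: [c - floor(s/2), c + s - 1 - floor(s/2)].
patch_lo_margin <- function(s) s %/% 2L
patch_hi_margin <- function(s) s - 1L - s %/% 2L

# Valid patch-center range along each axis for a volume of dimensions d.
valid_center_range <- function(d, patch_size) {
  lo <- 1L + patch_lo_margin(patch_size)
  hi <- as.integer(d) - patch_hi_margin(patch_size)
  if (any(hi < lo)) stop("patch size ", paste(patch_size, collapse = "x"),
                         " does not fit in a ", paste(d, collapse = "x"), " volume")
  list(lo = lo, hi = hi)
}

# Block edge offsets (0-based, relative to the patch start) for one axis of
# length s split into k blocks: block b covers cells [e[b], e[b+1]-1].
# When s %% k != 0 the remainder goes to the last blocks.
block_edges <- function(s, k) {
  base <- s %/% k
  rem <- s %% k
  sizes <- c(rep(base, k - rem), rep(base + 1L, rem))
  cumsum(c(0L, sizes))
}

#' Block feature of a single patch
#'
#' Computes the block mean (and, for CT, block variance) feature of the patch
#' of size `cfg$patch_size` centered on voxel `center`, from precomputed
#' integral volumes. The cost is `k^3` (MR) or `2 k^3` (CT) box lookups,
#' independent of the patch volume. Blocks are enumerated x-fastest, then y,
#' then z. An all-zero patch yields the uniform mean vector (`1/k^3`) with
#' zero variances, keeping the feature finite.
#'
#' @param iv [build_integral_volumes()] result.
#' @param center Length-3 integer voxel index of the patch center.
#' @param cfg A [feature_config].
#' @return Numeric vector of length `cfg$d_f`.
#' @export
patch_feature <- function(iv, center, cfg) {
  drop(patch_features(iv, matrix(as.integer(center), 1L, 3L), cfg))
}

#' Block features of many patches at once
#'
#' Vectorized form of [patch_feature] for an `n x 3` matrix of patch centers.
#'
#' @inheritParams patch_feature
#' @param centers Integer `n x 3` matrix of patch-center voxel indices.
#' @return `n x d_f` numeric matrix.
#' @export
patch_features <- function(iv, centers, cfg) {
  stopifnot(inherits(iv, "integral_volumes"), inherits(cfg, "feature_config"))
  centers <- rbind3(centers)
  s <- cfg$patch_size
  k <- cfg$k
  d <- iv$dim
  start <- sweep(centers, 2, patch_lo_margin(s), "-")       # n x 3, patch start voxel
  if (any(start < 1L) || any(sweep(start, 2, s - 1L, "+") > rep(d, each = nrow(start))))
    stop("patch exceeds volume bounds for at least one center")

  edges <- lapply(1:3, function(a) block_edges(s[a], k))
  D <- d + 1L                                               # padded integral dims
  # base linear index (1-based) of the padded-array cell at the patch start
  base <- start[, 1] + (start[, 2] - 1) * D[1] + (start[, 3] - 1) * D[1] * D[2]
  strides <- c(1, D[1], D[1] * D[2])

  n <- nrow(centers)
  nb <- k^3
  ct <- cfg$modality == "CT"
  sums_i <- matrix(0, n, nb)
  sums_s <- if (ct) matrix(0, n, nb) else NULL
  nv <- numeric(nb)
  Iv <- iv$I; Sv <- iv$S
  b <- 0L
  for (bz in seq_len(k)) for (by in seq_len(k)) for (bx in seq_len(k)) {
    b <- b + 1L
    off <- list(c(edges[[1]][bx], edges[[1]][bx + 1L]),
                c(edges[[2]][by], edges[[2]][by + 1L]),
                c(edges[[3]][bz], edges[[3]][bz + 1L]))
    nv[b] <- prod(vapply(off, diff, numeric(1)))
    acc_i <- numeric(n)
    acc_s <- if (ct) numeric(n) else NULL
    for (cx in 1:2) for (cy in 1:2) for (cz in 1:2) {
      sgn <- (-1)^(3 - (cx + cy + cz - 3))                  # (-1)^(number of low corners)
      lin <- base + off[[1]][cx] * strides[1] +
                    off[[2]][cy] * strides[2] +
                    off[[3]][cz] * strides[3]
      acc_i <- acc_i + sgn * Iv[lin]
      if (ct) acc_s <- acc_s + sgn * Sv[lin]
    }
    sums_i[, b] <- acc_i
    if (ct) sums_s[, b] <- acc_s
  }

  means <- sweep(sums_i, 2, nv, "/")
  tot <- rowSums(abs(means))
  zero <- tot <= 0
  feat <- means / ifelse(tot > 0, tot, 1)
  if (any(zero)) feat[zero, ] <- 1 / nb
  if (ct) {
    ex2 <- sweep(sums_s, 2, nv, "/")
    vars <- pmax(ex2 - means^2, 0)
    vtot <- rowSums(vars)
    vfeat <- vars / ifelse(vtot > 0, vtot, 1)               # constant patch: zero variances
    feat <- cbind(feat, vfeat)
  }
  feat
}
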