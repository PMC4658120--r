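cube_mask <- function(d, lo, hi) {
  arr <- array(0L, d)
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  arr
}

test_that("the spatial prior reduces to the aligned indicator for one mask, bandwidth 0", {
  d <- c(20, 20, 20)
  lab <- vb_labels(cube_mask(d, c(8, 7, 9), c(12, 13, 11)), c(1, 1, 1))
  ctr <- compute_centers(lab)
  pr <- learn_spatial_prior(list(lab), list(ctr), 1L, half_extent = c(5, 5, 5),
                            bandwidth = 0)
  # prior grid is 11^3 centered on the body center; the aligned indicator is
  # the cube shifted so its centroid sits at the grid center
  expect_true(all(pr$data %in% c(0, 1)))
  expect_equal(pr$data[6, 6, 6], 1)
  w <- which(pr$data == 1, arr.ind = TRUE)
  expect_equal(sum(pr$data), sum(lab$data))
  # identical trainers: unanimity, deep interior stays ~1 after smoothing
  lab_big <- vb_labels(cube_mask(d, c(6, 6, 6), c(14, 14, 14)), c(1, 1, 1))
  ctr_big <- compute_centers(lab_big)
  pr2 <- learn_spatial_prior(list(lab_big, lab_big, lab_big),
                             list(ctr_big, ctr_big, ctr_big), 1L,
                             half_extent = c(6, 6, 6), bandwidth = 1)
  cidx <- pr2$half_n + 1L
  expect_gt(pr2$data[cidx[1], cidx[2], cidx[3]], 0.95)
  expect_true(all(pr2$data >= 0 & pr2$data <= 1))
  expect_error(learn_spatial_prior(list(lab), list(ctr), 3L, c(5, 5, 5)),
               "absent")
})

test_that("the smoothed prior equals a brute-force kernel-weighted average", {
  set.seed(31)
  d <- c(16, 16, 16)
  labs <- list(); ctrs <- list()
  for (s in 1:3) {
    lo <- c(5, 5, 5) + sample(-1:1, 3, TRUE)
    labs[[s]] <- vb_labels(cube_mask(d, lo, lo + c(4, 5, 3)), c(1, 1, 1))
    ctrs[[s]] <- compute_centers(labs[[s]])
  }
  bw <- 1.5
  pr <- learn_spatial_prior(labs, ctrs, 1L, half_extent = c(5, 5, 5), bandwidth = bw)
  raw <- learn_spatial_prior(labs, ctrs, 1L, half_extent = c(5, 5, 5), bandwidth = 0)
  # direct Parzen oracle: truncated-Gaussian weighted average of the aligned
  # indicator average, separably per axis with boundary renormalization
  r <- ceiling(3 * bw)
  w <- dnorm(-r:r, sd = bw)
  dims <- dim(raw$data)
  oracle_at <- function(v) {
    acc <- raw$data
    for (a in 1:3) {
      out <- array(0, dims)
      for (i in seq_len(dims[a])) {
        j <- max(1, i - r):min(dims[a], i + r)
        wt <- w[j - i + r + 1]; wt <- wt / sum(wt)
        sl <- lapply(dims, seq_len); sl[[a]] <- j
        picked <- do.call(`[`, c(list(acc), sl, list(drop = FALSE)))
        idx_out <- lapply(dims, seq_len); idx_out[[a]] <- i
        out <- do.call(`[<-`, c(list(out), idx_out,
                                list(apply(picked, setdiff(1:3, a), function(x) sum(x * wt)))))
      }
      acc <- out
    }
    acc[v[1], v[2], v[3]]
  }
  set.seed(32)
  for (q in 1:20) {
    v <- c(sample(dims[1], 1), sample(dims[2], 1), sample(dims[3], 1))
    expect_equal(pr$data[v[1], v[2], v[3]], oracle_at(v), tolerance = 1e-9)
  }
})

test_that("the appearance likelihood averages the trees and honours the gate", {
  v <- random_volume(c(20, 20, 20), seed = 33)
  set.seed(34)
  feats <- matrix(runif(100 * 64), 100, 64)
  labels <- as.integer(feats[, 1] > 0.5)
  samples <- structure(list(features = feats, labels = labels),
                       class = "segmentation_samples")
  forest <- train_voxel_classifier(samples, forest_config(n_trees = 7, seed = 6))
  cfg <- feature_config("MR", c(8, 8, 8))
  box <- list(lo = c(6, 6, 6), hi = c(12, 12, 12))
  ps <- array(runif(prod(box$hi - box$lo + 1)), box$hi - box$lo + 1)
  ps[1, 1, 1] <- 0.05
  la <- appearance_likelihood(forest, v, box, ps, cfg, prefilter = 0.1)
  expect_equal(attr(la, "n_evaluated"), sum(ps > 0.1))
  expect_equal(la[1, 1, 1], 0)          # gated voxel: never evaluated
  expect_true(all(la[ps <= 0.1] == 0))
  # per-tree averaging oracle at random evaluated voxels
  iv <- build_integral_volumes(v)
  sel <- which(ps > 0.1)
  set.seed(35)
  for (q in sample(sel, 10)) {
    idx <- arrayInd(q, dim(ps)) + rep(box$lo - 1L, each = 1)
    f <- patch_feature(iv, as.integer(idx), cfg)
    pt <- predict_foreground(forest, matrix(f, 1), per_tree = TRUE)
    expect_equal(la[q], mean(pt), tolerance = 1e-12)
  }
})

test_that("posterior fusion is the stated convex combination", {
  ps <- array(1, c(3, 3, 3)); la <- array(1, c(3, 3, 3))
  expect_equal(fuse_posterior(ps, la)$data, array(1, c(3, 3, 3)))
  ps2 <- array(0.8, c(2, 2, 2)); la2 <- array(0.5, c(2, 2, 2))
  expect_equal(fuse_posterior(ps2, la2)$data[1], 0.4 * 0.8 + 0.6 * 0.5)
  expect_error(fuse_posterior(array(1, c(2, 2, 2)), array(1, c(3, 3, 3))), "differ")
  # L stays in [0,1] whenever alpha + beta = 1
  set.seed(36)
  for (r in 1:20) {
    a <- runif(1)
    L <- fuse_posterior(array(runif(27), c(3, 3, 3)),
                        array(runif(27), c(3, 3, 3)), a, 1 - a)$data
    expect_true(all(L >= 0 & L <= 1))
  }
})

test_that("binarization thresholds at 0.5 inclusive and keeps the largest component", {
  arr <- array(0, c(10, 10, 10))
  expect_true(all(!binarize_posterior(arr)))
  arr[2:3, 2:3, 2:3] <- 0.9           # 8 voxels... this one loses
  arr[6:8, 6:8, 6:8] <- 0.7           # 27 voxels... this one wins
  m <- binarize_posterior(arr)
  expect_equal(sum(m), 27L)
  expect_true(all(m[6:8, 6:8, 6:8]))
  # exact-0.5 voxels are included
  arr2 <- array(0, c(4, 4, 4)); arr2[2, 2, 2] <- 0.5
  expect_equal(sum(binarize_posterior(arr2)), 1L)
  arr2[2, 2, 2] <- 0.4999
  expect_equal(sum(binarize_posterior(arr2)), 0L)
  # diagonal voxels connect under 26- but not 6-connectivity
  arr3 <- array(0, c(5, 5, 5))
  arr3[2, 2, 2] <- 1; arr3[3, 3, 3] <- 1; arr3[1, 5, 1] <- 1
  expect_equal(sum(binarize_posterior(arr3, connectivity = 26)), 2L)
  expect_equal(sum(binarize_posterior(arr3, connectivity = 6)), 1L)
})

test_that("a constant-1 forest reduces segmentation to the thresholded prior", {
  ph <- generate_spine_phantom(small_phantom_config(seed = 61))
  labs <- list(ph$labels); ctrs <- list(ph$centers)
  hw <- roi_half_extent(labs, ctrs, 2L, dilate = 0.25)
  prior <- learn_spatial_prior(labs, ctrs, 2L, hw, bandwidth = 2)
  # degenerate forest: every leaf predicts foreground
  set.seed(37)
  feats <- matrix(runif(60 * 64), 60, 64)
  samples <- structure(list(features = feats,
                            labels = c(rep(1L, 58), 0L, 0L)),
                       class = "segmentation_samples")
  one_forest <- train_voxel_classifier(samples, forest_config(n_trees = 3, seed = 7,
                                                              min_leaf = 60,
                                                              bootstrap = FALSE))
  params <- segment_params("MR", forest = forest_config(n_trees = 3))
  model <- list(prior = prior, half_extent = hw, forest = one_forest)
  # with La ~ 58/60 everywhere, L = 0.4 Ps + 0.6 La >= 0.5 iff Ps >= (0.5 - 0.58)/0.4
  mask <- segment_vb(ph$volume, ph$centers$centers[2, ], model, params)
  la_const <- predict_foreground(one_forest, feats[1:2, ])
  expect_equal(la_const, rep(58 / 60, 2), tolerance = 1e-12)
  placed <- vbforest:::place_prior(prior, ph$volume, ph$centers$centers[2, ])
  ref <- array(FALSE, dim(ph$volume$data))
  sub <- (0.4 * placed$ps + 0.6 * (58 / 60) >= 0.5) & (placed$ps > 0.1)
  # clip to where a patch fits, as the likelihood path does
  sub_full <- array(FALSE, dim(ph$volume$data))
  sub_full[placed$box$lo[1]:placed$box$hi[1],
           placed$box$lo[2]:placed$box$hi[2],
           placed$box$lo[3]:placed$box$hi[3]] <- sub
  keep <- vbforest:::crop_array(sub_full, placed$box)
  ref[placed$box$lo[1]:placed$box$hi[1],
      placed$box$lo[2]:placed$box$hi[2],
      placed$box$lo[3]:placed$box$hi[3]] <-
    binarize_posterior(keep + 0, threshold = 0.5, connectivity = 26)
  # the mask from the pipeline equals the prior-only reference wherever the
  # patch fits (the ROI sits well inside the phantom here)
  expect_equal(mask, ref)
})

test_that("every foreground voxel of a segmentation has posterior >= 0.5, one component", {
  set.seed(38)
  arr <- array(runif(14 * 14 * 14, 0, 0.8), c(14, 14, 14))
  arr[4:9, 4:9, 4:9] <- runif(216, 0.45, 1)
  m <- binarize_posterior(arr)
  expect_true(all(arr[m] >= 0.5))
  lab <- vbforest:::cpp_largest_component(m, dim(m), 26L)
  expect_identical(lab, m)  # a single component survives by construction
})
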