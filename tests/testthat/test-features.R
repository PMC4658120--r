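test_that("integral volumes reproduce box sums of an all-ones volume", {
  iv <- build_integral_volumes(vb_volume(array(1, c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(iv$I[5, 5, 5], 64)
  expect_identical(iv$I, iv$S)  # 1^2 = 1
  expect_equal(box_sum(iv, c(1, 1, 1), c(4, 4, 4)), 64)
})

test_that("box sums match exhaustive voxel loops on random boxes", {
  v <- random_volume(c(9, 7, 11), seed = 11)
  iv <- build_integral_volumes(v)
  set.seed(12)
  for (r in 1:50) {
    lo <- c(sample(9, 1), sample(7, 1), sample(11, 1))
    hi <- pmin(lo + c(sample(0:4, 1), sample(0:4, 1), sample(0:4, 1)), c(9, 7, 11))
    brute <- sum(v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    expect_equal(box_sum(iv, lo, hi), brute, tolerance = 1e-12)
  }
  expect_error(box_sum(iv, c(0, 1, 1), c(2, 2, 2)), "bounds|box")
})

test_that("block statistics match brute-force mean and variance", {
  v <- random_volume(c(8, 8, 8), seed = 5)
  iv <- build_integral_volumes(v)

  const <- build_integral_volumes(vb_volume(array(3.7, c(5, 5, 5)), c(1, 1, 1)))
  st <- block_stats(const, c(2, 2, 2), c(4, 4, 4))
  expect_equal(unname(st["mean"]), 3.7)
  expect_equal(unname(st["variance"]), 0)

  st1 <- block_stats(iv, c(3, 4, 5), c(3, 4, 5))
  expect_equal(unname(st1["mean"]), v$data[3, 4, 5])
  expect_equal(unname(st1["variance"]), 0)

  st2 <- block_stats(iv, c(2, 1, 4), c(4, 5, 5))
  x <- as.vector(v$data[2:4, 1:5, 4:5])
  expect_equal(unname(st2["mean"]), mean(x), tolerance = 1e-9)
  expect_equal(unname(st2["variance"]), mean(x^2) - mean(x)^2, tolerance = 1e-9)
})

test_that("feature dimensions follow the modality (k^3 for MR, 2k^3 for CT)", {
  cfg_mr <- feature_config("MR", c(16, 20, 20), k = 4)
  cfg_ct <- feature_config("CT", c(12, 20, 20), k = 4)
  expect_equal(cfg_mr$d_f, 64L)
  expect_equal(cfg_ct$d_f, 128L)
  v <- random_volume(c(24, 24, 24), seed = 2)
  iv <- build_integral_volumes(v)
  expect_length(patch_feature(iv, c(12, 12, 12), cfg_mr), 64L)
  expect_length(patch_feature(iv, c(12, 12, 12), cfg_ct), 128L)
  expect_error(feature_config("MR", c(3, 8, 8), k = 4), ">= k")
})

test_that("a constant patch yields the uniform mean vector", {
  iv <- build_integral_volumes(vb_volume(array(9, c(10, 10, 10)), c(1, 1, 1)))
  f <- patch_feature(iv, c(5, 5, 5), feature_config("MR", c(8, 8, 8)))
  expect_equal(f, rep(1 / 64, 64))
  fc <- patch_feature(iv, c(5, 5, 5), feature_config("CT", c(8, 8, 8)))
  expect_equal(fc[1:64], rep(1 / 64, 64))
  expect_equal(fc[65:128], rep(0, 64))  # zero variance everywhere
  # all-zero patch stays finite and uniform
  iv0 <- build_integral_volumes(vb_volume(array(0, c(10, 10, 10)), c(1, 1, 1)))
  expect_equal(patch_feature(iv0, c(5, 5, 5), feature_config("MR", c(8, 8, 8))),
               rep(1 / 64, 64))
})

test_that("patch features equal the direct raw-voxel computation", {
  v <- random_volume(c(20, 22, 18), seed = 8)
  iv <- build_integral_volumes(v)
  # uneven patch sizes exercise the remainder-to-last-blocks partition
  for (ps in list(c(8, 8, 8), c(9, 10, 7), c(16, 20, 12))) {
    cfg <- feature_config("CT", ps, k = 4)
    ctr <- c(10, 11, 9)
    f <- patch_feature(iv, ctr, cfg)
    st0 <- ctr - ps %/% 2
    e <- lapply(1:3, function(a) {
      base <- ps[a] %/% 4; rem <- ps[a] %% 4
      cumsum(c(0L, c(rep(base, 4 - rem), rep(base + 1L, rem))))
    })
    mns <- vars <- numeric(64); b <- 0
    for (bz in 1:4) for (by in 1:4) for (bx in 1:4) {
      b <- b + 1
      xx <- v$data[(st0[1] + e[[1]][bx]):(st0[1] + e[[1]][bx + 1] - 1),
                   (st0[2] + e[[2]][by]):(st0[2] + e[[2]][by + 1] - 1),
                   (st0[3] + e[[3]][bz]):(st0[3] + e[[3]][bz + 1] - 1)]
      mns[b] <- mean(xx); vars[b] <- mean(xx^2) - mean(xx)^2
    }
    oracle <- c(mns / sum(abs(mns)), vars / sum(vars))
    expect_equal(f, oracle, tolerance = 1e-9)
  }
})

test_that("features are invariant to global intensity scaling", {
  v <- random_volume(c(16, 16, 16), seed = 4)
  cfg <- feature_config("CT", c(8, 8, 8))
  f1 <- patch_feature(build_integral_volumes(v), c(8, 8, 8), cfg)
  for (lambda in c(0.2, 3, 117)) {
    v2 <- vb_volume(v$data * lambda, v$spacing)
    f2 <- patch_feature(build_integral_volumes(v2), c(8, 8, 8), cfg)
    expect_equal(f2, f1, tolerance = 1e-9)
  }
})

test_that("per-block cost is a fixed number of box lookups, independent of patch size", {
  v <- random_volume(c(40, 40, 40), seed = 6)
  iv <- build_integral_volumes(v)
  counts <- vapply(list(c(8, 8, 8), c(16, 16, 16), c(32, 32, 32)), function(ps) {
    cfg <- feature_config("MR", ps)
    vbforest:::reset_box_count()
    for (b in 1:64) {
      e <- vbforest:::block_edges(ps[1], 4)
      block_stats(iv, c(20, 20, 20) - ps %/% 2 + 1, c(20, 20, 20) - ps %/% 2 + e[2])
    }
    vbforest:::box_count()
  }, numeric(1))
  expect_true(all(counts == counts[1]))  # 2 lookups (I and S) per block, always
})
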