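test_that("localization distance is the Euclidean norm of the center offset", {
  expect_equal(localization_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(localization_error(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(localization_error(c(1, 1, 1), c(0, 0, 0)), sqrt(3))
})

test_that("MLD uses the mean and SD the population divisor", {
  expect_equal(mld_sd(c(2, 2, 2)), c(mld = 2, sd = 0))
  expect_equal(mld_sd(c(1, 3)), c(mld = 2, sd = 1))  # population: sqrt(2/2)
  set.seed(41)
  r <- runif(37, 0, 5)
  ms <- mld_sd(r)
  expect_equal(unname(ms["mld"]), mean(r))
  expect_equal(unname(ms["sd"]), sqrt(sum((r - mean(r))^2) / length(r)))
  expect_equal(mld_sd(sample(r)), ms)  # order invariance
  expect_error(mld_sd(numeric(0)), "empty")
})

test_that("detection rate counts the boundary as success and is monotone in t", {
  errors <- c(rep(1, 123), rep(3, 34), rep(5, 4))  # 161 centers
  expect_equal(round(detection_rate(errors, 2.0), 1), 76.4)
  expect_equal(round(detection_rate(errors, 4.0), 1), 97.5)
  expect_equal(detection_rate(errors, 6.0), 100)
  expect_equal(detection_rate(c(1, 2, 3), 2), 100 * 2 / 3)  # <= t, not < t
  ts <- seq(0.5, 6, by = 0.25)
  rates <- vapply(ts, function(t) detection_rate(errors, t), numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("Dice behaves on identical, disjoint and partial overlaps", {
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 100)
  b <- array(FALSE, c(6, 6, 6)); b[5, 5, 5] <- TRUE
  expect_equal(dice(a, b), 0)
  a2 <- array(FALSE, c(6, 6, 6)); a2[1:2, 1:2, 1:2] <- TRUE       # 8 voxels
  b2 <- array(FALSE, c(6, 6, 6)); b2[1:2, 1:2, 2:3] <- TRUE       # 8, overlap 4
  expect_equal(dice(a2, b2), 50)
  expect_equal(dice(array(FALSE, c(3, 3, 3)), array(FALSE, c(3, 3, 3))), 100)
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "grids")
})

test_that("surface distances match hand geometry and the brute-force oracle", {
  a <- array(FALSE, c(6, 6, 6)); a[3, 3, 3] <- TRUE
  expect_equal(surface_distances(a, a, spacing = c(1, 1, 1)),
               c(aad = 0, hsd = 0))
  b <- array(FALSE, c(6, 6, 6)); b[4, 3, 3] <- TRUE
  sd1 <- surface_distances(a, b, spacing = c(1, 1, 1))
  expect_equal(unname(sd1["hsd"]), 1.0)
  expect_equal(unname(sd1["aad"]), 1.0)

  set.seed(43)
  for (r in 1:8) {
    a <- array(runif(5 * 6 * 5) > 0.6, c(5, 6, 5))
    g <- array(runif(5 * 6 * 5) > 0.6, c(5, 6, 5))
    if (!any(a) || !any(g)) next
    sp <- c(1, 2, 1.5)
    got <- surface_distances(a, g, spacing = sp)
    pa <- vbforest:::surface_points(a, sp)
    pg <- vbforest:::surface_points(g, sp)
    # O(n^2) all-pairs oracle over the same vertex sets
    dmat <- as.matrix(dist(rbind(pa, pg)))[seq_len(nrow(pa)),
                                           nrow(pa) + seq_len(nrow(pg)),
                                           drop = FALSE]
    aad <- mean(apply(dmat, 1, min))
    hsd <- max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
    expect_equal(unname(got["aad"]), aad, tolerance = 1e-12)
    expect_equal(unname(got["hsd"]), hsd, tolerance = 1e-12)
  }
  expect_error(surface_distances(array(FALSE, c(3, 3, 3)),
                                 array(TRUE, c(3, 3, 3)), spacing = c(1, 1, 1)),
               "empty")
})

test_that("AAD is directional (can be asymmetric) while HSD is symmetric", {
  a <- array(FALSE, c(8, 8, 8)); a[4, 4, 4] <- TRUE
  g <- array(FALSE, c(8, 8, 8)); g[2:7, 2:7, 2:7] <- TRUE
  sp <- c(1, 1, 1)
  ag <- surface_distances(a, g, spacing = sp)
  ga <- surface_distances(g, a, spacing = sp)
  expect_false(isTRUE(all.equal(ag["aad"], ga["aad"])))
  expect_equal(unname(ag["hsd"]), unname(ga["hsd"]))
  sym <- surface_distances(a, g, spacing = sp, symmetric = TRUE)
  expect_equal(unname(sym["aad"]),
               unname((ag["aad"] + ga["aad"]) / 2))
})

test_that("dice(A, A) = 100 and zero distances over random masks", {
  set.seed(44)
  for (r in 1:100) {
    a <- array(runif(4 * 4 * 4) > 0.5, c(4, 4, 4))
    expect_equal(dice(a, a), 100)
    if (any(a)) {
      sd0 <- surface_distances(a, a, spacing = c(1, 1, 1))
      expect_equal(unname(sd0), c(0, 0))
    }
  }
})

test_that("mid-sagittal metrics equal 3D metrics for a one-slice volume", {
  set.seed(45)
  a <- array(FALSE, c(1, 9, 9)); a[1, 3:6, 3:7] <- TRUE
  g <- array(FALSE, c(1, 9, 9)); g[1, 4:7, 3:6] <- TRUE
  sp <- c(2, 1.25, 1.25)
  m2 <- midsagittal_metrics(a, g, center = c(0, 5, 5), sagittal_axis = 1,
                            spacing = sp, origin = c(0, 0, 0))
  m3 <- surface_distances(a, g, spacing = sp)
  expect_equal(m2$dice, dice(a, g))
  expect_equal(m2$aad, unname(m3["aad"]))
  expect_equal(m2$hsd, unname(m3["hsd"]))

  # identical masks: perfect on any slice
  m0 <- midsagittal_metrics(a, a, c(0, 5, 5), 1, sp)
  expect_equal(m0$dice, 100)
  expect_equal(m0$aad, 0)
  expect_equal(m0$hsd, 0)
  expect_error(midsagittal_metrics(a, g, c(99, 5, 5), 1, sp), "outside")
})

test_that("2D metrics match a brute-force pixel/contour computation", {
  a <- array(FALSE, c(3, 12, 12)); a[2, 3:8, 4:9] <- TRUE
  g <- array(FALSE, c(3, 12, 12)); g[2, 5:10, 4:8] <- TRUE
  sp <- c(2, 1, 1)
  m2 <- midsagittal_metrics(a, g, center = c(2, 6, 6), sagittal_axis = 1,
                            spacing = sp, origin = c(0, 0, 0))
  a2 <- a[2, , ]; g2 <- g[2, , ]
  expect_equal(m2$dice, 200 * sum(a2 & g2) / (sum(a2) + sum(g2)))
  bound2d <- function(m) {
    pts <- NULL
    for (i in 1:12) for (j in 1:12) if (m[i, j]) {
      nb <- c(if (i > 1) !m[i - 1, j], if (i < 12) !m[i + 1, j],
              if (j > 1) !m[i, j - 1], if (j < 12) !m[i, j + 1])
      if (any(nb)) pts <- rbind(pts, c(i - 1, j - 1))
    }
    pts
  }
  pa <- bound2d(a2); pg <- bound2d(g2)
  dmat <- as.matrix(dist(rbind(pa, pg)))[seq_len(nrow(pa)),
                                         nrow(pa) + seq_len(nrow(pg)),
                                         drop = FALSE]
  expect_equal(m2$aad, mean(apply(dmat, 1, min)), tolerance = 1e-12)
  expect_equal(m2$hsd, max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min))),
               tolerance = 1e-12)
})

test_that("cohort reports pool errors over images and vertebrae", {
  gt <- list(vb_centers(rbind(c(0, 0, 0), c(0, 30, 0))),
             vb_centers(rbind(c(0, 0, 0), c(0, 30, 0))))
  pred <- list(vb_centers(rbind(c(3, 4, 0), c(0, 30, 1))),
               vb_centers(rbind(c(0, 0, 0), c(0, 28, 0))))
  rep <- localization_report(pred, gt, thresholds = c(2, 4, 6))
  expect_equal(dim(rep$errors), c(2L, 2L))
  expect_equal(sort(as.numeric(rep$errors)), c(0, 1, 2, 5))
  expect_equal(rep$mld, 2)
  expect_equal(unname(rep$rates["t2"]), 75)
  expect_equal(unname(rep$rates["t6"]), 100)
})
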