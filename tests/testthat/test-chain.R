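bump_response <- function(d, spacing, centers_mm, amps, sd_mm = 3) {
  g <- response_grid(vb_volume(array(0, d), spacing))
  pos <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing[a])
  arr <- array(0, d)
  for (i in seq_along(amps)) {
    qx <- (pos[[1]] - centers_mm[i, 1])^2
    qy <- (pos[[2]] - centers_mm[i, 2])^2
    qz <- (pos[[3]] - centers_mm[i, 3])^2
    arr <- arr + amps[i] * exp(-outer(outer(qx, qy, "+"), qz, "+") / (2 * sd_mm^2))
  }
  vbforest:::make_response(arr, g)
}

centers_ann <- function(mat) vb_centers(mat)

test_that("the chain prior matches sample statistics and applies the floor", {
  # identical offsets in every trainer: mean is the offset, covariance floors
  off <- c(1, 30, -2)
  anns <- lapply(1:4, function(s)
    centers_ann(rbind(c(0, 0, 0) + s, c(0, 0, 0) + s + off,
                      c(0, 0, 0) + s + 2 * off)))
  pr <- learn_chain_prior(anns, var_floor = 1)
  expect_equal(pr$m, 3L)
  expect_equal(dim(pr$mu), c(2L, 3L))
  for (i in 1:2) {
    expect_equal(unname(pr$mu[i, ]), off)
    expect_equal(pr$sigma[, , i], diag(3))
  }

  # random offsets with ample spread: matches brute-force sample statistics
  set.seed(13)
  base <- matrix(c(0, 0, 0, 0, 30, 0, 0, 60, 0, 0, 90, 0), 4, 3, byrow = TRUE)
  anns2 <- lapply(1:12, function(s) centers_ann(base + matrix(rnorm(12, 0, 4), 4, 3)))
  pr2 <- learn_chain_prior(anns2, var_floor = 1)
  for (i in 1:3) {
    offs <- t(vapply(anns2, function(a) a$centers[i + 1, ] - a$centers[i, ],
                     numeric(3)))
    expect_equal(unname(pr2$mu[i, ]), unname(colMeans(offs)), tolerance = 1e-12)
    expect_equal(pr2$sigma[, , i], unname(stats::cov(offs)), tolerance = 1e-9)
  }
  expect_error(learn_chain_prior(anns[1]), "at least 2")
})

test_that("single-vertebra decoding returns the global response argmax", {
  r <- bump_response(c(10, 12, 14), c(1, 1, 1),
                     matrix(c(4, 7, 9), 1, 3), amps = 1)
  dec <- decode_center_chain(list(r), prior = NULL, k_candidates = 10)
  expect_equal(unname(dec$centers[1, ]), c(4, 7, 9))
})

test_that("flat responses with a tight prior reproduce the prior offsets", {
  d <- c(6, 20, 6); sp <- c(1, 1, 1)
  g <- response_grid(vb_volume(array(0, d), sp))
  flat <- vbforest:::make_response(array(1, d), g)
  anns <- lapply(1:3, function(s) centers_ann(rbind(c(3, 2, 3), c(3, 8, 3), c(3, 14, 3))))
  pr <- learn_chain_prior(anns, var_floor = 0.05)
  dec <- decode_center_chain(list(flat, flat, flat), pr, k_candidates = Inf)
  o1 <- dec$centers[2, ] - dec$centers[1, ]
  o2 <- dec$centers[3, ] - dec$centers[2, ]
  expect_equal(unname(o1), c(0, 6, 0))
  expect_equal(unname(o2), c(0, 6, 0))
})

test_that("Viterbi decoding equals exhaustive enumeration on random instances", {
  set.seed(17)
  for (trial in 1:12) {
    m <- sample(2:4, 1)
    k <- sample(2:6, 1)
    d <- c(8, 14, 8); sp <- c(1, 1.5, 1)
    true <- cbind(runif(m, 2, 5), seq(2, 18, length.out = m), runif(m, 2, 5))
    amps <- runif(m, 0.5, 2)
    responses <- lapply(seq_len(m), function(i) {
      noise <- matrix(runif(3 * (k + 1), 0, 12), k + 1, 3)
      noise[, 2] <- runif(k + 1, 0, 19)
      bump_response(d, sp, rbind(true[i, , drop = FALSE], noise),
                    amps = c(amps[i], runif(k, 0.1, 1.5)))
    })
    anns <- lapply(1:4, function(s)
      centers_ann(true + matrix(rnorm(3 * m, 0, 1.5), m, 3)))
    pr <- learn_chain_prior(anns, var_floor = 1)
    cand <- lapply(responses, find_candidates, k = k)
    dec <- decode_center_chain(responses, pr, k_candidates = k)
    oracle <- enumerate_best_chain(cand, pr)
    for (i in seq_len(m))
      expect_equal(unname(dec$centers[i, ]),
                   unname(cand[[i]]$positions[oracle[i], ]))
  }
})

test_that("decoding is invariant to positive rescaling of one response", {
  set.seed(23)
  d <- c(8, 16, 8); sp <- c(1, 1, 1)
  true <- rbind(c(4, 3, 4), c(4, 8, 4), c(4, 13, 4))
  responses <- lapply(1:3, function(i)
    bump_response(d, sp, rbind(true[i, , drop = FALSE],
                               matrix(runif(6, 0, 14), 2, 3)),
                  amps = c(1, 0.4, 0.3)))
  anns <- lapply(1:3, function(s) centers_ann(true + matrix(rnorm(9, 0, 1), 3, 3)))
  pr <- learn_chain_prior(anns)
  base <- decode_center_chain(responses, pr, k_candidates = 5)
  responses[[2]]$data <- responses[[2]]$data * 37.5
  scaled <- decode_center_chain(responses, pr, k_candidates = 5)
  expect_equal(base$centers, scaled$centers)
})

test_that("chain decoding corrects a repetitive-pattern misassignment", {
  # three bodies 10 mm apart along y; the middle body's response is corrupted
  # so its argmax sits on its caudal neighbour, as the repetitive pattern does
  d <- c(12, 36, 12); sp <- c(1, 1, 1)
  true <- rbind(c(5, 8, 5), c(5, 18, 5), c(5, 28, 5))
  r1 <- bump_response(d, sp, true[1, , drop = FALSE], 1)
  r3 <- bump_response(d, sp, true[3, , drop = FALSE], 1)
  r2 <- bump_response(d, sp, rbind(true[3, ], true[2, ]), c(1, 0.6))
  expect_equal(unname(vbforest:::response_argmax(r2)), unname(true[3, ]))  # misassigned
  anns <- lapply(1:4, function(s)
    centers_ann(true + matrix(rnorm(9, 0, 0.8), 3, 3)))
  pr <- learn_chain_prior(anns, var_floor = 1)
  dec <- decode_center_chain(list(r1, r2, r3), pr, k_candidates = 6)
  for (i in 1:3)
    expect_lt(sqrt(sum((dec$centers[i, ] - true[i, ])^2)), 2)
  # and the corrected chain is the exhaustive optimum
  cand <- lapply(list(r1, r2, r3), find_candidates, k = 6)
  oracle <- enumerate_best_chain(cand, pr)
  for (i in 1:3)
    expect_equal(unname(dec$centers[i, ]), unname(cand[[i]]$positions[oracle[i], ]))
})
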