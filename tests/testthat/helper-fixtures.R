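# Shared fixtures, built in code at test time.

# Small phantom configuration: 3 bodies on a 32 x 96 x 96 grid, keeping the
# full pipeline exercisable in seconds.
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(n_vbs = 3L, grid_dim = c(32L, 96L, 96L),
                 spacing = c(2, 1.25, 1.25), seed = seed, ...)
}

random_volume <- function(dim, spacing = c(1, 1, 1), seed = 1L, origin = c(0, 0, 0)) {
  set.seed(seed)
  vb_volume(array(stats::runif(prod(dim)), dim), spacing, origin)
}

random_vote_set <- function(n, lo, hi, seed = 1L) {
  set.seed(seed)
  structure(list(votes = cbind(stats::runif(n, lo[1], hi[1]),
                               stats::runif(n, lo[2], hi[2]),
                               stats::runif(n, lo[3], hi[3])),
                 weights = rep(1, n)),
            class = "vote_set")
}

# Independent brute-force Gaussian transform (R double loop, mm -> grid units
# conversion done here on purpose so it does not share code with the package).
brute_gauss <- function(votes, grid, h) {
  src <- sweep(sweep(votes$votes, 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
  d <- grid$dim
  out <- array(0, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    dd <- (src[, 1] - x)^2 + (src[, 2] - y)^2 + (src[, 3] - z)^2
    out[x, y, z] <- sum(votes$weights * exp(-dd / h^2))
  }
  out
}

# Exhaustive best chain over candidate sets (enumeration oracle for the DP).
enumerate_best_chain <- function(cand, prior) {
  m <- length(cand)
  obs <- lapply(cand, function(cc) log(cc$values / sum(cc$values)))
  ks <- vapply(cand, function(cc) length(cc$values), integer(1))
  grid <- as.matrix(expand.grid(lapply(ks, seq_len)))
  best <- -Inf; best_path <- NULL
  for (r in seq_len(nrow(grid))) {
    path <- grid[r, ]
    s <- obs[[1]][path[1]]
    for (i in seq_len(m - 1)) {
      delta <- cand[[i + 1]]$positions[path[i + 1], ] - cand[[i]]$positions[path[i], ]
      S <- prior$sigma[, , i]
      dv <- delta - prior$mu[i, ]
      s <- s + obs[[i + 1]][path[i + 1]] -
        0.5 * (3 * log(2 * pi) + log(det(S)) + drop(t(dv) %*% solve(S) %*% dv))
    }
    if (s > best + 1e-12) { best <- s; best_path <- path }
  }
  best_path
}

# A deliberately constant regression "forest": every tree predicts d0.
constant_regressor <- function(d0, cfg, n = 60, d_f = 64, seed = 1L) {
  set.seed(seed)
  feats <- matrix(stats::runif(n * d_f), n, d_f)
  samples <- structure(list(features = feats,
                            displacements = matrix(rep(d0, each = n), n, 3),
                            patch_centers = matrix(1L, n, 3)),
                       class = "localization_samples")
  train_center_regressor(samples, cfg)
}
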