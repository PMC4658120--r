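#' Learn the inter-vertebra chain prior
#'
#' The spine is a cord of sequential vertebral bodies, so the relative offset
#' of adjacent centers is a strong geometric prior. For each adjacent pair
#' `(i, i+1)` the offsets `c_{i+1} - c_i` collected over the training
#' annotations are approximated by a Gaussian with sample mean and sample
#' covariance; a variance floor (default 1 mm^2 per diagonal element) keeps
#' the transition densities non-singular on small training sets.
#'
#' @param annotations List of [vb_centers], all with the same vertebra
#'   ordering; at least 2.
#' @param var_floor Minimum diagonal covariance entry (mm^2).
#' @return An object of class `chain_prior` with `mu` (`(m-1) x 3`) and
#'   `sigma` (`3 x 3 x (m-1)`).
#' @export
learn_chain_prior <- function(annotations, var_floor = 1) {
  if (length(annotations) < 2L)
    stop("need at least 2 training annotations to learn the chain prior")
  mats <- lapply(annotations, function(a) {
    stopifnot(inherits(a, "vb_centers"))
    a$centers
  })
  m <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, integer(1)) != m))
    stop("all annotations must contain the same vertebral bodies")
  if (m < 2L) stop("need at least 2 vertebral bodies for a chain prior")
  mu <- matrix(0, m - 1L, 3L)
  sigma <- array(0, c(3L, 3L, m - 1L))
  for (i in seq_len(m - 1L)) {
    off <- t(vapply(mats, function(x) x[i + 1L, ] - x[i, ], numeric(3)))
    mu[i, ] <- colMeans(off)
    s <- stats::cov(off)
    diag(s) <- pmax(diag(s), var_floor)
    # the sample covariance of few annotations is rank-deficient; flooring
    # the eigenvalues (not just the diagonal) keeps the density proper
    es <- eigen(s, symmetric = TRUE)
    sigma[, , i] <- es$vectors %*% diag(pmax(es$values, var_floor)) %*% t(es$vectors)
  }
  structure(list(mu = mu, sigma = sigma, m = m, var_floor = var_floor),
            class = "chain_prior")
}

# log density of N(mu, sigma) at rows of x (n x 3)
dmvnorm3_log <- function(x, mu, sigma) {
  x <- rbind3(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(sweep(x, 2, mu)), transpose = TRUE)
  -0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(z^2))
}

#' Candidate centers from a response volume
#'
#' The local maxima of the response under 26-connectivity (a voxel whose
#' value is `>=` all neighbours; plateau voxels qualify), ranked by response
#' value with ties broken toward the lower linear index, truncated to the
#' `k` best. `k = Inf` returns every voxel as a candidate (exhaustive
#' decoding on small grids).
#'
#' @param response A `response_volume`.
#' @param k Maximum number of candidates.
#' @return List with `positions` (`k x 3` mm), `values`, and `index`
#'   (linear voxel indices).
#' @export
find_candidates <- function(response, k = 50L) {
  arr <- response$data
  d <- dim(arr)
  if (is.infinite(k)) {
    lin <- seq_along(arr)
  } else {
    pad <- array(-Inf, d + 2L)
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- arr
    nbr <- array(-Inf, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nbr <- pmax(nbr, pad[2:(d[1] + 1L) + dx, 2:(d[2] + 1L) + dy, 2:(d[3] + 1L) + dz])
    }
    lin <- which(arr >= nbr)
  }
  if (length(lin) == 0L) stop("response volume has no candidate maxima")
  ord <- order(-arr[lin], lin)
  lin <- lin[utils::head(ord, if (is.infinite(k)) length(ord) else k)]
  list(positions = voxel_to_world(response, arrayInd(lin, d)),
       values = arr[lin],
       index = lin)
}

#' Decode the vertebral-body center chain
#'
#' Combines the per-vertebra response volumes (observation scores) with the
#' Gaussian chain prior (transition scores) in a hidden Markov model over the
#' ordered vertebrae, and returns the jointly most probable sequence of
#' centers by Viterbi dynamic programming in the log domain. This resolves
#' the ambiguity caused by the repetitive appearance of neighbouring
#' vertebrae, which a per-vertebra argmax cannot.
#'
#' Observation scores are each response's candidate values normalized to unit
#' sum; ties are broken toward the lower-index candidate. The decoded chain
#' is invariant to positive rescaling of any single response volume.
#'
#' @param responses List of `response_volume`s, one per vertebra, in chain
#'   order and sharing a physical frame.
#' @param prior A [learn_chain_prior()] result for the same vertebrae.
#' @param k_candidates Candidates per vertebra (`Inf` = every voxel).
#' @param vb_names Optional names for the returned centers.
#' @return A [vb_centers] with the decoded chain.
#' @export
decode_center_chain <- function(responses, prior, k_candidates = 50L,
                                vb_names = NULL) {
  m <- length(responses)
  if (m == 0L) stop("no response volumes supplied")
  cand <- lapply(responses, find_candidates, k = k_candidates)
  if (m == 1L)
    return(vb_centers(cand[[1]]$positions[1, , drop = FALSE], vb_names))
  if (!inherits(prior, "chain_prior") || prior$m != m)
    stop("chain prior does not match the number of response volumes")
  obs <- lapply(cand, function(cc) {
    v <- cc$values
    s <- sum(v)
    if (s <= 0) v <- rep(1, length(v)) else v <- v / s
    log(pmax(v, 1e-300))
  })
  # Viterbi in log domain
  delta <- obs[[1]]
  back <- vector("list", m)
  for (i in 2:m) {
    ni <- length(obs[[i]])
    pos_prev <- cand[[i - 1L]]$positions
    pos_cur <- cand[[i]]$positions
    d_new <- numeric(ni)
    b_new <- integer(ni)
    for (b in seq_len(ni)) {
      trans <- dmvnorm3_log(sweep(-pos_prev, 2, pos_cur[b, ], "+"),
                            prior$mu[i - 1L, ], prior$sigma[, , i - 1L])
      sc <- delta + trans
      b_new[b] <- which.max(sc)              # first max = lower-index candidate
      d_new[b] <- sc[b_new[b]] + obs[[i]][b]
    }
    delta <- d_new
    back[[i]] <- b_new
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  for (i in m:2) path[i - 1L] <- back[[i]][path[i]]
  centers <- t(vapply(seq_len(m), function(i) cand[[i]]$positions[path[i], ],
                      numeric(3)))
  vb_centers(centers, vb_names)
}
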