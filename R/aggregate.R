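#' Vote aggregation settings
#'
#' The response volume is the Gaussian-transform density of the center votes,
#' evaluated at every voxel of an aggregation grid:
#' `G(y_i) = sum_j W_j exp(-||y_i - y_j||^2 / h^2)`, with distances measured
#' in voxel units of the aggregation grid and a constant kernel width
#' `h = 1.5` voxels and unit vote weights by default. The improved fast Gauss
#' transform (IFGT) evaluates the same sum in roughly `O(M + N' T)` time by
#' clustering the votes (farthest-point clustering) and truncating a Taylor
#' expansion about the cluster centers.
#'
#' @param h Kernel width in grid voxel units.
#' @param ifgt_epsilon Maximum allowed relative error of the IFGT path versus
#'   the exact transform, at voxels whose exact value exceeds `1e-6` times
#'   the exact maximum.
#' @param ifgt_order Truncation order (maximum total degree of the Taylor
#'   terms).
#' @param ifgt_clusters Upper bound on the number of vote clusters; clusters
#'   are added until their covering radius falls below `h/2` or this cap is
#'   reached.
#' @return An object of class `aggregation_config`.
#' @export
aggregation_config <- function(h = 1.5, ifgt_epsilon = 1e-3, ifgt_order = 10L,
                               ifgt_clusters = 3000L) {
  if (!is.finite(h) || h <= 0) stop("`h` must be positive")
  if (!is.finite(ifgt_epsilon) || ifgt_epsilon <= 0 || ifgt_epsilon >= 1)
    stop("`ifgt_epsilon` must be in (0, 1)")
  structure(list(h = h, ifgt_epsilon = ifgt_epsilon,
                 ifgt_order = as.integer(ifgt_order),
                 ifgt_clusters = as.integer(ifgt_clusters)),
            class = "aggregation_config")
}

#' Aggregation grid geometry
#'
#' The grid on which a response volume is evaluated: the full voxel grid of a
#' volume, or a cropped box of it (used in the fine localization step, where
#' votes are aggregated only in a small region around the coarse center).
#'
#' @param vol A [vb_volume].
#' @param box Optional voxel box `list(lo=, hi=)` to crop to.
#' @return An object of class `vb_grid` with `dim`, `spacing`, `origin` and
#'   `slice_axis`.
#' @export
response_grid <- function(vol, box = NULL) {
  stopifnot(inherits(vol, "vb_volume") || inherits(vol, "integral_volumes"))
  d <- if (inherits(vol, "vb_volume")) dim(vol$data) else vol$dim
  origin <- vol$origin
  spacing <- vol$spacing
  slice_axis <- if (inherits(vol, "vb_volume")) vol$slice_axis else 1L
  if (!is.null(box)) {
    box <- clip_box(as_box(box$lo, box$hi), d)
    origin <- origin + (box$lo - 1) * spacing
    d <- box$hi - box$lo + 1L
  }
  structure(list(dim = as.integer(d), spacing = spacing, origin = origin,
                 slice_axis = slice_axis),
            class = "vb_grid")
}

# votes (mm) -> continuous voxel coordinates of the grid
votes_to_grid_units <- function(votes, grid) {
  sweep(sweep(rbind3(votes), 2, grid$origin, "-"), 2, grid$spacing, "/") + 1
}

# all voxel-center coordinates of the grid, in voxel units (m x 3)
grid_targets <- function(grid) {
  d <- grid$dim
  cbind(rep(seq_len(d[1]), times = d[2] * d[3]),
        rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

make_response <- function(values, grid) {
  structure(list(data = array(values, grid$dim), spacing = grid$spacing,
                 origin = grid$origin, slice_axis = grid$slice_axis),
            class = c("response_volume", "vb_volume"))
}

#' Exact Gaussian-transform vote aggregation
#'
#' Direct double loop over all grid voxels and all votes. Quadratic cost;
#' used as the numerical oracle for [aggregate_votes_ifgt] and for small
#' grids.
#'
#' @param votes A `vote_set` (votes in mm).
#' @param grid A [response_grid()].
#' @param agg An [aggregation_config].
#' @return A `response_volume` (also a [vb_volume]) of non-negative vote
#'   densities.
#' @export
aggregate_votes_exact <- function(votes, grid, agg = aggregation_config()) {
  src <- votes_to_grid_units(votes$votes, grid)
  vals <- cpp_gauss_exact(grid_targets(grid), src, as.numeric(votes$weights), agg$h)
  make_response(vals, grid)
}

#' IFGT vote aggregation
#'
#' Improved fast Gauss transform evaluation of the same vote density as
#' [aggregate_votes_exact]: votes are grouped by farthest-point clustering,
#' a truncated multivariate Taylor expansion is accumulated about each
#' cluster center, and each grid voxel sums the expansions of the nearby
#' clusters (clusters beyond an accuracy-derived cutoff radius are skipped).
#'
#' @inheritParams aggregate_votes_exact
#' @return A `response_volume`.
#' @export
aggregate_votes_ifgt <- function(votes, grid, agg = aggregation_config()) {
  src <- votes_to_grid_units(votes$votes, grid)
  h <- agg$h
  # tail cutoff: a skipped cluster contributes at most W_k exp(-cutoff^2/h^2)
  cutoff <- h * sqrt(log(1 / (agg$ifgt_epsilon * 1e-8)))
  vals <- cpp_gauss_ifgt(grid_targets(grid), src, as.numeric(votes$weights),
                         h, agg$ifgt_order, agg$ifgt_clusters,
                         0.5 * h, cutoff)
  make_response(pmax(vals, 0), grid)
}

# mm position of the response maximum (first index on ties)
response_argmax <- function(response) {
  i <- which.max(response$data)
  drop(voxel_to_world(response, arrayInd(i, dim(response$data))))
}
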