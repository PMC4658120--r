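#' Integral volumes of intensity and squared intensity
#'
#' Builds the 3D summed-area tables ("integral images") of the voxel
#' intensity `I` and of the squared intensity `S`. Once built, the sum of
#' either quantity over any axis-aligned box is an 8-corner lookup in O(1)
#' time, independent of the box size, which is what makes block mean/variance
#' features cheap. Both tables carry a zero leading plane along each axis so
#' the corner formula needs no boundary special-casing.
#'
#' @param vol A [vb_volume] (or a bare 3D array).
#' @return An object of class `integral_volumes` with padded cumulative
#'   arrays `I` and `S`, the source `dim`, `spacing` and `origin`.
#' @export
build_integral_volumes <- function(vol) {
  arr <- if (inherits(vol, "vb_volume")) vol$data else vol
  if (!is.array(arr) || length(dim(arr)) != 3L) stop("expected a 3D volume")
  d <- dim(arr)
  structure(list(I = pad_cumsum3(arr),
                 S = pad_cumsum3(arr * arr),
                 dim = d,
                 spacing = if (inherits(vol, "vb_volume")) vol$spacing else c(1, 1, 1),
                 origin = if (inherits(vol, "vb_volume")) vol$origin else c(0, 0, 0)),
            class = "integral_volumes")
}

# cumulative sum along all three axes, zero-padded with a leading plane:
# out[i+1, j+1, k+1] = sum(arr[1:i, 1:j, 1:k])
pad_cumsum3 <- function(arr) {
  a <- apply(arr, c(2, 3), cumsum)                       # cumsum axis 1
  a <- aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3))      # cumsum axis 2
  a <- aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))      # cumsum axis 3
  d <- dim(arr)
  out <- array(0, d + 1L)
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- a
  out
}

# counter for box-sum lookups (used to assert O(1)-per-block behaviour)
.box_counter <- new.env(parent = emptyenv())
.box_counter$n <- 0L

reset_box_count <- function() .box_counter$n <- 0L
box_count <- function() .box_counter$n

#' Box sum from an integral volume
#'
#' Sum of the intensity (`which = "I"`) or squared intensity (`which = "S"`)
#' over the inclusive voxel box `[lo, hi]`, via the 8-corner formula.
#'
#' @param iv An [build_integral_volumes()] result.
#' @param lo,hi Length-3 integer voxel indices (1-based, inclusive).
#' @param which `"I"` or `"S"`.
#' @return A single number.
#' @export
box_sum <- function(iv, lo, hi, which = c("I", "S")) {
  which <- match.arg(which)
  box <- as_box(lo, hi, iv$dim)
  .box_counter$n <- .box_counter$n + 1L
  P <- iv[[which]]
  l <- box$lo; h <- box$hi + 1L
  P[h[1], h[2], h[3]] - P[l[1], h[2], h[3]] - P[h[1], l[2], h[3]] - P[h[1], h[2], l[3]] +
    P[l[1], l[2], h[3]] + P[l[1], h[2], l[3]] + P[h[1], l[2], l[3]] - P[l[1], l[2], l[3]]
}

#' Mean and variance of the intensity inside a box
#'
#' Computes `E[X] = sum(I)/Nv`, `E[X^2] = sum(S)/Nv` and
#' `Var(X) = E[X^2] - E[X]^2` from the integral volumes, with the variance
#' clamped at zero as a floating-point guard.
#'
#' @inheritParams box_sum
#' @return Named numeric vector `c(mean = ..., variance = ...)`.
#' @export
block_stats <- function(iv, lo, hi) {
  box <- as_box(lo, hi, iv$dim)
  nv <- prod(box$hi - box$lo + 1)
  m <- box_sum(iv, box$lo, box$hi, "I") / nv
  ex2 <- box_sum(iv, box$lo, box$hi, "S") / nv
  c(mean = m, variance = max(ex2 - m * m, 0))
}
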