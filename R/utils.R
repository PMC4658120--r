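# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this, so identical seeds give identical outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a distinct, reproducible 31-bit sub-seed from a master seed.
sub_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 1e5) * 7919 + i * 104729 + 17) %% 2147483647)
}

# Inclusive voxel box: list(lo = c(..), hi = c(..)), both length-3 integer.
as_box <- function(lo, hi, dim = NULL) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(hi < lo))
    stop("invalid voxel box")
  if (!is.null(dim) && (any(lo < 1L) || any(hi > dim)))
    stop("voxel box exceeds volume bounds")
  list(lo = lo, hi = hi)
}

# Clip a box to volume bounds.
clip_box <- function(box, dim) {
  lo <- pmax(box$lo, 1L); hi <- pmin(box$hi, as.integer(dim))
  if (any(hi < lo)) stop("voxel box lies outside the volume")
  list(lo = lo, hi = hi)
}

# Extract a mask/array over a box.
crop_array <- function(arr, box) {
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3], drop = FALSE]
}
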