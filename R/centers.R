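#' Ordered vertebral-body center annotation
#'
#' Holds the physical coordinates (mm) of `m` vertebral-body centers, ordered
#' cranio-caudally, together with their anatomical names.
#'
#' @param centers m x 3 numeric matrix of positions in mm (or a length-3
#'   vector for a single center).
#' @param vb_names Character vector of length m; defaults to `L1, L2, ...`.
#' @return An object of class `vb_centers`.
#' @export
vb_centers <- function(centers, vb_names = NULL) {
  centers <- rbind3(centers)
  if (any(!is.finite(centers))) stop("center coordinates must be finite")
  m <- nrow(centers)
  if (is.null(vb_names)) vb_names <- paste0("L", seq_len(m))
  if (length(vb_names) != m) stop("`vb_names` must have one entry per center")
  dimnames(centers) <- list(vb_names, c("x", "y", "z"))
  structure(list(centers = centers, vb_names = as.character(vb_names)),
            class = "vb_centers")
}

#' @export
print.vb_centers <- function(x, ...) {
  cat(sprintf("<vb_centers> %d vertebral bodies (mm):\n", nrow(x$centers)))
  print(round(x$centers, 2))
  invisible(x)
}

#' Geometrical center of one labeled vertebral body
#'
#' The centroid of the voxels carrying label `vb_index`, converted to
#' physical coordinates (mm).
#'
#' @param labels A [vb_labels] volume.
#' @param vb_index Positive integer label to locate.
#' @return Length-3 numeric vector (mm).
#' @export
compute_center <- function(labels, vb_index) {
  stopifnot(inherits(labels, "vb_labels"))
  w <- which(labels$data == vb_index)
  if (length(w) == 0L) stop("label ", vb_index, " is absent from the volume")
  idx <- arrayInd(w, dim(labels$data))
  colMeans(voxel_to_world(labels, idx))
}

#' Centers of all labeled vertebral bodies
#'
#' @param labels A [vb_labels] volume.
#' @return A [vb_centers] with one row per positive label present.
#' @export
compute_centers <- function(labels) {
  m <- max(labels$data)
  if (m < 1) stop("no labeled vertebral bodies in the volume")
  ctr <- t(vapply(seq_len(m), function(i) compute_center(labels, i), numeric(3)))
  vb_centers(ctr, labels$vb_names[seq_len(m)])
}

#' Read/write center annotations as JSON
#'
#' Centers are stored as an ordered array of records
#' `{"vb_name": ..., "x_mm": ..., "y_mm": ..., "z_mm": ...}`.
#'
#' @param path JSON file path.
#' @return [read_centers] returns a [vb_centers]; [write_centers] returns
#'   `path` invisibly.
#' @export
read_centers <- function(path) {
  df <- jsonlite::fromJSON(path)
  need <- c("vb_name", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df))) stop("malformed centers file: ", path)
  vb_centers(as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), df$vb_name)
}

#' @rdname read_centers
#' @param centers A [vb_centers].
#' @export
write_centers <- function(centers, path) {
  stopifnot(inherits(centers, "vb_centers"))
  df <- data.frame(vb_name = centers$vb_names,
                   x_mm = centers$centers[, 1],
                   y_mm = centers$centers[, 2],
                   z_mm = centers$centers[, 3])
  jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
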