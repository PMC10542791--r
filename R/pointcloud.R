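#' Point cloud container
#'
#' A point cloud is a data frame with one row per LiDAR return and columns
#' `x`, `y`, `z` (metres; `z` is elevation, or height above ground after
#' [normalize_cloud()]), `return_number` (integer) and `classification`
#' (one of `"unclassified"`, `"ground"`, `"outlier"`). Extra columns (e.g.
#' simulation ground-truth labels) are carried along untouched.
#'
#' @param x,y,z numeric coordinate vectors (m).
#' @param return_number integer vector, recycled; defaults to 1.
#' @param classification character vector, recycled; defaults to
#'   `"unclassified"`.
#' @param ... additional per-return columns.
#' @return A `point_cloud` data frame.
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        return_number = 1L,
                        classification = "unclassified", ...) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n > 0 && !all(is.finite(x) & is.finite(y) & is.finite(z))) {
    stop_amz("point cloud coordinates must be finite")
  }
  cls <- rep_len(as.character(classification), n)
  bad <- setdiff(unique(cls), c("unclassified", "ground", "outlier"))
  if (length(bad)) stop_amz("unknown classification label: %s", bad[1])
  df <- data.frame(
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    return_number = rep_len(as.integer(return_number), n),
    classification = cls,
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  class(df) <- c("point_cloud", "data.frame")
  df
}

as_point_cloud <- function(df) {
  class(df) <- c("point_cloud", "data.frame")
  rownames(df) <- NULL
  df
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d returns", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(
      "; x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]",
      min(x$x), max(x$x), min(x$y), max(x$y), min(x$z), max(x$z)
    ))
    tb <- table(x$classification)
    cat("\n  ", paste(names(tb), tb, sep = ": ", collapse = "  "), "\n")
  } else {
    cat("\n")
  }
  invisible(x)
}

#' Remove isolated-point outliers on a voxel lattice
#'
#' Returns hit by the laser off birds, water vapour or sensor noise appear as
#' isolated points well away from the canopy and ground. A return is kept
#' when it has at least `min_neighbors` other returns inside its
#' `block_extent`-voxel cube (a 4 m cube of 1-m voxels by default);
#' otherwise it is moved to the removed set and labelled `"outlier"`.
#'
#' Two neighbourhood definitions are available. `"centered"` (default)
#' counts the other returns inside the cube centred on each return
#' (Chebyshev radius `voxel_size * block_extent / 2`, boundary inclusive):
#' every return sees its full physical neighbourhood, so only genuinely
#' isolated points fail the threshold. `"lattice"` partitions space into a
#' fixed lattice of aligned cubes (anchored at coordinates congruent to 0
#' modulo the cube side) and counts within the cube containing the return;
#' it is a single counting pass but clips the neighbourhood of returns near
#' cube corners, which measurably removes non-isolated returns in thin
#' strata such as the ground slab or the canopy surface.
#'
#' @param cloud a [point_cloud()].
#' @param voxel_size voxel edge length (m); default 1.
#' @param block_extent neighbourhood edge length in voxels; default 4 (a
#'   4 m cube).
#' @param min_neighbors minimum number of other returns in the cube for a
#'   return to survive; default 5, so a return with exactly 5 neighbours is
#'   kept and one with 4 is removed.
#' @param anchoring `"centered"` (point-centred cube) or `"lattice"`
#'   (anchored partition).
#' @return list with `kept` and `removed` point clouds partitioning the
#'   input (`removed` relabelled `"outlier"`). Order-independent in both
#'   modes.
#' @export
remove_outliers <- function(cloud, voxel_size = 1, block_extent = 4L,
                            min_neighbors = 5L,
                            anchoring = c("centered", "lattice")) {
  anchoring <- match.arg(anchoring)
  if (voxel_size <= 0) stop_amz("voxel_size must be positive")
  if (block_extent < 1L) stop_amz("block_extent must be >= 1")
  if (nrow(cloud) == 0L) {
    return(list(kept = cloud, removed = cloud))
  }
  block <- voxel_size * block_extent
  if (anchoring == "centered") {
    neighbors <- .cube_neighbor_counts(cloud$x, cloud$y, cloud$z, block / 2)
  } else {
    dt <- data.table::data.table(
      bx = floor(cloud$x / block),
      by = floor(cloud$y / block),
      bz = floor(cloud$z / block)
    )
    n <- NULL # data.table NSE
    dt[, n := .N, by = c("bx", "by", "bz")]
    neighbors <- dt$n - 1L
  }
  iso <- neighbors < min_neighbors
  removed <- cloud[iso, , drop = FALSE]
  removed$classification <- rep("outlier", nrow(removed))
  list(
    kept = as_point_cloud(cloud[!iso, , drop = FALSE]),
    removed = as_point_cloud(removed)
  )
}
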