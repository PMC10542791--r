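#' Ground-filter parameters
#'
#' Controls for progressive TIN densification. The seeds are the lowest
#' return in each `seed_cell_size` cell; unclassified returns join the
#' ground set while they stay within `max_distance` of the TIN facet beneath
#' them and, when further than `noise_floor` from the facet, subtend an
#' angle of at most `max_angle` at the nearest facet vertex. The
#' `noise_floor` exemption exists because at sub-noise vertical offsets the
#' subtended angle is dominated by ranging error, not by terrain shape; its
#' default is three times the nominal ground-echo noise SD of the sensor
#' class modelled here (0.15 m).
#'
#' @param seed_cell_size cell size (m) for the neighbourhood minima seeding
#'   the sparse TIN.
#' @param max_angle maximum angle (degrees) a candidate may subtend at the
#'   nearest facet vertex.
#' @param max_distance maximum absolute vertical distance (m) to the facet.
#' @param max_iterations densification iteration cap.
#' @param noise_floor vertical distance (m) under which the angle criterion
#'   is waived.
#' @param seed_spike_tolerance seeds more than this (m) above the median of
#'   their neighbouring seed minima are rejected before triangulation. In
#'   dense canopy a seed cell can be fully occluded, so its lowest return
#'   is a crown echo; left in place it would spike the terrain surface by
#'   tens of metres. The default tolerates the elevation change expected
#'   across neighbouring cells on undulating terrain.
#' @return A `ground_filter_params` list.
#' @export
ground_filter_params <- function(seed_cell_size = 10, max_angle = 6,
                                 max_distance = 1.0, max_iterations = 20L,
                                 noise_floor = 0.45,
                                 seed_spike_tolerance = 5) {
  vals <- c(seed_cell_size, max_angle, max_distance, max_iterations, noise_floor)
  if (any(!is.finite(vals)) || any(vals[1:4] <= 0) || noise_floor < 0) {
    stop_amz("ground filter parameters must be positive")
  }
  structure(
    list(
      seed_cell_size = seed_cell_size, max_angle = max_angle,
      max_distance = max_distance, max_iterations = as.integer(max_iterations),
      noise_floor = noise_floor, seed_spike_tolerance = seed_spike_tolerance
    ),
    class = "ground_filter_params"
  )
}

#' Classify ground returns by progressive TIN densification
#'
#' Builds a sparse triangulated irregular network (TIN) from the
#' neighbourhood minima of the cloud, then progressively densifies it:
#' at each iteration every still-unclassified return is tested against the
#' current TIN and accepted into the ground set when it lies close to the
#' facet beneath it (see [ground_filter_params()]); accepted returns become
#' TIN vertices for the next iteration. The ground set grows monotonically
#' and the loop stops when an iteration accepts nothing or the iteration cap
#' is reached. Run [remove_outliers()] first: low isolated noise below the
#' terrain would otherwise seed the TIN.
#'
#' @param cloud a [point_cloud()], outliers already removed.
#' @param params a [ground_filter_params()].
#' @return The cloud with accepted returns relabelled `"ground"`.
#' @export
classify_ground <- function(cloud, params = ground_filter_params()) {
  if (nrow(cloud) < 3L) stop_amz("ground classification needs >= 3 returns")
  cs <- params$seed_cell_size
  cellkey <- paste(floor(cloud$x / cs), floor(cloud$y / cs))
  lowest <- tapply(seq_len(nrow(cloud)), cellkey, function(i) i[which.min(cloud$z[i])])
  seed <- rep(FALSE, nrow(cloud))
  seed[unlist(lowest, use.names = FALSE)] <- TRUE
  # spike rejection: a fully occluded seed cell has no ground echo, so its
  # minimum is a crown return far above the neighbouring minima
  si <- which(seed)
  if (length(si) >= 5L) {
    k <- min(9L, length(si))
    nn <- RANN::nn2(cbind(cloud$x[si], cloud$y[si]), k = k)
    nb_med <- apply(matrix(cloud$z[si][nn$nn.idx[, -1, drop = FALSE]],
                           nrow = length(si)), 1, stats::median)
    spike <- cloud$z[si] > nb_med + params$seed_spike_tolerance
    if (sum(!spike) >= 3L) seed[si[spike]] <- FALSE
  }
  ns <- sum(seed)
  if (ns < 3L) {
    stop_amz("degenerate terrain: only %d seed minima (need >= 3)", ns)
  }
  sx <- cloud$x[seed]; sy <- cloud$y[seed]
  # collinearity check via the smaller eigenvalue of the xy covariance
  ev <- eigen(stats::cov(cbind(sx, sy)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-10 * max(ev[1], 1)) {
    stop_amz("degenerate triangulation: seed minima are collinear")
  }
  status <- .tin_densify(
    cloud$x, cloud$y, cloud$z, seed,
    params$max_distance, params$max_angle, params$noise_floor,
    params$max_iterations
  )
  cloud$classification[status >= 0L] <- "ground"
  attr(cloud, "densify_iterations") <- max(status)
  cloud
}

#' Build a digital terrain model from classified ground returns
#'
#' Linear interpolation on the Delaunay TIN of the ground returns, evaluated
#' at cell centres. Cells outside the TIN convex hull (a narrow strip at the
#' transect edge) are filled with the elevation of the nearest ground
#' return, so the DTM has no nodata holes that would break normalization.
#'
#' @param ground a [point_cloud()]; only rows classified `"ground"` are
#'   used (pass a fully ground-classified cloud or the output of
#'   [classify_ground()]).
#' @param cell_size DTM resolution (m), default 1.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   ground-return bounding box snapped outward to the grid.
#' @return An [amz_raster()] of bare-earth elevation (m).
#' @export
build_dtm <- function(ground, cell_size = 1, extent = NULL) {
  g <- ground[ground$classification == "ground", , drop = FALSE]
  if (nrow(g) < 3L) stop_amz("DTM needs >= 3 ground returns, got %d", nrow(g))
  ev <- eigen(stats::cov(cbind(g$x, g$y)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] < 1e-10 * max(ev[1], 1)) {
    stop_amz("degenerate TIN: ground returns are collinear")
  }
  if (is.null(extent)) {
    extent <- c(
      floor(min(g$x) / cell_size) * cell_size,
      ceiling(max(g$x) / cell_size) * cell_size,
      floor(min(g$y) / cell_size) * cell_size,
      ceiling(max(g$y) / cell_size) * cell_size
    )
  }
  nc <- max(1L, as.integer(round((extent[2] - extent[1]) / cell_size)))
  nr <- max(1L, as.integer(round((extent[4] - extent[3]) / cell_size)))
  cx <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  cy <- extent[3] + (seq_len(nr) - 0.5) * cell_size
  qx <- rep(cx, each = nr)
  qy <- rep(cy, times = nc)
  zi <- .tin_interpolate(g$x, g$y, g$z, qx, qy)
  out <- is.na(zi)
  if (any(out)) {
    nn <- RANN::nn2(cbind(g$x, g$y), cbind(qx[out], qy[out]), k = 1)
    zi[out] <- g$z[nn$nn.idx[, 1]]
  }
  amz_raster(matrix(zi, nr, nc), extent[1], extent[3], cell_size)
}

#' Normalize a point cloud to height above ground
#'
#' Subtracts from each return's elevation the DTM value of the pixel that
#' contains it (nearest-pixel lookup, not bilinear). Ground echoes end up
#' near zero — slightly negative values are expected from ranging noise.
#'
#' @param cloud a [point_cloud()] in elevation.
#' @param dtm DTM [amz_raster()] covering every return.
#' @return The cloud with `z` replaced by height above ground (m).
#' @export
normalize_cloud <- function(cloud, dtm) {
  zd <- raster_extract(dtm, cloud$x, cloud$y)
  bad <- which(is.na(zd))
  if (length(bad)) {
    stop_amz(
      "%d returns fall outside the DTM footprint (first offenders: %s)",
      length(bad), paste(head(bad, 5), collapse = ", ")
    )
  }
  cloud$z <- cloud$z - zd
  cloud
}
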