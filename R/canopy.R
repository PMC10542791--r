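#' Coefficients of the TCH power-law biomass model
#'
#' The LiDAR biomass model converts top-of-canopy height (TCH, m) to
#' aboveground biomass density as
#' `AGB (kg m^-2) = scale * a * TCH^b`, with defaults
#' `scale = 2`, `a = 0.025`, `b = 1.99`.
#'
#' @param a multiplicative coefficient (> 0).
#' @param b exponent (> 0).
#' @param scale outer multiplier (> 0).
#' @return An `allometric_coefficients` list.
#' @export
allometric_coefficients <- function(a = 0.025, b = 1.99, scale = 2) {
  if (a <= 0 || b <= 0 || scale <= 0) {
    stop_amz("allometric coefficients must be positive")
  }
  structure(list(a = a, b = b, scale = scale),
            class = "allometric_coefficients")
}

#' Build the canopy height model
#'
#' Assigns to each grid cell the highest normalized return inside it,
#' floored at 0 m (negative normalized heights are ground-noise artifacts).
#' Cells containing no returns are nodata.
#'
#' @param normalized a height-normalized [point_cloud()].
#' @param cell_size CHM resolution (m), default 1.
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the cloud
#'   bounding box snapped outward to the grid.
#' @return A CHM [amz_raster()] (m above ground).
#' @export
build_chm <- function(normalized, cell_size = 1, extent = NULL) {
  if (nrow(normalized) == 0L) stop_amz("cannot build a CHM from an empty cloud")
  if (max(normalized$z) > 120) {
    warning("returns above 120 m height: is this cloud really normalized?",
            call. = FALSE)
  }
  if (is.null(extent)) {
    extent <- c(
      floor(min(normalized$x) / cell_size) * cell_size,
      ceiling(max(normalized$x) / cell_size) * cell_size,
      floor(min(normalized$y) / cell_size) * cell_size,
      ceiling(max(normalized$y) / cell_size) * cell_size
    )
  }
  nc <- max(1L, as.integer(round((extent[2] - extent[1]) / cell_size)))
  nr <- max(1L, as.integer(round((extent[4] - extent[3]) / cell_size)))
  col <- floor((normalized$x - extent[1]) / cell_size) + 1L
  row <- floor((normalized$y - extent[3]) / cell_size) + 1L
  # returns exactly on the max edge belong to the last cell
  col[normalized$x == extent[2]] <- nc
  row[normalized$y == extent[4]] <- nr
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  idx <- (col[inside] - 1L) * nr + row[inside]
  v <- rep(NA_real_, nr * nc)
  mx <- tapply(normalized$z[inside], idx, max)
  v[as.integer(names(mx))] <- pmax(as.numeric(mx), 0)
  amz_raster(matrix(v, nr, nc), extent[1], extent[3], cell_size)
}

#' Aggregate the CHM to top-of-canopy height
#'
#' Block-averages 1-m CHM pixels into `target_cell` cells (50 m by default),
#' ignoring nodata pixels. Blocks whose valid-pixel fraction falls below
#' `min_valid_fraction` become nodata rather than being biased by sparse
#' coverage.
#'
#' @param chm CHM [amz_raster()].
#' @param target_cell output cell size (m); must be an integer multiple of
#'   the CHM cell size.
#' @param min_valid_fraction minimum fraction of valid source pixels.
#' @return A TCH [amz_raster()] (m).
#' @export
aggregate_tch <- function(chm, target_cell = 50, min_valid_fraction = 0.9) {
  f <- target_cell / chm$cell
  if (abs(f - round(f)) > 1e-9) {
    stop_amz("target cell %g m is not a multiple of the CHM cell %g m",
             target_cell, chm$cell)
  }
  block_aggregate(chm, as.integer(round(f)), min_valid_fraction)
}

#' Convert TCH to aboveground biomass
#'
#' Applies `AGB = scale * a * TCH^b` cellwise (kg m^-2). Applied after
#' aggregation to 50 m, so the model's predictor is the block-mean canopy
#' height, not per-pixel height.
#'
#' @param tch TCH [amz_raster()] (m) or a numeric vector of TCH values.
#' @param coeffs an [allometric_coefficients()].
#' @return AGB in kg m^-2, same container as the input.
#' @export
agb_from_tch <- function(tch, coeffs = allometric_coefficients()) {
  f <- function(h) coeffs$scale * coeffs$a * h^coeffs$b
  if (is_amz_raster(tch)) {
    v <- tch$values
    if (any(v < 0, na.rm = TRUE)) stop_amz("negative TCH values")
    out <- tch
    out$values <- f(v)
    out
  } else {
    if (any(tch < 0, na.rm = TRUE)) stop_amz("negative TCH values")
    f(tch)
  }
}

#' Convert biomass density units
#'
#' `to_mg_ha` converts kg m^-2 to Mg ha^-1 (x 10); `to_kg_m2` inverts it.
#'
#' @param agb AGB [amz_raster()] or numeric vector.
#' @return Same container, rescaled.
#' @export
to_mg_ha <- function(agb) {
  if (is_amz_raster(agb)) {
    agb$values <- agb$values * 10
    agb
  } else {
    agb * 10
  }
}

#' @rdname to_mg_ha
#' @export
to_kg_m2 <- function(agb) {
  if (is_amz_raster(agb)) {
    agb$values <- agb$values / 10
    agb
  } else {
    agb / 10
  }
}

#' Regrid a raster to a coarser cell by block mean
#'
#' Used to rescale 50-m LiDAR AGB to the 250-m wall-to-wall grid. The
#' coverage rule mirrors [aggregate_tch()]; the default
#' `min_valid_fraction = 0.5` is looser because LiDAR transects only
#' partially cover edge 250-m cells.
#'
#' @param raster an [amz_raster()].
#' @param target_cell output cell size (m), integer multiple of the source.
#' @param min_valid_fraction minimum fraction of valid source cells.
#' @return An [amz_raster()] on the coarser grid.
#' @export
regrid_mean <- function(raster, target_cell = 250, min_valid_fraction = 0.5) {
  f <- target_cell / raster$cell
  if (abs(f - round(f)) > 1e-9) {
    stop_amz("target cell %g m is not a multiple of the source cell %g m",
             target_cell, raster$cell)
  }
  block_aggregate(raster, as.integer(round(f)), min_valid_fraction)
}
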