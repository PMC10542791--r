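#' Convert biomass to biomass carbon
#'
#' Multiplies AGB by a carbon fraction (0.47 by default), preserving
#' nodata. Linear, hence exactly invertible by dividing the result by the
#' same fraction.
#'
#' @param agb AGB [amz_raster()] (Mg ha^-1) or numeric vector.
#' @param fraction carbon fraction in (0, 1].
#' @return AGBC in Mg C ha^-1, same container as the input.
#' @export
agb_to_carbon <- function(agb, fraction = 0.47) {
  if (fraction <= 0 || fraction > 1) {
    stop_amz("carbon fraction must be in (0, 1], got %g", fraction)
  }
  if (is_amz_raster(agb)) {
    agb$values <- agb$values * fraction
    agb
  } else {
    agb * fraction
  }
}

#' Compare a biomass map against a reference map
#'
#' Nearest-neighbour-resamples the reference onto the candidate grid and
#' returns `candidate - reference` restricted to `mask = 1` cells: negative
#' values mean the candidate is lower than the reference. Anthropized areas
#' are excluded by supplying a binary mask.
#'
#' @param candidate candidate [amz_raster()].
#' @param reference reference [amz_raster()] (any grid).
#' @param mask binary [amz_raster()] on the candidate grid (1 = compare).
#' @return Difference [amz_raster()] (nodata outside the mask).
#' @export
compare_maps <- function(candidate, reference, mask) {
  if (!same_grid(candidate, mask)) {
    stop_amz("mask must be on the candidate grid")
  }
  m <- mask$values
  if (!any(m == 1, na.rm = TRUE)) stop_amz("empty comparison mask")
  ref_r <- resample_covariate(reference, candidate, method = "nearest")
  out <- candidate
  out$values <- candidate$values - ref_r$values
  out$values[is.na(m) | m != 1] <- NA_real_
  out
}

#' Summary statistics of a biomass map
#'
#' Max, mean and SD over valid (optionally masked) cells, cell-weighted,
#' with the population (divide-by-n) SD convention.
#'
#' @param raster an [amz_raster()].
#' @param mask optional binary [amz_raster()] on the same grid.
#' @return list `max`, `mean`, `sd`, `valid_cell_count`,
#'   `nodata_cell_count`.
#' @export
summarize_map <- function(raster, mask = NULL) {
  v <- as.vector(raster$values)
  if (!is.null(mask)) {
    if (!same_grid(raster, mask)) stop_amz("mask grid mismatch")
    v[is.na(mask$values) | as.vector(mask$values) != 1] <- NA_real_
  }
  ok <- is.finite(v)
  if (!any(ok)) stop_amz("no valid cells to summarize")
  vv <- v[ok]
  list(
    max = max(vv),
    mean = mean(vv),
    sd = sqrt(mean((vv - mean(vv))^2)),
    valid_cell_count = sum(ok),
    nodata_cell_count = sum(!ok)
  )
}
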