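#' Synthetic-scene configuration
#'
#' Parameters of the synthetic forest transect generator. Defaults mirror
#' the acquisition design the pipeline targets — a 12.5 km x 300 m transect
#' surveyed at 4 returns per m^2 — truncated to a 500 m x 300 m test extent
#' so a full pipeline run stays cheap; the full transect length remains a
#' config choice. Terrain is an undulating correlated random field, stems
#' follow a homogeneous Poisson process, and ground echoes carry 0.15 m
#' vertical noise (well within a 0.5 m sensor vertical-accuracy class).
#'
#' @param extent_length,extent_width transect extent (m).
#' @param terrain_relief_amplitude peak-to-trough terrain relief (m).
#' @param terrain_correlation_length terrain correlation length (m).
#' @param terrain_cell_size terrain raster resolution (m).
#' @param base_elevation mean terrain elevation (m).
#' @param stem_density stems per hectare.
#' @param height_mean,height_sd stem height distribution (m), truncated to
#'   \[2, 60\] m.
#' @param dbh_height_coupling exponent linking DBH to height
#'   (`DBH ~ height^coupling`).
#' @param point_density mean LiDAR return density (returns per m^2).
#' @param outlier_count isolated noise points injected above the canopy.
#' @param ground_noise_sd vertical noise SD of ground echoes (m).
#' @param crown_interception per-crown-layer probability that a pulse is
#'   intercepted before reaching the ground.
#' @param top_echo_fraction fraction of crown echoes that reflect off the
#'   upper crown surface; the rest are distributed uniformly through the
#'   crown volume (cone-capped cylinder).
#' @param penetration_mean mean depth (m) of top echoes below the local
#'   crown surface (exponential, truncated at the crown base).
#' @param crown_base_fraction crown base height as a fraction of the local
#'   crown surface height.
#' @param ndvi_noise_sd,evi_noise_sd,hh_noise_sd,hv_noise_sd per-composite
#'   noise SDs of the synthetic satellite covariates (index units / dB).
#' @param seed master RNG seed; every generator is a pure function of
#'   (config, seed).
#' @return A `scene_config` list.
#' @export
scene_config <- function(extent_length = 500, extent_width = 300,
                         terrain_relief_amplitude = 20,
                         terrain_correlation_length = 50,
                         terrain_cell_size = 1,
                         base_elevation = 100,
                         stem_density = 500,
                         height_mean = 22, height_sd = 8,
                         dbh_height_coupling = 0.52,
                         point_density = 4,
                         outlier_count = 20L,
                         ground_noise_sd = 0.15,
                         crown_interception = 0.55,
                         top_echo_fraction = 0.25,
                         penetration_mean = 0.5,
                         crown_base_fraction = 0.80,
                         ndvi_noise_sd = 0.04, evi_noise_sd = 0.04,
                         hh_noise_sd = 0.9, hv_noise_sd = 0.5,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (extent_length <= 0 || extent_width <= 0) {
    stop_amz("invalid config: extent must be positive")
  }
  if (point_density <= 0) stop_amz("invalid config: point_density must be > 0")
  if (stem_density < 0) stop_amz("invalid config: stem_density must be >= 0")
  if (terrain_correlation_length <= 0 || terrain_cell_size <= 0) {
    stop_amz("invalid config: terrain scales must be positive")
  }
  if (terrain_relief_amplitude < 0 || ground_noise_sd < 0) {
    stop_amz("invalid config: amplitudes must be non-negative")
  }
  structure(cfg, class = "scene_config")
}

# Gaussian low-pass filter of a matrix, separable, with edge-replication
# padding so the output has no edge nodata. sigma in cells.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  w <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-w, w), sd = sigma)
  k <- k / sum(k)
  blur_vec <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], w), v, rep(v[n], w))
    as.numeric(stats::filter(padded, k, sides = 2))[(w + 1):(w + n)]
  }
  m <- apply(m, 2, blur_vec)
  t(apply(m, 1, blur_vec))
}

#' Generate undulating synthetic terrain
#'
#' A seeded white-noise field low-pass filtered with a Gaussian kernel of
#' the configured correlation length, then recentred on `base_elevation`
#' and rescaled so that peak-to-trough relief equals
#' `terrain_relief_amplitude`. Deterministic given the config seed.
#'
#' @param config a [scene_config()].
#' @return A terrain [amz_raster()] (elevation, m) with no nodata cells.
#' @export
generate_terrain <- function(config) {
  cs <- config$terrain_cell_size
  nc <- as.integer(round(config$extent_length / cs))
  nr <- as.integer(round(config$extent_width / cs))
  if (nc < 1L || nr < 1L) stop_amz("invalid config: extent smaller than one cell")
  with_seed(config$seed + 1L, {
    f <- matrix(rnorm(nr * nc), nr, nc)
    f <- gauss_blur(f, config$terrain_correlation_length / cs)
    rng <- max(f) - min(f)
    v <- if (config$terrain_relief_amplitude == 0 || rng == 0) {
      matrix(config$base_elevation, nr, nc)
    } else {
      config$base_elevation +
        (f - mean(f)) * (config$terrain_relief_amplitude / rng)
    }
    amz_raster(v, 0, 0, cs)
  })
}

#' Generate a synthetic forest stand
#'
#' Stem positions follow a homogeneous Poisson process at the configured
#' density. Heights are truncated-normal with 80% of their variance carried
#' by a smooth spatial field (~50 m range) — canopy height is strongly
#' autocorrelated in closed forest through site quality and gap-phase
#' dynamics, so neighbouring crowns reach similar heights. DBH is coupled
#' to height as a power law with lognormal scatter; wood density is
#' truncated-normal around 0.60 g cm^-3; crown radius grows linearly with
#' height. A small fraction of stems are palms and lianas so that
#' growth-form-specific allometries are exercised.
#'
#' @param config a [scene_config()].
#' @param terrain terrain raster (fixes the extent; stem attributes do not
#'   depend on elevation).
#' @return data frame of stems: `x`, `y`, `height` (m), `dbh` (cm),
#'   `wood_density` (g cm^-3), `growth_form`, `crown_radius` (m).
#' @export
generate_stand <- function(config, terrain) {
  area_ha <- config$extent_length * config$extent_width / 1e4
  with_seed(config$seed + 2L, {
    n <- rpois(1, config$stem_density * area_ha)
    if (n == 0L) {
      return(data.frame(
        x = numeric(), y = numeric(), height = numeric(), dbh = numeric(),
        wood_density = numeric(), growth_form = character(),
        crown_radius = numeric(), stringsAsFactors = FALSE
      ))
    }
    xs <- runif(n, 0, config$extent_length)
    ys <- runif(n, 0, config$extent_width)
    # spatially correlated height field sampled at the stem positions
    hc <- 10
    nch <- max(2L, ceiling(config$extent_length / hc))
    nrh <- max(2L, ceiling(config$extent_width / hc))
    g <- gauss_blur(matrix(rnorm(nrh * nch), nrh, nch), 50 / hc)
    g <- (g - mean(g)) / max(stats::sd(g), 1e-12)
    gi <- g[cbind(pmin(nrh, floor(ys / hc) + 1L), pmin(nch, floor(xs / hc) + 1L))]
    h <- config$height_mean +
      config$height_sd * (sqrt(0.8) * gi + sqrt(0.2) * rnorm(n))
    h <- pmin(pmax(h, 2), 60)
    dbh <- 3.77 * h^config$dbh_height_coupling * rlnorm(n, 0, 0.15)
    wd <- pmin(pmax(rnorm(n, 0.60, 0.10), 0.30), 0.90)
    gf <- sample(c("tree", "palm", "liana"), n, replace = TRUE,
                 prob = c(0.90, 0.07, 0.03))
    data.frame(
      x = xs, y = ys,
      height = h, dbh = dbh, wood_density = wd, growth_form = gf,
      crown_radius = 0.5 + 0.12 * h,
      stringsAsFactors = FALSE
    )
  })
}

# Per-1-m-column crown structure: number of overlapping crowns and the
# maximum crown-surface height (cone-capped cylinder: surface falls
# linearly from the apex to 85% of tree height at the crown edge..
crown_columns <- function(trees, nc, nr) {
  count <- matrix(0L, nr, nc)
  surface <- matrix(0, nr, nc)
  for (i in seq_len(nrow(trees))) {
    r <- trees$crown_radius[i]
    h <- trees$height[i]
    cx <- trees$x[i]; cy <- trees$y[i]
    jj <- max(1L, floor(cx - r) + 1L):min(nc, ceiling(cx + r))
    ii <- max(1L, floor(cy - r) + 1L):min(nr, ceiling(cy + r))
    if (!length(jj) || !length(ii)) next
    dx <- (jj - 0.5) - cx
    dy <- (ii - 0.5) - cy
    d <- sqrt(outer(dy^2, dx^2, "+"))
    inside <- d <= r
    if (!any(inside)) next
    s <- h - 0.15 * h * (d / r)
    blk_cnt <- count[ii, jj, drop = FALSE]
    blk_srf <- surface[ii, jj, drop = FALSE]
    blk_cnt[inside] <- blk_cnt[inside] + 1L
    blk_srf[inside] <- pmax(blk_srf[inside], s[inside])
    count[ii, jj] <- blk_cnt
    surface[ii, jj] <- blk_srf
  }
  list(count = count, surface = surface)
}

#' Simulate a LiDAR point cloud over a synthetic stand
#'
#' For every 1-m ground column the number of returns is Poisson with mean
#' `point_density`. Under crown cover a return is a crown echo with
#' probability `1 - (1 - crown_interception)^n_crowns`; a crown echo is
#' either a top echo (an exponential penetration depth below the local
#' crown surface) or, with probability `1 - top_echo_fraction`, an interior
#' echo uniform through the crown volume down to the crown base — so the
#' vertical return profile is top-weighted but fills the canopy stratum,
#' as discrete-return sensors see it. Ground echoes sit at the terrain
#' plus Gaussian ranging noise. `outlier_count` isolated points are injected
#' 10-100 m above the local canopy, constructed so that their 4 m voxel
#' block holds no other return (matching the downstream isolation filter's
#' definition); they are flagged in the `truth` column.
#'
#' @param terrain terrain [amz_raster()] covering the extent.
#' @param trees stand data frame from [generate_stand()].
#' @param config a [scene_config()].
#' @return A [point_cloud()] with a `truth` column
#'   (`"ground"`/`"crown"`/`"outlier"`).
#' @export
simulate_point_cloud <- function(terrain, trees, config) {
  nc <- as.integer(round(config$extent_length))
  nr <- as.integer(round(config$extent_width))
  if (nrow(trees) &&
      (any(trees$x < 0 | trees$x > config$extent_length) ||
       any(trees$y < 0 | trees$y > config$extent_width))) {
    stop_amz("trees outside the extent")
  }
  cc <- crown_columns(trees, nc, nr)
  with_seed(config$seed + 3L, {
    n_col <- rpois(nr * nc, config$point_density)
    total <- sum(n_col)
    col_of <- rep.int(seq_len(nr * nc), n_col)
    jj <- (col_of - 1L) %/% nr + 1L
    ii <- (col_of - 1L) %% nr + 1L
    x <- (jj - 1L) + runif(total)
    y <- (ii - 1L) + runif(total)
    zg <- raster_extract(terrain, x, y)
    ncr <- cc$count[cbind(ii, jj)]
    srf <- cc$surface[cbind(ii, jj)]
    p_crown <- ifelse(ncr > 0L, 1 - (1 - config$crown_interception)^ncr, 0)
    is_crown <- runif(total) < p_crown
    z <- numeric(total)
    n_cr <- sum(is_crown)
    s_cr <- srf[is_crown]
    base_cr <- config$crown_base_fraction * s_cr
    deficit <- if (config$penetration_mean > 0) {
      rexp(n_cr, 1 / config$penetration_mean)
    } else {
      numeric(n_cr)
    }
    top <- runif(n_cr) < config$top_echo_fraction
    zrel <- ifelse(top,
                   pmax(s_cr - deficit, base_cr),
                   base_cr + runif(n_cr) * (s_cr - base_cr))
    z[is_crown] <- zg[is_crown] + zrel
    z[!is_crown] <- zg[!is_crown] + rnorm(sum(!is_crown), 0, config$ground_noise_sd)
    truth <- ifelse(is_crown, "crown", "ground")
    rn <- ifelse(!is_crown & ncr > 0L, 2L, 1L)

    # inject isolated outliers: at >= 10 m above the local canopy no other
    # return can share a 4-m neighbourhood (centred or anchored), provided
    # the outliers themselves keep >= 8 m Chebyshev separation
    n_out <- config$outlier_count
    if (n_out > 0L) {
      # per-column elevation of the highest possible return (terrain + canopy)
      colx <- rep(seq_len(nc) - 0.5, each = nr)
      coly <- rep(seq_len(nr) - 0.5, times = nc)
      colmax <- matrix(raster_extract(terrain, colx, coly), nr, nc) + cc$surface
      ox <- numeric(0); oy <- numeric(0); oz <- numeric(0)
      tries <- 0L
      while (length(ox) < n_out && tries < 200L * n_out) {
        tries <- tries + 1L
        px <- runif(1, 0, config$extent_length)
        py <- runif(1, 0, config$extent_width)
        jj <- max(1L, floor(px) - 4L):min(nc, floor(px) + 6L)
        ii <- max(1L, floor(py) - 4L):min(nr, floor(py) + 6L)
        top <- max(colmax[ii, jj])
        pz <- top + runif(1, 10, 100)
        sep <- if (length(ox)) {
          min(pmax(pmax(abs(ox - px), abs(oy - py)), abs(oz - pz)))
        } else {
          Inf
        }
        if (sep >= 8) {
          ox <- c(ox, px); oy <- c(oy, py); oz <- c(oz, pz)
        }
      }
      x <- c(x, ox); y <- c(y, oy); z <- c(z, oz)
      truth <- c(truth, rep("outlier", length(ox)))
      rn <- c(rn, rep(1L, length(ox)))
    }
    point_cloud(x, y, z, return_number = rn, truth = truth)
  })
}

#' Rasterize true stand biomass
#'
#' Sums individual stem AGB (from the allometry registry) per grid cell and
#' divides by the cell area, the same definition used for field-plot AGB.
#' Cell totals conserve mass: summing the raster times the cell area
#' recovers the stem-summed AGB exactly.
#'
#' @param trees stand data frame (needs `x`, `y`, `dbh`, `height`,
#'   `wood_density`, `growth_form`).
#' @param grid_size cell size (m); must divide the extent.
#' @param registry an [allometry_registry()].
#' @param extent `c(xmin, xmax, ymin, ymax)` of the output grid.
#' @return An [amz_raster()] of true AGB (kg m^-2).
#' @export
true_agb_raster <- function(trees, grid_size = 50,
                            registry = allometry_registry(),
                            extent = c(0, 500, 0, 300)) {
  nc <- (extent[2] - extent[1]) / grid_size
  nr <- (extent[4] - extent[3]) / grid_size
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9) {
    stop_amz("grid_size %g does not divide the extent", grid_size)
  }
  nc <- as.integer(round(nc)); nr <- as.integer(round(nr))
  v <- matrix(0, nr, nc)
  if (nrow(trees)) {
    agb <- stem_agb(trees, registry)
    jj <- pmin(floor((trees$x - extent[1]) / grid_size) + 1L, nc)
    ii <- pmin(floor((trees$y - extent[3]) / grid_size) + 1L, nr)
    sums <- rowsum(agb, (jj - 1L) * nr + ii)
    v[as.integer(rownames(sums))] <- sums[, 1]
  }
  amz_raster(v / grid_size^2, extent[1], extent[3], grid_size)
}

#' Generate a regional true-biomass field
#'
#' A smooth correlated random field of AGB on a coarse grid (250 m by
#' default), standing in for regional biomass variation when exercising the
#' wall-to-wall extrapolation at scales no single transect covers. Values
#' are clamped to \[0, 450\] Mg ha^-1 around a 180 +/- 80 Mg ha^-1
#' distribution typical of dense tropical forest.
#'
#' @param extent_x,extent_y region size (m).
#' @param cell cell size (m).
#' @param agb_mean,agb_sd target mean and SD (Mg ha^-1).
#' @param correlation_length spatial correlation length (m).
#' @param seed RNG seed.
#' @return An [amz_raster()] of AGB (Mg ha^-1).
#' @export
generate_agb_field <- function(extent_x = 10000, extent_y = 10000, cell = 250,
                               agb_mean = 180, agb_sd = 80,
                               correlation_length = 1500, seed = 1L) {
  nc <- as.integer(round(extent_x / cell))
  nr <- as.integer(round(extent_y / cell))
  with_seed(seed + 5L, {
    f <- gauss_blur(matrix(rnorm(nr * nc), nr, nc), correlation_length / cell)
    f <- (f - mean(f)) / stats::sd(f)
    amz_raster(pmin(pmax(agb_mean + agb_sd * f, 0), 450), 0, 0, cell)
  })
}

#' Generate a synthetic satellite covariate stack
#'
#' Emulates the 250-m predictor layers of the wall-to-wall model: two
#' optical vegetation indices (23 pseudo-composites each, mirroring one
#' year of 16-day compositing, summarized to q1/mean/q3), L-band radar
#' backscatter (HV saturating in biomass, HH weaker), a smooth
#' precipitation gradient, elevation aggregated from the terrain, and
#' cell-center coordinates. The optical and radar layers are saturating
#' increasing functions of true AGB plus seeded per-composite noise.
#'
#' @param true_agb_250 true AGB [amz_raster()] in Mg ha^-1 on the target
#'   grid.
#' @param terrain terrain [amz_raster()]; aggregated by block mean to the
#'   target grid (its extent must match).
#' @param config a [scene_config()] (noise SDs and seed).
#' @return A [covariate_stack()].
#' @export
generate_covariates <- function(true_agb_250, terrain, config) {
  a <- true_agb_250$values
  nr <- nrow(a); nc <- ncol(a)
  srtm <- if (all(dim(terrain$values) == c(nr, nc)) &&
              abs(terrain$cell - true_agb_250$cell) < 1e-9) {
    terrain
  } else {
    f <- true_agb_250$cell / terrain$cell
    if (abs(f - round(f)) > 1e-9 ||
        nrow(terrain$values) %% round(f) != 0 ||
        ncol(terrain$values) %% round(f) != 0) {
      stop_amz("terrain grid cannot be co-registered to the AGB grid")
    }
    block_aggregate(terrain, as.integer(round(f)), 0)
  }
  if (!all(dim(srtm$values) == c(nr, nc))) {
    stop_amz("terrain and AGB grids do not co-register")
  }
  ras <- function(v) amz_raster(matrix(v, nr, nc), true_agb_250$xmin,
                                true_agb_250$ymin, true_agb_250$cell,
                                true_agb_250$crs)
  cen <- cell_centers(true_agb_250)
  xm <- matrix(rep(cen$x, each = nr), nr, nc)
  ym <- matrix(rep(cen$y, times = nc), nr, nc)
  with_seed(config$seed + 4L, {
    composites <- function(base, noise_sd, amp) {
      lapply(1:23, function(t) {
        ras(base + amp * sin(2 * pi * t / 23) +
              rnorm(length(base), 0, noise_sd))
      })
    }
    ndvi <- composites(0.35 + 0.55 * a / (a + 120), config$ndvi_noise_sd, 0.03)
    evi <- composites(0.22 + 0.42 * a / (a + 150), config$evi_noise_sd, 0.03)
    nq <- summarize_time_series(ndvi)
    eq <- summarize_time_series(evi)
    hv <- ras(-18 + 9 * a / (a + 90) + rnorm(length(a), 0, config$hv_noise_sd))
    hh <- ras(-9 + 4 * a / (a + 150) + rnorm(length(a), 0, config$hh_noise_sd))
    trmm <- ras(120 + 120 * (xm - min(xm)) / max(diff(range(xm)), 1) +
                  40 * sin(2 * pi * (ym - min(ym)) / max(diff(range(ym)), 1) / 4))
    covariate_stack(
      ndvi_q1 = nq$q1, ndvi_mean = nq$mean, ndvi_q3 = nq$q3,
      evi_q1 = eq$q1, evi_mean = eq$mean, evi_q3 = eq$q3,
      palsar_hh = hh, palsar_hv = hv, trmm_mean = trmm,
      srtm = srtm, x = ras(xm), y = ras(ym)
    )
  })
}

#' Rectangular transect polygon
#'
#' Rectangle of the given length and width centred on a point and rotated
#' by an azimuth (degrees clockwise from north, the long axis pointing
#' along the azimuth).
#'
#' @param center_x,center_y centre coordinates (m).
#' @param azimuth orientation (degrees clockwise from north).
#' @param length,width side lengths (m).
#' @return list with `polygon` (4 x 2 vertex matrix, counter-clockwise) and
#'   `area_ha` (`length * width / 1e4`).
#' @export
transect_polygon <- function(center_x, center_y, azimuth, length, width) {
  if (length <= 0 || width <= 0) stop_amz("length and width must be positive")
  a <- azimuth * pi / 180
  u <- c(sin(a), cos(a))            # along-track unit vector
  v <- c(cos(a), -sin(a))           # across-track unit vector
  hl <- length / 2; hw <- width / 2
  corners <- rbind(
    -hl * u - hw * v, hl * u - hw * v, hl * u + hw * v, -hl * u + hw * v
  )
  poly <- sweep(corners, 2, c(center_x, center_y), "+")
  colnames(poly) <- c("x", "y")
  list(polygon = poly, area_ha = length * width / 1e4)
}

#' Generate a complete synthetic scene
#'
#' Convenience wrapper chaining terrain, stand, point cloud and true 50-m
#' biomass; adds 250-m covariates when the extent is divisible by 250 m.
#'
#' @param config a [scene_config()].
#' @param registry allometry registry used for true stem biomass.
#' @return list with `config`, `terrain`, `trees`, `cloud`,
#'   `true_agb_50m` and (when available) `true_agb_250m` + `covariates`.
#' @export
generate_scene <- function(config = scene_config(),
                           registry = allometry_registry()) {
  terrain <- generate_terrain(config)
  trees <- generate_stand(config, terrain)
  cloud <- simulate_point_cloud(terrain, trees, config)
  extent <- c(0, config$extent_length, 0, config$extent_width)
  agb50 <- true_agb_raster(trees, 50, registry, extent)
  out <- list(config = config, terrain = terrain, trees = trees,
              cloud = cloud, true_agb_50m = agb50)
  if (config$extent_length %% 250 == 0 && config$extent_width %% 250 == 0) {
    agb250 <- to_mg_ha(regrid_mean(agb50, 250, min_valid_fraction = 0))
    out$true_agb_250m <- agb250
    out$covariates <- generate_covariates(agb250, terrain, config)
  }
  out
}
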