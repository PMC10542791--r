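#' Allometry registry for individual-stem biomass
#'
#' Maps each growth form to a function `(dbh, height, wood_density) -> AGB`
#' in kg. The defaults are documented stand-ins from the pantropical
#' allometry literature, fully overridable per growth form:
#' \describe{
#'   \item{tree}{moist-forest pantropical D-H-rho power law
#'     `0.0673 * (rho * D^2 * H)^0.976` (D in cm, H in m, rho in g cm^-3).}
#'   \item{palm}{diameter-based power law `exp(-3.3488 + 2.7483 * log(D))`.}
#'   \item{liana}{diameter-based power law `exp(-1.484 + 2.657 * log(D))`.}
#' }
#' Validation never depends on the specific coefficients, only on registry
#' mechanics and monotonicity; site-specific equations should be supplied
#' via `...` when available.
#'
#' @param ... named overrides, e.g.
#'   `tree = function(dbh, height, wood_density) ...`.
#' @return An `allometry_registry` (named list of functions).
#' @export
allometry_registry <- function(...) {
  defaults <- list(
    tree = function(dbh, height, wood_density) {
      0.0673 * (wood_density * dbh^2 * height)^0.976
    },
    palm = function(dbh, height, wood_density) {
      exp(-3.3488 + 2.7483 * log(dbh))
    },
    liana = function(dbh, height, wood_density) {
      exp(-1.484 + 2.657 * log(dbh))
    }
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!is.function(overrides[[nm]])) {
      stop_amz("registry entry '%s' must be a function", nm)
    }
    defaults[[nm]] <- overrides[[nm]]
  }
  structure(defaults, class = "allometry_registry")
}

#' Individual-stem aboveground biomass
#'
#' Applies the growth-form-specific allometric equation to one stem record
#' or to every row of a stem table.
#'
#' @param record data frame with columns `dbh` (cm), `height` (m),
#'   `wood_density` (g cm^-3) and `growth_form`.
#' @param registry an [allometry_registry()].
#' @return numeric vector of stem AGB (kg).
#' @export
stem_agb <- function(record, registry = allometry_registry()) {
  if (nrow(record) == 0L) return(numeric())
  missing_forms <- setdiff(unique(record$growth_form), names(registry))
  if (length(missing_forms)) {
    stop_amz("no allometric equation registered for growth form '%s'",
             missing_forms[1])
  }
  if (any(record$dbh <= 0) || any(record$height <= 0)) {
    stop_amz("stem records need positive dbh and height")
  }
  out <- numeric(nrow(record))
  for (gf in unique(record$growth_form)) {
    i <- record$growth_form == gf
    out[i] <- registry[[gf]](record$dbh[i], record$height[i],
                             record$wood_density[i])
  }
  out
}

#' Georeferenced field plot
#'
#' @param plot_id identifier.
#' @param polygon closed or open vertex matrix (2 columns, projected m).
#' @param stems stem table (see [stem_agb()]).
#' @param area plot area in m^2; computed from the polygon when omitted and
#'   checked against it (0.1% tolerance) when given.
#' @return A `field_plot` list.
#' @export
field_plot <- function(plot_id, polygon, stems, area = NULL) {
  polygon <- as.matrix(polygon)
  poly_area <- abs(polygon_area(polygon))
  if (is.null(area)) {
    area <- poly_area
  } else if (abs(area - poly_area) > 1e-3 * area) {
    stop_amz("plot %s: declared area %.1f m^2 differs from polygon area %.1f m^2",
             plot_id, area, poly_area)
  }
  if (area <= 0) stop_amz("plot %s: area must be positive", plot_id)
  structure(list(plot_id = plot_id, polygon = polygon, area = area,
                 stems = stems),
            class = "field_plot")
}

# signed shoelace area; accepts open or closed rings
polygon_area <- function(p) {
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

#' Field-plot aboveground biomass density
#'
#' Total stem biomass (kg) divided by plot area (m^2).
#'
#' @param plot a [field_plot()].
#' @param registry an [allometry_registry()].
#' @return AGB in kg m^-2.
#' @export
plot_agb <- function(plot, registry = allometry_registry()) {
  if (is.null(plot$stems) || nrow(plot$stems) == 0L) {
    warning(sprintf("plot %s has no stems; AGB = 0", plot$plot_id),
            call. = FALSE)
    return(0)
  }
  sum(stem_agb(plot$stems, registry)) / plot$area
}

# TRUE for points inside or on the boundary of a simple polygon
point_in_polygon <- function(px, py, poly) {
  if (all(poly[1, ] == poly[nrow(poly), ])) {
    poly <- poly[-nrow(poly), , drop = FALSE]
  }
  inside <- as.logical(mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]),
                                    cbind(px, py)))
  # mgcv::in.out is undefined on the boundary; close it explicitly
  n <- nrow(poly)
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    a <- poly[k, ]; b <- poly[if (k == n) 1 else k + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    within <- px >= min(a[1], b[1]) - 1e-9 & px <= max(a[1], b[1]) + 1e-9 &
      py >= min(a[2], b[2]) - 1e-9 & py <= max(a[2], b[2]) + 1e-9
    on_edge <- on_edge | (abs(cross) < 1e-9 * (1 + abs(px) + abs(py)) & within)
  }
  inside | on_edge
}

#' Clip a point cloud to a polygon
#'
#' Keeps returns strictly inside or on the boundary (closed polygon
#' semantics). An empty intersection returns an empty cloud, not an error.
#'
#' @param cloud a [point_cloud()].
#' @param polygon vertex matrix (2 columns) or a [field_plot()].
#' @return The clipped [point_cloud()].
#' @export
clip_cloud <- function(cloud, polygon) {
  if (inherits(polygon, "field_plot")) polygon <- polygon$polygon
  polygon <- as.matrix(polygon)
  if (abs(polygon_area(polygon)) <= 0) stop_amz("degenerate clip polygon")
  if (nrow(cloud) == 0L) return(cloud)
  keep <- point_in_polygon(cloud$x, cloud$y, polygon)
  as_point_cloud(cloud[keep, , drop = FALSE])
}

#' LiDAR-derived plot biomass
#'
#' Runs the LiDAR biomass chain over one field plot: clip the transect
#' cloud to the plot polygon, normalize against the transect DTM, build the
#' 1-m CHM, average it into a plot-mean top-of-canopy height, and apply the
#' TCH power law. Mirrors how plot-scale LiDAR AGB is computed when
#' validating the transect model against field plots.
#'
#' @param cloud transect [point_cloud()] (elevation, outliers removed).
#' @param plot a [field_plot()].
#' @param dtm transect DTM [amz_raster()].
#' @param coeffs an [allometric_coefficients()].
#' @return AGB in kg m^-2, with attribute `low_coverage = TRUE` when the
#'   clipped cloud has fewer than 1 return per 4 m^2.
#' @export
lidar_plot_agb <- function(cloud, plot, dtm,
                           coeffs = allometric_coefficients()) {
  clipped <- clip_cloud(cloud, plot)
  low <- nrow(clipped) < plot$area / 4
  if (low) {
    warning(sprintf("plot %s: only %d returns for %.0f m^2 (low coverage)",
                    plot$plot_id, nrow(clipped), plot$area), call. = FALSE)
  }
  if (nrow(clipped) == 0L) {
    return(structure(NA_real_, low_coverage = TRUE))
  }
  norm <- normalize_cloud(clipped, dtm)
  chm <- build_chm(norm, cell_size = 1)
  tch <- mean(chm$values, na.rm = TRUE)
  structure(agb_from_tch(tch, coeffs), low_coverage = low)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided two-sample rank test reported in both conventions: `U` is the
#' Mann-Whitney statistic of `x` (the convention R prints as `W`), and `W`
#' is the classical rank-sum of `x` in the pooled ranking
#' (`W = U + n_x (n_x + 1) / 2`). The p-value is exact (distribution
#' enumeration) when `n_x * n_y <= 400` and there are no ties, otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y numeric samples.
#' @return list with `U`, `W`, `p_two_sided`, `exact` (logical) and the
#'   sample sizes.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop_amz("both samples need at least one value")
  pooled <- c(x, y)
  r <- rank(pooled)
  w_rank <- sum(r[seq_len(nx)])
  u <- w_rank - nx * (nx + 1) / 2
  if (length(unique(pooled)) == 1L) {
    warning("degenerate data: all values identical; p = 1", call. = FALSE)
    return(list(U = u, W = w_rank, p_two_sided = 1, exact = FALSE,
                n_x = nx, n_y = ny))
  }
  ties <- anyDuplicated(pooled) > 0L
  exact <- (nx * ny <= 400) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE)
  )
  list(U = u, W = w_rank, p_two_sided = unname(ht$p.value), exact = exact,
       n_x = nx, n_y = ny)
}

#' Validate LiDAR biomass against field plots
#'
#' Computes field AGB and LiDAR AGB for each plot, compares the two samples
#' with the rank-sum test, and returns a tabular report. `clouds` may be a
#' single transect cloud (clipped per plot) or a named list of per-plot
#' clouds keyed by `plot_id`.
#'
#' @param plots list of [field_plot()]s (>= 2).
#' @param clouds transect [point_cloud()] or named list of clouds.
#' @param dtm transect DTM (or named list parallel to `clouds`).
#' @param registry an [allometry_registry()].
#' @param coeffs an [allometric_coefficients()].
#' @param csv_path,json_path optional output paths for the serialized
#'   report.
#' @return A `validation_report`: list with `table` (one row per plot),
#'   `mean_field`, `mean_lidar`, `W`, `U`, `p_two_sided`, `correlation`.
#' @export
validate_against_field <- function(plots, clouds, dtm,
                                   registry = allometry_registry(),
                                   coeffs = allometric_coefficients(),
                                   csv_path = NULL, json_path = NULL) {
  if (length(plots) < 2L) stop_amz("validation needs at least 2 plots")
  ids <- vapply(plots, function(p) as.character(p$plot_id), "")
  per_plot_clouds <- is.list(clouds) && !inherits(clouds, "point_cloud")
  if (per_plot_clouds) {
    orphans <- setdiff(ids, names(clouds))
    if (length(orphans)) {
      stop_amz("plots without a matching cloud: %s",
               paste(orphans, collapse = ", "))
    }
  }
  field <- vapply(plots, plot_agb, 0, registry = registry)
  lidar <- vapply(seq_along(plots), function(i) {
    cl <- if (per_plot_clouds) clouds[[ids[i]]] else clouds
    dt <- if (is.list(dtm) && !is_amz_raster(dtm)) dtm[[ids[i]]] else dtm
    as.numeric(lidar_plot_agb(cl, plots[[i]], dt, coeffs))
  }, 0)
  tab <- data.frame(plot_id = ids, field_agb_kg_m2 = field,
                    lidar_agb_kg_m2 = lidar, stringsAsFactors = FALSE)
  wt <- wilcoxon_rank_sum(field, lidar)
  rep <- list(
    table = tab,
    mean_field = mean(field), mean_lidar = mean(lidar, na.rm = TRUE),
    U = wt$U, W = wt$W, p_two_sided = wt$p_two_sided,
    correlation = if (stats::sd(field) > 0 && stats::sd(lidar, na.rm = TRUE) > 0)
      stats::cor(field, lidar, use = "complete.obs") else NA_real_
  )
  class(rep) <- "validation_report"
  if (!is.null(csv_path)) write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(rep[c("mean_field", "mean_lidar", "U", "W",
                               "p_two_sided", "correlation")],
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %d plots\n  mean field AGB %.2f kg m-2, mean LiDAR AGB %.2f kg m-2\n  rank-sum W = %g (U = %g), two-sided p = %.4f\n",
    nrow(x$table), x$mean_field, x$mean_lidar, x$W, x$U, x$p_two_sided
  ))
  invisible(x)
}

#' Sample square field plots from a synthetic scene
#'
#' Places non-overlapping axis-aligned square plots on the scene and fills
#' them with the stems that fall inside; used to close the loop between the
#' generator's stand and the plot-based calibration.
#'
#' @param trees stand data frame from [generate_stand()].
#' @param config a [scene_config()].
#' @param n_plots number of plots.
#' @param plot_size side length (m).
#' @param seed RNG seed.
#' @return list of [field_plot()]s.
#' @export
sample_field_plots <- function(trees, config, n_plots = 10, plot_size = 50,
                               seed = 1L) {
  nx <- floor(config$extent_length / plot_size)
  ny <- floor(config$extent_width / plot_size)
  if (n_plots > nx * ny) stop_amz("extent fits only %d plots", nx * ny)
  with_seed(seed + 7L, {
    cells <- sample(nx * ny, n_plots)
    lapply(seq_along(cells), function(k) {
      cx <- ((cells[k] - 1) %% nx) * plot_size
      cy <- ((cells[k] - 1) %/% nx) * plot_size
      poly <- cbind(
        x = c(cx, cx + plot_size, cx + plot_size, cx),
        y = c(cy, cy, cy + plot_size, cy + plot_size)
      )
      inside <- trees$x >= cx & trees$x < cx + plot_size &
        trees$y >= cy & trees$y < cy + plot_size
      field_plot(sprintf("plot_%02d", k), poly, trees[inside, , drop = FALSE])
    })
  })
}
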