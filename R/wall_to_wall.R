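# Names (and order) of the twelve predictors of the extrapolation model.
PREDICTOR_NAMES <- c(
  "ndvi_q1", "ndvi_mean", "ndvi_q3", "evi_q1", "evi_mean", "evi_q3",
  "palsar_hh", "palsar_hv", "trmm_mean", "srtm", "x", "y"
)

#' Co-registered 250-m covariate stack
#'
#' Holds exactly the twelve predictor layers of the wall-to-wall model:
#' NDVI and EVI time-series summaries (q1/mean/q3), PALSAR-2-style HH and
#' HV backscatter, TRMM-style mean precipitation, SRTM elevation, and the
#' cell-center X and Y coordinates. All layers must share one grid.
#'
#' @param ... the twelve named [amz_raster()] layers.
#' @return A `covariate_stack`.
#' @export
covariate_stack <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !is_amz_raster(layers[[1]])) {
    layers <- layers[[1]]
  }
  missing <- setdiff(PREDICTOR_NAMES, names(layers))
  if (length(missing)) {
    stop_amz("missing covariate layers: %s", paste(missing, collapse = ", "))
  }
  layers <- layers[PREDICTOR_NAMES]
  ref <- layers[[1]]
  for (nm in PREDICTOR_NAMES) {
    if (!same_grid(ref, layers[[nm]])) {
      stop_amz("layer '%s' is not co-registered with '%s'",
               nm, PREDICTOR_NAMES[1])
    }
  }
  structure(layers, class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  r <- x[[1]]
  cat(sprintf("<covariate_stack> 12 layers, %d x %d cells of %g m\n",
              nrow(r$values), ncol(r$values), r$cell))
  invisible(x)
}

#' Summarize a raster time series into quartiles and mean
#'
#' Per-pixel first quartile, arithmetic mean and third quartile across a
#' stack of co-registered composites, ignoring nodata. Quartiles use linear
#' interpolation between order statistics (the type-7 convention); pixels
#' valid in no layer become nodata.
#'
#' @param layers list of co-registered [amz_raster()]s (>= 4).
#' @return list of [amz_raster()]s: `q1`, `mean`, `q3`.
#' @export
summarize_time_series <- function(layers) {
  if (length(layers) < 4L) stop_amz("need at least 4 composites, got %d",
                                    length(layers))
  ref <- layers[[1]]
  for (l in layers) {
    if (!same_grid(ref, l)) stop_amz("composites are not co-registered")
  }
  m <- vapply(layers, function(l) as.vector(l$values),
              numeric(length(ref$values)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  q1 <- apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else quantile(v, 0.25, names = FALSE, type = 7)
  })
  q3 <- apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else quantile(v, 0.75, names = FALSE, type = 7)
  })
  mn <- rowMeans(m, na.rm = TRUE)
  mn[!is.finite(mn)] <- NA_real_
  wrap <- function(v) amz_raster(matrix(v, nrow(ref$values)), ref$xmin,
                                 ref$ymin, ref$cell, ref$crs)
  list(q1 = wrap(q1), mean = wrap(mn), q3 = wrap(q3))
}

#' Resample a raster onto a target grid
#'
#' `method = "mean"` block-averages onto a coarser aligned grid (the rule
#' used to bring optical and radar products to 250 m); `method = "nearest"`
#' picks the source cell containing each target cell centre (the rule used
#' for coarse layers such as gridded precipitation, and for reference-map
#' comparison).
#'
#' @param raster source [amz_raster()].
#' @param target_grid an [amz_raster()] defining the output geometry (its
#'   values are ignored).
#' @param method `"mean"` or `"nearest"`.
#' @return An [amz_raster()] on the target grid.
#' @export
resample_covariate <- function(raster, target_grid,
                               method = c("mean", "nearest")) {
  method <- match.arg(method)
  if (method == "mean") {
    f <- target_grid$cell / raster$cell
    if (f < 1 - 1e-9) {
      stop_amz("mean resampling to a finer grid (%g m -> %g m) is not defined",
               raster$cell, target_grid$cell)
    }
    if (abs(f - round(f)) > 1e-9) {
      stop_amz("mean resampling needs nested grids (factor %g)", f)
    }
    out <- block_aggregate(raster, as.integer(round(f)), 0)
    if (!same_grid(out, target_grid)) {
      stop_amz("aggregated grid does not align with the target grid")
    }
    return(out)
  }
  cen <- cell_centers(target_grid)
  nr <- nrow(target_grid$values); nc <- ncol(target_grid$values)
  qx <- rep(cen$x, each = nr)
  qy <- rep(cen$y, times = nc)
  amz_raster(matrix(raster_extract(raster, qx, qy), nr, nc),
             target_grid$xmin, target_grid$ymin, target_grid$cell,
             target_grid$crs)
}

#' Assemble the training table for the extrapolation model
#'
#' One row per cell where the LiDAR AGB response and all twelve predictors
#' are valid; rows lost to nodata predictors are counted in the
#' `dropped` attribute.
#'
#' @param agb_250 LiDAR AGB [amz_raster()] (Mg ha^-1), nodata where no
#'   transect coverage.
#' @param covariates a [covariate_stack()] on the same grid.
#' @return data frame with `cell` (index), `agb` and the twelve predictors.
#' @export
assemble_training <- function(agb_250, covariates) {
  if (!same_grid(agb_250, covariates[[1]])) {
    stop_amz("AGB raster and covariates are not co-registered")
  }
  resp <- as.vector(agb_250$values)
  pred <- vapply(covariates, function(l) as.vector(l$values),
                 numeric(length(resp)))
  colnames(pred) <- names(covariates)
  has_resp <- is.finite(resp)
  ok <- has_resp & apply(is.finite(pred), 1, all)
  if (!any(ok)) stop_amz("no usable training cells")
  tab <- data.frame(cell = which(ok), agb = resp[ok], pred[ok, , drop = FALSE])
  attr(tab, "dropped") <- sum(has_resp) - sum(ok)
  tab
}

#' Train the random-forest extrapolation model
#'
#' Fits a seeded random-forest regressor of LiDAR AGB on the twelve
#' covariates and scores it on a held-out fraction of cells. Variable
#' importance is the total squared-error reduction attributed to each
#' variable across all splits (the difference in squared error between a
#' node and its children), reported raw, scaled by its maximum, and as a
#' percentage of the total.
#'
#' @param table training table from [assemble_training()].
#' @param n_trees,mtry,min_leaf forest hyperparameters; `mtry` defaults to
#'   `ceiling(p / 3)`.
#' @param holdout_fraction fraction of rows held out for the fit report.
#' @param seed RNG seed controlling both the holdout split and the forest.
#' @return list with `model` (a `ranger` fit plus metadata) and `report`
#'   (`r2`, `rmse`, `rmse_relative`, `importance` data frame, `n_train`,
#'   `n_holdout`). `r2` and `rmse` are held-out statistics.
#' @export
train_model <- function(table, n_trees = 500L, mtry = NULL, min_leaf = 5L,
                        holdout_fraction = 0.2, seed = 1L) {
  if (nrow(table) < 50L) stop_amz("need >= 50 training rows, got %d", nrow(table))
  if (stats::sd(table$agb) == 0) stop_amz("degenerate constant response")
  p <- length(PREDICTOR_NAMES)
  mtry <- mtry %||% ceiling(p / 3)
  n_hold <- max(1L, round(nrow(table) * holdout_fraction))
  hold <- with_seed(seed + 11L, sample(nrow(table), n_hold))
  train <- table[-hold, , drop = FALSE]
  test <- table[hold, , drop = FALSE]
  fit <- ranger::ranger(
    dependent.variable.name = "agb",
    data = train[, c("agb", PREDICTOR_NAMES)],
    num.trees = n_trees, mtry = mtry, min.node.size = min_leaf,
    importance = "impurity", seed = seed, num.threads = 1
  )
  pred <- predict(fit, data = test[, PREDICTOR_NAMES],
                  num.threads = 1)$predictions
  rmse <- sqrt(mean((pred - test$agb)^2))
  r2 <- 1 - sum((pred - test$agb)^2) / sum((test$agb - mean(test$agb))^2)
  imp <- importance_percentages(fit$variable.importance)
  report <- list(
    r2 = r2, rmse = rmse, rmse_relative = rmse / mean(test$agb),
    importance = imp, n_train = nrow(train), n_holdout = nrow(test)
  )
  model <- structure(
    list(fit = fit, predictors = PREDICTOR_NAMES, seed = seed),
    class = "agb_rf_model"
  )
  list(model = model, report = report)
}

#' Scale a raw importance vector
#'
#' `scaled = raw / max(raw)`; `percentage = raw / sum(raw)`.
#'
#' @param raw_importance named non-negative vector with a positive maximum.
#' @return data frame `variable`, `raw`, `scaled`, `percentage`, sorted by
#'   decreasing importance.
#' @export
importance_percentages <- function(raw_importance) {
  if (any(raw_importance < 0)) stop_amz("importance values must be >= 0")
  if (max(raw_importance) <= 0) stop_amz("all-zero importance vector")
  ord <- order(raw_importance, decreasing = TRUE)
  raw <- raw_importance[ord]
  data.frame(
    variable = names(raw) %||% as.character(ord),
    raw = as.numeric(raw),
    scaled = as.numeric(raw / max(raw)),
    percentage = as.numeric(raw / sum(raw)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Predict the wall-to-wall biomass map
#'
#' Applies a trained extrapolation model to every cell of the covariate
#' stack. Cells with any nodata predictor become nodata; predictions are
#' clamped at zero (biomass is non-negative).
#'
#' @param model trained model from [train_model()].
#' @param covariates a [covariate_stack()].
#' @return An AGB [amz_raster()] (Mg ha^-1).
#' @export
predict_map <- function(model, covariates) {
  if (!inherits(model, "agb_rf_model")) stop_amz("not an agb_rf_model")
  missing <- setdiff(model$predictors, names(covariates))
  if (length(missing)) {
    stop_amz("covariate stack lacks predictor layers: %s",
             paste(missing, collapse = ", "))
  }
  ref <- covariates[[1]]
  pred <- vapply(covariates[model$predictors],
                 function(l) as.vector(l$values),
                 numeric(length(ref$values)))
  colnames(pred) <- model$predictors
  ok <- apply(is.finite(pred), 1, all)
  out <- rep(NA_real_, nrow(pred))
  if (any(ok)) {
    df <- as.data.frame(pred[ok, , drop = FALSE])
    out[ok] <- pmax(
      predict(model$fit, data = df, num.threads = 1)$predictions, 0
    )
  }
  amz_raster(matrix(out, nrow(ref$values)), ref$xmin, ref$ymin, ref$cell,
             ref$crs)
}
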