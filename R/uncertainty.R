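#' Calibration-uncertainty configuration
#'
#' The three uncertainty levels of the LiDAR calibration chain:
#' \enumerate{
#'   \item plot-level allometric error — each plot's AGB is perturbed by a
#'     relative Gaussian error (`plot_agb_relative_sd`);
#'   \item limited plot sampling — plots are bootstrap-resampled before
#'     each refit (`bootstrap_plots`);
#'   \item model residual variance — the fraction of variance the fitted
#'     power law cannot capture, drawn per cell from `residual_model`
#'     (a function of TCH and predicted AGB returning an SD in kg m^-2).
#' }
#'
#' @param plot_agb_relative_sd relative SD of plot AGB (level 1).
#' @param n_bootstrap Monte Carlo replicates.
#' @param bootstrap_plots resample plots between refits (level 2)?
#' @param residual_relative_sd default level-3 residual SD as a fraction of
#'   predicted AGB; ignored when `residual_model` is supplied.
#' @param residual_model optional `function(tch, pred_agb)` returning the
#'   heteroscedastic residual SD (kg m^-2).
#' @return A `calibration_uncertainty` list.
#' @export
calibration_uncertainty <- function(plot_agb_relative_sd = 0.10,
                                    n_bootstrap = 250L,
                                    bootstrap_plots = TRUE,
                                    residual_relative_sd = 0.10,
                                    residual_model = NULL) {
  if (plot_agb_relative_sd < 0 || residual_relative_sd < 0) {
    stop_amz("uncertainty SDs must be >= 0")
  }
  if (n_bootstrap < 2L) stop_amz("n_bootstrap must be >= 2")
  if (is.null(residual_model)) {
    residual_model <- local({
      rel <- residual_relative_sd
      function(tch, pred_agb) rel * pred_agb
    })
  }
  structure(
    list(plot_agb_relative_sd = plot_agb_relative_sd,
         n_bootstrap = as.integer(n_bootstrap),
         bootstrap_plots = bootstrap_plots,
         residual_model = residual_model),
    class = "calibration_uncertainty"
  )
}

#' Per-cell calibration uncertainty at 50 m
#'
#' Monte Carlo propagation of the three calibration uncertainty levels into
#' a per-cell SD of LiDAR AGB. Each replicate perturbs the calibration
#' plots (level 1), bootstrap-resamples them (level 2), refits the power
#' law `AGB = scale * a * TCH^b` by nonlinear least squares, predicts every
#' 50-m cell and adds a residual draw (level 3); the output is the per-cell
#' SD across replicates, in Mg ha^-1. Replicate seeds follow a counter
#' scheme (`seed + replicate`) so runs parallelize reproducibly.
#'
#' @param plots data frame with columns `tch` (m) and `agb` (kg m^-2):
#'   the calibration pairs (>= 10).
#' @param tch_50 TCH [amz_raster()] (m) at 50 m.
#' @param cfg a [calibration_uncertainty()].
#' @param seed master RNG seed.
#' @param coeffs starting [allometric_coefficients()]; `scale` is held
#'   fixed during refits.
#' @return SD [amz_raster()] (Mg ha^-1) with attribute `failed_replicates`.
#' @export
calibration_uncertainty_50m <- function(plots, tch_50,
                                        cfg = calibration_uncertainty(),
                                        seed = 1L,
                                        coeffs = allometric_coefficients()) {
  if (nrow(plots) < 10L) stop_amz("need >= 10 calibration pairs, got %d",
                                  nrow(plots))
  tch <- as.vector(tch_50$values)
  valid <- is.finite(tch)
  n_cell <- sum(valid)
  s <- coeffs$scale
  # accumulate deviations from a baseline prediction: the variance is
  # shift-invariant and this avoids catastrophic cancellation when the
  # replicate spread is tiny
  preds <- matrix(NA_real_, n_cell, cfg$n_bootstrap)
  failed <- 0L
  for (r in seq_len(cfg$n_bootstrap)) {
    pred <- with_seed(seed + r, {
      agb_r <- plots$agb *
        (1 + rnorm(nrow(plots), 0, cfg$plot_agb_relative_sd))
      agb_r <- pmax(agb_r, 1e-6)
      idx <- if (cfg$bootstrap_plots) {
        sample(nrow(plots), replace = TRUE)
      } else {
        seq_len(nrow(plots))
      }
      dat <- data.frame(tch = plots$tch[idx], agb = agb_r[idx])
      fit <- tryCatch(
        minpack.lm::nlsLM(
          agb ~ s * a * tch^b, data = dat,
          start = list(a = coeffs$a, b = coeffs$b),
          lower = c(1e-6, 0.1), upper = c(10, 5),
          control = minpack.lm::nls.lm.control(maxiter = 100)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        NULL
      } else {
        cf <- coef(fit)
        p <- s * cf[["a"]] * tch[valid]^cf[["b"]]
        p + rnorm(n_cell, 0, cfg$residual_model(tch[valid], p))
      }
    })
    if (is.null(pred)) {
      failed <- failed + 1L
      next
    }
    preds[, r] <- pred
  }
  if (failed > 0.2 * cfg$n_bootstrap) {
    stop_amz("power-law refit failed in %d of %d replicates", failed,
             cfg$n_bootstrap)
  }
  # sample SD across replicates, kg m^-2 -> Mg ha^-1
  keep <- !apply(is.na(preds), 2, any)
  out <- rep(NA_real_, length(tch))
  out[valid] <- 10 * apply(preds[, keep, drop = FALSE], 1, stats::sd)
  r50 <- amz_raster(matrix(out, nrow(tch_50$values)), tch_50$xmin,
                    tch_50$ymin, tch_50$cell, tch_50$crs)
  attr(r50, "failed_replicates") <- failed
  r50
}

#' Resample a 50-m SD map to the wall-to-wall grid
#'
#' Default aggregation is the block mean of SD values, which assumes full
#' within-block correlation of calibration error — conservative, and
#' consistent with the strong spatial correlation of canopy structure
#' within 250 m. `method = "independent"` gives the alternative
#' `sqrt(mean(sd^2) / n)` under block-wise independence.
#'
#' @param sd_50 SD [amz_raster()] at 50 m.
#' @param target_cell output cell (m), an integer multiple of 50.
#' @param method `"mean"` (full correlation) or `"independent"`.
#' @param min_valid_fraction coverage rule as in [regrid_mean()].
#' @return SD [amz_raster()] on the coarse grid.
#' @export
resample_uncertainty <- function(sd_50, target_cell = 250,
                                 method = c("mean", "independent"),
                                 min_valid_fraction = 0.5) {
  method <- match.arg(method)
  f <- target_cell / sd_50$cell
  if (abs(f - round(f)) > 1e-9) {
    stop_amz("target cell %g m is not a multiple of %g m", target_cell,
             sd_50$cell)
  }
  f <- as.integer(round(f))
  if (method == "mean") {
    return(block_aggregate(sd_50, f, min_valid_fraction))
  }
  var_r <- sd_50
  var_r$values <- sd_50$values^2
  agg <- block_aggregate(var_r, f, min_valid_fraction)
  agg$values <- sqrt(agg$values / f^2)
  agg
}

#' Propagate satellite-extrapolation uncertainty
#'
#' For each of `n_maps` replicates, the AGB of every LiDAR-covered cell is
#' drawn from `Normal(agb, sd)` truncated at zero, the extrapolation model
#' is retrained on the drawn responses (replicate seed = `seed + r`), and
#' the wall-to-wall map is re-predicted. The output is the per-pixel SD of
#' AGB across the replicate maps, with the nodata pattern of the
#' prediction.
#'
#' @param agb_250 LiDAR AGB [amz_raster()] (Mg ha^-1; nodata = no LiDAR).
#' @param sd_250 calibration SD [amz_raster()] on the same grid (>= 0).
#' @param covariates a [covariate_stack()].
#' @param n_maps number of replicate maps (>= 2). The operational choice is
#'   1000; convergence studies show a few dozen already rank pixels stably.
#' @param seed master RNG seed.
#' @param n_trees,mtry,min_leaf forest hyperparameters per replicate.
#' @return SD [amz_raster()] (Mg ha^-1) with attribute
#'   `truncated_fraction` (fraction of draws clamped at zero).
#' @export
propagate_satellite <- function(agb_250, sd_250, covariates, n_maps = 1000L,
                                seed = 1L, n_trees = 500L, mtry = NULL,
                                min_leaf = 5L) {
  if (!same_grid(agb_250, sd_250)) {
    stop_amz("agb_250 and sd_250 are not co-registered")
  }
  if (n_maps < 2L) stop_amz("n_maps must be >= 2")
  if (any(sd_250$values < 0, na.rm = TRUE)) stop_amz("negative SD input")
  agb <- as.vector(agb_250$values)
  sdv <- as.vector(sd_250$values)
  lidar <- is.finite(agb)
  if (!any(lidar)) stop_amz("no LiDAR cells in agb_250")
  sdv[lidar & !is.finite(sdv)] <- 0
  mtry <- mtry %||% ceiling(length(PREDICTOR_NAMES) / 3)

  pred_mat <- vapply(covariates, function(l) as.vector(l$values),
                     numeric(length(agb)))
  colnames(pred_mat) <- names(covariates)
  ok_pred <- apply(is.finite(pred_mat), 1, all)
  train_cells <- which(lidar & ok_pred)
  train_df <- as.data.frame(pred_mat[train_cells, , drop = FALSE])
  pred_df <- as.data.frame(pred_mat[ok_pred, , drop = FALSE])

  acc_sum <- numeric(sum(ok_pred))
  acc_sq <- numeric(sum(ok_pred))
  base <- NULL  # first replicate map; deviations accumulate against it
  n_trunc <- 0
  for (r in seq_len(n_maps)) {
    y <- with_seed(seed + r, {
      rnorm(length(train_cells), agb[train_cells], sdv[train_cells])
    })
    n_trunc <- n_trunc + sum(y < 0)
    y <- pmax(y, 0)
    dat <- cbind(agb = y, train_df)
    # the forest seed is fixed across replicates: the Monte Carlo measures
    # uncertainty propagated through the response draws, not the forest's
    # own bootstrap stochasticity
    fit <- ranger::ranger(
      dependent.variable.name = "agb", data = dat,
      num.trees = n_trees, mtry = mtry, min.node.size = min_leaf,
      seed = seed, num.threads = 1
    )
    m <- pmax(predict(fit, data = pred_df, num.threads = 1)$predictions, 0)
    if (is.null(base)) base <- m
    d <- m - base
    acc_sum <- acc_sum + d
    acc_sq <- acc_sq + d^2
  }
  v <- pmax((acc_sq - acc_sum^2 / n_maps) / (n_maps - 1), 0)
  out <- rep(NA_real_, length(agb))
  out[ok_pred] <- sqrt(v)
  ref <- covariates[[1]]
  res <- amz_raster(matrix(out, nrow(ref$values)), ref$xmin, ref$ymin,
                    ref$cell, ref$crs)
  attr(res, "truncated_fraction") <- n_trunc / (n_maps * length(train_cells))
  res
}
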