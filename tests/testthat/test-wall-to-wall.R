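make_stack <- function(nr = 8, nc = 8, cell = 250, seed = 1) {
  set.seed(seed)
  ras <- function(v) amz_raster(matrix(v, nr, nc), cell = cell)
  cen_x <- (seq_len(nc) - 0.5) * cell
  cen_y <- (seq_len(nr) - 0.5) * cell
  covariate_stack(
    ndvi_q1 = ras(runif(nr * nc)), ndvi_mean = ras(runif(nr * nc)),
    ndvi_q3 = ras(runif(nr * nc)), evi_q1 = ras(runif(nr * nc)),
    evi_mean = ras(runif(nr * nc)), evi_q3 = ras(runif(nr * nc)),
    palsar_hh = ras(rnorm(nr * nc, -9)), palsar_hv = ras(rnorm(nr * nc, -15)),
    trmm_mean = ras(runif(nr * nc, 100, 300)), srtm = ras(runif(nr * nc, 50, 200)),
    x = ras(matrix(rep(cen_x, each = nr), nr, nc)),
    y = ras(matrix(rep(cen_y, times = nc), nr, nc))
  )
}

test_that("the stack enforces the twelve predictors on one grid", {
  st <- make_stack()
  expect_named(st, amazonagb:::PREDICTOR_NAMES)
  bad <- unclass(st)
  bad$srtm <- amz_raster(matrix(0, 4, 4), cell = 250)
  expect_error(do.call(covariate_stack, bad), "co-registered")
  bad2 <- unclass(st)
  bad2$srtm <- NULL
  expect_error(do.call(covariate_stack, bad2), "missing covariate")
})

test_that("time-series summaries follow the stated quartile method", {
  r <- function(v) amz_raster(matrix(v, 1, 1))
  out <- summarize_time_series(list(r(1), r(2), r(3), r(4)))
  expect_equal(out$q1$values[1, 1], 1.75)
  expect_equal(out$mean$values[1, 1], 2.5)
  expect_equal(out$q3$values[1, 1], 3.25)

  const <- summarize_time_series(lapply(1:5, function(i) r(7)))
  expect_equal(const$q1$values[1, 1], 7)
  expect_equal(const$q3$values[1, 1], 7)

  # permutation invariance and nodata handling
  set.seed(3)
  layers <- lapply(1:6, function(i) amz_raster(matrix(rnorm(20), 4, 5)))
  layers[[2]]$values[1, 1] <- NA
  a <- summarize_time_series(layers)
  b <- summarize_time_series(layers[c(4, 1, 6, 2, 3, 5)])
  expect_equal(a$q1$values, b$q1$values)
  expect_equal(a$mean$values, b$mean$values)
  all_na <- lapply(1:4, function(i) amz_raster(matrix(NA_real_, 2, 2)))
  expect_true(all(is.na(summarize_time_series(all_na)$mean$values)))
  expect_error(summarize_time_series(layers[1:3]), "at least 4")
})

test_that("resampling covers the mean and nearest contracts", {
  src <- amz_raster(matrix(runif(100), 10, 10), cell = 50)
  tgt <- amz_raster(matrix(0, 2, 2), cell = 250)
  out <- resample_covariate(src, tgt, "mean")
  expect_equal(out$values, brute_block_mean(src$values, 5L, 0), tolerance = 1e-12)
  # identity grid
  same <- resample_covariate(src, src, "mean")
  expect_equal(same$values, src$values)
  # nearest from a coarse layer is blockwise constant
  coarse <- amz_raster(matrix(1:4, 2, 2), cell = 1000)
  fine <- amz_raster(matrix(0, 8, 8), cell = 250)
  nn <- resample_covariate(coarse, fine, "nearest")
  expect_equal(length(unique(as.vector(nn$values))), 4L)
  expect_equal(nn$values[1, 1], 1)
  expect_equal(nn$values[8, 8], 4)
  expect_error(resample_covariate(coarse, fine, "mean"), "finer")
})

test_that("training rows require a valid response and all 12 predictors", {
  st <- make_stack()
  agb <- amz_raster(matrix(NA_real_, 8, 8), cell = 250)
  agb$values[1:10] <- runif(10, 50, 300)
  tab <- assemble_training(agb, st)
  expect_equal(nrow(tab), 10L)
  expect_equal(attr(tab, "dropped"), 0L)

  st2 <- make_stack()
  st2$palsar_hv$values[2, 1] <- NA   # cell index 2 is in the response set
  tab2 <- assemble_training(agb, st2)
  expect_equal(nrow(tab2), 9L)
  expect_equal(attr(tab2, "dropped"), 1L)
  # brute-force validity intersection
  resp_ok <- is.finite(as.vector(agb$values))
  pred_ok <- Reduce(`&`, lapply(st2, function(l) is.finite(as.vector(l$values))))
  expect_equal(nrow(tab2), sum(resp_ok & pred_ok))

  empty <- amz_raster(matrix(NA_real_, 8, 8), cell = 250)
  expect_error(assemble_training(empty, st), "no usable")
})

test_that("importance scaling reproduces the published worked example", {
  scaled <- c(1, 0.7704, 0.6908, 0.6065, 0.5159, 0.4857, 0.4416,
              0.1546, 0.1098, 0.0816, 0.0685, 0.0632)
  names(scaled) <- amazonagb:::PREDICTOR_NAMES
  out <- importance_percentages(scaled)
  expect_equal(out$scaled, scaled[order(scaled, decreasing = TRUE)],
               ignore_attr = TRUE)
  expect_equal(
    out$percentage[1:3], c(0.2005, 0.1544, 0.1385), tolerance = 1e-3
  )
  expect_equal(
    out$percentage,
    c(0.2005, 0.1544, 0.1385, 0.1216, 0.1034, 0.0974, 0.0885, 0.0310,
      0.0220, 0.0164, 0.0137, 0.0127),
    tolerance = 1e-3
  )
  expect_equal(sum(out$percentage), 1, tolerance = 1e-9)

  expect_equal(importance_percentages(c(a = 5))$scaled, 1)
  two <- importance_percentages(c(a = 1, b = 3))
  expect_equal(two$scaled, c(1, 1 / 3))
  expect_equal(two$percentage, c(0.75, 0.25))
  expect_error(importance_percentages(c(0, 0)), "all-zero")
  expect_error(importance_percentages(c(-1, 2)), ">= 0")
})

test_that("the forest recovers a predictor-copied response and is seeded", {
  st <- make_stack(nr = 20, nc = 20, seed = 5)
  agb <- amz_raster(100 * st$ndvi_mean$values + 50, cell = 250)
  tab <- assemble_training(agb, st)
  fit <- train_model(tab, seed = 4)
  expect_equal(fit$report$importance$variable[1], "ndvi_mean")
  expect_equal(fit$report$importance$scaled[1], 1)
  expect_gt(fit$report$r2, 0.95)
  expect_equal(sum(fit$report$importance$percentage), 1, tolerance = 1e-9)

  # determinism: identical seed, table and config -> identical predictions
  fit2 <- train_model(tab, seed = 4)
  p1 <- predict_map(fit$model, st)
  p2 <- predict_map(fit2$model, st)
  expect_identical(p1$values, p2$values)

  const <- tab
  const$agb <- 5
  expect_error(train_model(const, seed = 1), "degenerate")
  expect_error(train_model(tab[1:20, ], seed = 1), ">= 50")
})

test_that("map prediction clamps, propagates nodata and checks names", {
  st <- make_stack(nr = 20, nc = 20, seed = 5)
  agb <- amz_raster(100 * st$ndvi_mean$values + 50, cell = 250)
  fit <- train_model(assemble_training(agb, st), seed = 4)
  st$ndvi_q1$values[3, 3] <- NA
  pm <- predict_map(fit$model, st)
  expect_true(is.na(pm$values[3, 3]))
  expect_true(all(pm$values >= 0, na.rm = TRUE))

  # in-bag predictions fit at least as well as held-out scoring
  resid <- pm$values - agb$values
  r2_all <- 1 - sum(resid^2, na.rm = TRUE) /
    sum((agb$values - mean(agb$values))^2, na.rm = TRUE)
  expect_gte(r2_all + 1e-9, fit$report$r2 - 0.1)

  bad <- unclass(st)[1:11]
  expect_error(predict_map(fit$model, bad), "lacks predictor")

  # constant covariates give a constant map
  stc <- make_stack(nr = 4, nc = 4)
  for (nm in names(stc)) stc[[nm]]$values[] <- 1
  pc <- predict_map(fit$model, stc)
  expect_equal(length(unique(as.vector(pc$values))), 1L)
})
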