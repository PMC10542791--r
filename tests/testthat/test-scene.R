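test_that("generators are pure functions of (config, seed)", {
  cfg <- scene_config(extent_length = 60, extent_width = 40, seed = 5)
  t1 <- generate_terrain(cfg)
  t2 <- generate_terrain(cfg)
  expect_identical(t1$values, t2$values)
  s1 <- generate_stand(cfg, t1)
  s2 <- generate_stand(cfg, t1)
  expect_identical(s1, s2)
  c1 <- simulate_point_cloud(t1, s1, cfg)
  c2 <- simulate_point_cloud(t1, s1, cfg)
  expect_identical(c1, c2)
})

test_that("zero relief produces a constant surface", {
  cfg <- scene_config(extent_length = 50, extent_width = 30,
                      terrain_relief_amplitude = 0, seed = 1)
  terr <- generate_terrain(cfg)
  expect_true(all(terr$values == cfg$base_elevation))
})

test_that("terrain statistics match an independent filter re-implementation", {
  cfg <- scene_config(extent_length = 50, extent_width = 40,
                      terrain_relief_amplitude = 20,
                      terrain_correlation_length = 10, seed = 8)
  terr <- generate_terrain(cfg)
  oracle <- amazonagb:::with_seed(cfg$seed + 1L, {
    f <- matrix(rnorm(40 * 50), 40, 50)
    brute_gauss_blur(f, 10)
  })
  oracle <- cfg$base_elevation +
    (oracle - mean(oracle)) * (20 / (max(oracle) - min(oracle)))
  expect_equal(sd(terr$values), sd(oracle), tolerance = 0.2 * sd(oracle))
  expect_equal(max(terr$values) - min(terr$values), 20, tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(extent_length = -1), "invalid config")
  expect_error(scene_config(point_density = 0), "invalid config")
  expect_error(scene_config(terrain_correlation_length = 0), "invalid config")
})

test_that("stem counts follow the Poisson design and supports are physical", {
  cfg <- scene_config(extent_length = 500, extent_width = 200,
                      stem_density = 500, seed = 10)  # 10 ha
  terr <- generate_terrain(cfg)
  stand <- generate_stand(cfg, terr)
  expect_lt(abs(nrow(stand) - 5000), 3 * sqrt(5000))
  expect_true(all(stand$height > 0))
  expect_true(all(stand$dbh > 0))
  expect_true(all(stand$wood_density >= 0.1 & stand$wood_density <= 1.2))
  # crown radius monotone in height
  o <- order(stand$height)
  expect_true(all(diff(stand$crown_radius[o]) >= 0))

  empty_cfg <- scene_config(extent_length = 100, extent_width = 100,
                            stem_density = 0, seed = 1)
  expect_equal(nrow(generate_stand(empty_cfg, terr)), 0L)
})

test_that("a treeless scene yields ground-hugging returns at ~4 per m^2", {
  cfg <- scene_config(extent_length = 100, extent_width = 100,
                      stem_density = 0, outlier_count = 0, seed = 3)
  terr <- generate_terrain(cfg)
  cl <- simulate_point_cloud(terr, generate_stand(cfg, terr), cfg)
  expect_equal(nrow(cl) / 1e4, 4, tolerance = 0.05)
  dz <- cl$z - raster_extract(terr, cl$x, cl$y)
  expect_true(all(abs(dz) < 5 * cfg$ground_noise_sd))
  expect_true(all(cl$truth == "ground"))
})

test_that("trees outside the extent are rejected", {
  cfg <- scene_config(extent_length = 50, extent_width = 50, seed = 2)
  terr <- generate_terrain(cfg)
  bad <- data.frame(x = 60, y = 10, height = 20, dbh = 20,
                    wood_density = 0.6, growth_form = "tree", crown_radius = 3)
  expect_error(simulate_point_cloud(terr, bad, cfg), "outside the extent")
})

test_that("outlier_count = 0 leaves the ground-truth outlier set empty", {
  cfg <- scene_config(extent_length = 60, extent_width = 40,
                      outlier_count = 0, seed = 4)
  terr <- generate_terrain(cfg)
  cl <- simulate_point_cloud(terr, generate_stand(cfg, terr), cfg)
  expect_equal(sum(cl$truth == "outlier"), 0L)
})

test_that("true biomass rasterization conserves stem-summed mass", {
  s <- small_scene()
  reg <- allometry_registry()
  r <- true_agb_raster(s$scene$trees, 50, reg, extent = c(0, 200, 0, 100))
  total_raster <- sum(r$values) * 50^2
  total_stems <- sum(stem_agb(s$scene$trees, reg))
  expect_equal(total_raster, total_stems, tolerance = 1e-9)

  # one known tree in one cell
  one <- data.frame(x = 10, y = 10, height = 25, dbh = 30,
                    wood_density = 0.6, growth_form = "tree", crown_radius = 3)
  reg1 <- allometry_registry(tree = function(dbh, height, wood_density) 2500)
  r1 <- true_agb_raster(one, 50, reg1, extent = c(0, 100, 0, 100))
  expect_equal(r1$values[1, 1], 1.0)
  expect_equal(sum(r1$values != 0), 1L)

  # empty stand -> all-zero raster
  r0 <- true_agb_raster(one[0, ], 50, reg1, extent = c(0, 100, 0, 100))
  expect_true(all(r0$values == 0))
})

test_that("covariates link to biomass as documented", {
  agbf <- generate_agb_field(4000, 4000, 250, seed = 6)
  cfg <- scene_config(extent_length = 4000, extent_width = 4000,
                      terrain_cell_size = 250,
                      terrain_correlation_length = 1000,
                      seed = 6)
  terr <- generate_terrain(cfg)
  cov <- generate_covariates(agbf, terr, cfg)
  cen <- cell_centers(agbf)
  expect_equal(cov$x$values[1, ], cen$x)
  expect_equal(cov$y$values[, 1], cen$y)
  expect_equal(cov$srtm$values, terr$values)
  hv_cor <- cor(as.vector(cov$palsar_hv$values), as.vector(agbf$values),
                method = "spearman")
  expect_gt(hv_cor, 0.5)

  # noiseless link is non-decreasing in biomass
  cfg0 <- scene_config(extent_length = 4000, extent_width = 4000,
                       terrain_cell_size = 250,
                       terrain_correlation_length = 1000,
                       ndvi_noise_sd = 0, evi_noise_sd = 0,
                       hh_noise_sd = 0, hv_noise_sd = 0, seed = 6)
  cov0 <- generate_covariates(agbf, terr, cfg0)
  o <- order(as.vector(agbf$values))
  expect_true(all(diff(as.vector(cov0$ndvi_mean$values)[o]) >= -1e-12))

  # co-registration is enforced
  terr_bad <- amz_raster(matrix(0, 5, 5), cell = 300)
  expect_error(generate_covariates(agbf, terr_bad, cfg), "co-register")
})

test_that("transect polygons have the designed geometry", {
  tp <- transect_polygon(0, 0, 0, 12500, 300)
  expect_equal(tp$area_ha, 375)
  expect_equal(transect_polygon(5, 5, 30, 100, 100)$area_ha, 1)
  # rotation preserves area and maps vertices by the rotation
  t0 <- transect_polygon(10, 20, 0, 1000, 300)
  t90 <- transect_polygon(10, 20, 90, 1000, 300)
  expect_equal(t90$area_ha, t0$area_ha)
  rot <- function(p, cx, cy) {
    cbind(cx + (p[, 2] - cy), cy - (p[, 1] - cx))
  }
  expect_equal(unname(t90$polygon), unname(rot(t0$polygon, 10, 20)),
               tolerance = 1e-9)
  expect_error(transect_polygon(0, 0, 0, -5, 10), "positive")
})
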