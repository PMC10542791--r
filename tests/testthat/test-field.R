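test_that("registry equations evaluate exactly and stay monotone", {
  reg <- allometry_registry()
  rec <- data.frame(dbh = 30, height = 25, wood_density = 0.6,
                    growth_form = "tree")
  expect_equal(stem_agb(rec, reg), 0.0673 * (0.6 * 900 * 25)^0.976)
  rec2 <- rec; rec2$dbh <- 60
  expect_gt(stem_agb(rec2, reg), stem_agb(rec, reg))

  # user override contract
  regc <- allometry_registry(tree = function(dbh, height, wood_density) 123)
  expect_equal(stem_agb(rec, regc), 123)
  expect_error(allometry_registry(tree = 5), "must be a function")

  liana <- data.frame(dbh = 5, height = 15, wood_density = 0.4,
                      growth_form = "liana")
  expect_gt(stem_agb(liana, reg), 0)
  weird <- data.frame(dbh = 10, height = 10, wood_density = 0.5,
                      growth_form = "bamboo")
  expect_error(stem_agb(weird, reg), "bamboo")
})

test_that("plot AGB is total stem mass over area, linear and order-invariant", {
  poly <- cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))
  stems <- data.frame(dbh = 30, height = 25, wood_density = 0.6,
                      growth_form = "tree")
  reg <- allometry_registry(tree = function(dbh, height, wood_density) 2500)
  p <- field_plot("p1", poly, stems)
  expect_equal(p$area, 2500)
  expect_equal(plot_agb(p, reg), 1.0)

  set.seed(2)
  stems <- data.frame(dbh = runif(40, 10, 60), height = runif(40, 5, 35),
                      wood_density = runif(40, 0.4, 0.8),
                      growth_form = "tree")
  p1 <- field_plot("p1", poly, stems)
  reg <- allometry_registry()
  a1 <- plot_agb(p1, reg)
  # doubling every stem (by duplication) doubles plot AGB
  p2 <- field_plot("p2", poly, rbind(stems, stems))
  expect_equal(plot_agb(p2, reg), 2 * a1)
  # stem order does not matter; disjoint subsets add
  p3 <- field_plot("p3", poly, stems[sample(40), ])
  expect_equal(plot_agb(p3, reg), a1)
  pa <- field_plot("pa", poly, stems[1:15, ])
  pb <- field_plot("pb", poly, stems[16:40, ])
  expect_equal(plot_agb(pa, reg) + plot_agb(pb, reg), a1)

  expect_warning(pe <- plot_agb(field_plot("pe", poly, stems[0, ]), reg),
                 "no stems")
  expect_equal(pe, 0)
  expect_error(field_plot("bad", poly, stems, area = 1000), "differs")
})

test_that("plot AGB closes the loop with the generator's truth raster", {
  s <- small_scene()
  reg <- allometry_registry()
  truth <- true_agb_raster(s$scene$trees, 50, reg, extent = c(0, 200, 0, 100))
  # a plot aligned with a 50-m truth cell must match it exactly
  poly <- cbind(c(50, 100, 100, 50), c(0, 0, 50, 50))
  inside <- s$scene$trees$x >= 50 & s$scene$trees$x < 100 &
    s$scene$trees$y >= 0 & s$scene$trees$y < 50
  p <- field_plot("cell", poly, s$scene$trees[inside, ])
  expect_equal(plot_agb(p, reg), raster_extract(truth, 75, 25),
               tolerance = 1e-12)
})

test_that("cloud clipping agrees with a brute-force point-in-polygon test", {
  set.seed(5)
  cl <- point_cloud(runif(2000, 0, 100), runif(2000, 0, 100), runif(2000))
  tri <- cbind(c(10, 90, 50), c(10, 20, 90))
  clipped <- clip_cloud(cl, tri)
  keep <- brute_pip(cl$x, cl$y, tri)
  expect_equal(nrow(clipped), sum(keep))
  expect_equal(sort(clipped$x), sort(cl$x[keep]))

  # whole-extent polygon is the identity; disjoint polygon is empty
  all_poly <- cbind(c(-1, 101, 101, -1), c(-1, -1, 101, 101))
  expect_equal(nrow(clip_cloud(cl, all_poly)), nrow(cl))
  far <- cbind(c(200, 210, 210, 200), c(200, 200, 210, 210))
  expect_equal(nrow(clip_cloud(cl, far)), 0L)

  # vertex order must not matter
  rev_tri <- tri[3:1, ]
  expect_equal(nrow(clip_cloud(cl, rev_tri)), nrow(clipped))

  # union over disjoint polygons equals the sum of the parts
  left <- cbind(c(0, 49.5, 49.5, 0), c(0, 0, 100, 100))
  right <- cbind(c(50.5, 100, 100, 50.5), c(0, 0, 100, 100))
  expect_equal(
    nrow(clip_cloud(cl, left)) + nrow(clip_cloud(cl, right)),
    sum(brute_pip(cl$x, cl$y, left) | brute_pip(cl$x, cl$y, right))
  )
})

test_that("plot-scale LiDAR biomass recovers a known uniform canopy", {
  # flat terrain, all returns at exactly 20 m above ground
  set.seed(8)
  n <- 60 * 60 * 4
  cl <- point_cloud(runif(n, 0, 60), runif(n, 0, 60), rep(120, n))
  dtm <- amz_raster(matrix(100, 60, 60), cell = 1)
  poly <- cbind(c(5, 55, 55, 5), c(5, 5, 55, 55))
  p <- field_plot("u", poly, data.frame())
  agb <- lidar_plot_agb(cl, p, dtm)
  expect_equal(as.numeric(agb), 2 * 0.025 * 20^1.99, tolerance = 0.05)
  # zero-height scene gives zero biomass
  cl0 <- point_cloud(runif(n, 0, 60), runif(n, 0, 60), rep(100, n))
  expect_equal(as.numeric(lidar_plot_agb(cl0, p, dtm)), 0)
  # polygon vertex order does not matter
  p2 <- field_plot("u2", poly[4:1, ], data.frame())
  expect_equal(as.numeric(lidar_plot_agb(cl, p2, dtm)), as.numeric(agb))
})

test_that("low plot coverage attaches a warning", {
  cl <- point_cloud(c(10, 12, 14), c(10, 12, 14), c(5, 5, 5))
  dtm <- amz_raster(matrix(0, 60, 60), cell = 1)
  p <- field_plot("sparse", cbind(c(0, 50, 50, 0), c(0, 0, 50, 50)),
                  data.frame())
  expect_warning(res <- lidar_plot_agb(cl, p, dtm), "low coverage")
  expect_true(attr(res, "low_coverage"))
})

test_that("rank-sum test matches enumeration and reports both conventions", {
  w <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(w$U, 0)
  expect_equal(w$W, 3)
  expect_equal(w$p_two_sided, 1 / 3, tolerance = 1e-12)

  expect_warning(wd <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "degenerate")
  expect_equal(wd$p_two_sided, 1)

  set.seed(6)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)          # tie-free
    x <- v[1:nx]; y <- v[-(1:nx)]
    w <- wilcoxon_rank_sum(x, y)
    expect_true(w$exact)
    expect_equal(w$p_two_sided, enum_wilcox_p(x, y), tolerance = 1e-12)
    expect_equal(w$W, w$U + nx * (nx + 1) / 2)
  }

  # normal approximation tracks the exact distribution at moderate n
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15, 0.3)
  exact_p <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
  approx_p <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
  expect_lt(abs(exact_p - approx_p), 0.02)
  # the package picks the approximation above the exact-size cutoff
  w_big <- wilcoxon_rank_sum(rnorm(25), rnorm(25))
  expect_false(w_big$exact)
})

test_that("field validation produces a coherent per-plot report", {
  s <- small_scene()
  plots <- sample_field_plots(s$scene$trees, s$cfg, n_plots = 6, seed = 3)
  rep <- suppressWarnings(validate_against_field(plots, s$classified, s$dtm))
  expect_equal(nrow(rep$table), 6L)
  expect_true(all(is.finite(rep$table$field_agb_kg_m2)))
  expect_gt(rep$p_two_sided, 0.05)
  expect_gt(rep$correlation, 0.8)

  # identical samples give p = 1
  f <- rep$table$field_agb_kg_m2
  expect_equal(wilcoxon_rank_sum(f, f)$p_two_sided, 1)

  # orphan plots are reported when per-plot clouds are supplied
  named <- list(plot_01 = s$classified)
  expect_error(validate_against_field(plots, named, s$dtm), "matching cloud")
  expect_error(validate_against_field(plots[1], s$classified, s$dtm),
               "at least 2")
})
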