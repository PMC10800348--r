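# Kernel heatmaps, quartile masking and the masked Pearson spatial match.

test_that("point rasterization places mass in the right cells", {
  g <- grid_spec(c(0, 0), 100, 10, 10)
  m <- rasterize_events(x = 550, y = 350, grid = g)
  expect_equal(m[4, 6], 1)
  expect_equal(sum(m), 1)
  # out-of-grid point contributes nothing
  expect_equal(sum(rasterize_events(x = -50, y = 50, grid = g)), 0)
})

test_that("rectangle rasterization conserves area exactly", {
  g <- grid_spec(c(0, 0), 100, 10, 10)
  # rectangle exactly covering 4 cells
  r <- data.frame(xmin = 200, ymin = 300, xmax = 400, ymax = 500)
  m <- rasterize_events(rects = r, grid = g, type = "rects")
  expect_equal(m[4, 3], 1); expect_equal(m[5, 4], 1)
  expect_equal(sum(m) * 100^2, 200 * 200)
  # off-lattice rectangle still conserves area to numerical precision
  r2 <- data.frame(xmin = 137, ymin = 212.5, xmax = 512.25, ymax = 803)
  m2 <- rasterize_events(rects = r2, grid = g, type = "rects")
  expect_equal(sum(m2) * 100^2, (512.25 - 137) * (803 - 212.5),
               tolerance = 1e-12)
  expect_warning(
    rasterize_events(rects = data.frame(xmin = 1, ymin = 1, xmax = 1, ymax = 5),
                     grid = g, type = "rects"), "degenerate")
})

test_that("kernel density peaks at events and is symmetric for equal points", {
  g <- grid_spec(c(0, 0), 100, 60, 60)
  cfg <- spatial_match_config(bandwidth_m = 800, cell_size_m = 100)
  d <- kernel_density(3050, 2950, g, cfg)
  idx <- which(d$values == max(d$values), arr.ind = TRUE)
  expect_equal(unname(idx[1, ]), c(30, 31))
  # two equal points far apart: two equal maxima
  d2 <- kernel_density(c(1050, 4850), c(1050, 4850), g, cfg)
  peaks <- which(d2$values == max(d2$values), arr.ind = TRUE)
  expect_equal(nrow(peaks), 2)
  expect_error(kernel_density(-1e6, -1e6, g, cfg), "in-grid")
})

test_that("kernel mass is conserved and matches the brute-force oracle", {
  g <- grid_spec(c(0, 0), 100, 80, 80)
  set.seed(99)
  n <- 100
  # interior events at least one bandwidth from the border
  h <- 900
  x <- runif(n, h, 8000 - h); y <- runif(n, h, 8000 - h)
  for (kern in c("quartic", "gaussian")) {
    cfg <- spatial_match_config(bandwidth_m = h, kernel = kern,
                                cell_size_m = 100)
    d <- kernel_density(x, y, g, cfg)
    mass <- sum(d$values) * 100^2
    expect_equal(mass, n, tolerance = 0.01)
    oracle <- brute_force_kde(x, y, g, h, kern)
    expect_equal(d$values, oracle, tolerance = 1e-12)
  }
})

test_that("quartile mask follows the sample quantile of positive cells", {
  g <- grid_spec(c(0, 0), 1, 4, 4)
  v <- matrix(0, 4, 4)
  v[1, 1:4] <- 1:4; v[2, 1:4] <- 5:8
  d <- density_raster(g, v)
  m <- quartile_mask(d, 0.25)
  # oracle: order statistic floor(0.25 * 8) + 1 = 3rd smallest of the sample
  thr <- sort(1:8)[floor(0.25 * 8) + 1]
  expect_equal(m$meta$mask_threshold, thr)
  expect_equal(sum(m$mask), 6)                 # 1 and 2 masked, 6 survive
  expect_false(m$mask[1, 1]); expect_false(m$mask[1, 2])
  expect_true(all(!m$mask[3:4, ]))             # zero cells always nulled
  # ties: all-equal positive raster keeps everything
  d2 <- density_raster(g, matrix(3, 4, 4))
  expect_equal(sum(quartile_mask(d2, 0.25)$mask), 16)
  # q = 0 masks only zeros
  expect_equal(sum(quartile_mask(d, 0)$mask), 8)
  expect_error(quartile_mask(density_raster(g, matrix(0, 4, 4))), "positive")
})

test_that("masking more aggressively never increases the valid-cell count", {
  g <- grid_spec(c(0, 0), 1, 20, 20)
  set.seed(5)
  d <- density_raster(g, matrix(rexp(400), 20, 20))
  n_valid <- vapply(c(0, 0.1, 0.25, 0.5, 0.9),
                    function(q) sum(quartile_mask(d, q)$mask), 0)
  expect_true(all(diff(n_valid) <= 0))
  # at most a share q of positive cells is removed
  expect_gte(sum(quartile_mask(d, 0.25)$mask), 0.75 * 400)
})

test_that("masked Pearson correlation behaves at its extremes", {
  g <- grid_spec(c(0, 0), 1, 20, 20)
  set.seed(8)
  v <- matrix(rexp(400) + 0.1, 20, 20)
  a <- quartile_mask(density_raster(g, v), 0.25)
  expect_equal(spatial_match_correlation(a, a)$pearson_r, 1.0)
  # affine reversal over the joint support
  b <- density_raster(g, max(v) + 1 - v, mask = a$mask)
  expect_equal(spatial_match_correlation(a, b)$pearson_r, -1.0)
  # invariance under positive affine rescaling
  b2 <- density_raster(g, 0.3 + 2.5 * v, mask = a$mask)
  expect_equal(spatial_match_correlation(a, b2)$pearson_r, 1.0)
  # error paths
  g2 <- grid_spec(c(0, 0), 2, 20, 20)
  expect_error(spatial_match_correlation(a, density_raster(g2, v)), "grid")
  const <- density_raster(g, matrix(1, 20, 20))
  expect_error(spatial_match_correlation(a, const), "constant")
})

test_that("independent random fields correlate near zero (frozen seed)", {
  g <- grid_spec(c(0, 0), 1, 100, 100)
  set.seed(123)
  a <- density_raster(g, matrix(runif(10000), 100, 100))
  b <- density_raster(g, matrix(runif(10000), 100, 100))
  res <- spatial_match_correlation(a, b)
  expect_equal(res$n_valid_cells, 10000)
  expect_lt(abs(res$pearson_r), 0.05)
})

test_that("the trailing moving average matches its arithmetic definition", {
  s <- enforcelens:::moving_average(c(1, 2, 3, 4) / 10, 4)
  expect_equal(s, c(NA, NA, NA, 0.25))
  # a constant series is its own moving average where defined
  cs <- enforcelens:::moving_average(rep(0.4, 8), 4)
  expect_equal(cs[4:8], rep(0.4, 5))
})

test_that("the annual series couples fines to deforestation through the kernels", {
  cfg <- small_cfg(seed = 13, coupling_rho = 1, geolocation_prob = 1)
  ls <- generate_landscape(cfg)
  b <- generate_enforcement(ls)
  nt <- b$records[b$records$sanction_type == "infraction_notice", ]
  nt$year <- as.integer(substr(nt$date, 1, 4))
  sm_cfg <- spatial_match_config(bandwidth_m = 1500, cell_size_m = 200)
  g <- grid_spec(c(0, 0), 200, 100, 100)
  ms <- spatial_match_series(data.frame(year = nt$year, x = nt$x, y = nt$y),
                             ls$patches, g, sm_cfg)
  expect_s3_class(ms, "spatial_match_series")
  expect_true(all(abs(ms$pearson_r) <= 1, na.rm = TRUE))
  expect_true(all(ms$n_valid_cells >= 2, na.rm = TRUE))
  # trailing MA defined exactly where the 4-year window is full
  expect_true(all(is.na(ms$ma[1:3])))
  expect_equal(ms$ma[5], mean(ms$pearson_r[2:5]))
  # a year with no fines yields a missing correlation
  ms2 <- spatial_match_series(
    data.frame(year = nt$year, x = nt$x, y = nt$y)[nt$year != 2012, ],
    ls$patches, g, sm_cfg)
  expect_true(is.na(ms2$pearson_r[ms2$year == 2012]))
})
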