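make_dem <- function(seed = 2, cell_m = 200) {
  gen_transect_dem(cell_m = cell_m, seed = seed)
}

station_frame <- function(dem, n = 9, value_fun, seed = 4) {
  set.seed(seed)
  ok <- which(!is.na(dem$elevation))
  cells <- sample(ok, n)
  rc <- arrayInd(cells, dim(dem$elevation))
  xs <- antestiarisk:::.grid_x(dem)
  ys <- antestiarisk:::.grid_y(dem)
  df <- data.frame(lon = xs[rc[, 2]], lat = ys[rc[, 1]],
                   elevation_m = dem$elevation[cells])
  df$value <- value_fun(df)
  df
}

test_that("constant station values give a constant surface", {
  dem <- make_dem()
  st <- station_frame(dem, value_fun = function(d) rep(0.7, nrow(d)))
  f <- fit_interpolator(st)
  r <- suppressWarnings(interpolate(f, dem))
  expect_true(all(abs(r$values - 0.7) < 1e-8, na.rm = TRUE))
})

test_that("a linear-in-elevation field is recovered exactly", {
  dem <- make_dem()
  a <- 0.2; b <- 4e-4
  st <- station_frame(dem, value_fun = function(d) a + b * d$elevation_m)
  f <- fit_interpolator(st)
  expect_lt(abs(f$beta[4] - b), 1e-6)
  expect_lt(max(abs(f$w)), 1e-6)
  r <- suppressWarnings(interpolate(f, dem))
  truth <- a + b * dem$elevation
  expect_lt(max(abs(r$values - truth), na.rm = TRUE), 1e-4)
})

test_that("smoothing-zero fits interpolate station values exactly", {
  dem <- make_dem()
  st <- station_frame(dem, value_fun = function(d)
    sin(d$lon * 50) + 0.001 * d$elevation_m, seed = 8)
  f <- fit_interpolator(st)
  pred <- predict(f, st$lon, st$lat, st$elevation_m)
  expect_lt(max(abs(pred - st$value)), 1e-6)
})

test_that("increasing smoothing never improves the training fit", {
  dem <- make_dem()
  st <- station_frame(dem, value_fun = function(d)
    cos(d$lat * 80) + 5e-4 * d$elevation_m, seed = 9)
  rss <- vapply(c(0, 1e-6, 1e-4, 1e-2), function(s) {
    f <- fit_interpolator(st, smoothing = s)
    sum((predict(f, st$lon, st$lat, st$elevation_m) - st$value)^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-10))
})

test_that("degenerate station designs are rejected with diagnostics", {
  dem <- make_dem()
  st <- station_frame(dem, value_fun = function(d) d$elevation_m)
  expect_error(fit_interpolator(st[1:3, ]), "at least 4 stations")
  flat <- st
  flat$elevation_m <- 1500
  expect_error(fit_interpolator(flat), "rank-deficient")
})

test_that("ERI maps are clipped to [0, 1] after interpolation", {
  dem <- make_dem()
  st <- station_frame(dem, value_fun = function(d)
    0.5 + 0.002 * (d$elevation_m - 1350), seed = 10)  # overshoots [0,1]
  f <- fit_interpolator(st)
  r <- suppressWarnings(interpolate(f, dem, clip = c(0, 1)))
  expect_gte(min(r$values, na.rm = TRUE), 0)
  expect_lte(max(r$values, na.rm = TRUE), 1)
})

test_that("point sampling is a nearest-cell lookup with error records", {
  dem <- make_dem()
  ramp <- raster_map(dem$elevation * 2, dem, name = "ramp")
  xs <- antestiarisk:::.grid_x(dem)
  ys <- antestiarisk:::.grid_y(dem)
  pick <- cbind(c(3, 10, 50, 50, 20), c(2, 7, 1, 1, 5))
  coords <- data.frame(lon = xs[pick[, 2]], lat = ys[pick[, 1]])
  got <- sample_points(ramp, coords)
  expect_equal(got$value, ramp$values[pick])
  expect_true(all(got$status == "ok"))
  # repeated coordinate -> repeated value (rows 3 and 4)
  expect_equal(got$value[3], got$value[4])
  oob <- sample_points(ramp, data.frame(lon = 0, lat = 0))
  expect_equal(oob$status, "out_of_bounds")
  expect_true(is.na(oob$value))
})

test_that("band sampling is paired, in-band, sized and seed-reproducible", {
  dem <- make_dem(cell_m = 100)
  r1 <- raster_map(dem$elevation, dem, "cur")
  r2 <- raster_map(dem$elevation + 10, dem, "fut")
  centres <- seq(1000, 1700, by = 100)
  pts <- band_sample(dem, list(cur = r1, fut = r2), centres,
                     n_per_band = 20, seed = 42)
  expect_equal(nrow(pts), 160)   # 8 bands x 20 points
  expect_true(all(pts$elevation_m >= pts$band - 50 &
                  pts$elevation_m < pts$band + 50))
  expect_equal(pts$fut - pts$cur, rep(10, 160))  # pairing: same cells
  pts2 <- band_sample(dem, list(cur = r1, fut = r2), centres,
                      n_per_band = 20, seed = 42)
  expect_identical(pts, pts2)
  expect_error(band_sample(dem, list(cur = r1), 5000, n_per_band = 20),
               "band 5000")
})

test_that("ASCII grid and XYZ rasters round-trip value-exactly", {
  dem <- make_dem()
  vals <- dem$elevation / 3 + pi
  r <- raster_map(vals, dem, name = "v")
  p1 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, p1)
  r1 <- read_ascii_grid(p1, as = "raster_map")
  expect_identical(r1$values, unname(r$values))
  expect_equal(r1$xll, r$xll)
  expect_equal(r1$cellsize, r$cellsize)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_xyz_grid(r, p2)
  r2 <- read_xyz_grid(p2, as = "raster_map")
  expect_identical(r2$values, unname(r$values))
  # DEM round trip as well
  p3 <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(dem, p3)
  d3 <- read_ascii_grid(p3)
  expect_identical(d3$elevation, unname(dem$elevation))
})

test_that("density maps apply the fitted regression cellwise", {
  dem <- make_dem()
  set.seed(31)
  df <- data.frame(elevation_m = runif(24, 1000, 1700))
  df$count <- rpois(24, exp(-3.4 + 0.0038 * df$elevation_m))
  fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
  r <- density_map_from_glm(fit, dem)
  cf <- fit$coefficients$estimate
  expect_equal(r$values,
               exp(cf[1] + cf[2] * dem$elevation) / 15, tolerance = 1e-12)
  expect_true(all(r$values >= 0, na.rm = TRUE))
  # slope 0, intercept log(15): uniform density of one bug per tree
  flat <- fit
  flat$coefficients$estimate <- c(log(15), 0)
  ru <- density_map_from_glm(flat, dem)
  expect_true(all(abs(ru$values - 1) < 1e-12, na.rm = TRUE))
  # positive slope: raster monotone in elevation
  ord <- order(dem$elevation[!is.na(dem$elevation)])
  expect_true(all(diff(r$values[!is.na(r$values)][ord]) >= 0))
})
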