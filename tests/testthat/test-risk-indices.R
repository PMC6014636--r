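test_that("hourly profile reproduces the daily extremes and mean", {
  expect_equal(hourly_profile(20, 20), rep(20, 24))
  h <- hourly_profile(10, 30)
  expect_equal(min(h), 10)
  expect_equal(max(h), 30)
  expect_lt(abs(mean(h) - 20), 1e-9)
  # matches a direct evaluation of the cosine formula
  expect_equal(h, 20 - 10 * cos(2 * pi * (0:23) / 24))
  expect_error(hourly_profile(30, 10), "t_min must not exceed")
})

test_that("day-level demography is consistent with the constant life table", {
  m <- default_models_cached()
  dd <- daily_demography(m, 22, 22)
  lt <- life_table_at(m, 22)
  expect_equal(dd$lambda_d, lt$lambda, tolerance = 1e-12)
  expect_equal(dd$T_d, lt$T, tolerance = 1e-12)
  expect_false(dd$lethal)
  expect_equal(unname(dd$stage_survival),
               unname(immature_survival(m, 22)$stage_survival),
               tolerance = 1e-12)
})

test_that("a day entirely above the development window is lethal for all stages", {
  m <- default_models_cached()
  dd <- daily_demography(m, 33.5, 35)
  expect_true(all(dd$lethal_stage))
  expect_true(dd$lethal)
  expect_equal(dd$rm_d, index_options()$rm_floor)
})

test_that("daily demography matches an independent hourly-hazard recomputation", {
  m <- default_models_cached()
  for (day in list(c(15, 29), c(12, 22), c(20, 32))) {
    dd <- daily_demography(m, day[1], day[2])
    hrs <- (day[1] + day[2]) / 2 -
      (day[2] - day[1]) / 2 * cos(2 * pi * (0:23) / 24)
    surv <- vapply(m$stages, function(st) {
      mm <- eval_response(st$mortality, hrs)
      if (any(mm >= 1)) return(0)
      exp(mean(log(1 - mm)))
    }, numeric(1))
    expect_equal(unname(dd$stage_survival), unname(surv), tolerance = 1e-9)
    lt <- life_table_at(m, mean(hrs))
    expect_equal(dd$lambda_d, lt$lambda, tolerance = 1e-9)
  }
})

test_that("ERI counts lethal days out of 365", {
  m <- default_models_cached()
  expect_equal(eri(constant_series(22), m), 1)
  mixed <- daily_temperature_series("mix", 37.45, -3.33, 1200,
                                    c(rep(34, 73), rep(22, 292)),
                                    c(rep(34, 73), rep(22, 292)))
  expect_equal(eri(mixed, m), 0.8)
  expect_equal(eri(constant_series(34), m), 0)
})

test_that("turning favourable days lethal never increases ERI", {
  m <- default_models_cached()
  set.seed(5)
  tmin <- runif(365, 16, 22)
  tmax <- tmin + runif(365, 8, 12)
  base <- daily_temperature_series("a", 37.45, -3.33, 1200, tmin, tmax)
  e0 <- eri(base, m)
  for (k in c(10, 50, 200)) {
    tmin2 <- tmin; tmax2 <- tmax
    tmin2[1:k] <- 34; tmax2[1:k] <- 35
    e1 <- eri(daily_temperature_series("a", 37.45, -3.33, 1200,
                                       tmin2, tmax2), m)
    expect_lte(e1, e0)
    e0 <- e1  # nesting: each step adds lethal days
  }
})

test_that("GI equals 365/T at constant temperature and is a day sum", {
  m <- default_models_cached()
  lt <- life_table_at(m, 21)
  expect_equal(gi(constant_series(21), m), 365 / lt$T, tolerance = 1e-9)
  set.seed(7)
  d <- 1:365
  tmin <- 16 + 1.5 * cos(2 * pi * (d - 14) / 365) + rnorm(365, 0, 0.7)
  tmax <- tmin + 11
  s1 <- daily_temperature_series("a", 37.45, -3.33, 1200, tmin, tmax)
  # brute-force day loop through the exported day-level operation
  loop_gi <- sum(vapply(d, function(i) {
    1 / daily_demography(m, tmin[i], tmax[i])$T_d
  }, numeric(1)))
  expect_equal(gi(s1, m), loop_gi, tolerance = 1e-9)
  # permutation invariance
  p <- sample(365)
  s2 <- daily_temperature_series("a", 37.45, -3.33, 1200, tmin[p], tmax[p])
  expect_equal(gi(s2, m), gi(s1, m), tolerance = 1e-12)
  expect_equal(ai(s2, m), ai(s1, m), tolerance = 1e-12)
})

test_that("AI is the summed log10 of daily finite rates", {
  m <- default_models_cached()
  set.seed(9)
  d <- 1:365
  tmin <- 15 + 2 * cos(2 * pi * (d - 14) / 365) + rnorm(365, 0, 1)
  tmax <- tmin + 11.5
  s <- daily_temperature_series("a", 37.45, -3.33, 1300, tmin, tmax)
  # product-then-log oracle in log space via the day-level operation
  loop_ai <- sum(vapply(d, function(i)
    log10(daily_demography(m, tmin[i], tmax[i])$lambda_d), numeric(1)))
  expect_equal(ai(s, m), loop_ai, tolerance = 1e-9)
  # constant series: AI = 365 * log10(lambda)
  expect_equal(ai(constant_series(21), m),
               365 * log10(life_table_at(m, 21)$lambda), tolerance = 1e-9)
})

test_that("uniform warming raises GI while rates are increasing", {
  m <- default_models_cached()
  set.seed(13)
  tmin <- runif(365, 12, 14)
  tmax <- tmin + 10   # means 17-19, below the development optimum
  g0 <- gi(daily_temperature_series("a", 37.45, -3.33, 1500, tmin, tmax), m)
  g1 <- gi(daily_temperature_series("a", 37.45, -3.33, 1500,
                                    tmin + 2, tmax + 2), m)
  expect_gt(g1, g0)
})

test_that("growth factor is the base-10 antilog of the activity index", {
  expect_equal(growth_factor(4), 10000)
  expect_equal(growth_factor(0), 1)
  expect_equal(round(growth_factor(2.94), -1), 870)
  expect_equal(round(growth_factor(4.84), -2), 69200)
})

test_that("station index tables carry coordinates and reject duplicates", {
  m <- default_models_cached()
  s1 <- constant_series(21, elevation = 1500, id = "A")
  s2 <- constant_series(21, elevation = 1100, id = "B")
  tab <- indices_at_stations(list(s1), m)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$eri, eri(s1, m))
  expect_equal(tab$gi, gi(s1, m))
  expect_equal(tab$ai, ai(s1, m))
  tab2 <- indices_at_stations(list(s1, s2), m)
  expect_equal(tab2$eri[1], tab2$eri[2])  # identical series, identical rows
  expect_equal(tab2$ai[1], tab2$ai[2])
  expect_error(indices_at_stations(list(s1, s1), m), "duplicate station ids")
})

test_that("series construction enforces 365 ordered valid days", {
  expect_error(daily_temperature_series("x", 0, 0, 100, rep(20, 100),
                                        rep(21, 100)), "365")
  expect_error(daily_temperature_series("x", 0, 0, 100, rep(22, 365),
                                        rep(20, 365)), "exceeds")
  # leap day dropped on ingest
  s <- daily_temperature_series("x", 0, 0, 100, rep(20, 366), rep(21, 366))
  expect_length(s$t_min, 365)
})

test_that("station CSV files round-trip", {
  m <- default_models_cached()
  dem <- gen_transect_dem(cell_m = 200, seed = 3)
  st <- gen_station_temperatures(dem, n_stations = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_station_csv(st, path)
  st2 <- read_station_csv(path)
  expect_equal(names(st2), sort(names(st)))
  expect_equal(st2$S2$t_max, st$S2$t_max, tolerance = 1e-12)
  expect_equal(st2$S3$elevation, st$S3$elevation)
})
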