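# run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

#' Annual temperature summary of the transect logger locations
#'
#' Mean and standard deviation of the daily minimum and maximum air
#' temperatures at five logger locations on the Mt. Kilimanjaro coffee
#' transect (1081-1705 m asl), for the 2013 observation year ("current")
#' and for a mid-century RCP 4.5 projection at the same points ("future"),
#' together with the future-minus-current differences. These summaries
#' calibrate the defaults of the synthetic temperature generator and of the
#' future scenario.
#'
#' @return Data frame with one row per logger location.
#' @export
logger_summary <- function() {
  utils::read.csv(system.file("extdata", "kilimanjaro_logger_summary.csv",
                              package = "antestiarisk"))
}

#' Default calibrated species parameter set
#'
#' A synthetic-but-constrained thermal life-history model for the antestia
#' bug, calibrated so that all of the following hold (and are re-checkable
#' with [check_species_constraints()]):
#'
#' * development occurs exactly within the 14.6-32.9 degree C thermal window;
#' * the intrinsic rate of increase is positive exactly on the 19-25 degree C
#'   interval (0.5 degree grid);
#' * total immature mortality at 30 degrees C is 89% (survival 0.11);
#' * the potential number of generations per year (365/T) lies within
#'   2.6-4.4 across 19-25 degrees C;
#' * total immature survival is maximal on the 22-24 degree C interval.
#'
#' The functional forms are standard insect phenology families (a unimodal
#' limited development-rate curve per stage, a U-shaped
#' polynomial-in-exponent stage mortality curve, a unimodal fecundity curve
#' and an increasing senescence rate); the specific coefficients are a
#' calibration to the published constraints, not a re-fit of any original
#' life-table observations.
#'
#' @return A [stage_model_set()].
#' @export
default_species_params <- function() {
  durations <- c(egg = 8, n1 = 7, n2 = 9, n3 = 11, n4 = 13, n5 = 15)
  # Stage mortality: m(T) = min(1, exp(p(T - 23.9))) with quartic p chosen
  # so that the per-stage minimum is 0.025 at 23.9 C, the six-stage survival
  # at 30 C is 0.11 (89% total immature mortality), and mortality saturates
  # at 1 at/below 9 C and at/above 31 C. p'(0) = 0 keeps the minimum at the
  # reference temperature.
  tref <- 23.9
  xs <- c(0, 30 - tref, 31 - tref, 9 - tref)
  A <- t(vapply(xs, function(x) c(1, x^2, x^3, x^4), numeric(4)))
  b <- c(log(0.025), log(1 - 0.11^(1 / 6)), 0, 0)
  qc <- solve(A, b)
  mort_params <- c(tref = tref, c0 = qc[[1]], c1 = 0, c2 = qc[[2]],
                   c3 = qc[[3]], c4 = qc[[4]])
  stages <- lapply(names(durations), function(s) {
    list(rate = temperature_response(
           "development_rate", "beta",
           c(rmax = 1 / durations[[s]], tmin = 14.6, topt = 24.5,
             tmax = 32.9), stage = s),
         mortality = temperature_response(
           "immature_mortality", "poly_exp", mort_params, stage = s))
  })
  names(stages) <- names(durations)
  stage_model_set(
    stages,
    fecundity = temperature_response(
      "fecundity", "ramp",
      c(fmax = 250, topt = 25.4, beta = 0.71, kappa = 480), stage = "adult"),
    senescence = temperature_response(
      "senescence_rate", "exponential",
      c(rate_ref = 0.02, slope = 0.06, tref = 23), stage = "adult"),
    sex_ratio = 0.5)
}

#' Verify the printed thermal constraints of a species set
#'
#' Re-runs the five calibration checks listed under
#' [default_species_params()] on any [stage_model_set()].
#'
#' @param models A [stage_model_set()].
#' @param grid_step Grid resolution in degrees C (default 0.5).
#' @return Named logical vector with elements `development_limits`,
#'   `rm_window_19_25`, `mortality_89_at_30`, `generations_2.6_4.4`,
#'   `survival_optimum_22_24`.
#' @export
check_species_constraints <- function(models, grid_step = 0.5) {
  grid <- seq(10, 35, by = grid_step)
  lt <- lapply(grid, function(T) life_table_at(models, T))
  rm_pos <- grid[vapply(lt, function(x) x$rm > 0, logical(1))]
  rates_all <- sapply(models$stages, function(st)
    eval_response(st$rate, c(14.6, 32.9, 10, 35, 20)))
  dev_ok <- all(rates_all[1:4, ] == 0) && all(rates_all[5, ] > 0)
  surv30 <- immature_survival(models, 30)$total
  gi_grid <- grid[grid >= 19 & grid <= 25]
  gens <- vapply(gi_grid, function(T) 365 / life_table_at(models, T)$T,
                 numeric(1))
  surv_grid <- vapply(grid, function(T) immature_survival(models, T)$total,
                      numeric(1))
  opt <- grid[which.max(surv_grid)]
  c(development_limits = dev_ok,
    rm_window_19_25 = length(rm_pos) > 0 &&
      isTRUE(all.equal(range(rm_pos), c(19, 25))),
    mortality_89_at_30 = abs(surv30 - 0.11) <= 0.005,
    generations_2.6_4.4 = all(gens >= 2.6 & gens <= 4.4),
    survival_optimum_22_24 = opt >= 22 && opt <= 24)
}

#' Generate a synthetic elevation-transect DEM
#'
#' A north-up grid emulating the study transect: roughly 11 km x 2 km,
#' elevation ramping linearly from the southern (low) to the northern (high)
#' edge across exactly the requested range, plus seeded low-amplitude smooth
#' roughness whose along-axis slope never overturns the ramp (so every
#' ridge-line profile is strictly monotone).
#'
#' @param length_km,width_km Transect dimensions (default 11 x 2 km).
#' @param elev_range Elevation range in metres (default 1000-1700).
#' @param cell_m Cell size in metres (default 100).
#' @param origin Longitude/latitude of the lower-left corner.
#' @param roughness Roughness amplitude in metres (default 10).
#' @param seed Integer seed.
#' @return A [dem_grid()].
#' @export
gen_transect_dem <- function(length_km = 11, width_km = 2,
                             elev_range = c(1000, 1700), cell_m = 100,
                             origin = c(lon = 37.40, lat = -3.45),
                             roughness = 10, seed = 1) {
  stopifnot(length_km > 0, width_km > 0, elev_range[2] > elev_range[1])
  if (cell_m > width_km * 1000) {
    stop("cell size (", cell_m, " m) exceeds the transect width",
         call. = FALSE)
  }
  nr <- round(length_km * 1000 / cell_m)
  nc <- round(width_km * 1000 / cell_m)
  ramp <- matrix(seq(elev_range[2], elev_range[1], length.out = nr),
                 nr, nc)
  noise <- .with_seed(seed, {
    amp <- roughness * c(1, 0.8, 0.6, 0.4)
    frow <- c(0.5, 1, 1.5, 2)
    fcol <- c(1, 2, 3, 1.5)
    ph <- stats::runif(8, 0, 2 * pi)
    rows <- matrix(seq_len(nr) / nr, nr, nc)
    cols <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
    out <- 0
    for (k in 1:4) {
      out <- out + amp[k] * sin(2 * pi * (frow[k] * rows + fcol[k] * cols) +
                                ph[k]) *
        cos(2 * pi * (0.3 * frow[k] * rows) + ph[k + 4])
    }
    out
  })
  el <- ramp + noise
  el <- (el - min(el)) / (max(el) - min(el)) *
    diff(elev_range) + elev_range[1]
  dem_grid(el, xll = origin[["lon"]], yll = origin[["lat"]],
           cellsize = cell_m / 111320)
}

#' Generate daily station temperature series along the transect
#'
#' Places `n_stations` stations at evenly spaced target elevations on the
#' DEM and generates one 365-day minimum/maximum series per station:
#' annual mean decreasing with elevation at `lapse_rate`, a single-harmonic
#' seasonal cycle (warmest around mid-January, coolest around mid-July, as
#' in the southern-hemisphere-adjacent east African seasons), a fixed
#' diurnal range, and day-to-day weather anomalies that are shared across
#' stations (regional weather) with separate standard deviations for the
#' daily minimum and maximum. Defaults are calibrated to the
#' [logger_summary()] table: the lapse rate 5.08 degrees C per km and
#' sea-level intercept 28.38 degrees C come from its lowest and highest
#' rows; a standard-atmosphere preset of 6.5 degrees C per km may be passed
#' instead.
#'
#' @param dem A [dem_grid()].
#' @param n_stations Number of stations (default 9).
#' @param sea_level_mean Annual mean at sea level by linear extrapolation
#'   (degrees C).
#' @param lapse_rate Decrease of the annual mean with elevation
#'   (degrees C per km).
#' @param seasonal_amplitude Amplitude of the annual harmonic (degrees C).
#' @param peak_doy Day of year of the warmest day (default 13.5, giving the
#'   coolest point around day 196, mid-July).
#' @param diurnal_range Mean daily maximum minus minimum (degrees C).
#' @param noise_sd_min,noise_sd_max Standard deviations of the shared daily
#'   anomalies of the minimum and maximum.
#' @param seed Integer seed.
#' @return Named list of [daily_temperature_series()].
#' @export
gen_station_temperatures <- function(dem, n_stations = 9,
                                     sea_level_mean = 28.38,
                                     lapse_rate = 5.08,
                                     seasonal_amplitude = 1.2,
                                     peak_doy = 13.5,
                                     diurnal_range = 11.5,
                                     noise_sd_min = 0.73,
                                     noise_sd_max = 3.30,
                                     seed = 1) {
  stopifnot(inherits(dem, "dem_grid"), n_stations >= 1)
  targets <- seq(min(dem$elevation, na.rm = TRUE),
                 max(dem$elevation, na.rm = TRUE),
                 length.out = n_stations)
  cells <- integer(n_stations)
  avail <- which(!is.na(dem$elevation))
  for (i in seq_len(n_stations)) {
    k <- avail[which.min(abs(dem$elevation[avail] - targets[i]))]
    cells[i] <- k
    avail <- setdiff(avail, k)
  }
  xs <- .grid_x(dem); ys <- .grid_y(dem)
  d <- 1:365
  seasonal <- seasonal_amplitude * cos(2 * pi * (d - peak_doy) / 365)
  anoms <- .with_seed(seed, list(a_min = stats::rnorm(365, 0, noise_sd_min),
                                 a_max = stats::rnorm(365, 0, noise_sd_max)))
  out <- lapply(seq_len(n_stations), function(i) {
    rc <- arrayInd(cells[i], dim(dem$elevation))
    elev <- dem$elevation[cells[i]]
    mean_d <- sea_level_mean - lapse_rate * elev / 1000 + seasonal
    tn <- mean_d - diurnal_range / 2 + anoms$a_min
    tx <- mean_d + diurnal_range / 2 + anoms$a_max
    daily_temperature_series(sprintf("S%d", i), lon = xs[rc[2]],
                             lat = ys[rc[1]], elevation = elev,
                             t_min = pmin(tn, tx), t_max = pmax(tn, tx))
  })
  names(out) <- vapply(out, `[[`, character(1), "station_id")
  out
}

#' Future temperature scenario specification
#'
#' Additive per-station deltas for the daily minimum and maximum
#' temperatures (degrees C), as extracted for a future climate projection at
#' the station coordinates.
#'
#' @param station_id Character vector.
#' @param d_tmin,d_tmax Deltas per station.
#' @param label Scenario label (non-empty), e.g. `"RCP4.5-2055-like"`.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(station_id, d_tmin, d_tmax,
                          label = "RCP4.5-2055-like") {
  stopifnot(length(station_id) == length(d_tmin),
            length(d_tmin) == length(d_tmax),
            all(is.finite(d_tmin)), all(is.finite(d_tmax)),
            nzchar(label))
  structure(list(deltas = data.frame(station_id = as.character(station_id),
                                     d_tmin = d_tmin, d_tmax = d_tmax,
                                     stringsAsFactors = FALSE),
                 label = label), class = "scenario_spec")
}

#' Default future scenario from the logger summary
#'
#' Interpolates the future-minus-current differences of the
#' [logger_summary()] table linearly in elevation to each station
#' (constant extrapolation beyond the table's elevation range).
#'
#' @param series_list Named list of [daily_temperature_series()].
#' @return A [scenario_spec()].
#' @export
default_scenario_spec <- function(series_list) {
  tab <- logger_summary()
  elev <- vapply(series_list, `[[`, numeric(1), "elevation")
  d_tmin <- stats::approx(tab$elevation_m, tab$tmin_delta_c, elev,
                          rule = 2)$y
  d_tmax <- stats::approx(tab$elevation_m, tab$tmax_delta_c, elev,
                          rule = 2)$y
  scenario_spec(vapply(series_list, `[[`, character(1), "station_id"),
                d_tmin, d_tmax)
}

#' Apply a future scenario to current temperature series
#'
#' Shifts every day's minimum and maximum by the station's scenario deltas,
#' exactly.
#'
#' @param current Named list of [daily_temperature_series()].
#' @param spec A [scenario_spec()] covering every station.
#' @return Named list of future [daily_temperature_series()].
#' @export
gen_future_scenario <- function(current, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  ids <- vapply(current, `[[`, character(1), "station_id")
  missing_ids <- setdiff(ids, spec$deltas$station_id)
  if (length(missing_ids)) {
    stop("scenario spec is missing station(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  out <- lapply(current, function(s) {
    row <- spec$deltas[spec$deltas$station_id == s$station_id, ]
    daily_temperature_series(s$station_id, s$lon, s$lat, s$elevation,
                             s$t_min + row$d_tmin, s$t_max + row$d_tmax)
  })
  names(out) <- names(current)
  out
}

#' Generate synthetic farm survey counts
#'
#' Places farms in groups of `farms_per_band` at the requested elevation
#' bands and draws, for each farm and season, a farm-total count (bugs over
#' the 15 trees) from a negative-binomial process with log-link mean
#' `exp(intercept + slope * elevation + season effect)` and a Pearson
#' dispersion of `dispersion` at each mean (`dispersion = 1` gives Poisson
#' draws). With the defaults the cool dry season has about twice the warm
#' dry season's mean, about 0.1 bug per tree is expected at 1000 m and more
#' than 1 bug per tree at 1600-1700 m.
#'
#' @param dem A [dem_grid()].
#' @param n_farms Total number of farms (default 24).
#' @param farms_per_band Farms per elevation band (default 4).
#' @param band_centres Band centre elevations (default 1100-1600 m).
#' @param glm_truth Named vector `intercept`, `slope` (log-link, farm
#'   totals).
#' @param dispersion Variance inflation at the mean (>= 1).
#' @param seasonal_effects Named additive log-scale season effects.
#' @param trees_per_farm Trees per farm (15).
#' @param per_tree If `TRUE`, also decompose each farm total uniformly over
#'   the trees (multinomial) and return one row per tree.
#' @param seed Integer seed.
#' @return Data frame `farm_id, lon, lat, elevation_m, season, count`
#'   (plus `tree_index` if `per_tree`).
#' @export
gen_farm_counts <- function(dem, n_farms = 24, farms_per_band = 4,
                            band_centres = seq(1100, 1600, by = 100),
                            glm_truth = c(intercept = -3.4, slope = 0.0038),
                            dispersion = 2,
                            seasonal_effects = c(cool_dry_2014 = 0,
                                                 short_rainy_2014 = -0.35,
                                                 warm_dry_2015 = -0.64,
                                                 cool_dry_2015 = -0.15),
                            trees_per_farm = 15, per_tree = FALSE,
                            seed = 1) {
  stopifnot(inherits(dem, "dem_grid"), dispersion >= 1,
            n_farms == farms_per_band * length(band_centres))
  xs <- .grid_x(dem); ys <- .grid_y(dem)
  .with_seed(seed, {
    rows <- list()
    f <- 0
    for (ctr in band_centres) {
      in_band <- which(dem$elevation >= ctr - 50 & dem$elevation < ctr + 50)
      if (length(in_band) < farms_per_band) {
        stop("not enough DEM cells in band ", ctr, " m", call. = FALSE)
      }
      cells <- sample(in_band, farms_per_band)
      for (k in cells) {
        f <- f + 1
        rc <- arrayInd(k, dim(dem$elevation))
        for (season in names(seasonal_effects)) {
          mu <- exp(glm_truth[["intercept"]] +
                    glm_truth[["slope"]] * dem$elevation[k] +
                    seasonal_effects[[season]])
          count <- if (dispersion > 1) {
            stats::rnbinom(1, mu = mu, size = mu / (dispersion - 1))
          } else {
            stats::rpois(1, mu)
          }
          rows[[length(rows) + 1]] <- data.frame(
            farm_id = sprintf("F%02d", f), lon = xs[rc[2]], lat = ys[rc[1]],
            elevation_m = dem$elevation[k], season = season, count = count,
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out$season <- factor(out$season, levels = names(seasonal_effects))
    if (per_tree) {
      out <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
        split_counts <- stats::rmultinom(
          1, out$count[i], rep(1 / trees_per_farm, trees_per_farm))[, 1]
        data.frame(out[rep(i, trees_per_farm),
                       c("farm_id", "lon", "lat", "elevation_m", "season")],
                   tree_index = seq_len(trees_per_farm),
                   count = split_counts, row.names = NULL)
      }))
    }
    out
  })
}
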