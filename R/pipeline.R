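#' Pipeline run configuration
#'
#' Collects the file paths, seeds and index options a pipeline run needs.
#' `NULL` input paths mean "generate synthetically with the packaged
#' defaults" (see [make_fixtures()], which materialises all inputs to disk
#' first).
#'
#' @param outdir Output directory (created if absent).
#' @param species Path to a species parameter YAML, or `NULL` for
#'   [default_species_params()].
#' @param dem Path to an Arc/Info ASCII DEM, or `NULL`.
#' @param stations Path to a station temperature CSV, or `NULL`.
#' @param scenario Path to a scenario CSV (`station_id,d_tmin,d_tmax`), or
#'   `NULL` for [default_scenario_spec()].
#' @param survey Path to a farm survey CSV, or `NULL`.
#' @param seed Integer seed recorded in the manifest and used for all
#'   generated inputs and band sampling.
#' @param lethality_threshold,rm_floor See [index_options()].
#' @param smoothing Interpolator smoothing (default 0, exact interpolation).
#' @param band_centres,n_per_band Elevation-band sampling design for the
#'   current-vs-future comparison (default 8 bands x 20 points = 160
#'   points).
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir = "antestia-run", species = NULL, dem = NULL,
                       stations = NULL, scenario = NULL, survey = NULL,
                       seed = 1, lethality_threshold = 0.005,
                       rm_floor = -0.005, smoothing = 0,
                       band_centres = seq(1000, 1700, by = 100),
                       n_per_band = 20) {
  structure(list(outdir = outdir, species = species, dem = dem,
                 stations = stations, scenario = scenario, survey = survey,
                 seed = as.integer(seed),
                 lethality_threshold = lethality_threshold,
                 rm_floor = rm_floor, smoothing = smoothing,
                 band_centres = band_centres, n_per_band = n_per_band),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with any subset of the `run_config()` fields.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Read and write scenario delta CSVs
#'
#' @param spec A [scenario_spec()].
#' @param path CSV path (`station_id,d_tmin,d_tmax,label`).
#' @export
write_scenario_csv <- function(spec, path) {
  df <- spec$deltas
  df$label <- spec$label
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scenario_csv
#' @export
read_scenario_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  scenario_spec(df$station_id, df$d_tmin, df$d_tmax,
                label = if ("label" %in% names(df)) df$label[1]
                        else "scenario")
}

#' Materialise a complete synthetic study directory
#'
#' Writes every input the pipeline reads -- species parameter file, DEM,
#' current station temperatures, future scenario deltas, farm survey -- plus
#' a ready-to-run `config.yml`, all generated with the packaged defaults
#' under one seed.
#'
#' @param dir Target directory.
#' @param seed Integer seed.
#' @param cell_m DEM cell size in metres.
#' @return The [run_config()] (invisibly); its `outdir` points at
#'   `file.path(dir, "out")`.
#' @export
make_fixtures <- function(dir, seed = 1, cell_m = 100) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- default_species_params()
  write_species_params(models, file.path(dir, "species.yml"))
  dem <- gen_transect_dem(cell_m = cell_m, seed = seed)
  write_ascii_grid(dem, file.path(dir, "dem.asc"))
  stations <- gen_station_temperatures(dem, seed = seed)
  write_station_csv(stations, file.path(dir, "stations_current.csv"))
  write_scenario_csv(default_scenario_spec(stations),
                     file.path(dir, "scenario.csv"))
  survey <- gen_farm_counts(dem, seed = seed)
  utils::write.csv(survey, file.path(dir, "survey.csv"), row.names = FALSE,
                   quote = FALSE)
  cfg <- run_config(outdir = file.path(dir, "out"),
                    species = file.path(dir, "species.yml"),
                    dem = file.path(dir, "dem.asc"),
                    stations = file.path(dir, "stations_current.csv"),
                    scenario = file.path(dir, "scenario.csv"),
                    survey = file.path(dir, "survey.csv"),
                    seed = seed)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yml"))
  invisible(cfg)
}

.load_world <- function(config) {
  models <- if (is.null(config$species)) default_species_params()
            else read_species_params(config$species)
  dem <- if (is.null(config$dem)) gen_transect_dem(seed = config$seed)
         else read_ascii_grid(config$dem)
  stations <- if (is.null(config$stations))
    gen_station_temperatures(dem, seed = config$seed)
  else read_station_csv(config$stations)
  list(models = models, dem = dem, stations = stations,
       options = index_options(config$lethality_threshold, config$rm_floor))
}

.write_manifest <- function(config, inputs, outputs, name) {
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("antestiarisk")),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  path <- file.path(config$outdir, name)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.index_rasters <- function(idx, dem, smoothing) {
  clips <- list(eri = c(0, 1), gi = NULL, ai = NULL)
  out <- list()
  for (ix in c("eri", "gi", "ai")) {
    interp <- fit_interpolator(idx, value_col = ix, smoothing = smoothing)
    out[[ix]] <- interpolate(interp, dem, clip = clips[[ix]], name = ix)
  }
  out
}

#' Run the current-climate risk mapping stage
#'
#' Stations to indices to interpolated maps: computes (ERI, GI, AI) per
#' station, writes them as CSV, interpolates each index over the DEM
#' (thin-plate spline + elevation covariate) and writes one ASCII raster per
#' index plus a manifest of input/output checksums.
#'
#' @param config A [run_config()].
#' @return List with `indices` (data frame) and `rasters` (named list of
#'   [raster_map()]), invisibly.
#' @export
run_current <- function(config) {
  w <- .load_world(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  idx <- indices_at_stations(w$stations, w$models, w$options)
  idx_path <- file.path(config$outdir, "indices_current.csv")
  utils::write.csv(idx, idx_path, row.names = FALSE, quote = FALSE)
  rasters <- .index_rasters(idx, w$dem, config$smoothing)
  paths <- vapply(names(rasters), function(ix) {
    p <- file.path(config$outdir, paste0(ix, "_current.asc"))
    write_ascii_grid(rasters[[ix]], p)
    p
  }, character(1))
  .write_manifest(config,
                  Filter(Negate(is.null),
                         config[c("species", "dem", "stations")]),
                  c(idx_path, paths), "manifest_current.json")
  invisible(list(indices = idx, rasters = rasters))
}

#' Run the future-scenario stage
#'
#' Applies the scenario deltas, recomputes and maps the three indices under
#' the future temperatures, writes future and future-minus-current
#' difference rasters, samples the same random points per 100-m elevation
#' band from the current and future maps, and writes the per-band paired
#' Wilcoxon comparison table.
#'
#' @param config A [run_config()].
#' @return List with `indices_future`, `rasters_future`, `diff_rasters` and
#'   `band_tests`, invisibly.
#' @export
run_future <- function(config) {
  w <- .load_world(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  spec <- if (is.null(config$scenario)) default_scenario_spec(w$stations)
          else read_scenario_csv(config$scenario)
  future <- gen_future_scenario(w$stations, spec)
  idx_cur <- indices_at_stations(w$stations, w$models, w$options)
  idx_fut <- indices_at_stations(future, w$models, w$options)
  fut_path <- file.path(config$outdir, "indices_future.csv")
  utils::write.csv(idx_fut, fut_path, row.names = FALSE, quote = FALSE)
  ras_cur <- .index_rasters(idx_cur, w$dem, config$smoothing)
  ras_fut <- .index_rasters(idx_fut, w$dem, config$smoothing)
  ras_diff <- lapply(c(eri = "eri", gi = "gi", ai = "ai"), function(ix) {
    raster_map(ras_fut[[ix]]$values - ras_cur[[ix]]$values, w$dem,
               name = paste0(ix, "_change"))
  })
  paths <- character(0)
  for (ix in names(ras_fut)) {
    p1 <- file.path(config$outdir, paste0(ix, "_future.asc"))
    p2 <- file.path(config$outdir, paste0(ix, "_change.asc"))
    write_ascii_grid(ras_fut[[ix]], p1)
    write_ascii_grid(ras_diff[[ix]], p2)
    paths <- c(paths, p1, p2)
  }
  all_ras <- c(stats::setNames(ras_cur, paste0(names(ras_cur), "_current")),
               stats::setNames(ras_fut, paste0(names(ras_fut), "_future")))
  pts <- band_sample(w$dem, all_ras, config$band_centres,
                     n_per_band = config$n_per_band, seed = config$seed)
  long <- do.call(rbind, lapply(c("eri", "gi", "ai"), function(ix) {
    data.frame(band = pts$band, index = ix,
               current = pts[[paste0(ix, "_current")]],
               future = pts[[paste0(ix, "_future")]],
               stringsAsFactors = FALSE)
  }))
  tests <- compare_bands(long)
  tests_path <- file.path(config$outdir, "band_tests.csv")
  utils::write.csv(tests, tests_path, row.names = FALSE, quote = FALSE)
  .write_manifest(config,
                  Filter(Negate(is.null),
                         config[c("species", "dem", "stations", "scenario")]),
                  c(fut_path, paths, tests_path), "manifest_future.json")
  invisible(list(indices_future = idx_fut, rasters_future = ras_fut,
                 diff_rasters = ras_diff, band_tests = tests))
}

#' Run the survey regression stage
#'
#' Fits the overdispersion-corrected Poisson regression of farm totals on
#' elevation separately per season, writes the regression report
#' (chi-squared, df, z, slope per season), the all-season pairwise
#' comparison table, and one predicted bug-density raster per season.
#'
#' @param config A [run_config()]; its `survey` path must be set (or a
#'   synthetic survey is generated with the packaged defaults).
#' @return List with `fits`, `report`, `posthoc` and `density_rasters`,
#'   invisibly.
#' @export
run_survey <- function(config) {
  w <- .load_world(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  survey <- if (is.null(config$survey)) {
    s <- gen_farm_counts(w$dem, seed = config$seed)
    s$season <- factor(s$season)
    s
  } else read_survey_csv(config$survey)
  fits <- lapply(split(survey, survey$season), function(d)
    fit_overdispersed_poisson(d, count ~ elevation_m))
  report <- do.call(rbind, lapply(names(fits), function(season) {
    f <- fits[[season]]
    sl <- f$coefficients[f$coefficients$term == "elevation_m", ]
    data.frame(season = season, chi2 = f$chi2, df = f$df,
               slope = sl$estimate, se = sl$se, z = sl$z, p = sl$p,
               dispersion = f$dispersion, stringsAsFactors = FALSE)
  }))
  report_path <- file.path(config$outdir, "survey_report.csv")
  utils::write.csv(report, report_path, row.names = FALSE, quote = FALSE)
  season_fit <- fit_overdispersed_poisson(survey, count ~ season)
  posthoc <- season_posthoc(season_fit)
  posthoc_path <- file.path(config$outdir, "season_posthoc.csv")
  utils::write.csv(posthoc, posthoc_path, row.names = FALSE)
  density <- lapply(fits, function(f) density_map_from_glm(f, w$dem))
  paths <- vapply(names(density), function(season) {
    p <- file.path(config$outdir, paste0("density_", season, ".asc"))
    write_ascii_grid(density[[season]], p)
    p
  }, character(1))
  .write_manifest(config,
                  Filter(Negate(is.null),
                         config[c("species", "dem", "survey")]),
                  c(report_path, posthoc_path, paths),
                  "manifest_survey.json")
  invisible(list(fits = fits, report = report, posthoc = posthoc,
                 density_rasters = density))
}

#' Run all pipeline stages
#'
#' @param config A [run_config()].
#' @return List with the three stage results, invisibly.
#' @export
run_all <- function(config) {
  invisible(list(current = run_current(config),
                 future = run_future(config),
                 survey = run_survey(config)))
}
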