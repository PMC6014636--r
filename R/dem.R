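#' Digital elevation model grid
#'
#' A north-up regular grid in WGS84 longitude/latitude: row 1 is the
#' northernmost row, cells are registered at their centres, and `nodata`
#' cells are excluded from every computation.
#'
#' @param elevation Numeric matrix of elevations (m asl); `NA` allowed and
#'   treated as nodata.
#' @param xll,yll Coordinates of the lower-left corner of the grid (degrees).
#' @param cellsize Cell size in degrees (> 0).
#' @param nodata Sentinel written to files for missing cells.
#' @param crs CRS tag (informational; WGS84 lon/lat assumed).
#' @return Object of class `dem_grid`.
#' @export
dem_grid <- function(elevation, xll, yll, cellsize, nodata = -9999,
                     crs = "EPSG:4326") {
  stopifnot(is.matrix(elevation), cellsize > 0)
  structure(list(elevation = elevation, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata, crs = crs),
            class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  cat(sprintf("<dem_grid> %d x %d cells, cellsize %g deg, elev %s-%s m\n",
              nrow(x$elevation), ncol(x$elevation), x$cellsize,
              format(min(x$elevation, na.rm = TRUE)),
              format(max(x$elevation, na.rm = TRUE))))
  invisible(x)
}

# cell-centre coordinates; row 1 = north
.grid_x <- function(g) g$xll + (seq_len(ncol(.grid_of(g))) - 0.5) * g$cellsize
.grid_y <- function(g) {
  n <- nrow(.grid_of(g))
  g$yll + (n - seq_len(n) + 0.5) * g$cellsize
}

#' Value raster aligned with a DEM
#'
#' @param values Numeric matrix with the same shape as the DEM's elevation
#'   matrix; nodata cells of the DEM are propagated as `NA`.
#' @param dem A [dem_grid()].
#' @param name Variable name.
#' @param units Units string.
#' @return Object of class `raster_map` (itself a `dem_grid`-compatible
#'   georeferenced grid).
#' @export
raster_map <- function(values, dem, name = "value", units = "") {
  stopifnot(inherits(dem, "dem_grid"), is.matrix(values),
            all(dim(values) == dim(dem$elevation)))
  values[is.na(dem$elevation)] <- NA_real_
  structure(list(values = values, xll = dem$xll, yll = dem$yll,
                 cellsize = dem$cellsize, nodata = dem$nodata,
                 crs = dem$crs, name = name, units = units),
            class = "raster_map")
}

#' @export
print.raster_map <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("<raster_map> '%s' %d x %d, range %.4g-%.4g %s\n", x$name,
              nrow(x$values), ncol(x$values), rng[1], rng[2], x$units))
  invisible(x)
}

.grid_of <- function(x) {
  if (inherits(x, "dem_grid")) x$elevation else x$values
}

#' Read and write Arc/Info ASCII grids
#'
#' Plain-text ESRI ASCII raster format (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value` header, then rows north to
#' south). Values are written with 17 significant digits by default so a
#' write/read cycle is value-exact.
#'
#' @param x A [dem_grid()] or [raster_map()].
#' @param path File path (conventionally `.asc`).
#' @param digits Significant digits to write.
#' @param as Class of the object returned by `read_ascii_grid()`:
#'   `"dem_grid"` or `"raster_map"`.
#' @return `read_ascii_grid()` returns the grid object.
#' @export
write_ascii_grid <- function(x, path, digits = 17) {
  vals <- .grid_of(x)
  vals[is.na(vals)] <- x$nodata
  hdr <- c(paste("ncols", ncol(vals)), paste("nrows", nrow(vals)),
           paste("xllcorner", sprintf("%.*g", digits, x$xll)),
           paste("yllcorner", sprintf("%.*g", digits, x$yll)),
           paste("cellsize", sprintf("%.*g", digits, x$cellsize)),
           paste("NODATA_value", format(x$nodata)))
  body <- apply(vals, 1, function(r)
    paste(sprintf("%.*g", digits, r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, as = c("dem_grid", "raster_map")) {
  as <- match.arg(as)
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, character(1), 1)
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  m[m == vals[["nodata_value"]]] <- NA_real_
  if (as == "dem_grid") {
    dem_grid(m, vals[["xllcorner"]], vals[["yllcorner"]],
             vals[["cellsize"]], vals[["nodata_value"]])
  } else {
    g <- dem_grid(matrix(0, nrow(m), ncol(m)), vals[["xllcorner"]],
                  vals[["yllcorner"]], vals[["cellsize"]],
                  vals[["nodata_value"]])
    g$elevation[] <- 0
    raster_map(m, g)
  }
}

#' Read and write XYZ (long-form CSV) rasters
#'
#' Each non-nodata cell is one row `x,y,value` (cell-centre coordinates).
#' The grid geometry is recovered from the coordinates on read.
#'
#' @inheritParams write_ascii_grid
#' @export
write_xyz_grid <- function(x, path, digits = 17) {
  vals <- .grid_of(x)
  xs <- .grid_x(x); ys <- .grid_y(x)
  df <- data.frame(x = rep(xs, each = nrow(vals)), y = rep(ys, ncol(vals)),
                   value = as.vector(vals))
  df <- df[!is.na(df$value), ]
  lines <- c("x,y,value",
             sprintf("%.*g,%.*g,%.*g", digits, df$x, digits, df$y,
                     digits, df$value))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz_grid
#' @export
read_xyz_grid <- function(path, as = c("dem_grid", "raster_map")) {
  as <- match.arg(as)
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y), decreasing = TRUE)
  cs <- min(c(diff(xs), -diff(ys)))
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(df$y, ys), match(df$x, xs))] <- df$value
  xll <- min(xs) - cs / 2
  yll <- min(df$y) - cs / 2
  if (as == "dem_grid") {
    dem_grid(m, xll, yll, cs)
  } else {
    raster_map(m, dem_grid(matrix(0, nrow(m), ncol(m)), xll, yll, cs))
  }
}

#' Sample raster values at point coordinates
#'
#' Nearest-cell lookup. Out-of-bounds coordinates and nodata cells are
#' reported per point rather than raising an error.
#'
#' @param raster A [raster_map()] (or [dem_grid()], in which case elevation
#'   is sampled).
#' @param coords Data frame with columns `lon` and `lat`.
#' @return Data frame `lon`, `lat`, `value`, `status` (`"ok"`,
#'   `"out_of_bounds"` or `"nodata"`).
#' @export
sample_points <- function(raster, coords) {
  stopifnot(all(c("lon", "lat") %in% names(coords)))
  vals <- .grid_of(raster)
  nr <- nrow(vals); nc <- ncol(vals)
  col <- floor((coords$lon - raster$xll) / raster$cellsize) + 1
  row <- nr - floor((coords$lat - raster$yll) / raster$cellsize)
  out <- data.frame(lon = coords$lon, lat = coords$lat,
                    value = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  oob <- col < 1 | col > nc | row < 1 | row > nr
  out$status[oob] <- "out_of_bounds"
  idx <- which(!oob)
  v <- vals[cbind(row[idx], col[idx])]
  out$value[idx] <- v
  out$status[idx][is.na(v)] <- "nodata"
  out
}

#' Paired random sampling of raster values in elevation bands
#'
#' Draws `n_per_band` distinct cells in each elevation band (band centre
#' plus/minus `half_width`, half-open at the upper edge) and extracts the
#' value of every supplied raster at exactly the same cells, so current and
#' future indices are paired point-by-point. Reproducible under `seed`.
#'
#' @param dem A [dem_grid()].
#' @param rasters Named list of [raster_map()] aligned with `dem`.
#' @param band_centres Numeric vector of band centre elevations (m).
#' @param n_per_band Points per band (default 20).
#' @param half_width Band half width in metres (default 50).
#' @param seed Integer seed.
#' @return Data frame with `band`, `lon`, `lat`, `elevation_m` and one
#'   column per raster.
#' @export
band_sample <- function(dem, rasters, band_centres, n_per_band = 20,
                        half_width = 50, seed = 1) {
  stopifnot(inherits(dem, "dem_grid"), length(rasters) >= 1,
            !is.null(names(rasters)))
  xs <- .grid_x(dem); ys <- .grid_y(dem)
  out <- vector("list", length(band_centres))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_along(band_centres)) {
    ctr <- band_centres[b]
    in_band <- which(dem$elevation >= ctr - half_width &
                     dem$elevation < ctr + half_width)
    if (length(in_band) < n_per_band) {
      stop("elevation band ", ctr, " m has only ", length(in_band),
           " cells (need ", n_per_band, ")", call. = FALSE)
    }
    cells <- sample(in_band, n_per_band)
    rc <- arrayInd(cells, dim(dem$elevation))
    row <- data.frame(band = ctr, lon = xs[rc[, 2]], lat = ys[rc[, 1]],
                      elevation_m = dem$elevation[cells])
    for (nm in names(rasters)) row[[nm]] <- rasters[[nm]]$values[cells]
    out[[b]] <- row
  }
  do.call(rbind, out)
}

#' Map predicted bug density per tree from a fitted elevation regression
#'
#' Applies the fitted log-link regression of farm totals (counts over 15
#' trees) on elevation to every DEM cell and divides by 15 to express the
#' prediction as mean bugs per tree.
#'
#' @param fit A [fit_overdispersed_poisson()] fit with an elevation
#'   predictor.
#' @param dem A [dem_grid()].
#' @param trees_per_farm Trees per surveyed farm (default 15).
#' @return A [raster_map()] of mean bugs per tree.
#' @export
density_map_from_glm <- function(fit, dem, trees_per_farm = 15) {
  stopifnot(inherits(fit, "dispersed_glm_fit"), inherits(dem, "dem_grid"))
  cf <- fit$coefficients$estimate
  names(cf) <- fit$coefficients$term
  if (!"elevation_m" %in% names(cf)) {
    stop("fit has no elevation predictor", call. = FALSE)
  }
  vals <- exp(cf[["(Intercept)"]] + cf[["elevation_m"]] * dem$elevation) /
    trees_per_farm
  raster_map(vals, dem, name = "bug_density", units = "bugs per tree")
}
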