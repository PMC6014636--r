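#' Thin-plate-spline interpolator with a linear elevation covariate
#'
#' Fits the surface `value = a0 + a1*lon + a2*lat + b*elev + sum_j w_j *
#' phi(||(lon,lat) - (lon_j,lat_j)||)` with the thin-plate radial basis
#' `phi(r) = r^2 log r`, i.e. a planar thin-plate spline on the coordinates
#' augmented by a fixed linear elevation term. With `smoothing = 0` the
#' surface interpolates every station value exactly; positive smoothing
#' relaxes the fit (ridge term on the spline coefficients).
#'
#' Coordinates are WGS84 degrees; at the few-kilometre scale of an elevation
#' transect a planar spline on degrees is adequate.
#'
#' @param stations Data frame with columns `lon`, `lat`, `elevation_m` and
#'   the value column named by `value_col`.
#' @param value_col Name of the value column (default `"value"`).
#' @param smoothing Non-negative smoothing parameter (default 0 = exact
#'   interpolation).
#' @return Object of class `tps_elev` with a `predict()` method.
#' @export
fit_interpolator <- function(stations, value_col = "value", smoothing = 0) {
  need <- c("lon", "lat", "elevation_m", value_col)
  if (!all(need %in% names(stations))) {
    stop("stations must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(smoothing >= 0)
  n <- nrow(stations)
  if (n < 4) {
    stop("need at least 4 stations to fit the interpolator (got ", n, ")",
         call. = FALSE)
  }
  P <- cbind(1, stations$lon, stations$lat, stations$elevation_m)
  if (qr(P)$rank < 4) {
    stop("station design is rank-deficient (collinear coordinates or ",
         "constant elevation); cannot separate the spatial spline from the ",
         "elevation term", call. = FALSE)
  }
  y <- stations[[value_col]]
  K <- .tps_phi(as.matrix(stats::dist(stations[, c("lon", "lat")])))
  A <- rbind(cbind(K + smoothing * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- c(y, numeric(4))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("interpolator system is singular (duplicate station coordinates?): ",
         conditionMessage(e), call. = FALSE))
  structure(list(w = sol[1:n], beta = sol[n + 1:4],
                 lon = stations$lon, lat = stations$lat,
                 elev_range = range(stations$elevation_m),
                 smoothing = smoothing, value_col = value_col),
            class = "tps_elev")
}

.tps_phi <- function(r) {
  out <- r * 0
  pos <- r > 0
  out[pos] <- r[pos]^2 * log(r[pos])
  out
}

#' @param object A `tps_elev` fit.
#' @param lon,lat,elev Coordinates and elevation of prediction points.
#' @param ... Unused.
#' @rdname fit_interpolator
#' @export
predict.tps_elev <- function(object, lon, lat, elev, ...) {
  d <- sqrt(outer(lon, object$lon, "-")^2 + outer(lat, object$lat, "-")^2)
  drop(.tps_phi(d) %*% object$w) +
    object$beta[1] + object$beta[2] * lon + object$beta[3] * lat +
    object$beta[4] * elev
}

#' Interpolate a fitted surface over a DEM
#'
#' Evaluates the interpolator at every non-nodata DEM cell (cell-centre
#' coordinates, cell elevation as covariate). If the DEM's elevations extend
#' beyond the range spanned by the training stations a warning is issued
#' (the elevation term is then extrapolating), not an error.
#'
#' @param interp A `tps_elev` fit from [fit_interpolator()].
#' @param dem A [dem_grid()].
#' @param clip Optional length-2 numeric; values are clamped to this range
#'   after interpolation (used for the establishment risk index, which is
#'   clipped to \[0, 1\]).
#' @param name,units Passed to [raster_map()].
#' @return A [raster_map()].
#' @export
interpolate <- function(interp, dem, clip = NULL, name = "value",
                        units = "") {
  stopifnot(inherits(interp, "tps_elev"), inherits(dem, "dem_grid"))
  rng <- range(dem$elevation, na.rm = TRUE)
  pad <- 0.05 * diff(interp$elev_range)
  if (rng[1] < interp$elev_range[1] - pad ||
      rng[2] > interp$elev_range[2] + pad) {
    warning("DEM elevations (", rng[1], "-", rng[2],
            " m) extend beyond the stations' range (",
            interp$elev_range[1], "-", interp$elev_range[2],
            " m); the elevation term extrapolates", call. = FALSE)
  }
  vals <- dem$elevation
  ok <- which(!is.na(vals))
  rc <- arrayInd(ok, dim(vals))
  xs <- .grid_x(dem); ys <- .grid_y(dem)
  pred <- predict(interp, lon = xs[rc[, 2]], lat = ys[rc[, 1]],
                  elev = vals[ok])
  if (!is.null(clip)) pred <- pmin(pmax(pred, clip[1]), clip[2])
  out <- matrix(NA_real_, nrow(vals), ncol(vals))
  out[ok] <- pred
  raster_map(out, dem, name = name, units = units)
}
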