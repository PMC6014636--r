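#' Options for the daily index engine
#'
#' @param lethality_threshold A stage is flagged as suffering total (100%)
#'   mortality on a day when its rate-summed daily survival is at or below
#'   this value. Strict zero is unreachable with smooth mortality curves, so
#'   "100% mortality" is operationalised as survival <= 0.005 by default.
#' @param rm_floor Per-day floor (day^-1) for the intrinsic rate of increase
#'   used when the day-level life table is degenerate (no development or zero
#'   reproduction); also the lower clamp for `rm` on extremely unfavourable
#'   days. Default -0.005.
#' @return List of class `index_options`.
#' @export
index_options <- function(lethality_threshold = 0.005, rm_floor = -0.005) {
  stopifnot(lethality_threshold > 0, lethality_threshold < 1,
            is.finite(rm_floor), rm_floor <= 0)
  structure(list(lethality_threshold = lethality_threshold,
                 rm_floor = rm_floor), class = "index_options")
}

#' Reconstruct 24 hourly temperatures from a daily minimum and maximum
#'
#' Standard cosine interpolation: `T_h = m - a * cos(2*pi*h/24)` for
#' `h = 0 ... 23`, with `m = (t_min + t_max)/2` and `a = (t_max - t_min)/2`.
#' The minimum of the 24 values equals `t_min`, the maximum equals `t_max`
#' and their mean equals `m` exactly (the sampled cosine sums to zero).
#'
#' @param t_min,t_max Daily extremes in degrees Celsius, `t_min <= t_max`.
#' @return Numeric vector of 24 hourly temperatures.
#' @export
hourly_profile <- function(t_min, t_max) {
  stopifnot(length(t_min) == 1, length(t_max) == 1,
            is.finite(t_min), is.finite(t_max))
  if (t_min > t_max) stop("t_min must not exceed t_max", call. = FALSE)
  (t_min + t_max) / 2 - (t_max - t_min) / 2 * cos(2 * pi * (0:23) / 24)
}

# Vectorised daily engine. tmin, tmax: vectors over days. Returns a list of
# per-day vectors: rm, lambda, Tgen, lethal (any stage), and per-stage daily
# survival matrix (days x stages).
#
# Convention: stage lethality is judged from the reconstructed hourly cycle
# (the daily extremes are what kill), by averaging instantaneous mortality
# hazards over the 24 hourly samples; the day's growth quantities (lambda_d,
# T_d) are taken from the life table evaluated at the daily mean temperature.
.daily_engine <- function(models, tmin, tmax, options = index_options()) {
  n <- length(tmin)
  stopifnot(length(tmax) == n)
  if (any(tmin > tmax)) stop("t_min > t_max in series", call. = FALSE)
  hrs <- outer(-cos(2 * pi * (0:23) / 24), (tmax - tmin) / 2) +
    rep((tmin + tmax) / 2, each = 24)  # 24 x n
  hvec <- as.vector(hrs)
  nst <- length(models$stages)
  surv_day <- matrix(NA_real_, n, nst,
                     dimnames = list(NULL, names(models$stages)))
  for (i in seq_len(nst)) {
    m <- eval_response(models$stages[[i]]$mortality, hvec)
    haz <- -log(pmax(1 - m, .Machine$double.xmin))
    haz[m >= 1] <- Inf
    surv_day[, i] <- exp(-colMeans(matrix(haz, 24, n)))
  }
  lethal_stage <- surv_day <= options$lethality_threshold
  lethal <- rowSums(lethal_stage) > 0

  X <- (tmin + tmax) / 2
  inv_rate_sum <- numeric(n)
  any_zero <- logical(n)
  surv_prod <- rep(1, n)
  for (i in seq_len(nst)) {
    r <- eval_response(models$stages[[i]]$rate, X)
    zero <- r <= 0
    any_zero <- any_zero | zero
    inv_rate_sum <- inv_rate_sum + ifelse(zero, 0, 1 / r)
    surv_prod <- surv_prod * (1 - eval_response(models$stages[[i]]$mortality, X))
  }
  D <- ifelse(any_zero, Inf, inv_rate_sum)
  L <- 1 / eval_response(models$senescence, X)
  Tgen <- D + 0.5 * L
  R0 <- models$sex_ratio * eval_response(models$fecundity, X) * surv_prod
  rm <- ifelse(R0 <= 0 | !is.finite(Tgen), options$rm_floor,
               pmax(options$rm_floor,
                    log(pmax(R0, .Machine$double.xmin)) / Tgen))
  list(rm = rm, lambda = exp(rm), Tgen = Tgen, lethal = lethal,
       lethal_stage = lethal_stage, stage_survival = surv_day)
}

#' Day-level demography from a daily minimum/maximum pair
#'
#' Computes the finite rate of increase `lambda_d` and generation time `T_d`
#' for one Julian day (life table evaluated at the daily mean temperature)
#' together with per-stage daily survival and lethality flags derived from
#' the reconstructed hourly temperature cycle (mortality hazards averaged
#' over the 24 hourly samples, so a single hour outside the survivable range
#' is enough to make a stage's daily survival collapse).
#'
#' @param models A [stage_model_set()].
#' @param t_min,t_max Daily extremes (degrees Celsius).
#' @param options An [index_options()].
#' @return List with `lambda_d`, `T_d`, `rm_d`, `lethal` (any stage),
#'   `lethal_stage` (named logical) and `stage_survival` (named numeric).
#' @export
daily_demography <- function(models, t_min, t_max,
                             options = index_options()) {
  stopifnot(inherits(models, "stage_model_set"),
            length(t_min) == 1, length(t_max) == 1)
  eng <- .daily_engine(models, t_min, t_max, options)
  list(lambda_d = eng$lambda[1], T_d = eng$Tgen[1], rm_d = eng$rm[1],
       lethal = eng$lethal[1],
       lethal_stage = eng$lethal_stage[1, ],
       stage_survival = eng$stage_survival[1, ])
}

#' Daily temperature series for one station
#'
#' Exactly 365 ordered (t_min, t_max) pairs indexed by Julian day, tagged
#' with station id, WGS84 coordinates and elevation. If 366 days are supplied
#' the leap day (Julian day 60) is dropped.
#'
#' @param station_id Character scalar.
#' @param lon,lat Decimal degrees (WGS84).
#' @param elevation Metres above sea level.
#' @param t_min,t_max Numeric vectors of length 365 (or 366, see above).
#' @return Object of class `daily_temperature_series`.
#' @export
daily_temperature_series <- function(station_id, lon, lat, elevation,
                                     t_min, t_max) {
  if (length(t_min) == 366 && length(t_max) == 366) {
    t_min <- t_min[-60]
    t_max <- t_max[-60]
  }
  if (length(t_min) != 365 || length(t_max) != 365) {
    stop("a daily temperature series must have exactly 365 days (got ",
         length(t_min), ")", call. = FALSE)
  }
  if (any(!is.finite(t_min)) || any(!is.finite(t_max))) {
    stop("non-finite temperatures in series", call. = FALSE)
  }
  if (any(t_min > t_max)) {
    stop("t_min exceeds t_max on day(s) ",
         paste(utils::head(which(t_min > t_max), 5), collapse = ", "),
         call. = FALSE)
  }
  structure(list(station_id = as.character(station_id), lon = lon, lat = lat,
                 elevation = elevation, t_min = t_min, t_max = t_max),
            class = "daily_temperature_series")
}

#' @export
print.daily_temperature_series <- function(x, ...) {
  cat(sprintf(
    "<daily_temperature_series> %s (%.4f, %.4f, %d m): mean tmin %.1f, mean tmax %.1f\n",
    x$station_id, x$lon, x$lat, round(x$elevation), mean(x$t_min),
    mean(x$t_max)))
  invisible(x)
}

.check_series <- function(series) {
  if (!inherits(series, "daily_temperature_series")) {
    stop("expected a daily_temperature_series", call. = FALSE)
  }
  series
}

#' Establishment risk index
#'
#' `ERI = 1 - (number of lethal days)/365`, where a lethal day is a Julian
#' day on which at least one immature stage suffers total mortality. The
#' index is 1 when all immature stages survive throughout the year and 0 when
#' no day is survivable.
#'
#' @param series A [daily_temperature_series()].
#' @param models A [stage_model_set()].
#' @param options An [index_options()].
#' @return Scalar in \[0, 1\].
#' @export
eri <- function(series, models, options = index_options()) {
  series <- .check_series(series)
  eng <- .daily_engine(models, series$t_min, series$t_max, options)
  1 - sum(eng$lethal) / 365
}

#' Generation index
#'
#' Expected number of generations per year, accumulated as the sum of daily
#' generation fractions `GI = sum_d 1/T_d`. At constant temperature this
#' coincides with the textbook definition 365/T; under fluctuating regimes
#' the day-sum form is order-invariant.
#'
#' @inheritParams eri
#' @return Scalar, non-negative (generations per year).
#' @export
gi <- function(series, models, options = index_options()) {
  series <- .check_series(series)
  eng <- .daily_engine(models, series$t_min, series$t_max, options)
  sum(ifelse(is.finite(eng$Tgen), 1 / eng$Tgen, 0))
}

#' Activity index
#'
#' Base-10 logarithm of the product of the daily finite rates of increase:
#' `AI = sum_d log10(lambda_d)`. `10^AI` is the potential annual population
#' multiplication factor (see [growth_factor()]); an AI of 4 corresponds to a
#' 10,000-fold potential increase in one year. Days on which the day-level
#' life table is degenerate contribute `log10(exp(rm_floor))`.
#'
#' @inheritParams eri
#' @return Scalar (dimensionless, log10 scale).
#' @export
ai <- function(series, models, options = index_options()) {
  series <- .check_series(series)
  eng <- .daily_engine(models, series$t_min, series$t_max, options)
  sum(eng$rm) / log(10)
}

#' Annual multiplication factor implied by an activity index
#'
#' @param ai_value Activity index (finite scalar or vector).
#' @return `10^ai_value`.
#' @examples
#' growth_factor(4)  # 10000
#' @export
growth_factor <- function(ai_value) {
  stopifnot(is.numeric(ai_value), all(is.finite(ai_value)))
  10^ai_value
}

#' Risk indices for a set of stations
#'
#' @param series_list List of [daily_temperature_series()] with unique
#'   station ids.
#' @param models A [stage_model_set()].
#' @param options An [index_options()].
#' @return Data frame with one row per station: `station_id`, `lon`, `lat`,
#'   `elevation_m`, `eri`, `gi`, `ai`.
#' @export
indices_at_stations <- function(series_list, models,
                                options = index_options()) {
  stopifnot(length(series_list) >= 1)
  ids <- vapply(series_list, function(s) .check_series(s)$station_id,
                character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate station ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(series_list, function(s) {
    eng <- .daily_engine(models, s$t_min, s$t_max, options)
    data.frame(station_id = s$station_id, lon = s$lon, lat = s$lat,
               elevation_m = s$elevation,
               eri = 1 - sum(eng$lethal) / 365,
               gi = sum(ifelse(is.finite(eng$Tgen), 1 / eng$Tgen, 0)),
               ai = sum(eng$rm) / log(10),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read and write station temperature series as CSV
#'
#' Long format with columns `station_id, lon, lat, elevation_m, julian_day,
#' tmin_c, tmax_c`. On read, a 366-day year has its leap day dropped.
#'
#' @param path CSV path.
#' @param series_list List of [daily_temperature_series()].
#' @return `read_station_csv()` returns a named list of series.
#' @export
read_station_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "elevation_m", "julian_day",
            "tmin_c", "tmax_c")
  if (!all(need %in% names(df))) {
    stop("station CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$station_id), function(d) {
    d <- d[order(d$julian_day), ]
    daily_temperature_series(d$station_id[1], d$lon[1], d$lat[1],
                             d$elevation_m[1], d$tmin_c, d$tmax_c)
  })
  out[order(names(out))]
}

#' @rdname read_station_csv
#' @export
write_station_csv <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(station_id = s$station_id, lon = s$lon, lat = s$lat,
               elevation_m = s$elevation, julian_day = 1:365,
               tmin_c = s$t_min, tmax_c = s$t_max, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
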