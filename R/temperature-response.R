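#' Temperature-response functions
#'
#' A `temperature_response` couples a named function family with a parameter
#' vector and evaluates a biological rate at any temperature. Four kinds are
#' supported, each with its own range invariants:
#'
#' * `development_rate` (day^-1): non-negative everywhere, exactly 0 at or
#'   below the lower thermal limit and at or above the upper limit;
#' * `immature_mortality` (probability over the whole stage): in \[0, 1\];
#' * `fecundity` (eggs per female over her lifetime): non-negative;
#' * `senescence_rate` (day^-1, reciprocal of the remaining adult lifespan):
#'   strictly positive.
#'
#' @section Function families:
#' \describe{
#'   \item{`beta`}{Unimodal performance curve with explicit limits
#'     (`rmax`, `tmin`, `topt`, `tmax`): zero outside `(tmin, tmax)`,
#'     maximum `rmax` exactly at `topt`.}
#'   \item{`briere1`}{`a * T * (T - tmin) * sqrt(tmax - T)` inside
#'     `(tmin, tmax)`, zero outside (`a`, `tmin`, `tmax`).}
#'   \item{`poly_exp`}{`min(1, exp(c0 + c1*x + c2*x^2 + ...))` with
#'     `x = T - tref`; with a U-shaped polynomial this is a stage-mortality
#'     curve that saturates at 1 (total mortality) in the cold and hot tails
#'     (`tref`, `c0`, `c1`, ...).}
#'   \item{`gaussian`}{`fmax * exp(-(T - topt)^2 / (2*sigma^2))`
#'     (`fmax`, `topt`, `sigma`).}
#'   \item{`ramp`}{`fmax * exp(beta*(T - topt) - kappa*max(0, T - topt)^2)`:
#'     log-linear rise to a peak at (essentially) `topt`, quadratic-in-log
#'     collapse above it (`fmax`, `topt`, `beta`, `kappa`).}
#'   \item{`exponential`}{`rate_ref * exp(slope * (T - tref))`
#'     (`rate_ref`, `slope`, `tref`).}
#' }
#'
#' @param kind One of `"development_rate"`, `"immature_mortality"`,
#'   `"fecundity"`, `"senescence_rate"`.
#' @param family Family identifier (see Details).
#' @param params Named numeric vector of family parameters.
#' @param stage Optional stage label (`"egg"`, `"n1"`, ... `"n5"`, `"adult"`).
#' @return An object of class `temperature_response`.
#' @examples
#' dev <- temperature_response("development_rate", "beta",
#'   c(rmax = 0.125, tmin = 14.6, topt = 24.5, tmax = 32.9), stage = "egg")
#' eval_response(dev, 22)
#' eval_response(dev, 14.6)  # 0 at the lower limit
#' @export
temperature_response <- function(kind, family, params, stage = NULL) {
  kinds <- c("development_rate", "immature_mortality", "fecundity",
             "senescence_rate")
  kind <- match.arg(kind, kinds)
  if (!family %in% names(.tr_families)) {
    stop("unknown temperature-response family: '", family,
         "' (configuration error). Known families: ",
         paste(names(.tr_families), collapse = ", "), call. = FALSE)
  }
  spec <- .tr_families[[family]]
  params <- unlist(params)
  if (!is.numeric(params) || any(!is.finite(params))) {
    stop("parameters must be finite numerics (configuration error)",
         call. = FALSE)
  }
  if (is.null(spec$variadic)) {
    missing_p <- setdiff(spec$pars, names(params))
    extra_p <- setdiff(names(params), spec$pars)
    if (length(missing_p) || length(extra_p)) {
      stop("family '", family, "' expects parameters {",
           paste(spec$pars, collapse = ", "), "}; got {",
           paste(names(params), collapse = ", "), "} (configuration error)",
           call. = FALSE)
    }
    params <- params[spec$pars]
  } else {
    fixed <- spec$pars
    if (!all(fixed %in% names(params)) ||
        !any(grepl("^c[0-9]+$", names(params)))) {
      stop("family '", family, "' expects {", paste(fixed, collapse = ", "),
           "} plus polynomial coefficients c0, c1, ... (configuration error)",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, family = family, params = params,
                 stage = stage),
            class = "temperature_response")
}

# family registry: parameter names and vectorized evaluators
.tr_families <- list(
  beta = list(
    pars = c("rmax", "tmin", "topt", "tmax"),
    eval = function(p, temp) {
      a <- (p[["topt"]] - p[["tmin"]]) / (p[["tmax"]] - p[["topt"]])
      out <- numeric(length(temp))
      inside <- temp > p[["tmin"]] & temp < p[["tmax"]]
      ti <- temp[inside]
      out[inside] <- p[["rmax"]] *
        ((p[["tmax"]] - ti) / (p[["tmax"]] - p[["topt"]])) *
        ((ti - p[["tmin"]]) / (p[["topt"]] - p[["tmin"]]))^a
      pmax(out, 0)
    }),
  briere1 = list(
    pars = c("a", "tmin", "tmax"),
    eval = function(p, temp) {
      out <- numeric(length(temp))
      inside <- temp > p[["tmin"]] & temp < p[["tmax"]]
      ti <- temp[inside]
      out[inside] <- p[["a"]] * ti * (ti - p[["tmin"]]) *
        sqrt(p[["tmax"]] - ti)
      pmax(out, 0)
    }),
  poly_exp = list(
    pars = "tref", variadic = TRUE,
    eval = function(p, temp) {
      co <- p[grepl("^c[0-9]+$", names(p))]
      co <- co[order(as.integer(sub("^c", "", names(co))))]
      x <- temp - p[["tref"]]
      acc <- numeric(length(temp))
      for (i in seq_along(co)) acc <- acc + co[[i]] * x^(i - 1)
      pmin(1, exp(acc))
    }),
  gaussian = list(
    pars = c("fmax", "topt", "sigma"),
    eval = function(p, temp) {
      p[["fmax"]] * exp(-(temp - p[["topt"]])^2 / (2 * p[["sigma"]]^2))
    }),
  ramp = list(
    pars = c("fmax", "topt", "beta", "kappa"),
    eval = function(p, temp) {
      d <- temp - p[["topt"]]
      p[["fmax"]] * exp(p[["beta"]] * d - p[["kappa"]] * pmax(0, d)^2)
    }),
  exponential = list(
    pars = c("rate_ref", "slope", "tref"),
    eval = function(p, temp) {
      p[["rate_ref"]] * exp(p[["slope"]] * (temp - p[["tref"]]))
    })
)

#' Evaluate a temperature response
#'
#' @param model A [temperature_response()].
#' @param temp Temperature(s) in degrees Celsius; finite.
#' @return Numeric vector of the same length as `temp`, in the units of the
#'   response kind (day^-1 for rates, probability for mortality, eggs per
#'   female for fecundity).
#' @export
eval_response <- function(model, temp) {
  stopifnot(inherits(model, "temperature_response"))
  if (!is.numeric(temp) || any(!is.finite(temp))) {
    stop("temp must be finite numeric", call. = FALSE)
  }
  .tr_families[[model$family]]$eval(model$params, temp)
}

#' @export
print.temperature_response <- function(x, ...) {
  cat("<temperature_response> kind:", x$kind,
      if (!is.null(x$stage)) paste0("stage: ", x$stage), "\n")
  cat("  family:", x$family, "\n  params:",
      paste(names(x$params), signif(unlist(x$params), 6), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
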