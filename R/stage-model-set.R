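#' Stage-structured species model set
#'
#' Bundles one development-rate and one stage-mortality response per immature
#' stage (egg, N1...N5 in fixed order), an adult fecundity response, an adult
#' senescence-rate response and a sex ratio into the full thermal life-history
#' model of the species.
#'
#' @param stages Named list in the order `egg`, `n1` ... `n5`; each element a
#'   list with components `rate` (a `development_rate` response) and
#'   `mortality` (an `immature_mortality` response).
#' @param fecundity A `fecundity` [temperature_response()].
#' @param senescence A `senescence_rate` [temperature_response()].
#' @param sex_ratio Proportion of female offspring (default 0.5).
#' @return An object of class `stage_model_set`.
#' @seealso [default_species_params()] for the packaged calibrated set.
#' @export
stage_model_set <- function(stages, fecundity, senescence, sex_ratio = 0.5) {
  expected <- c("egg", "n1", "n2", "n3", "n4", "n5")
  if (!identical(names(stages), expected)) {
    stop("stages must be named ", paste(expected, collapse = ", "),
         " in that order", call. = FALSE)
  }
  for (s in expected) {
    st <- stages[[s]]
    if (!is.list(st) || !all(c("rate", "mortality") %in% names(st))) {
      stop("stage '", s, "' must have exactly a 'rate' and a 'mortality' ",
           "response", call. = FALSE)
    }
    if (!inherits(st$rate, "temperature_response") ||
        st$rate$kind != "development_rate") {
      stop("stage '", s, "': 'rate' must be a development_rate response",
           call. = FALSE)
    }
    if (!inherits(st$mortality, "temperature_response") ||
        st$mortality$kind != "immature_mortality") {
      stop("stage '", s, "': 'mortality' must be an immature_mortality ",
           "response", call. = FALSE)
    }
  }
  stopifnot(inherits(fecundity, "temperature_response"),
            fecundity$kind == "fecundity",
            inherits(senescence, "temperature_response"),
            senescence$kind == "senescence_rate",
            is.numeric(sex_ratio), sex_ratio > 0, sex_ratio <= 1)
  structure(list(stages = stages, fecundity = fecundity,
                 senescence = senescence, sex_ratio = sex_ratio),
            class = "stage_model_set")
}

#' Stage-wise immature survival at constant temperature
#'
#' Evaluates each stage's mortality response and returns per-stage survival
#' probabilities together with their product (the probability of completing
#' the whole immature development).
#'
#' @param models A [stage_model_set()].
#' @param temp Temperature in degrees Celsius (scalar).
#' @return List with `stage_survival` (named vector) and `total` (product).
#' @export
immature_survival <- function(models, temp) {
  stopifnot(inherits(models, "stage_model_set"), length(temp) == 1)
  surv <- vapply(models$stages, function(st) {
    1 - eval_response(st$mortality, temp)
  }, numeric(1))
  list(stage_survival = surv, total = prod(surv))
}

#' Read and write species parameter files
#'
#' The species parameter file is a structured YAML document with one block per
#' stage/response carrying the family name and the named parameter vector,
#' plus the sex ratio. Numeric values are stored at full double precision so a
#' write/read cycle is lossless.
#'
#' @param models A [stage_model_set()].
#' @param path File path.
#' @return `read_species_params()` returns a [stage_model_set()];
#'   `write_species_params()` returns `path` invisibly.
#' @export
write_species_params <- function(models, path) {
  stopifnot(inherits(models, "stage_model_set"))
  as_block <- function(tr) {
    list(kind = tr$kind, family = tr$family,
         params = lapply(as.list(tr$params), function(v)
           sprintf("%.17g", v)))
  }
  doc <- list(
    species = "synthetic antestia bug default",
    sex_ratio = sprintf("%.17g", models$sex_ratio),
    stages = lapply(models$stages, function(st)
      list(rate = as_block(st$rate), mortality = as_block(st$mortality))),
    adult = list(fecundity = as_block(models$fecundity),
                 senescence = as_block(models$senescence))
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_species_params
#' @export
read_species_params <- function(path) {
  doc <- yaml::read_yaml(path)
  from_block <- function(b, stage = NULL) {
    temperature_response(b$kind, b$family,
                         vapply(b$params, as.numeric, numeric(1)),
                         stage = stage)
  }
  stages <- lapply(names(doc$stages), function(s) {
    list(rate = from_block(doc$stages[[s]]$rate, s),
         mortality = from_block(doc$stages[[s]]$mortality, s))
  })
  names(stages) <- names(doc$stages)
  stage_model_set(stages,
                  fecundity = from_block(doc$adult$fecundity, "adult"),
                  senescence = from_block(doc$adult$senescence, "adult"),
                  sex_ratio = as.numeric(doc$sex_ratio))
}

#' @export
print.stage_model_set <- function(x, ...) {
  cat("<stage_model_set>", length(x$stages), "immature stages (",
      paste(names(x$stages), collapse = ", "), "), sex ratio",
      x$sex_ratio, "\n")
  invisible(x)
}
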