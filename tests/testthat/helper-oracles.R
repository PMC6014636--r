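# Independent oracles used across the suite. These re-derive quantities by
# different routes than the package implementation.

# Life-table oracle: explicit cohort survivorship/fecundity schedule l(t),
# b(t) integrated numerically (midpoint rule on segment-aligned grids).
# Stages have constant hazards h_i = -log(1 - m_i) * r_i over durations
# 1/r_i; adults lay at a constant rate over a fixed lifespan and then die.
cohort_lt_oracle <- function(models, temp, nsub = 400) {
  rates <- vapply(models$stages, function(st) eval_response(st$rate, temp),
                  numeric(1))
  morts <- vapply(models$stages,
                  function(st) eval_response(st$mortality, temp),
                  numeric(1))
  stopifnot(all(rates > 0), all(morts < 1))
  tau <- 1 / rates
  haz <- -log(1 - morts) * rates
  D <- sum(tau)
  L <- 1 / eval_response(models$senescence, temp)
  fec <- eval_response(models$fecundity, temp)
  b <- models$sex_ratio * fec / L           # daughters per female per day
  # cumulative hazard at adult entry
  H_adult <- sum(haz * tau)
  l_adult <- exp(-H_adult)
  # integrate R0 and the mean age of reproduction over the adult span
  dt <- L / nsub
  t_mid <- D + (seq_len(nsub) - 0.5) * dt
  integrand <- rep(l_adult * b, nsub)          # l(t) * b(t) on the adult span
  R0 <- sum(integrand * dt)
  Tgen <- sum(t_mid * integrand * dt) / R0
  rm <- log(R0) / Tgen
  list(GRR = b * L, R0 = R0, T = Tgen, rm = rm, lambda = exp(rm),
       Dt = if (rm > 0) log(2) / rm else Inf)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments.
enum_signrank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- drop(signs %*% r)
  p_ge <- mean(W_all >= W_obs)
  p_le <- mean(W_all <= W_obs)
  list(W = W_obs, p = min(1, 2 * min(p_ge, p_le)))
}

# Random valid stage model set for property tests (symmetric mortality,
# Gaussian fecundity; parameters drawn wide but valid).
random_species <- function() {
  tmin <- runif(1, 8, 14)
  tmax <- runif(1, 30, 38)
  topt <- runif(1, 0.55, 0.8) * (tmax - tmin) + tmin
  durations <- runif(6, 4, 20)
  tm <- runif(1, 20, 26)
  m0 <- runif(1, 0.01, 0.1)
  width <- runif(1, 6, 10)
  c2 <- -log(m0) / width^2   # m reaches 1 at tm +/- width
  stages <- lapply(seq_len(6), function(i) {
    list(rate = temperature_response(
           "development_rate", "beta",
           c(rmax = 1 / durations[i], tmin = tmin, topt = topt,
             tmax = tmax)),
         mortality = temperature_response(
           "immature_mortality", "poly_exp",
           c(tref = tm, c0 = log(m0), c1 = 0, c2 = c2)))
  })
  names(stages) <- c("egg", "n1", "n2", "n3", "n4", "n5")
  stage_model_set(
    stages,
    fecundity = temperature_response(
      "fecundity", "gaussian",
      c(fmax = runif(1, 30, 200), topt = tm, sigma = runif(1, 2, 5))),
    senescence = temperature_response(
      "senescence_rate", "exponential",
      c(rate_ref = runif(1, 0.01, 0.05), slope = runif(1, 0.02, 0.1),
        tref = 23)),
    sex_ratio = runif(1, 0.4, 0.6))
}

# Constant-temperature series helper
constant_series <- function(temp, elevation = 1200, id = "S") {
  daily_temperature_series(id, 37.45, -3.33, elevation,
                           rep(temp, 365), rep(temp, 365))
}

default_models_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- default_species_params()
    m
  }
})
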