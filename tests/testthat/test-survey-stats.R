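sim_counts <- function(n = 24, intercept = -3.4, slope = 0.003,
                       dispersion = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  elev <- rep(seq(1100, 1600, by = 100), length.out = n)
  mu <- exp(intercept + slope * elev)
  count <- if (dispersion > 1) {
    rnbinom(n, mu = mu, size = mu / (dispersion - 1))
  } else rpois(n, mu)
  data.frame(elevation_m = elev, count = count)
}

test_that("equidispersed data need no correction", {
  df <- sim_counts(seed = 1, dispersion = 1)
  fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
  plain <- glm(count ~ elevation_m, poisson, data = df)
  expect_lt(max(abs(fit$coefficients$estimate - coef(plain))), 1e-6)
  if (sum(residuals(plain, "pearson")^2) / plain$df.residual <= 1) {
    expect_equal(fit$dispersion, 1)
    expect_lt(max(abs(fit$coefficients$se -
                      summary(plain)$coefficients[, 2])), 1e-6)
  }
})

test_that("the weighting loop is a fixed point under equidispersion and inflates SEs otherwise", {
  df <- sim_counts(seed = 3, dispersion = 4)
  fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
  plain <- glm(count ~ elevation_m, poisson, data = df)
  expect_gt(fit$dispersion, 1)
  expect_true(all(fit$coefficients$se >=
                  summary(plain)$coefficients[, 2] - 1e-12))
  # coefficients are unchanged by uniform downweighting
  expect_lt(max(abs(fit$coefficients$estimate - coef(plain))), 1e-8)
  # cross-check: SEs agree with the quasi-Poisson route when phi > 1
  qp <- fit_overdispersed_poisson(df, count ~ elevation_m,
                                  method = "quasipoisson")
  expect_equal(fit$coefficients$se, qp$coefficients$se, tolerance = 0.05)
})

test_that("reported deviance equals the direct chi-squared formula", {
  df <- sim_counts(seed = 5, dispersion = 2)
  fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
  mu <- fitted(fit$glm)
  y <- df$count
  w <- fit$weights
  dev <- 2 * sum(w * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
  expect_equal(fit$chi2, dev, tolerance = 1e-8)
  expect_gte(fit$chi2, 0)
  # z agrees with estimate/se
  expect_lt(max(abs(fit$coefficients$z -
                    fit$coefficients$estimate / fit$coefficients$se)), 1e-9)
})

test_that("invalid counts and degenerate designs are rejected", {
  df <- sim_counts(seed = 7)
  df$count[1] <- 2.5
  expect_error(fit_overdispersed_poisson(df, count ~ elevation_m),
               "non-negative integers")
  df2 <- sim_counts(seed = 7)
  df2$elevation_m <- 1300
  expect_error(fit_overdispersed_poisson(df2, count ~ elevation_m),
               "zero variance")
  expect_error(fit_overdispersed_poisson(df2[1:2, ], count ~ elevation_m),
               "at least 3")
})

test_that("the elevation slope is recovered across seeded replicates", {
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    df <- sim_counts(seed = 100 + r, dispersion = 2, slope = 0.003)
    fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
    sl <- fit$coefficients[fit$coefficients$term == "elevation_m", ]
    if (abs(sl$estimate - 0.003) <= 3 * sl$se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("season post-hoc flags constructed separations and only those", {
  set.seed(9)
  seasons <- rep(c("cool_dry_2014", "short_rainy_2014", "warm_dry_2015",
                   "cool_dry_2015"), each = 24)
  # identical means: nothing significant
  df0 <- data.frame(season = factor(seasons), count = rpois(96, 8))
  fit0 <- fit_overdispersed_poisson(df0, count ~ season)
  ph0 <- season_posthoc(fit0)
  expect_equal(nrow(ph0), 6)  # all pairwise contrasts
  expect_false(any(ph0$significant))
  # adjusted p never below unadjusted p
  expect_true(all(ph0$p_adj >= ph0$p_unadj - 1e-10))
  # one season strongly shifted: exactly its three pairs flagged
  mu <- ifelse(seasons == "warm_dry_2015", 40, 8)
  df1 <- data.frame(season = factor(seasons), count = rpois(96, mu))
  ph1 <- season_posthoc(fit_overdispersed_poisson(df1, count ~ season))
  hot <- grepl("warm_dry_2015", ph1$contrast)
  expect_true(all(ph1$significant[hot]))
  expect_false(any(ph1$significant[!hot]))
})

test_that("season post-hoc needs a season model", {
  df <- sim_counts(seed = 11)
  fit <- fit_overdispersed_poisson(df, count ~ elevation_m)
  expect_error(season_posthoc(fit), "season model")
})

test_that("a saturated paired comparison reaches the W ceiling", {
  set.seed(13)
  cur <- runif(20)
  fut <- cur + runif(20, 0.05, 0.2)
  res <- wilcoxon_signed_rank(cur, fut)
  expect_equal(res$W, 210)      # n(n+1)/2 at n = 20
  expect_lt(res$p, 1e-4)
  expect_true(res$exact)
  expect_equal(res$direction, 1)
})

test_that("exact signed-rank p matches brute-force enumeration", {
  set.seed(15)
  for (i in 1:5) {
    cur <- rnorm(6)
    fut <- cur + rnorm(6, 0.3, 1)
    while (any(fut == cur) || any(duplicated(abs(fut - cur)))) {
      fut <- cur + rnorm(6, 0.3, 1)
    }
    res <- wilcoxon_signed_rank(cur, fut)
    or <- enum_signrank(fut - cur)
    expect_equal(res$W, or$W)
    expect_equal(res$p, or$p, tolerance = 1e-12)
  }
})

test_that("signed-rank statistic is symmetric under swapping the arms", {
  set.seed(17)
  cur <- rnorm(12)
  fut <- cur + rnorm(12, 0.2, 0.5)
  a <- wilcoxon_signed_rank(cur, fut)
  b <- wilcoxon_signed_rank(fut, cur)
  expect_equal(a$W + b$W, a$n * (a$n + 1) / 2)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_true(a$W >= 0 && a$W <= a$n * (a$n + 1) / 2)
})

test_that("degenerate paired inputs error", {
  expect_error(wilcoxon_signed_rank(1:5, 1:4), "equal length")
  x <- rnorm(10)
  expect_error(wilcoxon_signed_rank(x, x), "usable pairs")
})

test_that("band comparison flags only the shifted bands", {
  set.seed(19)
  bands <- rep(seq(1000, 1700, by = 100), each = 20)
  cur <- rnorm(160, 2, 0.2)
  fut <- cur + ifelse(bands >= 1600, 0.1, 0)
  pts <- data.frame(band = bands, index = "gi", current = cur, future = fut)
  res <- suppressWarnings(compare_bands(pts))
  expect_lte(nrow(res), 8)
  top <- res$band >= 1600
  expect_true(all(res$p[top] < 1e-4))
  expect_true(all(res$direction[top] == 1))
  expect_true(all(res$stars[top] == "***"))
  # unshifted bands were dropped (all-zero differences) with warnings
  w <- testthat::capture_warnings(compare_bands(pts))
  expect_true(all(grepl("skipped", w)) && length(w) > 0)
  # permuting point order leaves results unchanged
  p <- sample(160)
  res2 <- suppressWarnings(
    compare_bands(pts[p, ]))
  expect_equal(res2, suppressWarnings(compare_bands(pts)))
})
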