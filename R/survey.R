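#' Overdispersion-corrected Poisson regression of survey counts
#'
#' Fits a log-link Poisson GLM of farm totals (bugs counted over the 15
#' trees of each farm) on elevation or on season, then corrects for
#' overdispersion by iterative observation weighting: fit, estimate the
#' dispersion from the Pearson statistic (`X^2 / df`), downweight every
#' observation by `1 / (1 + (dispersion - 1))`, and refit until the weighted
#' dispersion estimate stabilises (change below 1e-8). The reported standard
#' errors and z statistics come from the final weighted fit; the deviance of
#' the fit is reported as the chi-squared goodness-of-fit statistic. When the
#' data are equidispersed (or underdispersed) no correction is applied and
#' the fit equals the plain Poisson GLM.
#'
#' A quasi-Poisson fit is available as an independent cross-check
#' (`method = "quasipoisson"`).
#'
#' @param data Data frame with a `count` column (non-negative integers) plus
#'   the predictors named in `formula`.
#' @param formula Model formula, e.g. `count ~ elevation_m` or
#'   `count ~ season`.
#' @param method `"weighted"` (iterative dispersed-Poisson weighting,
#'   default) or `"quasipoisson"`.
#' @param max_iter Iteration cap for the weighting loop.
#' @return Object of class `dispersed_glm_fit`: coefficient table
#'   (`term`, `estimate`, `se`, `z`, `p`), `dispersion` (>= 1), `chi2`
#'   (deviance), `df` (residual degrees of freedom), `weights`, the inner
#'   `glm` object, `iterations` and `converged`.
#' @export
fit_overdispersed_poisson <- function(data, formula = count ~ elevation_m,
                                      method = c("weighted", "quasipoisson"),
                                      max_iter = 100) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- length(y)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  rhs <- all.vars(formula)[-1]
  if ("elevation_m" %in% rhs && stats::var(data$elevation_m) == 0) {
    stop("elevation has zero variance", call. = FALSE)
  }
  if (method == "quasipoisson") {
    fit <- stats::glm(formula, family = stats::quasipoisson(), data = data)
    sm <- summary(fit)
    co <- sm$coefficients
    tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 1] / co[, 2],
                      p = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])),
                      row.names = NULL, stringsAsFactors = FALSE)
    return(structure(list(coefficients = tab,
                          dispersion = max(1, sm$dispersion),
                          chi2 = fit$deviance, df = fit$df.residual,
                          weights = rep(1, n), glm = fit, iterations = 1L,
                          converged = TRUE, method = method,
                          formula = formula),
                     class = "dispersed_glm_fit"))
  }
  data$.w <- rep(1, n)
  disp_total <- 1
  phi <- Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    fit <- stats::glm(formula, family = stats::poisson(), data = data,
                      weights = .w)
    x2 <- sum(stats::residuals(fit, type = "pearson")^2)
    phi_new <- x2 / fit$df.residual
    if (phi_new <= 1 || abs(phi_new - 1) < 1e-8 ||
        abs(phi_new - phi) < 1e-8) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    data$.w <- data$.w / (1 + (phi_new - 1))
    disp_total <- disp_total * (1 + (phi_new - 1))
    phi <- phi_new
  }
  if (!converged) {
    stop("dispersion-weighting loop failed to converge in ", max_iter,
         " iterations", call. = FALSE)
  }
  sm <- summary(fit, dispersion = 1)
  co <- sm$coefficients
  z <- co[, 1] / co[, 2]
  tab <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    z = z, p = 2 * stats::pnorm(-abs(z)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, dispersion = max(1, disp_total),
                 chi2 = fit$deviance, df = fit$df.residual,
                 weights = data$.w, glm = fit, iterations = iter,
                 converged = converged, method = method, formula = formula),
            class = "dispersed_glm_fit")
}

#' @export
print.dispersed_glm_fit <- function(x, ...) {
  cat(sprintf(
    "<dispersed_glm_fit> %s | chi2 = %.3f, df = %d, dispersion = %.3f\n",
    deparse(x$formula), x$chi2, x$df, x$dispersion))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Pairwise season comparisons after a season GLM
#'
#' All pairwise contrasts between season levels on the linear-predictor
#' scale, with single-step adjusted p-values (multivariate-normal
#' adjustment, the GLM analogue of a Tukey test). Pairs significant at the
#' 0.05 level are flagged.
#'
#' @param fit A [fit_overdispersed_poisson()] fit of `count ~ season`.
#' @param level Significance level for the flag (default 0.05).
#' @return Data frame `contrast`, `estimate`, `se`, `z`, `p_unadj`, `p_adj`,
#'   `significant`.
#' @export
season_posthoc <- function(fit, level = 0.05) {
  stopifnot(inherits(fit, "dispersed_glm_fit"))
  g <- fit$glm
  trm <- attr(stats::terms(g), "term.labels")
  if (!"season" %in% trm) {
    stop("fit must be a season model (count ~ season)", call. = FALSE)
  }
  if (nlevels(factor(g$model$season)) < 2) {
    stop("need at least 2 seasons", call. = FALSE)
  }
  gh <- multcomp::glht(g, linfct = multcomp::mcp(season = "Tukey"))
  sm <- summary(gh)
  z <- sm$test$tstat
  data.frame(contrast = names(z),
             estimate = unname(sm$test$coefficients),
             se = unname(sm$test$sigma),
             z = unname(z),
             p_unadj = unname(2 * stats::pnorm(-abs(z))),
             p_adj = unname(as.numeric(sm$test$pvalues)),
             significant = unname(as.numeric(sm$test$pvalues) < level),
             stringsAsFactors = FALSE)
}

#' Paired Wilcoxon signed-rank test
#'
#' `W` is the sum of the ranks of the positive differences
#' `future - current` (average ranks for ties, zero differences dropped).
#' For `n <= 25` usable pairs without ties in the absolute differences the
#' exact null distribution is used; otherwise a normal approximation with
#' tie correction and continuity correction.
#'
#' @param current,future Equal-length paired numeric vectors.
#' @param min_pairs Minimum usable pairs after dropping zero differences.
#' @return Object of class `wilcoxon_result`: `W`, `p` (two-sided), `n`
#'   (pairs used), `exact` flag and `direction` (sign of the median
#'   difference).
#' @export
wilcoxon_signed_rank <- function(current, future, min_pairs = 5) {
  if (length(current) != length(future)) {
    stop("current and future must have equal length", call. = FALSE)
  }
  d <- future - current
  d <- d[d != 0]
  n <- length(d)
  if (n < min_pairs) {
    stop("fewer than ", min_pairs, " usable pairs after dropping zero ",
         "differences (", n, ")", call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25 && !ties
  if (exact) {
    # psignrank is the exact signed-rank null CDF
    p <- 2 * min(stats::psignrank(W, n),
                 stats::psignrank(W - 1, n, lower.tail = FALSE))
    p <- min(1, p)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(W = W, p = p, n = n, exact = exact,
                 direction = sign(stats::median(d))),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> W = %g, n = %d, p = %.4g (%s)\n",
              x$W, x$n, x$p,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

.signif_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**",
                                 ifelse(p < 0.05, "*", "ns")))
}

#' Current-vs-future index comparison per elevation band
#'
#' Runs a paired Wilcoxon signed-rank test per (elevation band x index)
#' on point-paired current and future index values (as produced by
#' [band_sample()] on current and future rasters), reports the direction of
#' change (sign of the median paired difference) and renders significance
#' stars (`*` p < 0.05, `**` p < 0.001, `***` p < 0.0001).
#'
#' @param points Data frame with columns `band`, `index`, `current`,
#'   `future` (long format, one row per sampled point and index).
#' @param min_pairs Bands with fewer usable pairs are skipped with a
#'   warning.
#' @return Data frame `band`, `index`, `n`, `W`, `p`, `direction`, `stars`.
#' @export
compare_bands <- function(points, min_pairs = 5) {
  need <- c("band", "index", "current", "future")
  if (!all(need %in% names(points))) {
    stop("points must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (b in sort(unique(points$band))) {
    for (ix in unique(points$index)) {
      sub <- points[points$band == b & points$index == ix, ]
      res <- tryCatch(
        wilcoxon_signed_rank(sub$current, sub$future,
                             min_pairs = min_pairs),
        error = function(e) {
          warning("band ", b, " (", ix, ") skipped: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
      if (is.null(res)) next
      out[[length(out) + 1]] <- data.frame(
        band = b, index = ix, n = res$n, W = res$W, p = res$p,
        direction = res$direction, stars = .signif_stars(res$p),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(band = numeric(0), index = character(0),
                      n = integer(0), W = numeric(0), p = numeric(0),
                      direction = numeric(0), stars = character(0)))
  }
  do.call(rbind, out)
}

#' Read a farm survey CSV
#'
#' Accepts either one row per farm and season (column `count` = farm total
#' over 15 trees) or one row per tree (column `tree_index` present; counts
#' are summed to the farm total).
#'
#' @param path CSV with columns `farm_id, lon, lat, elevation_m, season` and
#'   `count` (plus optional `tree_index`).
#' @return Data frame with one row per farm and season.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("farm_id", "elevation_m", "season", "count")
  if (!all(need %in% names(df))) {
    stop("survey CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if ("tree_index" %in% names(df)) {
    agg <- stats::aggregate(count ~ farm_id + elevation_m + season,
                            data = df, FUN = sum)
    keep <- df[!duplicated(df[, c("farm_id", "season")]),
               intersect(c("farm_id", "lon", "lat", "season"), names(df))]
    df <- merge(agg, keep, by = c("farm_id", "season"), sort = FALSE)
  }
  df$season <- factor(df$season)
  df
}
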