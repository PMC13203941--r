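#' Build the design for the hierarchical trend model
#'
#' Applies the inclusion rule (at least `min_waves` distinct survey years
#' spanning at least `min_span_frac` of the observation window; excluded
#' countries are reported with a warning), attaches cultural-zone labels, and
#' aggregates respondent scores to country-year-age-sex cell means with cell
#' sizes. The residual variance is estimated from pooled within-cell
#' variation, so the weighted cell-level Gaussian fit is likelihood-equivalent
#' to the respondent-level fit.
#'
#' @param survey scored survey table (`country, year, agesex, grb`).
#' @param zones lookup data frame (`country, zone`, optionally `hdi_class`).
#' @param years observation window the model predicts over.
#' @param min_waves,min_span_frac inclusion rule.
#' @return object of class `trend_design`: list with `cells` (aggregated
#'   data), `sigma2` (residual variance), `dropped` (excluded countries),
#'   `zones`, `years`.
#' @export
build_trend_design <- function(survey, zones, years = 1995:2022,
                               min_waves = 2L, min_span_frac = 0.25) {
  check_cols(survey, c("country", "year", "agesex", "grb"), "survey")
  check_cols(zones, c("country", "zone"), "zones")
  survey <- survey[!is.na(survey$grb), ]
  span <- diff(range(years))
  per <- tapply(survey$year, survey$country, function(y) {
    u <- unique(y); c(waves = length(u), span = diff(range(u)))
  })
  keep <- names(per)[vapply(per, function(v)
    v["waves"] >= min_waves && v["span"] >= min_span_frac * span, logical(1))]
  dropped <- setdiff(unique(survey$country), keep)
  if (length(dropped))
    warning("excluding countries below the inclusion rule: ",
            paste(dropped, collapse = ", "))
  survey <- survey[survey$country %in% keep, ]
  if (!nrow(survey)) stop("no country satisfies the inclusion rule")

  agg <- aggregate(grb ~ country + year + agesex, survey,
                   function(x) c(m = mean(x), n = length(x), ss = sum((x - mean(x))^2)))
  cells <- data.frame(country = agg$country, year = agg$year,
                      agesex = agg$agesex, m = agg$grb[, "m"],
                      n = agg$grb[, "n"], ss = agg$grb[, "ss"],
                      stringsAsFactors = FALSE)
  cells$zone <- zones$zone[match(cells$country, zones$country)]
  if (anyNA(cells$zone))
    stop("zone lookup missing for: ",
         paste(unique(cells$country[is.na(cells$zone)]), collapse = ", "))
  ntot <- sum(cells$n)
  df_within <- ntot - nrow(cells)
  sigma2 <- if (df_within > 0) sum(cells$ss) / df_within else NA_real_
  cells$country <- factor(cells$country)
  cells$zone <- factor(cells$zone)
  cells$agesex <- factor(cells$agesex, levels = agesex_levels()[
    agesex_levels() %in% cells$agesex])
  structure(list(cells = cells, sigma2 = sigma2, dropped = dropped,
                 zones = zones, years = as.integer(years),
                 n_respondents = ntot), class = "trend_design")
}

## assemble the gam formula for the available factor structure
trend_formula <- function(cells, k_zone, k_country) {
  nz <- nlevels(cells$zone); nc <- nlevels(cells$country)
  ng <- nlevels(cells$agesex)
  tm <- character(0)
  if (ng > 1L) tm <- c(tm, "agesex")
  if (nz > 1L) {
    tm <- c(tm, "zone",
            sprintf("s(year, by = zone, bs = 'bs', k = %d, m = c(3, 2))", k_zone))
  } else {
    tm <- c(tm, sprintf("s(year, bs = 'bs', k = %d, m = c(3, 2))", k_zone))
  }
  if (nc > 1L)
    tm <- c(tm, sprintf(
      "s(year, country, bs = 'fs', xt = list(bs = 'bs'), k = %d, m = c(3, 1))",
      k_country))
  if (nc > 1L && ng > 1L) tm <- c(tm, "s(country, agesex, bs = 're')")
  stats::as.formula(paste("m ~", paste(tm, collapse = " + ")),
                    env = globalenv())
}

#' Fit the hierarchical smooth trend model for mean GRB
#'
#' Gaussian hierarchical generalized additive model: a smooth calendar-year
#' effect per cultural zone (cubic B-splines, second-order difference
#' penalty), country-specific smooth deviations as factor-interaction splines
#' sharing one common wiggliness penalty (which also supplies penalized
#' country intercepts and linear deviations), fixed effects for the six
#' age-sex groups, and random country deviations from the age-sex effects.
#' Smoothing and variance parameters are selected by restricted marginal
#' likelihood (REML) via \pkg{mgcv}; the coefficient covariance conditional on
#' the selected smoothing parameters supplies the multivariate-normal
#' posterior approximation used by [draw_posterior()].
#'
#' Respondent scores are internally aggregated to weighted cell means with a
#' residual variance fixed at the pooled within-cell estimate, which leaves
#' coefficients, smoothing selection and the coefficient covariance identical
#' to the respondent-level fit.
#'
#' @param survey scored survey table (or a prebuilt [build_trend_design()]).
#' @param zones country-to-zone lookup (ignored when `survey` is a design).
#' @param years prediction window.
#' @param k_zone,k_country basis dimensions of the zone and country smooths.
#' @param min_waves,min_span_frac inclusion rule (see
#'   [build_trend_design()]).
#' @param sp optional fixed smoothing parameters passed to [mgcv::gam()]
#'   (e.g. all zero for an unpenalized fit).
#' @param ... further arguments to [mgcv::gam()].
#' @return object of class `grb_trend`.
#' @export
grb_trend <- function(survey, zones = NULL, years = 1995:2022,
                      k_zone = 8, k_country = 5,
                      min_waves = 2L, min_span_frac = 0.25, sp = NULL, ...) {
  design <- if (inherits(survey, "trend_design")) survey else
    build_trend_design(survey, zones, years, min_waves, min_span_frac)
  cells <- design$cells
  f <- trend_formula(cells, k_zone, k_country)
  environment(f) <- environment()   # so gam() can see `cells` for weights
  scale_arg <- if (is.finite(design$sigma2)) design$sigma2 else -1
  if (!is.finite(design$sigma2))
    warning("no within-cell replication; estimating the scale by REML")
  fit <- mgcv::gam(f, data = cells, weights = cells$n, scale = scale_arg,
                   method = "REML", sp = sp,
                   knots = list(year = range(design$years)), ...)
  if (!fit$converged)
    warning("smoothing-parameter selection did not converge; ",
            "inspect $gam for diagnostics")
  structure(list(gam = fit, design = design, years = design$years,
                 countries = levels(cells$country),
                 agesex = levels(cells$agesex),
                 sigma2 = design$sigma2, formula = f),
            class = "grb_trend")
}

#' @export
print.grb_trend <- function(x, ...) {
  cat("Hierarchical GRB trend model\n")
  cat("  countries:", length(x$countries),
      " zones:", nlevels(x$design$cells$zone),
      " age-sex groups:", length(x$agesex), "\n")
  cat("  cells:", nrow(x$design$cells),
      " respondents:", x$design$n_respondents,
      " residual SD:", round(sqrt(x$sigma2), 2), "\n")
  if (length(x$design$dropped))
    cat("  excluded countries:", paste(x$design$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.grb_trend <- function(object, ...) summary(object$gam, ...)

#' @export
coef.grb_trend <- function(object, ...) coef(object$gam)

## full prediction grid: every country x year x age-sex cell
trend_grid <- function(object) {
  expand.grid(country = factor(object$countries, levels = object$countries),
              year = object$years,
              agesex = factor(object$agesex, levels = object$agesex),
              KEEP.OUT.ATTRS = FALSE)
}

#' @export
predict.grb_trend <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- trend_grid(object)
  if (nlevels(object$design$cells$zone) > 1L || is.null(newdata$zone)) {
    zl <- object$design$zones
    newdata$zone <- factor(zl$zone[match(as.character(newdata$country),
                                         zl$country)],
                           levels = levels(object$design$cells$zone))
  }
  predict(object$gam, newdata = newdata, ...)
}

#' @export
fitted.grb_trend <- function(object, ...) fitted(object$gam)

#' @export
residuals.grb_trend <- function(object, ...) residuals(object$gam, ...)

#' @export
plot.grb_trend <- function(x, ...) plot(x$gam, ...)

#' Draw from the posterior approximation of the trend model
#'
#' Samples coefficient vectors from the multivariate normal approximation of
#' the model's joint posterior (mean = penalized fit, covariance = Bayesian
#' coefficient covariance conditional on the selected smoothing parameters)
#' and pushes them through the design to predicted mean GRB for every
#' country, year and age-sex cell - including survey-free years, where
#' information is borrowed across time and cultural space.
#'
#' @param object a [grb_trend()] fit.
#' @param n_draws number of posterior draws (default 2000).
#' @param seed optional RNG seed.
#' @param unconditional use the smoothing-parameter-uncertainty-corrected
#'   coefficient covariance (available when the model was fit with the
#'   default outer Newton optimizer); the default `FALSE` conditions on the
#'   selected smoothing parameters (empirical Bayes).
#' @return object of class `grb_draws`: list with `draws` (`n_draws` x cells
#'   matrix) and `cells` (country, year, agesex per column).
#' @export
draw_posterior <- function(object, n_draws = 2000, seed = NULL,
                           unconditional = FALSE) {
  stopifnot(inherits(object, "grb_trend"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- trend_grid(object)
  Xp <- predict(object, newdata = grid, type = "lpmatrix")
  Vp <- if (unconditional) {
    if (is.null(object$gam$Vc))
      stop("corrected covariance unavailable; refit with the default optimizer")
    object$gam$Vc
  } else object$gam$Vp
  ev <- min(eigen(Vp, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6 * max(abs(Vp)))
    stop("coefficient covariance is not positive semidefinite")
  beta <- mgcv::rmvn(n_draws, coef(object$gam), Vp)
  if (n_draws == 1L) beta <- matrix(beta, nrow = 1L)
  draws <- beta %*% t(Xp)
  structure(list(draws = draws,
                 cells = data.frame(country = as.character(grid$country),
                                    year = grid$year,
                                    agesex = as.character(grid$agesex),
                                    stringsAsFactors = FALSE),
                 level = "cell"),
            class = "grb_draws")
}

#' @export
print.grb_draws <- function(x, ...) {
  cat("GRB posterior draws:", nrow(x$draws), "draws x", ncol(x$draws),
      "cells (", length(unique(x$cells$country)), "countries,",
      length(unique(x$cells$year)), "years )\n")
  invisible(x)
}
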