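#' Relative trend excess of a counterfactual over the observed change
#'
#' `100 * ((cf_to - obs_from) / (obs_to - obs_from) - 1)`: how much larger
#' (in percent) the change would have been under the counterfactual. Applied
#' per posterior draw and then summarized by the posterior median. A
#' near-zero observed change makes the ratio unstable and is flagged.
#'
#' @param obs_from,obs_to observed series values at the anchor and end years.
#' @param cf_to counterfactual value at the end year (the counterfactual
#'   coincides with the observed series in the anchor year).
#' @param tol observed changes smaller than this trigger a warning and `NA`.
#' @return percent excess (vectorized).
#' @examples
#' relative_trend_excess(52.7, 55.2, 57.0)  # 72
#' @export
relative_trend_excess <- function(obs_from, obs_to, cf_to, tol = 1e-8) {
  d <- obs_to - obs_from
  unstable <- abs(d) < tol
  if (any(unstable)) {
    warning("near-zero observed change: relative excess unstable, set to NA")
    d[unstable] <- NA_real_
  }
  100 * ((cf_to - obs_from) / d - 1)
}

#' Fixed-composition counterfactual of the global series
#'
#' Recomputes the global population-weighted series per posterior draw with
#' national shares of the global adult population frozen at their anchor-year
#' (1995) values, while within-country age-sex weighting follows the observed
#' year. The contrast with the observed global series isolates the effect of
#' changes in the national composition of the global population.
#'
#' @param country_series country-level [poststratify()] result.
#' @param pop population table.
#' @param anchor_year year whose national shares are held fixed (default
#'   first year of the series).
#' @return object of class `counterfactual_result`: `observed` and
#'   `counterfactual` global `grb_series`, per-draw `excess_draws` (relative
#'   trend excess over the full window), and a `summary` row (posterior
#'   median with 90% equal-tailed interval).
#' @export
counterfactual_series <- function(country_series, pop, anchor_year = NULL) {
  stopifnot(inherits(country_series, "grb_series"),
            country_series$level == "country")
  idx <- country_series$index
  years <- sort(unique(idx$year))
  if (is.null(anchor_year)) anchor_year <- min(years)
  countries <- sort(unique(idx$unit))
  ptot <- aggregate(count ~ country + year, pop, sum)
  ptot <- ptot[ptot$country %in% countries, ]
  p0 <- ptot$count[match(paste(countries, anchor_year),
                         paste(ptot$country, ptot$year))]
  if (anyNA(p0)) stop("missing anchor-year population shares")
  w0 <- p0 / sum(p0)
  D <- country_series$draws
  Dobs <- matrix(NA_real_, nrow(D), length(years))
  Dcf <- Dobs; repp <- numeric(length(years))
  for (j in seq_along(years)) {
    cols <- match(paste(countries, years[j]), paste(idx$unit, idx$year))
    sub <- D[, cols, drop = FALSE]
    pc <- ptot$count[match(paste(countries, years[j]),
                           paste(ptot$country, ptot$year))]
    Dobs[, j] <- sub %*% (pc / sum(pc))
    Dcf[, j] <- sub %*% w0
    repp[j] <- sum(pc)
  }
  mk <- function(Dm) structure(list(
    draws = Dm, index = data.frame(unit = "global", year = years,
                                   stringsAsFactors = FALSE),
    represented = repp, level = "global"), class = "grb_series")
  j1 <- which(years == min(years)); j2 <- which(years == max(years))
  excess <- suppressWarnings(
    relative_trend_excess(Dobs[, j1], Dobs[, j2], Dcf[, j2]))
  structure(list(observed = mk(Dobs), counterfactual = mk(Dcf),
                 anchor_year = anchor_year, excess_draws = excess,
                 summary = c(median = median(excess, na.rm = TRUE),
                             eti(excess))),
            class = "counterfactual_result")
}

#' @export
print.counterfactual_result <- function(x, ...) {
  y <- x$observed$index$year
  j1 <- which.min(y); j2 <- which.max(y)
  cat(sprintf("Observed global mean %d -> %d: %.1f -> %.1f\n",
              min(y), max(y), mean(x$observed$draws[, j1]),
              mean(x$observed$draws[, j2])))
  cat(sprintf("Counterfactual (composition fixed at %d): %.1f\n",
              x$anchor_year, mean(x$counterfactual$draws[, j2])))
  cat(sprintf("Relative trend excess: %.0f%% [%.0f%%, %.0f%%] (posterior median, 90%% ETI)\n",
              x$summary["median"], x$summary["lo"], x$summary["hi"]))
  invisible(x)
}

#' Spearman correlation between population size and national GRB
#'
#' Rank correlation between national adult population size in a year and the
#' poststratified national mean GRB, computed per posterior draw (the same
#' draw index across countries, preserving cross-country posterior
#' correlation); ties get average ranks.
#'
#' @param country_series country-level [poststratify()] result.
#' @param pop population table.
#' @param year year at which both quantities are taken.
#' @return list with per-draw `draws`, posterior `mean`, and `lo90`/`hi90`.
#' @export
size_grb_correlation <- function(country_series, pop, year) {
  stopifnot(inherits(country_series, "grb_series"),
            country_series$level == "country")
  idx <- country_series$index
  countries <- sort(unique(idx$unit))
  if (length(countries) < 5L) stop("need at least 5 countries")
  ptot <- aggregate(count ~ country, pop[pop$year == year, ], sum)
  psz <- ptot$count[match(countries, ptot$country)]
  if (anyNA(psz)) stop("population sizes missing in ", year)
  cols <- match(paste(countries, year), paste(idx$unit, idx$year))
  sub <- country_series$draws[, cols, drop = FALSE]
  rp <- rank(psz)   # average ranks for ties
  draws <- apply(sub, 1L, function(v) cor(rp, rank(v)))
  iv <- eti(draws)
  list(draws = draws, mean = mean(draws), lo90 = iv["lo"], hi90 = iv["hi"],
       year = year)
}

## JAGS: log population growth regressed on true national GRB, observed with
## known measurement SD (from the trend model's posterior spread)
growth_jags <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(off[i] + alpha + beta * xt[i], pow(sigma, -2))
    xobs[i] ~ dnorm(xt[i], pow(se[i], -2))
    xt[i] ~ dnorm(0, 0.25)
  }
  alpha ~ dnorm(0, 0.01)
  beta ~ dnorm(0, pow(2.5 * sdy, -2))
  sigma ~ dt(0, pow(2.5 * sdy, -2), 3) T(0,)
}"

#' Bayesian measurement-error regression of population growth on GRB
#'
#' Fits `log(pop_end) = log(pop_start) + alpha + beta * GRB_true` with the
#' observed national mean GRB treated as a noisy measurement of `GRB_true`
#' (`GRB_obs ~ Normal(GRB_true, se)`, `se` from the posterior spread of the
#' poststratified national means). The predictor is standardized internally;
#' priors are weakly informative and zero-centered with scales set from the
#' response range. Sampled with JAGS.
#'
#' @param grb_mean,grb_se per-country posterior mean and SD of national GRB
#'   in the anchor year.
#' @param pop_start,pop_end adult population totals at the window ends.
#' @param n_chains,n_adapt,n_burn,n_iter,thin sampler settings.
#' @param seed RNG seed.
#' @return object of class `growth_regression` with draws of `alpha`,
#'   `beta_per_sd`, `beta_per_point`, `sigma`, plus data summaries.
#' @export
growth_regression <- function(grb_mean, grb_se, pop_start, pop_end,
                              n_chains = 3, n_adapt = 1000, n_burn = 1000,
                              n_iter = 3000, thin = 3, seed = 1) {
  n <- length(grb_mean)
  stopifnot(length(grb_se) == n, length(pop_start) == n, length(pop_end) == n)
  if (any(pop_start <= 0 | pop_end <= 0)) stop("non-positive populations")
  y <- log(pop_end); off <- log(pop_start)
  mx <- mean(grb_mean); sx <- sd(grb_mean)
  jd <- list(N = n, y = y, off = off, xobs = (grb_mean - mx) / sx,
             se = pmax(grb_se / sx, 1e-6), sdy = sd(y - off))
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, 200 + ch)))
  jm <- rjags::jags.model(textConnection(growth_jags), data = jd,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("alpha", "beta", "sigma"),
                            n.iter = n_iter, thin = thin,
                            progress.bar = "none")
  m <- as.matrix(sm)
  structure(list(alpha = m[, "alpha"], beta_per_sd = m[, "beta"],
                 beta_per_point = m[, "beta"] / sx, sigma = m[, "sigma"],
                 x_mean = mx, x_sd = sx,
                 rhat = coda::gelman.diag(sm, multivariate = FALSE,
                                          autoburnin = FALSE)$psrf[, 1]),
            class = "growth_regression")
}

#' @export
print.growth_regression <- function(x, ...) {
  b <- x$beta_per_sd; iv <- eti(b)
  cat(sprintf("Growth on GRB: beta = %.3f [%.3f, %.3f] per SD (%.4f per point)\n",
              mean(b), iv["lo"], iv["hi"], mean(x$beta_per_point)))
  cat(sprintf("  residual sigma = %.3f, max R-hat = %.3f\n",
              mean(x$sigma), max(x$rhat)))
  invisible(x)
}

#' Predicted population growth factor as a function of national GRB
#'
#' Transforms the regression draws into the multiplicative change of the
#' adult population over the window, `exp(alpha + beta * (grb - mean))`,
#' monotone in the linear predictor.
#'
#' @param object a [growth_regression()] fit.
#' @param newdata optional data frame with a `grb` column (0-100 scale);
#'   default: a grid over mean +- 2 SD.
#' @param ... unused.
#' @return data frame `grb, mean, lo90, hi90` of the growth factor.
#' @export
predict.growth_regression <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- data.frame(grb = object$x_mean +
                            seq(-2, 2, by = 0.25) * object$x_sd)
  z <- (newdata$grb - object$x_mean) / object$x_sd
  out <- t(vapply(z, function(zz) {
    f <- exp(object$alpha + object$beta_per_sd * zz)
    c(mean = mean(f), eti(f))
  }, numeric(3L)))
  data.frame(grb = newdata$grb, mean = out[, 1], lo90 = out[, 2],
             hi90 = out[, 3])
}
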