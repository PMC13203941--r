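#' Build poststratification weights from population counts
#'
#' For `level = "country"`, each country-year's six age-sex cells are weighted
#' by their within-country population shares. For higher levels (cultural
#' zone, HDI class, global) cells are weighted by their share of the
#' aggregation unit's total adult population, so country series aggregate
#' according to national adult population shares.
#'
#' @param pop population table (`country, year, agesex, count`).
#' @param level one of `"country"`, `"zone"`, `"hdi"`, `"global"`.
#' @param lookup country lookup with `zone` / `hdi_class` columns (required
#'   for those levels).
#' @return object of class `weight_scheme`: data frame
#'   `unit, country, year, agesex, weight, count` with attribute `level`;
#'   weights sum to 1 within every unit-year.
#' @export
build_weights <- function(pop, level = c("country", "zone", "hdi", "global"),
                          lookup = NULL) {
  level <- match.arg(level)
  check_cols(pop, c("country", "year", "agesex", "count"), "pop")
  if (any(is.na(pop$count))) stop("population counts contain NA")
  if (any(pop$count < 0)) stop("population counts must be nonnegative")
  unit <- switch(level,
    country = pop$country,
    global = rep("global", nrow(pop)),
    zone = {
      check_cols(lookup, c("country", "zone"), "lookup")
      lookup$zone[match(pop$country, lookup$country)]
    },
    hdi = {
      check_cols(lookup, c("country", "hdi_class"), "lookup")
      lookup$hdi_class[match(pop$country, lookup$country)]
    })
  if (anyNA(unit)) stop("lookup does not cover all countries in pop")
  key <- paste(unit, pop$year)
  tot <- tapply(pop$count, key, sum)
  w <- data.frame(unit = unit, country = pop$country, year = pop$year,
                  agesex = pop$agesex,
                  weight = pop$count / as.numeric(tot[key]),
                  count = pop$count, stringsAsFactors = FALSE)
  structure(w, level = level, class = c("weight_scheme", "data.frame"))
}

#' Poststratify posterior cell draws into unit-year means
#'
#' Computes the weighted average of cell-level posterior draws independently
#' for every draw, preserving full uncertainty propagation. Draw cells and
#' weight cells must align; missing cells abort with a list of gaps.
#'
#' @param draws a [draw_posterior()] object (cell level).
#' @param weights a [build_weights()] scheme.
#' @return object of class `grb_series`: list with `draws` (`n_draws` x
#'   unit-years), `index` (`unit, year`), `represented` (population totals)
#'   and `level`.
#' @export
poststratify <- function(draws, weights) {
  stopifnot(inherits(draws, "grb_draws"), inherits(weights, "weight_scheme"))
  ckey <- paste(draws$cells$country, draws$cells$year, draws$cells$agesex)
  wkey <- paste(weights$country, weights$year, weights$agesex)
  pos <- match(wkey, ckey)
  if (anyNA(pos)) {
    gaps <- unique(wkey[is.na(pos)])
    stop("draws are missing cells required by the weights, e.g.: ",
         paste(head(gaps, 5L), collapse = "; "))
  }
  uy <- unique(weights[, c("unit", "year")])
  uy <- uy[order(uy$unit, uy$year), ]
  W <- matrix(0, ncol(draws$draws), nrow(uy))
  rep_pop <- numeric(nrow(uy))
  ukey_all <- paste(weights$unit, weights$year)
  ukey <- paste(uy$unit, uy$year)
  for (j in seq_len(nrow(uy))) {
    sel <- ukey_all == ukey[j]
    W[pos[sel], j] <- W[pos[sel], j] + weights$weight[sel]
    rep_pop[j] <- sum(weights$count[sel])
  }
  bad <- abs(colSums(W) - 1) > 1e-9
  if (any(bad)) stop("weights do not sum to 1 within unit-year")
  structure(list(draws = draws$draws %*% W,
                 index = data.frame(unit = uy$unit, year = uy$year,
                                    stringsAsFactors = FALSE),
                 represented = rep_pop,
                 level = attr(weights, "level")),
            class = "grb_series")
}

#' @export
print.grb_series <- function(x, ...) {
  cat("Poststratified GRB series (", x$level, "):", nrow(x$draws), "draws x",
      nrow(x$index), "unit-years\n")
  invisible(x)
}

#' Summarize a poststratified series
#'
#' Posterior mean and 90% equal-tailed interval per unit-year (percentiles by
#' linear interpolation between order statistics), with the represented adult
#' population.
#'
#' @param series a [poststratify()] result.
#' @param level interval mass (default 0.9).
#' @return data frame `unit, year, mean, lo90, hi90, represented_population`.
#' @export
summarize_series <- function(series, level = 0.9) {
  stopifnot(inherits(series, "grb_series"), nrow(series$draws) >= 2L)
  mu <- colMeans(series$draws)
  qs <- apply(series$draws, 2L, eti, level = level)
  out <- data.frame(series$index, mean = mu, lo90 = qs["lo", ],
                    hi90 = qs["hi", ],
                    represented_population = series$represented,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
summary.grb_series <- function(object, ...) summarize_series(object, ...)

#' Per-draw change between two years of a series
#'
#' @param series a [poststratify()] result.
#' @param from,to years to difference (`to` minus `from`).
#' @return data frame `unit, mean, lo90, hi90` of the per-draw change.
#' @export
series_change <- function(series, from, to) {
  stopifnot(inherits(series, "grb_series"))
  units <- unique(series$index$unit)
  out <- lapply(units, function(u) {
    i1 <- which(series$index$unit == u & series$index$year == from)
    i2 <- which(series$index$unit == u & series$index$year == to)
    if (!length(i1) || !length(i2)) return(NULL)
    d <- series$draws[, i2] - series$draws[, i1]
    data.frame(unit = u, mean = mean(d), lo90 = eti(d)["lo"],
               hi90 = eti(d)["hi"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average-country versus average-citizen global series
#'
#' From country-level poststratified draws, computes two global series per
#' draw: the simple average with countries weighted equally (the trend in
#' the average country) and the population-weighted average using national
#' adult population shares (the trend for the average global citizen).
#'
#' @param country_series country-level [poststratify()] result.
#' @param pop population table used for the population weights.
#' @return list of two `grb_series`: `equal` and `weighted`.
#' @export
equal_vs_weighted <- function(country_series, pop) {
  stopifnot(inherits(country_series, "grb_series"),
            country_series$level == "country")
  idx <- country_series$index
  years <- sort(unique(idx$year))
  countries <- sort(unique(idx$unit))
  ptot <- aggregate(count ~ country + year, pop, sum)
  ptot <- ptot[ptot$country %in% countries, ]
  Deq <- matrix(NA_real_, nrow(country_series$draws), length(years))
  Dwt <- Deq; repp <- numeric(length(years))
  for (j in seq_along(years)) {
    cols <- match(paste(countries, years[j]), paste(idx$unit, idx$year))
    sub <- country_series$draws[, cols, drop = FALSE]
    pc <- ptot$count[match(paste(countries, years[j]),
                           paste(ptot$country, ptot$year))]
    if (anyNA(pc)) stop("population totals missing for year ", years[j])
    Deq[, j] <- rowMeans(sub)
    Dwt[, j] <- sub %*% (pc / sum(pc))
    repp[j] <- sum(pc)
  }
  mk <- function(D) structure(list(
    draws = D, index = data.frame(unit = "global", year = years,
                                  stringsAsFactors = FALSE),
    represented = repp, level = "global"), class = "grb_series")
  list(equal = mk(Deq), weighted = mk(Dwt))
}
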