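#' Scenario configuration for the synthetic survey generator
#'
#' Defines the generative world the pipeline is tested against: country trends
#' in latent gender-role beliefs (GRB) nested in cultural zones, six age-sex
#' strata, ordinal survey items, differential population growth tied to a
#' country's 1995 GRB, and fertility schedules whose level and timing depend
#' on a woman's GRB subgroup.
#'
#' Latent country trends are a scaled logistic zone curve plus a country
#' intercept and a low-order (two-term Legendre) smooth deviation. Items are
#' the latent person score plus item noise, discretized onto ordinal scales
#' with 2, 3 and 4 response levels by fixed equal-width thresholds on the
#' 0-100 scale. The two fertility subgroups use four-parameter
#' age-specific-fertility-rate (ASFR) schedules calibrated so the less
#' egalitarian ("low") group has total fertility 0.17 children higher and
#' reaches cumulative fertility 0.5 about 1.52 years earlier than the "high"
#' group.
#'
#' @param n_countries number of countries (default 20).
#' @param zones data frame with columns `zone`, `base` (1995 latent level),
#'   `gain` (total latent change over the window), `mid` (logistic midpoint
#'   year), `rate` (logistic rate per year).
#' @param years contiguous integer survey window (default 1995:2022).
#' @param agesex_effects named offsets (0-100 latent units) for the six
#'   age-sex groups; must sum to zero.
#' @param country_intercept_sd,trend_dev_sd,agesex_dev_sd SDs of country-level
#'   deviations: intercept, smooth-deviation coefficients, age-sex offsets.
#' @param person_sd SD of a person's latent GRB around their cell mean.
#' @param item_noise_sd SD of item-specific noise before discretization.
#' @param item_levels response-scale lengths of the three ordinal items.
#' @param n_per_wave respondents sampled per national survey wave.
#' @param waves_range inclusive range for the number of waves per country.
#' @param min_span_frac_gen minimum fraction of the window the first-to-last
#'   wave must span (wave years are redrawn until satisfied).
#' @param base_growth mean total log growth of the adult population over the
#'   window.
#' @param growth_slope effect of a one-point higher 1995 country GRB on total
#'   log adult-population growth (negative: egalitarian countries grow less).
#' @param growth_noise_sd SD of country-level log-growth noise.
#' @param init_pop_meanlog,init_pop_sdlog lognormal parameters of initial
#'   adult population sizes.
#' @param fertility_link list with `split` (numeric 0-100 or `"median"`),
#'   per-group ASFR parameters `low` and `high` as `c(c, mu, s1, s2)`, and
#'   integer `support` ages.
#' @param lmm_coefs generating coefficients for the dedicated fertility
#'   mixed-model sample: `intercept`, `within`, `between` (per SD of GRB),
#'   `intercept_sd`, `slope_sd`, `residual_sd`.
#' @param seed master seed; all stages derive child seeds from it.
#' @return an object of class `grb_scenario` (a validated list).
#' @seealso [generate_population()], [generate_survey()],
#'   [generate_fertility()], [simulate_scenario()]
#' @export
scenario_config <- function(n_countries = 20,
                            zones = data.frame(
                              zone = c("west", "east", "south"),
                              base = c(58, 48, 42),
                              gain = c(13, 7, -3),
                              mid  = c(2008, 2010, 2006),
                              rate = c(0.22, 0.18, 0.15)),
                            years = 1995:2022,
                            agesex_effects = c(
                              "female.18-34" = 4,   "female.35-59" = 2.5,
                              "female.60+"   = 0,   "male.18-34"   = -0.5,
                              "male.35-59"   = -2.5, "male.60+"    = -3.5),
                            country_intercept_sd = 4,
                            trend_dev_sd = 1.5,
                            agesex_dev_sd = 1,
                            person_sd = 16,
                            item_noise_sd = 20,
                            item_levels = c(2L, 3L, 4L),
                            n_per_wave = 500,
                            waves_range = c(2L, 5L),
                            min_span_frac_gen = 0.3,
                            base_growth = 0.35,
                            growth_slope = -0.01,
                            growth_noise_sd = 0.08,
                            init_pop_meanlog = log(5e6),
                            init_pop_sdlog = 1.2,
                            fertility_link = list(
                              split = "median",
                              low  = c(c = 0.154167, mu = 27.821639, s1 = 4.5, s2 = 9.0),
                              high = c(c = 0.140,    mu = 29.0,      s1 = 4.5, s2 = 9.0),
                              support = 15:49),
                            lmm_coefs = list(
                              intercept = 2.2, within = -0.102, between = -0.622,
                              intercept_sd = 0.574, slope_sd = 0.05,
                              residual_sd = 1.205),
                            seed = 1L) {
  cfg <- list(n_countries = as.integer(n_countries), zones = zones,
              years = as.integer(years), agesex_effects = agesex_effects,
              country_intercept_sd = country_intercept_sd,
              trend_dev_sd = trend_dev_sd, agesex_dev_sd = agesex_dev_sd,
              person_sd = person_sd, item_noise_sd = item_noise_sd,
              item_levels = as.integer(item_levels),
              n_per_wave = as.integer(n_per_wave),
              waves_range = as.integer(waves_range),
              min_span_frac_gen = min_span_frac_gen,
              base_growth = base_growth, growth_slope = growth_slope,
              growth_noise_sd = growth_noise_sd,
              init_pop_meanlog = init_pop_meanlog,
              init_pop_sdlog = init_pop_sdlog,
              fertility_link = fertility_link, lmm_coefs = lmm_coefs,
              seed = as.integer(seed))
  validate_scenario(cfg)
}

## six fixed age-sex strata: {18-34, 35-59, 60+} x {female, male}
agesex_levels <- function() {
  c("female.18-34", "female.35-59", "female.60+",
    "male.18-34", "male.35-59", "male.60+")
}

validate_scenario <- function(cfg) {
  with(cfg, {
    if (n_countries < 1L) stop("need at least one country")
    if (!identical(sort(names(agesex_effects)), sort(agesex_levels())))
      stop("agesex_effects must name exactly the six age-sex groups")
    if (abs(sum(agesex_effects)) > 1e-8)
      stop("agesex_effects must sum to zero")
    if (!identical(years, years[1]:years[length(years)]))
      stop("years must form a contiguous range")
    sc <- c(country_intercept_sd, trend_dev_sd, agesex_dev_sd, person_sd,
            item_noise_sd, growth_noise_sd)
    if (any(sc < 0)) stop("scale parameters must be nonnegative")
    if (length(item_levels) != 3L || any(item_levels < 2L))
      stop("item_levels must give three scales with >= 2 levels each")
    if (waves_range[1] < 1L || waves_range[2] < waves_range[1])
      stop("invalid waves_range")
    if (n_per_wave < 1L) stop("n_per_wave must be >= 1")
    for (g in c("low", "high")) {
      p <- fertility_link[[g]]
      if (p[1] < 0 || p[3] <= 0 || p[4] <= 0)
        stop("ASFR parameters need c >= 0 and s1, s2 > 0")
    }
  })
  structure(cfg, class = "grb_scenario")
}

#' @export
print.grb_scenario <- function(x, ...) {
  cat("Synthetic GRB scenario:",
      x$n_countries, "countries in", nrow(x$zones), "zones,",
      "years", min(x$years), "-", max(x$years), "\n")
  cat("  waves/country:", x$waves_range[1], "-", x$waves_range[2],
      " respondents/wave:", x$n_per_wave, "\n")
  cat("  growth slope per GRB point:", x$growth_slope,
      " master seed:", x$seed, "\n")
  invisible(x)
}

## ---- latent structure ------------------------------------------------------

## logistic zone curve on the latent 0-100 scale,
## anchored so curve(first year) = base and curve(last year) = base + gain
zone_curve <- function(year, base, gain, mid, rate, years) {
  lo <- stats::plogis(rate * (min(years) - mid))
  hi <- stats::plogis(rate * (max(years) - mid))
  base + gain * (stats::plogis(rate * (year - mid)) - lo) / (hi - lo)
}

#' Ground truth of a scenario
#'
#' Deterministically expands a scenario configuration into the full generative
#' ground truth: per-country latent trend curves, age-sex offsets, expected
#' composite-score cell means for every country-year-cell, population paths,
#' and the fertility parameters per GRB subgroup. Every generated respondent
#' row is traceable to one of these cell means.
#'
#' Cell means are stored on the *composite* scale: the latent cell mean pushed
#' through item discretization and 0-100 rescaling (see
#' [expected_composite()]), which is the scale the fitted models see.
#'
#' @param config a [scenario_config()] object.
#' @return an object of class `grb_truth`: list with `countries` (country,
#'   zone, hdi_class, intercept, growth factors, 1995 level), `latent`
#'   (country x year latent means), `cell_mean` (country x year x agesex
#'   expected composite), `agesex_offsets` (country x group), `population`
#'   (long table), and `config`.
#' @export
scenario_truth <- function(config) {
  stopifnot(inherits(config, "grb_scenario"))
  cfg <- config
  set.seed(child_seed(cfg$seed, 1L))
  yrs <- cfg$years; ny <- length(yrs); nc <- cfg$n_countries
  grp <- agesex_levels()

  country <- sprintf("C%02d", seq_len(nc))
  zone <- cfg$zones$zone[(seq_len(nc) - 1L) %% nrow(cfg$zones) + 1L]

  intercept <- rnorm(nc, 0, cfg$country_intercept_sd)
  dev1 <- rnorm(nc, 0, cfg$trend_dev_sd)
  dev2 <- rnorm(nc, 0, cfg$trend_dev_sd)
  u <- 2 * (yrs - min(yrs)) / (max(yrs) - min(yrs)) - 1  # [-1, 1]

  latent <- matrix(NA_real_, nc, ny, dimnames = list(country, yrs))
  for (i in seq_len(nc)) {
    z <- cfg$zones[match(zone[i], cfg$zones$zone), ]
    latent[i, ] <- zone_curve(yrs, z$base, z$gain, z$mid, z$rate, yrs) +
      intercept[i] + dev1[i] * u + dev2[i] * (3 * u^2 - 1) / 2
  }

  off <- matrix(rnorm(nc * 6L, 0, cfg$agesex_dev_sd), nc, 6L,
                dimnames = list(country, grp))
  off <- sweep(off, 1L, rowMeans(off))            # country deviations centered
  off <- sweep(off, 2L, cfg$agesex_effects[grp], `+`)

  sd_tot <- sqrt(cfg$person_sd^2 + cfg$item_noise_sd^2)
  cell <- array(NA_real_, c(nc, ny, 6L), dimnames = list(country, yrs, grp))
  for (g in seq_len(6L))
    cell[, , g] <- expected_composite(latent + off[, g], sd_tot, cfg$item_levels)

  ## population: initial sizes, fixed within-country age-sex shares, log-linear
  ## growth whose slope decreases in the 1995 composite level by growth_slope
  pop0 <- rlnorm(nc, cfg$init_pop_meanlog, cfg$init_pop_sdlog)
  base_share <- c(0.17, 0.20, 0.13, 0.17, 0.20, 0.13)
  shares <- t(vapply(seq_len(nc), function(i) {
    s <- rgamma(6L, shape = 300 * base_share)
    s / sum(s)
  }, numeric(6L)))
  g95 <- apply(cell[, 1L, , drop = FALSE], 1L, mean)  # 1995 composite mean
  gfac <- cfg$base_growth + cfg$growth_slope * (g95 - mean(g95)) +
    rnorm(nc, 0, cfg$growth_noise_sd)
  span <- max(yrs) - min(yrs)
  tot <- outer(pop0, rep(1, ny)) * exp(outer(gfac, (yrs - min(yrs)) / span))
  if (any(tot <= 0)) stop("non-positive population generated")

  pop <- expand.grid(country = country, year = yrs, agesex = grp,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pop$count <- pmax(1, round(tot[cbind(match(pop$country, country),
                                       match(pop$year, yrs))] *
                               shares[cbind(match(pop$country, country),
                                            match(pop$agesex, grp))]))
  pop <- pop[order(pop$country, pop$year, pop$agesex), ]
  rownames(pop) <- NULL

  ## HDI class by 1995 level quartile (config input in real analyses)
  qs <- quantile(g95, c(0.25, 0.5, 0.75), type = 7)
  hdi <- if (length(unique(qs)) < 3L) factor(rep("high", nc)) else
    cut(g95, c(-Inf, qs, Inf),
        labels = c("low", "medium", "high", "very high"))

  structure(list(
    countries = data.frame(country = country, zone = zone,
                           hdi_class = as.character(hdi),
                           intercept = intercept, growth_log = gfac,
                           level_1995 = g95, pop_1995 = tot[, 1L],
                           pop_last = tot[, ny], stringsAsFactors = FALSE),
    latent = latent, agesex_offsets = off, cell_mean = cell,
    population = pop, shares = shares, sd_total = sd_tot,
    config = cfg), class = "grb_truth")
}

#' Expected composite score given a latent mean
#'
#' Pushes a latent GRB mean through the item-generation process (normal noise,
#' equal-width discretization onto each ordinal scale, 0-100 rescaling,
#' three-item mean) and returns the expected composite score. This is the
#' scale on which generated survey scores live, so recovery tests compare
#' model estimates against this pushforward, not the raw latent mean.
#'
#' @param m latent mean(s), 0-100 units (vector or matrix).
#' @param sd total per-item noise SD (person + item components).
#' @param item_levels integer scale lengths.
#' @return expected composite, same shape as `m`.
#' @export
expected_composite <- function(m, sd, item_levels = c(2L, 3L, 4L)) {
  out <- 0
  for (L in item_levels) {
    th <- 100 * (0:L) / L; th[1] <- -Inf; th[L + 1L] <- Inf
    vals <- 100 * (seq_len(L) - 1L) / (L - 1L)
    e <- 0
    for (l in seq_len(L))
      e <- e + vals[l] * (pnorm((th[l + 1L] - m) / sd) - pnorm((th[l] - m) / sd))
    out <- out + e
  }
  out / length(item_levels)
}

## discretize a continuous 0-100 value onto a 1..L ordinal scale
discretize_item <- function(x, L) {
  as.integer(pmin(pmax(ceiling(x / (100 / L)), 1), L))
}
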