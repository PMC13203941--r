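#' Generate the country-year-age-sex population table
#'
#' Adult (18+) population counts for every country, year and age-sex cell.
#' Within-country age-sex shares are fixed over time; total adult population
#' grows log-linearly, with the total log growth decreasing in the country's
#' 1995 composite GRB level by `growth_slope` (plus country noise).
#'
#' @param config a [scenario_config()].
#' @param truth optional precomputed [scenario_truth()] (avoids recomputation).
#' @return data frame `country, year, agesex, count`.
#' @export
generate_population <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- scenario_truth(config)
  truth$population
}

#' Generate survey microdata with known ground truth
#'
#' Draws a sparse-wave survey design (2-5 waves per country at heterogeneous
#' year gaps), samples respondents per wave with age-sex cells proportional to
#' the population table, and generates three ordinal GRB item responses from
#' each respondent's latent score (country trend + age-sex offset + person
#' noise + item noise, discretized). Also generates the socio-demographic
#' covariates used by the fertility mixed model (education, income, town
#' size, four religiosity items).
#'
#' @param config a [scenario_config()].
#' @param pop population table from [generate_population()] (regenerated when
#'   missing).
#' @param truth optional precomputed [scenario_truth()].
#' @return list with `survey` (one row per respondent) and `truth`.
#' @export
generate_survey <- function(config, pop = NULL, truth = NULL) {
  stopifnot(inherits(config, "grb_scenario"))
  if (config$n_per_wave < 1L) stop("requested respondents per wave < 1")
  if (is.null(truth)) truth <- scenario_truth(config)
  if (is.null(pop)) pop <- truth$population
  cfg <- config
  set.seed(child_seed(cfg$seed, 2L))
  yrs <- cfg$years; grp <- agesex_levels()
  countries <- truth$countries$country
  span <- max(yrs) - min(yrs)

  ## wave schedule: heterogeneous gaps, first-to-last span kept wide enough
  ## that default-scenario countries satisfy downstream inclusion rules
  waves <- lapply(countries, function(cc) {
    rng <- cfg$waves_range
    nw <- if (rng[1] == rng[2]) rng[1] else
      (rng[1]:rng[2])[sample.int(rng[2] - rng[1] + 1L, 1L)]
    nw <- max(nw, 2L)
    repeat {
      w <- sort(sample(yrs, nw))
      if (diff(range(w)) >= cfg$min_span_frac_gen * span) return(w)
    }
  })
  names(waves) <- countries

  age_lo <- c(18L, 35L, 60L, 18L, 35L, 60L)
  age_hi <- c(34L, 59L, 84L, 34L, 59L, 84L)

  rows <- vector("list", length(countries))
  for (i in seq_along(countries)) {
    cc <- countries[i]
    per_wave <- lapply(waves[[cc]], function(yy) {
      sh <- pop$count[pop$country == cc & pop$year == yy]
      sh <- sh / sum(sh)
      gidx <- sample.int(6L, cfg$n_per_wave, replace = TRUE, prob = sh)
      age <- age_lo[gidx] + floor(runif(cfg$n_per_wave) * (age_hi[gidx] - age_lo[gidx] + 1L))
      lat_cell <- truth$latent[cc, as.character(yy)] +
        truth$agesex_offsets[cc, gidx]
      lat <- lat_cell + rnorm(cfg$n_per_wave, 0, cfg$person_sd)
      it <- vapply(cfg$item_levels, function(L)
        discretize_item(lat + rnorm(cfg$n_per_wave, 0, cfg$item_noise_sd), L),
        integer(cfg$n_per_wave))
      ## covariates: education/religiosity mildly tied to the latent score
      ed_lat <- 0.03 * (lat - 50) + rnorm(cfg$n_per_wave)
      education <- findInterval(ed_lat, c(-0.6, 0.3, 1.1)) + 1L      # 1..4
      income <- findInterval(0.3 * ed_lat + rnorm(cfg$n_per_wave),
                             c(-0.5, 0.8)) + 1L                     # 1..3
      town_size <- sample.int(5L, cfg$n_per_wave, replace = TRUE)    # 1..5
      rel_lat <- -0.04 * (lat - 50) + rnorm(cfg$n_per_wave)
      rel_scales <- c(4L, 5L, 7L, 10L)
      rel <- vapply(rel_scales, function(L)
        as.integer(pmin(pmax(ceiling(pnorm(rel_lat + rnorm(cfg$n_per_wave, 0, 0.8)) * L), 1), L)),
        integer(cfg$n_per_wave))
      data.frame(country = cc, year = yy,
                 agesex = grp[gidx], age = age,
                 sex = ifelse(gidx <= 3L, "female", "male"),
                 item1 = it[, 1L], item2 = it[, 2L], item3 = it[, 3L],
                 n_children = NA_integer_,
                 education = education, income = income,
                 town_size = town_size,
                 rel1 = rel[, 1L], rel2 = rel[, 2L], rel3 = rel[, 3L],
                 rel4 = rel[, 4L],
                 latent = lat, stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_wave)
  }
  survey <- do.call(rbind, rows)
  rownames(survey) <- NULL
  truth$waves <- waves
  list(survey = survey, truth = truth)
}

#' Attach Poisson children counts driven by cumulative age-specific fertility
#'
#' For women aged within the fertile observation window, draws the reported
#' number of children as Poisson with mean equal to the cumulative ASFR of
#' her GRB subgroup up to her age. Subgroup membership compares her composite
#' score with the configured split (ties to "low", the less egalitarian
#' group). Other respondents keep `NA`.
#'
#' @param config a [scenario_config()].
#' @param survey survey table from [generate_survey()]; a `grb` column is
#'   added via [score_survey()] when absent.
#' @param age_range women in this age range receive children counts
#'   (default 18-49).
#' @return the survey table with `n_children` (and `grb`, `grb_group`) filled.
#' @export
generate_fertility <- function(config, survey, age_range = c(18L, 49L)) {
  stopifnot(inherits(config, "grb_scenario"))
  check_cols(survey, c("age", "sex"), "survey")
  if (anyNA(survey$age) || anyNA(survey$sex)) stop("missing age or sex")
  if (!"grb" %in% names(survey))
    survey <- score_survey(survey, item_levels = config$item_levels)
  set.seed(child_seed(config$seed, 3L))
  fl <- config$fertility_link
  idx <- survey$sex == "female" & survey$age >= age_range[1] &
    survey$age <= age_range[2]
  split <- fl$split
  if (identical(split, "median")) split <- median(survey$grb[idx], na.rm = TRUE)
  gr <- median_split(survey$grb, split)
  survey$grb_group <- NA_character_
  survey$grb_group[idx] <- as.character(gr[idx])
  lam <- numeric(sum(idx))
  sub <- survey[idx, ]
  for (g in c("low", "high")) {
    sel <- sub$grb_group == g
    lam[sel] <- cumulative_fertility(sub$age[sel], fl[[g]], support = fl$support)
  }
  survey$n_children[idx] <- rpois(sum(idx), lam)
  attr(survey, "split_value") <- split
  survey
}

#' Generate a dedicated sample for the fertility mixed model
#'
#' Women aged 40-49, one survey per country, with a *Gaussian* children
#' outcome generated directly from the hybrid model: country-mean GRB effect
#' (between), individual deviation effect (within, with a random country
#' slope), random country intercept, and residual noise. Generating
#' coefficients come from `config$lmm_coefs` and are on the per-SD scale the
#' fitted model estimates, so estimates are directly comparable to truth.
#' Covariates are generated without effects.
#'
#' @param config a [scenario_config()].
#' @param n_countries,n_per_country sample dimensions (defaults 100 x 150).
#' @param seed optional override of the derived child seed.
#' @return data frame shaped like a scored survey (including `grb` on a 0-100
#'   scale) with attribute `"truth"` holding the generating coefficients.
#' @export
generate_lmm_survey <- function(config, n_countries = 100L,
                                n_per_country = 150L, seed = NULL) {
  stopifnot(inherits(config, "grb_scenario"))
  lc <- config$lmm_coefs
  set.seed(if (is.null(seed)) child_seed(config$seed, 4L) else seed)
  nb <- n_countries; np <- n_per_country; n <- nb * np
  country <- rep(sprintf("L%03d", seq_len(nb)), each = np)
  sd_b <- 0.5; sd_w <- sqrt(1 - sd_b^2)       # respondent-level SD of GRB = 1
  b <- rep(rnorm(nb, 0, sd_b), each = np)
  w <- rnorm(n, 0, sd_w)
  u0 <- rep(rnorm(nb, 0, lc$intercept_sd), each = np)
  u1 <- rep(rnorm(nb, 0, lc$slope_sd), each = np)
  kids <- lc$intercept + lc$between * b + (lc$within + u1) * w + u0 +
    rnorm(n, 0, lc$residual_sd)
  grbz <- b + w
  out <- data.frame(country = country, year = 2018L,
                    age = sample(40:49, n, replace = TRUE), sex = "female",
                    grb = 50 + 15 * grbz, n_children = kids,
                    education = sample.int(4L, n, TRUE),
                    income = sample.int(3L, n, TRUE),
                    town_size = sample.int(5L, n, TRUE),
                    rel1 = sample.int(4L, n, TRUE),
                    rel2 = sample.int(5L, n, TRUE),
                    rel3 = sample.int(7L, n, TRUE),
                    rel4 = sample.int(10L, n, TRUE),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- lc
  out
}

#' Run the full synthetic-data stage
#'
#' @param config a [scenario_config()].
#' @return list with `survey` (scored, with fertility), `population`, `truth`
#'   and `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  truth <- scenario_truth(config)
  pop <- generate_population(config, truth)
  gs <- generate_survey(config, pop, truth)
  survey <- score_survey(gs$survey, item_levels = config$item_levels)
  survey <- generate_fertility(config, survey)
  list(survey = survey, population = pop, truth = gs$truth, config = config)
}
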