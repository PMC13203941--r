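test_that("regeneration with the same seed reproduces tables exactly", {
  cfg <- small_config(seed = 77)
  a <- simulate_scenario(cfg)
  b <- simulate_scenario(cfg)
  expect_identical(a$survey, b$survey)
  expect_identical(a$population, b$population)
  ## a different master seed changes the data
  c2 <- simulate_scenario(small_config(seed = 78))
  expect_false(identical(a$survey$grb, c2$survey$grb))
})

test_that("scenario validation enforces its invariants", {
  expect_error(scenario_config(years = c(1995L, 1997L, 1998L)), "contiguous")
  expect_error(scenario_config(person_sd = -1), "nonnegative")
  expect_error(scenario_config(agesex_effects = c(
    "female.18-34" = 4, "female.35-59" = 2.5, "female.60+" = 0,
    "male.18-34" = -0.5, "male.35-59" = -2.5, "male.60+" = 0)), "sum to zero")
  expect_error(scenario_config(n_per_wave = 0), ">= 1")
})

test_that("population growth is log-linear with a GRB-dependent slope", {
  base <- list(n_countries = 2, country_intercept_sd = 0, trend_dev_sd = 0,
               agesex_dev_sd = 0, growth_noise_sd = 0,
               zones = data.frame(zone = c("lo", "hi"), base = c(40, 80),
                                  gain = c(0, 0), mid = c(2008, 2008),
                                  rate = c(0.2, 0.2)))
  ## no differential growth: identical growth factors
  cfg0 <- do.call(scenario_config, c(base, list(growth_slope = 0, seed = 3)))
  pop0 <- generate_population(cfg0)
  tot <- tapply(pop0$count, list(pop0$country, pop0$year), sum)
  ratio <- tot[, ncol(tot)] / tot[, 1]
  expect_equal(unname(ratio[1]), unname(ratio[2]),
               tolerance = 1e-2)  # integer rounding only
  ## zero growth entirely: totals constant over years
  cfg00 <- do.call(scenario_config, c(base, list(growth_slope = 0,
                                                 base_growth = 0, seed = 3)))
  tot00 <- tapply(generate_population(cfg00)$count,
                  list(generate_population(cfg00)$country,
                       generate_population(cfg00)$year), sum)
  expect_true(all(abs(tot00 - tot00[, 1]) / tot00[, 1] < 1e-2))
  ## negative slope: the less egalitarian country grows strictly faster
  cfgn <- do.call(scenario_config, c(base, list(growth_slope = -0.01, seed = 3)))
  tr <- scenario_truth(cfgn)
  popn <- tr$population
  totn <- tapply(popn$count, list(popn$country, popn$year), sum)
  rat <- totn[, ncol(totn)] / totn[, 1]
  lo_country <- tr$countries$country[which.min(tr$countries$level_1995)]
  expect_gt(rat[lo_country], rat[setdiff(rownames(totn), lo_country)])
  ## closed form: log-ratio difference equals slope x GRB difference
  dg <- diff(tr$countries$level_1995[order(tr$countries$country)])
  expect_equal(diff(log(rat))[[1]], -(-0.01) * abs(dg) * sign(-dg),
               tolerance = 0.02)
})

test_that("survey waves are sparse with heterogeneous gaps and full traceability", {
  sim <- small_sim()
  per <- tapply(sim$survey$year, sim$survey$country, function(y) length(unique(y)))
  expect_true(all(per >= 2 & per <= 5))
  gaps <- unlist(tapply(sim$survey$year, sim$survey$country,
                        function(y) diff(sort(unique(y)))))
  expect_gt(length(unique(gaps)), 1)   # heterogeneous spacing
  ## every respondent row is traceable to a stored latent cell mean
  tm <- sim$truth$cell_mean
  idx <- cbind(match(sim$survey$country, rownames(tm)),
               match(sim$survey$year, colnames(tm)),
               match(sim$survey$agesex, dimnames(tm)[[3]]))
  expect_false(anyNA(tm[idx]))
})

test_that("age-sex cell shares match the configured sampling scheme", {
  sim <- small_sim()
  pop <- sim$population
  for (cc in unique(sim$survey$country)[1:3]) {
    yy <- max(sim$survey$year[sim$survey$country == cc])
    sub <- sim$survey[sim$survey$country == cc & sim$survey$year == yy, ]
    p <- pop$count[pop$country == cc & pop$year == yy]
    p <- p[match(agesex_levels(),
                 pop$agesex[pop$country == cc & pop$year == yy])] / sum(p)
    emp <- tabulate(match(sub$agesex, agesex_levels()), 6) / nrow(sub)
    ## binomial error bound (4 Sds)
    expect_true(all(abs(emp - p) < 4 * sqrt(p * (1 - p) / nrow(sub)) + 1e-9))
  }
})

test_that("large waves put the sample mean composite within a point of the latent truth", {
  cfg <- scenario_config(n_countries = 2, n_per_wave = 5000, seed = 17)
  sim <- simulate_scenario(cfg)
  tm <- sim$truth$cell_mean
  key <- paste(sim$survey$country, sim$survey$year)
  for (k in unique(key)) {
    sub <- sim$survey[key == k, ]
    truth_cell <- tm[cbind(match(sub$country, rownames(tm)),
                           match(sub$year, colnames(tm)),
                           match(sub$agesex, dimnames(tm)[[3]]))]
    expect_lt(abs(mean(sub$grb) - mean(truth_cell)), 1)
  }
})

test_that("fertility generation follows the cumulative subgroup schedule", {
  fl <- fert_truth()
  ## zero-height curve: no children
  survey <- data.frame(country = "A", year = 2018, age = rep(30L, 50),
                       sex = "female", grb = runif(50, 0, 100),
                       n_children = NA_integer_)
  cfg <- scenario_config(fertility_link = list(
    split = 50, low = c(c = 0, mu = 28, s1 = 4.5, s2 = 9),
    high = c(c = 0, mu = 28, s1 = 4.5, s2 = 9), support = 15:49))
  out <- generate_fertility(cfg, survey)
  expect_true(all(out$n_children == 0))
  ## missing age rejected
  bad <- survey; bad$age[1] <- NA
  expect_error(generate_fertility(cfg, bad), "missing age")
  ## 10,000 women aged 49 in one subgroup: mean within 2 SE of the group TFR
  cfg2 <- scenario_config(seed = 23)
  w <- data.frame(country = "A", year = 2018, age = rep(49L, 10000),
                  sex = "female", grb = 10, n_children = NA_integer_)
  out2 <- generate_fertility(cfg2, w)   # all "low" under the realized median
  tfr_low <- cumulative_fertility(49, fert_truth()$low)
  se <- sqrt(tfr_low / 10000)
  expect_lt(abs(mean(out2$n_children) - tfr_low), 2 * se)
})

test_that("the dedicated mixed-model sample encodes the generating coefficients", {
  cfg <- scenario_config()
  d <- generate_lmm_survey(cfg, n_countries = 40, n_per_country = 60, seed = 4)
  expect_equal(nrow(d), 40 * 60)
  expect_true(all(d$age >= 40 & d$age <= 49))
  expect_identical(attr(d, "truth")$within, -0.102)
  expect_identical(attr(d, "truth")$between, -0.622)
})
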