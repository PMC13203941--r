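toy_pop <- function() {
  expand.grid(country = c("A", "B"), year = c(1995L, 2022L),
              agesex = agesex_levels(), KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

test_that("weights are population shares that sum to one within unit-years", {
  pop <- toy_pop()
  pop$count <- 100
  w <- build_weights(pop, "country")
  expect_true(all(abs(tapply(w$weight, paste(w$unit, w$year), sum) - 1) < 1e-9))
  expect_true(all(abs(w$weight - 1 / 6) < 1e-12))     # equal cells: 1/6 each
  ## two countries with adult populations 100 and 300: national shares .25/.75
  pop2 <- toy_pop()
  pop2$count <- ifelse(pop2$country == "A", 100 / 6, 300 / 6)
  wg <- build_weights(pop2, "global")
  sh <- tapply(wg$weight, list(wg$country, wg$year), sum)
  expect_equal(unname(sh["A", ]), c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(unname(sh["B", ]), c(0.75, 0.75), tolerance = 1e-12)
  ## single country: national share is one
  w1 <- build_weights(pop[pop$country == "A", ], "global")
  expect_true(all(abs(tapply(w1$weight, w1$year, sum) - 1) < 1e-12))
  expect_error(build_weights(transform(pop, count = -1), "country"))
})

test_that("poststratification is the per-draw weighted average", {
  ## 2-cell worked example: values 40 and 60 with weights .25/.75 give 55
  dr <- toy_draws(rbind(c(40, 60), c(40, 60), c(20, 80)),
                  country = "A", year = 2000L, agesex = c("f", "m"))
  pop <- data.frame(country = "A", year = 2000L, agesex = c("f", "m"),
                    count = c(25, 75))
  s <- poststratify(dr, build_weights(pop, "country"))
  expect_equal(unname(s$draws[, 1]), c(55, 55, 65))
  ## uniform weights reduce to the simple mean
  pop$count <- c(50, 50)
  s2 <- poststratify(dr, build_weights(pop, "country"))
  expect_equal(unname(s2$draws[, 1]), rowMeans(dr$draws))
  ## single-cell unit is the identity
  dr1 <- toy_draws(cbind(c(41, 42)), "A", 2000L, "f")
  pop1 <- data.frame(country = "A", year = 2000L, agesex = "f", count = 10)
  expect_equal(unname(poststratify(dr1, build_weights(pop1, "country"))$draws[, 1]),
               c(41, 42))
  ## misalignment aborts
  popx <- data.frame(country = "A", year = 2001L, agesex = "f", count = 1)
  expect_error(poststratify(dr1, build_weights(popx, "country")), "missing cells")
})

test_that("summaries use interpolated percentiles and ordered intervals", {
  dr <- toy_draws(cbind(1:100), "A", 2000L, "f")
  pop1 <- data.frame(country = "A", year = 2000L, agesex = "f", count = 1)
  s <- poststratify(dr, build_weights(pop1, "country"))
  sm <- summarize_series(s)
  ## linear interpolation between order statistics
  expect_equal(sm$lo90, 5.95)
  expect_equal(sm$hi90, 95.05)
  expect_true(sm$lo90 <= sm$mean & sm$mean <= sm$hi90)
  ## constant draws: zero-width interval
  dc <- toy_draws(cbind(rep(7, 50)), "A", 2000L, "f")
  smc <- summarize_series(poststratify(dc, build_weights(pop1, "country")))
  expect_equal(smc$hi90 - smc$lo90, 0)
  ## change between identical years is zero
  dr2 <- toy_draws(matrix(rep(c(3, 9), each = 20), 20), "A",
                   c(1995L, 2022L), "f")
  pop2 <- data.frame(country = "A", year = c(1995L, 2022L), agesex = "f",
                     count = 1)
  ch <- series_change(poststratify(dr2, build_weights(pop2, "country")),
                      1995, 2022)
  expect_equal(ch$mean, 6)
  dr3 <- toy_draws(matrix(5, 20, 2), "A", c(1995L, 2022L), "f")
  ch3 <- series_change(poststratify(dr3, build_weights(pop2, "country")),
                       1995, 2022)
  expect_equal(ch3$mean, 0)
})

test_that("poststratified means are convex and aggregation is associative", {
  sim <- small_sim()
  draws <- small_draws()
  pop <- sim$population
  cs <- poststratify(draws, build_weights(pop, "country"))
  ## convexity: every unit-year mean lies within its cells' range, per draw
  idx <- draws$cells
  for (j in sample(ncol(cs$draws), 5)) {
    u <- cs$index$unit[j]; y <- cs$index$year[j]
    cols <- which(idx$country == u & idx$year == y)
    rng <- t(apply(draws$draws[, cols], 1, range))
    expect_true(all(cs$draws[, j] >= rng[, 1] - 1e-9 &
                      cs$draws[, j] <= rng[, 2] + 1e-9))
  }
  ## associativity: cells -> global directly vs country series -> global
  gs <- poststratify(draws, build_weights(pop, "global"))
  ptot <- aggregate(count ~ country + year, pop, sum)
  years <- sort(unique(cs$index$year))
  for (y in years[c(1, length(years))]) {
    cols <- which(cs$index$year == y)
    pc <- ptot$count[match(paste(cs$index$unit[cols], y),
                           paste(ptot$country, ptot$year))]
    via_country <- cs$draws[, cols] %*% (pc / sum(pc))
    direct <- gs$draws[, gs$index$year == y]
    expect_lt(max(abs(via_country - direct)), 1e-9)
  }
})

test_that("equal and population weighting agree only under homogeneity", {
  ## explicit toy: two countries at 40 and 60 with populations 1 and 3
  dr <- toy_draws(rbind(c(40, 60), c(40, 60)), c("A", "B"), 2000L, c("f", "f"))
  pop <- data.frame(country = c("A", "B"), year = 2000L, agesex = "f",
                    count = c(1, 3))
  cs <- poststratify(dr, build_weights(pop, "country"))
  ew <- equal_vs_weighted(cs, pop)
  expect_equal(unname(ew$equal$draws[1, 1]), 50)
  expect_equal(unname(ew$weighted$draws[1, 1]), 55)
  ## identical countries: the two series coincide
  dr2 <- toy_draws(rbind(c(42, 42)), c("A", "B"), 2000L, c("f", "f"))
  cs2 <- poststratify(dr2, build_weights(pop, "country"))
  ew2 <- equal_vs_weighted(cs2, pop)
  expect_equal(ew2$equal$draws, ew2$weighted$draws)
})

test_that("recovery of the global composition-weighted series is accurate", {
  ## default scenario size: this is where the < 1 point bound applies
  sim <- cached("default_sim", simulate_scenario(scenario_config(seed = 208)))
  draws <- cached("default_draws", {
    zl <- sim$truth$countries[, c("country", "zone", "hdi_class")]
    fit <- suppressWarnings(grb_trend(sim$survey, zl, optimizer = "efs"))
    draw_posterior(fit, 300, seed = 2)
  })
  pop <- sim$population
  gs <- poststratify(draws, build_weights(pop, "global"))
  ## truth: population-weighted mean of true cell means
  tm <- sim$truth$cell_mean
  w <- build_weights(pop, "global")
  w <- w[w$country %in% rownames(tm), ]
  tv <- tm[cbind(match(w$country, rownames(tm)), match(w$year, colnames(tm)),
                 match(w$agesex, dimnames(tm)[[3]]))]
  truth_series <- tapply(tv * w$weight / tapply(w$weight, w$year, sum)[
    as.character(w$year)], w$year, sum)
  est <- colMeans(gs$draws)[match(names(truth_series),
                                  as.character(gs$index$year))]
  expect_lt(max(abs(est - truth_series)), 1)
})
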