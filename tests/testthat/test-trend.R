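test_that("the design applies the inclusion rule and aggregates cells faithfully", {
  sim <- small_sim()
  sv <- sim$survey
  zl <- small_zones()
  ## a country observed in a single wave is excluded with a warning
  extra <- sv[sv$country == sv$country[1], ][1:50, ]
  extra$country <- "ZZ"
  extra$year <- 2015L
  zl2 <- rbind(zl, data.frame(country = "ZZ", zone = zl$zone[1],
                              hdi_class = "low"))
  expect_warning(d <- build_trend_design(rbind(sv, extra), zl2), "ZZ")
  expect_true("ZZ" %in% d$dropped)
  ## a short-span country (waves 2008 and 2009 only) fails the 25% rule
  extra$year <- rep(c(2008L, 2009L), length.out = nrow(extra))
  expect_warning(d2 <- build_trend_design(rbind(sv, extra), zl2), "ZZ")
  expect_true("ZZ" %in% d2$dropped)
  ## aggregation reproduces cell means and sizes
  d3 <- build_trend_design(sv, zl)
  i <- 5L
  sel <- sv$country == as.character(d3$cells$country[i]) &
    sv$year == d3$cells$year[i] & sv$agesex == as.character(d3$cells$agesex[i])
  expect_equal(d3$cells$m[i], mean(sv$grb[sel]))
  expect_equal(d3$cells$n[i], sum(sel))
})

test_that("the year basis matches an independent de Boor recursion", {
  ## evaluate the cubic B-spline basis used for the year smooth, without
  ## identifiability constraints, and compare at probe points
  years <- 1995:2022
  sm <- mgcv::smoothCon(mgcv::s(year, bs = "bs", k = 8, m = c(3, 2)),
                        data = data.frame(year = years),
                        absorb.cons = FALSE)[[1]]
  knots <- sm$knots
  deboor <- function(x, knots, degree) {
    ## Cox-de Boor recursion, order 0 base case upward
    nb <- length(knots) - degree - 1L
    B <- outer(x, seq_len(length(knots) - 1L), function(xx, j)
      as.numeric(knots[j] <= xx & xx < knots[j + 1L]))
    ## make the basis right-continuous at the last knot
    B[x == max(knots), max(which(knots < max(knots)))] <- 1
    for (d in seq_len(degree)) {
      Bn <- matrix(0, length(x), ncol(B) - 1L)
      for (j in seq_len(ncol(Bn))) {
        den1 <- knots[j + d] - knots[j]
        den2 <- knots[j + d + 1L] - knots[j + 1L]
        t1 <- if (den1 > 0) (x - knots[j]) / den1 * B[, j] else 0
        t2 <- if (den2 > 0) (knots[j + d + 1L] - x) / den2 * B[, j + 1L] else 0
        Bn[, j] <- t1 + t2
      }
      B <- Bn
    }
    B[, seq_len(nb), drop = FALSE]
  }
  probes <- c(1995, 1999.5, 2008, 2017.2, 2022)
  Xo <- deboor(probes, knots, 3L)
  Xm <- mgcv::PredictMat(sm, data.frame(year = probes))
  expect_equal(unname(Xm), unname(Xo), tolerance = 1e-8)
})

test_that("the zero-penalty single-country fit equals unpenalized least squares", {
  cfg <- scenario_config(n_countries = 1, waves_range = c(5L, 5L),
                         n_per_wave = 400, seed = 13)
  sim <- simulate_scenario(cfg)
  zl <- sim$truth$countries[, c("country", "zone", "hdi_class")]
  fit <- grb_trend(sim$survey, zl, k_zone = 5, sp = 0)
  X <- predict(fit$gam, type = "lpmatrix")
  w <- fit$design$cells$n
  ols <- lm.fit(X * sqrt(w), fit$design$cells$m * sqrt(w))
  ols_fit <- ols$fitted.values / sqrt(w)
  expect_lt(max(abs(fitted(fit$gam) - ols_fit)) /
              max(abs(fitted(fit$gam))), 1e-6)
})

test_that("flat-trend data is recovered within 1.5 points", {
  ## scores fed directly to the trend module: flat country levels plus
  ## person-level noise, 4 waves x 500 = 2000 respondents per country
  set.seed(31)
  countries <- sprintf("C%02d", 1:12)
  zl <- data.frame(country = countries, zone = rep(c("a", "b"), 6))
  lev <- ifelse(zl$zone == "a", 50, 58) + rnorm(12, 0, 4)
  rows <- do.call(rbind, lapply(1:12, function(i) {
    wy <- sort(sample(1995:2022, 4))
    while (diff(range(wy)) < 17) wy <- sort(sample(1995:2022, 4))
    do.call(rbind, lapply(wy, function(y) data.frame(
      country = countries[i], year = y,
      agesex = sample(agesex_levels(), 500, TRUE),
      grb = lev[i] + rnorm(500, 0, 16))))
  }))
  fit <- suppressWarnings(grb_trend(rows, zl, optimizer = "efs"))
  grid <- expand.grid(country = factor(fit$countries, levels = fit$countries),
                      year = fit$years,
                      agesex = factor(fit$agesex, levels = fit$agesex))
  pred <- predict(fit, newdata = grid)
  tr <- lev[match(as.character(grid$country), countries)]
  key <- paste(grid$country, grid$year)
  expect_lt(max(abs(tapply(pred, key, mean) - tapply(tr, key, mean))), 1.5)
})

test_that("the infinite-penalty limit collapses country curves onto the zone trend", {
  fit <- small_trend_fit()
  spn <- fit$gam$sp
  sp2 <- spn
  sp2[grepl("country", names(spn))] <- 1e10
  refit <- suppressWarnings(grb_trend(small_sim()$survey, small_zones(),
                                      sp = unname(sp2)))
  ## two countries in the same zone must now share one curve up to age-sex
  zl <- small_zones()
  zz <- zl$zone[1]
  pair <- zl$country[zl$zone == zz][1:2]
  grid <- expand.grid(country = factor(pair, levels = refit$countries),
                      year = refit$years,
                      agesex = factor(refit$agesex[1], levels = refit$agesex))
  pr <- predict(refit, newdata = grid)
  d <- pr[grid$country == pair[1]] - pr[grid$country == pair[2]]
  expect_lt(max(abs(d - mean(d))), 0.05)   # same shape; level soaks into re
})

test_that("posterior draws behave like the normal approximation they come from", {
  fit <- small_trend_fit()
  draws <- small_draws()
  grid <- expand.grid(country = factor(fit$countries, levels = fit$countries),
                      year = fit$years,
                      agesex = factor(fit$agesex, levels = fit$agesex))
  pred <- predict(fit, newdata = grid)
  ## draw means concentrate on the point fit
  expect_lt(mean(abs(colMeans(draws$draws) - pred)), 0.15)
  ## zero covariance: all draws equal the point fit
  degen <- fit
  degen$gam$Vp[] <- 0
  d0 <- draw_posterior(degen, n_draws = 5, seed = 1)
  expect_equal(max(abs(sweep(d0$draws, 2, pred))), 0, tolerance = 1e-10)
  ## information borrowing: unsurveyed years are not less uncertain
  sv <- small_sim()$survey
  sds <- apply(draws$draws, 2, sd)
  per <- tapply(sds, paste(draws$cells$country, draws$cells$year), mean)
  surveyed <- unique(paste(sv$country, sv$year))
  s_in <- per[names(per) %in% surveyed]
  s_out <- per[!names(per) %in% surveyed]
  expect_lt(mean(s_in), mean(s_out))
})

test_that("predictions are equivariant under country relabeling and response shifts", {
  sim <- small_sim()
  zl <- small_zones()
  fit <- small_trend_fit()
  grid <- expand.grid(country = factor(fit$countries, levels = fit$countries),
                      year = c(2000L, 2010L),
                      agesex = factor(fit$agesex, levels = fit$agesex))
  pred <- predict(fit, newdata = grid)
  ## relabel countries (reverse names) and refit
  map <- setNames(rev(sort(unique(sv <- sim$survey$country))),
                  sort(unique(sim$survey$country)))
  sv2 <- sim$survey
  sv2$country <- unname(map[sv2$country])
  zl2 <- zl
  zl2$country <- unname(map[zl2$country])
  fit2 <- suppressWarnings(grb_trend(sv2, zl2, optimizer = "efs"))
  grid2 <- grid
  grid2$country <- factor(unname(map[as.character(grid$country)]),
                          levels = fit2$countries)
  pred2 <- predict(fit2, newdata = grid2)
  expect_equal(unname(pred2), unname(pred), tolerance = 1e-5)
  ## adding a constant to all responses shifts all predictions by it
  sv3 <- sim$survey
  sv3$grb <- sv3$grb + 7
  fit3 <- suppressWarnings(grb_trend(sv3, zl, optimizer = "efs"))
  pred3 <- predict(fit3, newdata = grid)
  expect_equal(unname(pred3), unname(pred) + 7, tolerance = 1e-5)
})
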