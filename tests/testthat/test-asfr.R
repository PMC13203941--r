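test_that("the fertility curve peaks at mu with height c and switches steepness", {
  p <- c(0.2, 28, 5, 9)
  expect_equal(asfr_curve(28, p), 0.2)
  expect_equal(asfr_curve(23, p), 0.2 * exp(-1))
  ## symmetric when s1 = s2
  ps <- c(0.15, 30, 6, 6)
  expect_equal(asfr_curve(27, ps), asfr_curve(33, ps))
  ## asymmetric otherwise: slower decay after the peak when s2 > s1
  expect_gt(asfr_curve(33, p), asfr_curve(23, p))
  ## unimodal, nonnegative
  a <- seq(15, 49, by = 0.5)
  v <- asfr_curve(a, p)
  expect_true(all(v >= 0))
  expect_equal(a[which.max(v)], 28)
  expect_error(asfr_curve(30, c(0.2, 28, -1, 9)))
})

test_that("cumulative fertility is a nondecreasing sum over the support", {
  p <- c(0.17, 27.5, 4.2, 8.3)
  ## term-by-term oracle at probe ages
  for (age in c(20, 30, 45)) {
    oracle <- 0
    for (x in 15:age) oracle <- oracle + asfr_curve(x, p)
    expect_equal(cumulative_fertility(age, p), oracle, tolerance = 1e-12)
  }
  expect_equal(cumulative_fertility(15, p), asfr_curve(15, p))  # single term
  expect_equal(cumulative_fertility(14, p), 0)                  # below support
  expect_equal(cumulative_fertility(30, c(0, 28, 5, 9)), 0)     # zero height
  ages <- 15:49
  expect_true(all(diff(cumulative_fertility(ages, p)) >= 0))
})

test_that("the Poisson likelihood matches the closed-form log-pmf", {
  set.seed(5)
  for (k in 1:20) {
    p <- c(runif(1, 0.05, 0.3), runif(1, 22, 34), runif(1, 2, 8),
           runif(1, 4, 12))
    age <- sample(18:49, 7)
    kids <- rpois(7, 2)
    lam <- cumulative_fertility(age, p)
    oracle <- sum(dpois(kids, lam, log = TRUE))
    expect_equal(asfr_loglik(p, age, kids), oracle, tolerance = 1e-10)
  }
})

test_that("derived metrics match fine-grid and dominance oracles", {
  ## age at half: linear interpolation vs a fine-grid inversion oracle
  p <- c(0.16, 28, 4.5, 9)
  cum <- cumsum(asfr_curve(15:49, p))
  fine <- seq(15, 49, by = 1e-4)
  cum_fine <- approx(15:49, cum, xout = fine)$y
  oracle <- fine[which(cum_fine >= 0.5)[1]]
  got <- grbtrends:::age_at_half(p, 15:49)
  expect_lt(abs(got - oracle), 0.01)
  ## monotonicity: raising c raises TFR and weakly lowers the half age
  p_hi <- p; p_hi[1] <- p[1] * 1.3
  expect_gt(grbtrends:::tfr_of(p_hi, 15:49), grbtrends:::tfr_of(p, 15:49))
  expect_lte(grbtrends:::age_at_half(p_hi, 15:49),
             grbtrends:::age_at_half(p, 15:49))
  ## a fit whose low-group curve strictly dominates gives proportion one
  D <- 20
  pars <- list(low = c(0.20, 27, 4.5, 9), high = c(0.12, 29, 4.5, 9))
  cols <- list()
  for (i in 1:2) for (g in 1:2) {
    pg <- pars[[g]]
    cols[[sprintf("cc[%d,%d]", i, g)]] <- rep(pg[1], D)
    cols[[sprintf("mu[%d,%d]", i, g)]] <- rep(pg[2], D)
    cols[[sprintf("s1[%d,%d]", i, g)]] <- rep(pg[3], D)
    cols[[sprintf("s2[%d,%d]", i, g)]] <- rep(pg[4], D)
  }
  for (g in 1:2) {
    pg <- pars[[g]]
    cols[[sprintf("h_lc[%d]", g)]] <- rep(log(pg[1]), D)
    cols[[sprintf("h_mu[%d]", g)]] <- rep(pg[2], D)
    cols[[sprintf("h_ls1[%d]", g)]] <- rep(log(pg[3]), D)
    cols[[sprintf("h_ls2[%d]", g)]] <- rep(log(pg[4]), D)
  }
  draws <- do.call(cbind, cols)
  fake <- structure(list(draws = draws, countries = c("C1", "C2"),
                         groups = c("low", "high"), hierarchical = TRUE,
                         support = 15:49,
                         diagnostics = list(rhat = 1, neff = D),
                         n_obs = 0), class = "asfr_fit")
  m <- derive_metrics(fake)
  expect_true(all(m$prop_low_higher_tfr == 1))
  expect_true(all(m$prop_low_earlier == 1))
  expect_true(all(m$tfr_diff > 0))
  ## identical groups: zero contrast
  draws2 <- draws
  for (nm in colnames(draws2))
    draws2[, nm] <- draws[, sub("2\\]", "1]", sub(",2\\]", ",1]", nm))]
  fake2 <- fake; fake2$draws <- draws2
  m2 <- derive_metrics(fake2)
  expect_equal(unname(m2$summary["tfr_diff", "mean"]), 0)
  expect_equal(unname(m2$summary["aah_gap", "mean"]), 0)
})

test_that("a single-country fit recovers its generating schedule", {
  truth <- list(low = c(0.18, 27, 4, 8), high = c(0.14, 29, 4.5, 9))
  dat <- make_asfr_women(truth, 4000, seed = 3)
  f <- suppressWarnings(fit_asfr(dat, n_chains = 2, n_adapt = 800,
                                 n_burn = 200, n_iter = 1200, thin = 2,
                                 seed = 1))
  expect_false(f$hierarchical)
  pm <- coef(f)
  tv <- c(truth$low[1], truth$high[1], truth$low[2], truth$high[2],
          truth$low[3], truth$high[3], truth$low[4], truth$high[4])
  ## loose per-dataset bound; the tight bias check lives in the
  ## acceptance suite over replicates
  expect_true(all(abs(pm[1:8] / tv - 1) < 0.3))
  expect_lt(max(f$diagnostics$rhat, na.rm = TRUE), 1.2)
})

test_that("the hierarchy shrinks data-poor countries toward the average", {
  ## all countries share identical schedules: hierarchy SDs concentrate
  ## near zero and country draws collapse toward the hierarchical means
  truth <- fert_truth()
  dat <- make_asfr_women(truth, 150, countries = sprintf("C%d", 1:6),
                         seed = 9)
  f <- suppressWarnings(fit_asfr(dat, n_chains = 2, n_adapt = 800,
                                 n_burn = 200, n_iter = 1000, thin = 2,
                                 seed = 2, rhat_fail = Inf))
  expect_lt(mean(f$draws[, "sd_mu"]), 1.5)
  expect_lt(mean(f$draws[, "sd_lc"]), 0.25)
  arr <- grbtrends:::asfr_par_array(f)
  hyp <- grbtrends:::asfr_hyper_array(f)
  ## country-level posterior means stay close to the average country
  dev <- abs(colMeans(arr[, , 1, "mu"]) - mean(hyp[, 1, "mu"]))
  expect_lt(max(dev), 1.5)
})
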