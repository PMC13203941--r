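# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

## small default-style scenario used across modules
small_config <- function(seed = 101, ...) {
  scenario_config(n_countries = 9, n_per_wave = 300, seed = seed, ...)
}

small_sim <- function() cached("small_sim", simulate_scenario(small_config()))

small_zones <- function() {
  sim <- small_sim()
  sim$truth$countries[, c("country", "zone", "hdi_class")]
}

small_trend_fit <- function() cached("small_trend_fit", {
  sim <- small_sim()
  suppressWarnings(grb_trend(sim$survey, small_zones(), optimizer = "efs"))
})

small_draws <- function() cached("small_draws",
  draw_posterior(small_trend_fit(), n_draws = 300, seed = 1))

## truth cell means aligned with a prediction grid
truth_cells <- function(sim, grid) {
  tm <- sim$truth$cell_mean
  tm[cbind(match(as.character(grid$country), rownames(tm)),
           match(grid$year, colnames(tm)),
           match(as.character(grid$agesex), dimnames(tm)[[3]]))]
}

## build a minimal cell-draws object by hand (for poststrat arithmetic tests)
toy_draws <- function(draws, country, year, agesex) {
  structure(list(draws = draws,
                 cells = data.frame(country = country, year = year,
                                    agesex = agesex,
                                    stringsAsFactors = FALSE),
                 level = "cell"),
            class = "grb_draws")
}

## calibrated subgroup fertility schedules (generator defaults)
fert_truth <- function() {
  list(low = c(0.154167, 27.821639, 4.5, 9.0),
       high = c(0.140, 29.0, 4.5, 9.0))
}

## synthetic women table for direct ASFR fitting
make_asfr_women <- function(pars_by_group, n_per_group, countries = "C1",
                            seed = 1, ages = 18:49,
                            sd_log = c(0, 0, 0, 0), sd_mu = 0) {
  set.seed(seed)
  do.call(rbind, lapply(countries, function(cc) {
    do.call(rbind, lapply(names(pars_by_group), function(g) {
      p <- pars_by_group[[g]]
      p <- c(p[1] * exp(rnorm(1, 0, sd_log[1])),
             p[2] + rnorm(1, 0, sd_mu),
             p[3] * exp(rnorm(1, 0, sd_log[3])),
             p[4] * exp(rnorm(1, 0, sd_log[4])))
      age <- sample(ages, n_per_group, replace = TRUE)
      lam <- cumulative_fertility(age, p, support = 15:49)
      data.frame(country = cc, grb_group = g, age = age,
                 n_children = rpois(n_per_group, lam),
                 stringsAsFactors = FALSE)
    }))
  }))
}
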