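#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir output directory (created if needed).
#' @param scenario a [scenario_config()] for the simulate stage.
#' @param stages character vector of stages to run, in dependency order
#'   among `simulate, score, trends, poststrat, composition, lmm, asfr,
#'   report`.
#' @param n_draws posterior draws from the trend model.
#' @param k_zone,k_country trend-model basis dimensions.
#' @param min_waves,min_span_frac trend-model inclusion rule.
#' @param lmm_min_year survey-recency cutoff for the fertility LMM.
#' @param split GRB subgroup split rule (`"median"` or a value).
#' @param asfr_settings list of sampler settings for [fit_asfr()].
#' @param growth_settings list of sampler settings for
#'   [growth_regression()].
#' @param write_draws write the full draws tensor as long CSV (large; off by
#'   default, summaries are always written).
#' @param seed master seed; stage seeds derive from it.
#' @return object of class `grb_run_config`.
#' @export
run_config <- function(out_dir = tempfile("grbrun"),
                       scenario = scenario_config(),
                       stages = c("simulate", "score", "trends", "poststrat",
                                  "composition", "lmm", "asfr", "report"),
                       n_draws = 2000, k_zone = 8, k_country = 5,
                       min_waves = 2L, min_span_frac = 0.25,
                       lmm_min_year = 2010, split = "median",
                       asfr_settings = list(n_chains = 3, n_adapt = 1000,
                                            n_burn = 1000, n_iter = 3000,
                                            thin = 3),
                       growth_settings = list(n_chains = 3, n_adapt = 1000,
                                              n_burn = 1000, n_iter = 3000,
                                              thin = 3),
                       write_draws = FALSE, seed = 1L) {
  structure(list(out_dir = out_dir, scenario = scenario, stages = stages,
                 n_draws = n_draws, k_zone = k_zone, k_country = k_country,
                 min_waves = min_waves, min_span_frac = min_span_frac,
                 lmm_min_year = lmm_min_year, split = split,
                 asfr_settings = asfr_settings,
                 growth_settings = growth_settings,
                 write_draws = write_draws, seed = as.integer(seed)),
            class = "grb_run_config")
}

## table schemas for validate_table(); each check returns row indices in error
schema_registry <- function() {
  list(
    survey = list(
      required = c("country", "year", "age", "sex", "item1", "item2", "item3"),
      checks = list(
        age_range = function(d) which(!is.na(d$age) & (d$age < 18 | d$age > 120)),
        sex_levels = function(d) which(!d$sex %in% c("female", "male")),
        grb_range = function(d) if (!"grb" %in% names(d)) integer(0) else
          which(!is.na(d$grb) & (d$grb < 0 | d$grb > 100)),
        children_nonneg = function(d) if (!"n_children" %in% names(d)) integer(0) else
          which(!is.na(d$n_children) & d$n_children < 0))),
    population = list(
      required = c("country", "year", "agesex", "count"),
      checks = list(
        count_pos = function(d) which(is.na(d$count) | d$count <= 0),
        key_unique = function(d) {
          k <- paste(d$country, d$year, d$agesex); which(duplicated(k))
        })),
    draws = list(
      required = c("draw", "country", "year", "agesex", "value"),
      checks = list(
        finite = function(d) which(!is.finite(d$value)),
        key_unique = function(d) {
          k <- paste(d$draw, d$country, d$year, d$agesex); which(duplicated(k))
        })),
    series_summary = list(
      required = c("unit", "year", "mean", "lo90", "hi90"),
      checks = list(
        interval_order = function(d) which(d$lo90 > d$hi90 + 1e-12),
        mean_in_interval = function(d)
          which(d$mean < d$lo90 - 1e-9 | d$mean > d$hi90 + 1e-9))),
    lmm_table = list(
      required = c("term", "effect_level", "estimate", "se", "p", "model"),
      checks = list(
        se_pos = function(d) which(!is.na(d$se) & d$se <= 0),
        p_range = function(d) which(!is.na(d$p) & (d$p < 0 | d$p > 1)))),
    asfr_draws = list(
      required = c("draw", "country", "group", "c", "mu", "s1", "s2"),
      checks = list(
        pos_pars = function(d) which(d$c < 0 | d$s1 <= 0 | d$s2 <= 0),
        group_levels = function(d) which(!d$group %in% c("low", "high")))))
}

#' Validate a pipeline table against a registered schema
#'
#' Checks required columns, value ranges (GRB in 0-100, ages 18-120,
#' positive counts) and key uniqueness, reporting offending rows.
#'
#' @param x data frame or path to a CSV file.
#' @param schema one of `survey`, `population`, `draws`, `series_summary`,
#'   `lmm_table`, `asfr_draws`.
#' @return object of class `validation_result`: list with `ok` and
#'   `messages` (row-level).
#' @export
validate_table <- function(x, schema) {
  reg <- schema_registry()
  if (!schema %in% names(reg)) stop("unknown schema: ", schema)
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  sc <- reg[[schema]]
  msgs <- character(0)
  miss <- setdiff(sc$required, names(x))
  if (length(miss)) {
    msgs <- sprintf("missing column(s): %s", paste(miss, collapse = ", "))
  } else {
    for (nm in names(sc$checks)) {
      bad <- sc$checks[[nm]](x)
      if (length(bad))
        msgs <- c(msgs, sprintf("rule '%s' violated at row(s) %s%s", nm,
                                paste(head(bad, 5L), collapse = ", "),
                                if (length(bad) > 5L)
                                  sprintf(" (+%d more)", length(bad) - 5L)
                                else ""))
    }
  }
  structure(list(ok = length(msgs) == 0L, schema = schema, messages = msgs),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("Schema '%s': %s\n", x$schema, if (x$ok) "PASS" else "FAIL"))
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in dependency order - synthetic-data
#' generation, composite scoring, trend model, poststratification,
#' compositional counterfactuals and growth regression, fertility mixed
#' model, ASFR model, report - writing each stage's outputs as plain CSV
#' under `config$out_dir` together with a JSON manifest (seeds, package
#' version, input checksums). Rerunning with the same config reproduces
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all in-memory stage results plus the
#'   output directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "grb_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  res <- list(out_dir = config$out_dir)
  wpath <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% st) {
    sim <- simulate_scenario(config$scenario)
    res$sim <- sim
    write.csv(sim$survey[, setdiff(names(sim$survey), "latent")],
              wpath("survey.csv"), row.names = FALSE)
    write.csv(sim$population, wpath("population.csv"), row.names = FALSE)
    write.csv(sim$truth$countries[, c("country", "zone", "hdi_class")],
              wpath("zones.csv"), row.names = FALSE)
    v1 <- validate_table(sim$survey, "survey")
    v2 <- validate_table(sim$population, "population")
    if (!v1$ok || !v2$ok) stop("simulate stage failed validation")
  }
  survey <- res$sim$survey
  pop <- res$sim$population
  zones <- res$sim$truth$countries[, c("country", "zone", "hdi_class")]

  if ("score" %in% st) {
    if (!"grb" %in% names(survey))
      survey <- score_survey(survey, config$scenario$item_levels)
    rel <- cronbach_alpha(vapply(1:3, function(k)
      rescale_item(survey[[paste0("item", k)]], 1,
                   config$scenario$item_levels[k]),
      numeric(nrow(survey))))
    res$reliability <- rel
    writeLines(sprintf("cronbach_alpha,%0.6f\nn_respondents,%d",
                       rel$alpha, rel$n_respondents),
               wpath("reliability.csv"))
  }

  if ("trends" %in% st) {
    fit <- grb_trend(survey, zones, k_zone = config$k_zone,
                     k_country = config$k_country,
                     min_waves = config$min_waves,
                     min_span_frac = config$min_span_frac)
    draws <- draw_posterior(fit, config$n_draws,
                            seed = child_seed(config$seed, 10L))
    res$trend <- fit; res$draws <- draws
    if (config$write_draws) {
      long <- data.frame(draw = rep(seq_len(nrow(draws$draws)),
                                    times = ncol(draws$draws)),
                         draws$cells[rep(seq_len(ncol(draws$draws)),
                                         each = nrow(draws$draws)), ],
                         value = as.vector(draws$draws))
      write.csv(long, wpath("trend_draws.csv"), row.names = FALSE)
    }
  }

  if ("poststrat" %in% st) {
    cw <- build_weights(pop, "country")
    cs <- poststratify(res$draws, cw)
    res$country_series <- cs
    summ <- summarize_series(cs)
    write.csv(summ, wpath("series_country.csv"), row.names = FALSE)
    for (lv in c("zone", "hdi", "global")) {
      w <- build_weights(pop, lv, zones)
      s <- poststratify(res$draws, w)
      res[[paste0(lv, "_series")]] <- s
      write.csv(summarize_series(s), wpath(sprintf("series_%s.csv", lv)),
                row.names = FALSE)
    }
    ew <- equal_vs_weighted(cs, pop)
    res$global_equal <- ew$equal
    write.csv(summarize_series(ew$equal), wpath("series_global_equal.csv"),
              row.names = FALSE)
  }

  if ("composition" %in% st) {
    cf <- counterfactual_series(res$country_series, pop)
    res$counterfactual <- cf
    write.csv(rbind(cbind(series = "observed", summarize_series(cf$observed)),
                    cbind(series = "counterfactual",
                          summarize_series(cf$counterfactual))),
              wpath("counterfactual.csv"), row.names = FALSE)
    y0 <- min(cf$observed$index$year); y1 <- max(cf$observed$index$year)
    res$spearman <- list(
      first = size_grb_correlation(res$country_series, pop, y0),
      last = size_grb_correlation(res$country_series, pop, y1))
    ## growth regression: anchor-year national mean and SD from the draws
    idx <- res$country_series$index
    countries <- sort(unique(idx$unit))
    c0 <- match(paste(countries, y0), paste(idx$unit, idx$year))
    gm <- colMeans(res$country_series$draws[, c0, drop = FALSE])
    gs <- apply(res$country_series$draws[, c0, drop = FALSE], 2L, sd)
    ptot <- aggregate(count ~ country + year, pop, sum)
    p0 <- ptot$count[match(paste(countries, y0), paste(ptot$country, ptot$year))]
    p1 <- ptot$count[match(paste(countries, y1), paste(ptot$country, ptot$year))]
    res$growth <- do.call(growth_regression,
                          c(list(grb_mean = gm, grb_se = gs,
                                 pop_start = p0, pop_end = p1,
                                 seed = child_seed(config$seed, 11L)),
                            config$growth_settings))
    excess <- cf$summary
    write.csv(data.frame(
      quantity = c("relative_trend_excess_pct", "spearman_first_year",
                   "spearman_last_year", "growth_beta_per_sd"),
      estimate = c(excess["median"], res$spearman$first$mean,
                   res$spearman$last$mean, mean(res$growth$beta_per_sd)),
      lo90 = c(excess["lo"], res$spearman$first$lo90,
               res$spearman$last$lo90, eti(res$growth$beta_per_sd)["lo"]),
      hi90 = c(excess["hi"], res$spearman$first$hi90,
               res$spearman$last$hi90, eti(res$growth$beta_per_sd)["hi"])),
      wpath("composition_summary.csv"), row.names = FALSE)
  }

  if ("lmm" %in% st) {
    samp <- build_lmm_sample(survey, min_year = config$lmm_min_year)
    samp$religiosity <- religiosity_index(samp[, paste0("rel", 1:4)])
    res$lmm <- lapply(1:3, function(m) fit_hybrid_lmm(samp, model = m))
    tabs <- lapply(1:3, function(m) {
      f <- res$lmm[[m]]
      cbind(f$table, model = m,
            n_obs = f$n_obs, n_countries = f$n_countries,
            cond_r2 = f$cond_r2)
    })
    write.csv(do.call(rbind, tabs), wpath("lmm_table.csv"), row.names = FALSE)
  }

  if ("asfr" %in% st) {
    women <- survey[survey$sex == "female" & survey$age >= 18 &
                      survey$age <= 49 & !is.na(survey$n_children), ]
    res$asfr <- do.call(fit_asfr,
                        c(list(data = women, split = config$split,
                               seed = child_seed(config$seed, 12L)),
                          config$asfr_settings))
    res$metrics <- derive_metrics(res$asfr)
    write.csv(data.frame(res$metrics$summary,
                         quantity = rownames(res$metrics$summary)),
              wpath("asfr_metrics.csv"), row.names = FALSE)
  }

  if ("report" %in% st) make_report(config$out_dir, res)

  manifest <- list(
    package_version = as.character(utils::packageVersion("grbtrends")),
    seed = config$seed, stages = st,
    timestamp = format(Sys.time(), tz = "UTC"),
    checksums = as.list(tools::md5sum(
      list.files(config$out_dir, pattern = "\\.csv$", full.names = TRUE))))
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(res)
}

#' Write the headline-results report of a pipeline run
#'
#' Juxtaposes all headline quantities: observed versus counterfactual global
#' endpoints, relative trend excess, size-GRB correlations, the fertility
#' LMM table and the ASFR contrasts with their intervals. Regeneration from
#' the same run directory is idempotent.
#'
#' @param run_dir directory of a completed [run_pipeline()] run.
#' @param res optional in-memory results (avoids re-reading CSVs).
#' @return invisibly, the report lines; also written to `report.txt`.
#' @export
make_report <- function(run_dir, res = NULL) {
  rd <- function(f) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) read.csv(p, stringsAsFactors = FALSE) else NULL
  }
  lines <- c("Gender-role-belief trends: pipeline report",
             strrep("=", 44))
  gl <- rd("series_global.csv")
  if (!is.null(gl)) {
    y0 <- min(gl$year); y1 <- max(gl$year)
    g0 <- gl[gl$year == y0, ]; g1 <- gl[gl$year == y1, ]
    lines <- c(lines, sprintf(
      "Global population-weighted mean GRB: %.1f [%.1f, %.1f] (%d) -> %.1f [%.1f, %.1f] (%d)",
      g0$mean, g0$lo90, g0$hi90, y0, g1$mean, g1$lo90, g1$hi90, y1))
  }
  cfs <- rd("counterfactual.csv")
  if (!is.null(cfs)) {
    y1 <- max(cfs$year)
    cf1 <- cfs[cfs$series == "counterfactual" & cfs$year == y1, ]
    lines <- c(lines, sprintf(
      "Counterfactual %d mean (fixed national composition): %.1f [%.1f, %.1f]",
      y1, cf1$mean, cf1$lo90, cf1$hi90))
  }
  cs <- rd("composition_summary.csv")
  if (!is.null(cs)) {
    for (i in seq_len(nrow(cs)))
      lines <- c(lines, sprintf("%s: %.3f [%.3f, %.3f]", cs$quantity[i],
                                cs$estimate[i], cs$lo90[i], cs$hi90[i]))
  }
  lt <- rd("lmm_table.csv")
  if (!is.null(lt)) {
    lines <- c(lines, "Fertility LMM (children of women 40-49):")
    g <- lt[lt$term == "grb", ]
    for (i in seq_len(nrow(g)))
      lines <- c(lines, sprintf(
        "  model %d GRB %s: %.3f (SE %.3f, p %.3g)", g$model[i],
        g$effect_level[i], g$estimate[i], g$se[i], g$p[i]))
  }
  am <- rd("asfr_metrics.csv")
  if (!is.null(am)) {
    lines <- c(lines, "ASFR contrasts (low vs high GRB subpopulation):")
    for (i in seq_len(nrow(am)))
      lines <- c(lines, sprintf("  %s: %.3f [%.3f, %.3f]", am$quantity[i],
                                am$mean[i], am$lo[i], am$hi[i]))
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(lines)
}
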