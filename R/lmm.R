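#' Split a predictor into within- and between-country components
#'
#' Between component = country mean (constant within country); within
#' component = individual deviation from the country mean. The two components
#' reconstruct the input exactly.
#'
#' @param x numeric predictor (typically already standardized at the
#'   respondent level).
#' @param group grouping labels (country).
#' @return list with `within` and `between`, both of length `length(x)`.
#' @export
within_between_split <- function(x, group) {
  stopifnot(length(x) == length(group))
  gm <- tapply(x, group, mean)
  between <- as.numeric(gm[as.character(group)])
  list(within = x - between, between = between)
}

#' Select the analysis sample for the fertility mixed model
#'
#' Keeps women in the completed-fertility age range from each country's most
#' recent survey no older than the cutoff (countries whose latest survey
#' predates the cutoff are dropped), then applies listwise deletion on the
#' model variables.
#'
#' @param survey scored survey table.
#' @param min_year survey-recency cutoff (default 2010).
#' @param age_range inclusive age window (default 40-49).
#' @param vars variables required complete (default: the model-3 set).
#' @return filtered data frame; countries with fewer than 10 eligible women
#'   are retained but reported via a message (hierarchical shrinkage handles
#'   them).
#' @export
build_lmm_sample <- function(survey, min_year = 2010, age_range = c(40L, 49L),
                             vars = c("grb", "n_children", "age", "education",
                                      "income", "town_size")) {
  check_cols(survey, c("country", "year", "age", "sex"), "survey")
  latest <- tapply(survey$year, survey$country, max)
  keep_c <- names(latest)[latest >= min_year]
  out <- survey[survey$country %in% keep_c, ]
  out <- out[out$year == latest[out$country], ]
  out <- out[out$sex == "female" & out$age >= age_range[1] &
               out$age <= age_range[2], ]
  vars <- intersect(vars, names(out))
  out <- out[complete.cases(out[, vars, drop = FALSE]), ]
  few <- table(out$country)
  few <- names(few)[few < 10L]
  if (length(few))
    message("countries with < 10 eligible women (retained): ",
            paste(few, collapse = ", "))
  rownames(out) <- NULL
  out
}

## dummy-code a categorical, split every dummy within/between
dummy_wb <- function(f, group, prefix) {
  f <- factor(f)
  mm <- model.matrix(~ f)[, -1, drop = FALSE]
  colnames(mm) <- paste0(prefix, levels(f)[-1])
  out <- list()
  for (j in seq_len(ncol(mm))) {
    sp <- within_between_split(mm[, j], group)
    out[[paste0(colnames(mm)[j], "_w")]] <- sp$within
    out[[paste0(colnames(mm)[j], "_b")]] <- sp$between
  }
  out
}

#' Hybrid within-between mixed model for completed fertility
#'
#' Linear mixed model for women's reported number of children with the GRB
#' predictor split into a between-country component (the country mean) and a
#' within-country component (the individual deviation), random country
#' intercepts and random country slopes for within-GRB. Model 1 contains GRB
#' only; model 2 adds age (pooled, not split, since the sample is restricted
#' to one age band), education, income and town size (each split
#' within/between); model 3 adds religiosity (split). Continuous predictors
#' are standardized to respondent-level mean 0, SD 1 before centering.
#' Categorical reference levels: primary-or-less education, low income,
#' smallest town band. Estimated by REML via \pkg{lme4}; p-values use a
#' normal approximation on the t-ratios; the conditional R-squared uses the
#' variance-partition formulation for mixed models.
#'
#' @param data analysis sample from [build_lmm_sample()] (needs `country`,
#'   `grb`, `n_children`; model >= 2 needs `age`, `education`, `income`,
#'   `town_size`; model 3 needs `religiosity` or the four `rel1..rel4`
#'   items, which are then combined via [religiosity_index()]).
#' @param model 1, 2 or 3.
#' @param reml fit by REML (default) or ML (for deviance comparisons of
#'   nested models).
#' @return object of class `hybrid_lmm`: coefficient table (term, level,
#'   estimate, SE, p), variance components, sample sizes, conditional
#'   R-squared, and the underlying \pkg{lme4} fit.
#' @export
fit_hybrid_lmm <- function(data, model = 1L, reml = TRUE) {
  stopifnot(model %in% 1:3)
  check_cols(data, c("country", "grb", "n_children"), "data")
  d <- data.frame(country = factor(data$country),
                  children = as.numeric(data$n_children))
  zs <- function(x) (x - mean(x)) / sd(x)
  sp <- within_between_split(zs(data$grb), d$country)
  d$grb_w <- sp$within; d$grb_b <- sp$between
  rhs <- c("grb_w", "grb_b")
  if (model >= 2L) {
    check_cols(data, c("age", "education", "income", "town_size"), "data")
    d$age_p <- zs(as.numeric(data$age))     # pooled within-between effect
    rhs <- c(rhs, "age_p")
    for (nm in c("education", "income", "town_size")) {
      dm <- dummy_wb(data[[nm]], d$country, paste0(nm, "_"))
      for (k in names(dm)) d[[k]] <- dm[[k]]
      rhs <- c(rhs, names(dm))
    }
  }
  if (model == 3L) {
    rel <- if ("religiosity" %in% names(data)) data$religiosity else {
      check_cols(data, paste0("rel", 1:4), "data")
      religiosity_index(data[, paste0("rel", 1:4)])
    }
    keep <- !is.na(rel)
    if (!all(keep)) { d <- d[keep, , drop = FALSE]; rel <- rel[keep] }
    sp <- within_between_split(zs(rel), d$country)
    d$rel_w <- sp$within; d$rel_b <- sp$between
    rhs <- c(rhs, "rel_w", "rel_b")
  }
  f <- stats::as.formula(paste("children ~", paste(rhs, collapse = " + "),
                               "+ (1 + grb_w | country)"))
  fit <- lme4::lmer(f, data = d, REML = reml,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      calc.derivs = FALSE))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  tv <- est / se
  p <- 2 * pnorm(-abs(tv))
  term <- names(est)
  lvl <- ifelse(grepl("_w$", term), "within",
                ifelse(grepl("_b$", term), "between",
                       ifelse(term == "age_p", "pooled", "")))
  tab <- data.frame(term = sub("_[wb]$|_p$", "", term), effect_level = lvl,
                    estimate = unname(est), se = unname(se), p = unname(p),
                    stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_int <- vc$sdcor[vc$grp == "country" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)]
  sd_slope <- vc$sdcor[vc$grp == "country" & vc$var1 == "grb_w" &
                         is.na(vc$var2)]
  sd_res <- vc$sdcor[vc$grp == "Residual"]
  ## conditional R^2, variance-partition form: fixed + random over total
  X <- lme4::getME(fit, "X")
  var_f <- var(as.numeric(X %*% est))
  Z <- lme4::getME(fit, "Z")
  Lt <- lme4::getME(fit, "Lambdat")
  var_r <- sd_res^2 * mean(Matrix::rowSums((Z %*% Matrix::t(Lt))^2))
  r2c <- (var_f + var_r) / (var_f + var_r + sd_res^2)
  structure(list(table = tab, model = model,
                 varcomp = c(country_intercept_sd = sd_int,
                             country_slope_sd = sd_slope,
                             residual_sd = sd_res),
                 n_obs = stats::nobs(fit),
                 n_countries = nlevels(d$country),
                 cond_r2 = r2c, deviance = stats::deviance(fit, REML = FALSE),
                 reml = reml, fit = fit),
            class = "hybrid_lmm")
}

#' @export
print.hybrid_lmm <- function(x, digits = 3, ...) {
  cat(sprintf("Hybrid within-between LMM (model %d): %d women in %d countries\n",
              x$model, x$n_obs, x$n_countries))
  tab <- x$table
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$p <- signif(tab$p, 2)
  print(tab, row.names = FALSE)
  cat(sprintf("Country intercept SD %.3f | slope SD %.3f | residual SD %.3f | cond. R2 %.3f\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3], x$cond_r2))
  invisible(x)
}

#' @export
coef.hybrid_lmm <- function(object, ...) {
  setNames(object$table$estimate,
           paste0(object$table$term,
                  ifelse(object$table$effect_level == "",
                         "", paste0(".", object$table$effect_level))))
}

#' @export
summary.hybrid_lmm <- function(object, ...) {
  list(table = object$table, varcomp = object$varcomp,
       n_obs = object$n_obs, n_countries = object$n_countries,
       cond_r2 = object$cond_r2)
}
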