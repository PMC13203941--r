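#' Four-parameter age-specific fertility rate curve
#'
#' `f(a) = c * exp(-((a - mu) / s(a))^2)` with `s(a) = s1` below the peak age
#' `mu` and `s2` at or above it: a unimodal schedule with height `c` (births
#' per woman-year) at its peak and differential steepness before and after.
#'
#' @param age ages in years (vector).
#' @param pars numeric vector `c(c, mu, s1, s2)`.
#' @return rates, same length as `age`.
#' @examples
#' asfr_curve(23, c(0.2, 28, 5, 9))  # 0.2 * exp(-1)
#' @export
asfr_curve <- function(age, pars) {
  stopifnot(length(pars) >= 4, pars[1] >= 0, pars[3] > 0, pars[4] > 0)
  s <- ifelse(age < pars[2], pars[3], pars[4])
  pars[1] * exp(-((age - pars[2]) / s)^2)
}

#' Cumulative fertility by age
#'
#' Sum of the ASFR schedule at all integer ages of the fertility support up
#' to and including `age` - a woman's expected lifetime accumulated
#' fertility by that age. Ages below the support return 0.
#'
#' @param age ages in years (vector; fractional ages use the floor).
#' @param pars `c(c, mu, s1, s2)`.
#' @param support integer-age grid of the fertile range (default 15:49).
#' @return expected children by each age.
#' @export
cumulative_fertility <- function(age, pars, support = 15:49) {
  cum <- c(0, cumsum(asfr_curve(support, pars)))
  idx <- pmin(pmax(floor(age) - support[1] + 1L, 0L), length(support))
  cum[idx + 1L]
}

#' Poisson log-likelihood of children counts under an ASFR schedule
#'
#' Each woman's reported children count is Poisson with mean equal to her
#' cumulative fertility at her age.
#'
#' @param pars `c(c, mu, s1, s2)`.
#' @param age,children observed ages and children counts.
#' @param support fertility support ages.
#' @return total log-likelihood.
#' @export
asfr_loglik <- function(pars, age, children, support = 15:49) {
  lam <- cumulative_fertility(age, pars, support)
  if (any(lam <= 0 & children > 0)) return(-Inf)
  ok <- lam > 0
  sum(children[ok] * log(lam[ok]) - lam[ok] - lgamma(children[ok] + 1)) +
    sum(-lam[!ok])
}

## ---- posterior sampler -----------------------------------------------------
##
## Parameter blocks: one (log c, mu, log s1, log s2) quadruple per
## country x subgroup. Given the hierarchical means and SDs the blocks are
## conditionally independent, so one joint Metropolis proposal per block is
## made each sweep and all block likelihoods are evaluated in one vectorized
## pass. Proposal covariances adapt per block during warmup (frozen
## afterwards); hierarchical means have conjugate normal updates; hierarchy
## SDs use slice sampling, which never touches the data likelihood.

## vectorized log-likelihood of all B blocks; th = B x 4 matrix on the
## sampling scale (log c, mu, log s1, log s2)
blocks_loglik <- function(th, dat, blocks = NULL) {
  if (is.null(blocks)) {
    brows <- seq_len(nrow(th)); drows <- seq_along(dat$block)
    bmap <- dat$block
  } else {
    brows <- blocks; drows <- which(dat$block %in% blocks)
    bmap <- match(dat$block[drows], blocks)
    th <- th[blocks, , drop = FALSE]
  }
  B <- nrow(th)
  cc <- exp(th[, 1]); mu <- th[, 2]
  s1 <- exp(th[, 3]); s2 <- exp(th[, 4])
  A <- dat$A[seq_len(B), , drop = FALSE]  # B x ages matrix of support ages
  Z <- A - mu
  S <- s2 + (s1 - s2) * (Z < 0)
  R <- cc * exp(-(Z / S)^2)
  CUM <- R
  for (a in 2:ncol(R)) CUM[, a] <- CUM[, a - 1L] + R[, a]
  lam <- CUM[cbind(bmap, dat$aidx[drows])]
  contrib <- dat$y[drows] * log(dat$n[drows] * lam) - dat$n[drows] * lam
  out <- numeric(B)                       # blocks without data stay at 0
  rs <- rowsum(contrib, bmap, reorder = TRUE)
  out[as.integer(rownames(rs))] <- as.numeric(rs)
  out
}

## log prior of each block given hyper means hm (B x 4) and per-parameter
## SDs (length 4 or a B x 4 matrix)
blocks_logprior <- function(th, hm, sds) {
  sdm <- if (is.matrix(sds)) sds else
    matrix(sds, nrow(th), 4L, byrow = TRUE)
  rowSums(matrix(dnorm(th, hm, sdm, log = TRUE), nrow(th), 4L))
}

## half-t(3) log density (scale parameter prior)
half_t_log <- function(x, scale) {
  ifelse(x <= 0, -Inf, stats::dt(x / scale, df = 3, log = TRUE) - log(scale))
}

## univariate slice sampler (stepping out), used for hierarchy SDs
slice_draw <- function(x0, logf, w = 0.5, max_step = 20L) {
  y <- logf(x0) - stats::rexp(1)
  L <- x0 - runif(1) * w; R <- L + w
  for (k in seq_len(max_step)) { if (logf(L) < y) break; L <- L - w }
  for (k in seq_len(max_step)) { if (logf(R) < y) break; R <- R + w }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## one MCMC chain; returns matrix of draws with JAGS-style column names
asfr_chain <- function(dat, hierarchical, init, prior, n_adapt, n_burn,
                       n_iter, thin, seed) {
  set.seed(seed)
  B <- dat$B; C <- dat$C
  th <- init$th                       # B x 4
  hmean <- init$hmean                 # 2 x 4 (per group)
  hsd <- init$hsd                     # length 4
  hm_of <- function() hmean[dat$block_group, , drop = FALSE]
  ll <- blocks_loglik(th, dat)
  lp <- if (hierarchical) blocks_logprior(th, hm_of(), hsd) else
    blocks_logprior(th, prior$single_mean[dat$block_group, , drop = FALSE],
                    prior$single_sd_mat)
  ## adaptive proposal state
  scale2 <- rep(0.1, B)               # per-block scale factor
  run_n <- 0; run_mean <- th; run_m2 <- array(0, c(B, 4, 4))
  CH <- array(0, c(B, 4, 4))          # per-block proposal Cholesky factors
  for (i in 1:4) CH[, i, i] <- c(0.05, 0.3, 0.05, 0.05)[i]
  ## group translation moves: shift a group's hyper mean and all its country
  ## parameters together, so the hierarchy can slide along likelihood ridges
  ## (peak age trades off against post-peak steepness in cumulative data)
  g_scale2 <- rep(0.02, 2)
  s_scale2 <- rep(0.25, 4)            # rescaling-move step sizes (log scale)
  g_n <- 0; g_mean <- matrix(0, 2, 4); g_m2 <- array(0, c(2, 4, 4))
  g_chol <- rep(list(diag(c(0.03, 0.2, 0.03, 0.03))), 2)
  n_keep <- floor(n_iter / thin)
  keep <- matrix(NA_real_, n_keep, B * 4 + if (hierarchical) 12 else 0)
  ki <- 0L
  total <- n_adapt + n_burn + n_iter
  for (it in seq_len(total)) {
    adapting <- it <= n_adapt
    ## --- blocked Metropolis update of all country-group quadruples
    eps <- matrix(rnorm(B * 4), B, 4)
    step <- matrix(0, B, 4)
    for (i in 1:4) for (j in 1:4)
      step[, j] <- step[, j] + eps[, i] * CH[, i, j]
    prop <- th + sqrt(scale2) * step
    ll_p <- blocks_loglik(prop, dat)
    lp_p <- if (hierarchical) blocks_logprior(prop, hm_of(), hsd) else
      blocks_logprior(prop, prior$single_mean[dat$block_group, , drop = FALSE],
                      prior$single_sd_mat)
    acc <- log(runif(B)) < (ll_p + lp_p - ll - lp)
    acc[!is.finite(ll_p + lp_p)] <- FALSE
    th[acc, ] <- prop[acc, ]; ll[acc] <- ll_p[acc]; lp[acc] <- lp_p[acc]
    if (adapting) {
      gam <- min(0.05, 5 / it)
      scale2 <- scale2 * exp(gam * (as.numeric(acc) - 0.234))
      ## running covariance (Welford), vectorized across blocks
      run_n <- run_n + 1
      d1 <- th - run_mean
      run_mean <- run_mean + d1 / run_n
      d2 <- th - run_mean
      for (i in 1:4) for (j in 1:4)
        run_m2[, i, j] <- run_m2[, i, j] + d1[, i] * d2[, j]
      if (run_n > 50 && it %% 25 == 0) {
        for (b in seq_len(B)) {
          cv <- run_m2[b, , ] / (run_n - 1) + diag(1e-8, 4)
          ch <- try(chol(cv), silent = TRUE)
          if (!inherits(ch, "try-error")) CH[b, , ] <- ch
        }
      }
    }
    ## --- group translation moves (hierarchical only)
    if (hierarchical) {
      for (g in 1:2) {
        rows <- which(dat$block_group == g)
        delta <- sqrt(g_scale2[g]) * as.numeric(rnorm(4) %*% g_chol[[g]])
        th_p <- th; th_p[rows, ] <- sweep(th[rows, , drop = FALSE], 2, delta, `+`)
        ll_g <- blocks_loglik(th_p, dat, blocks = rows)
        dprior <- sum(dnorm(hmean[g, ] + delta, prior$h_mean[g, ],
                            prior$h_sd, log = TRUE)) -
          sum(dnorm(hmean[g, ], prior$h_mean[g, ], prior$h_sd, log = TRUE))
        a <- log(runif(1)) < (sum(ll_g) - sum(ll[rows]) + dprior)
        if (isTRUE(a) && all(is.finite(ll_g))) {
          th <- th_p; ll[rows] <- ll_g
          hmean[g, ] <- hmean[g, ] + delta
        }
        if (adapting) {
          gam <- min(0.05, 5 / it)
          g_scale2[g] <- g_scale2[g] * exp(gam * (as.numeric(isTRUE(a)) - 0.234))
        }
      }
      if (adapting) {
        g_n <- g_n + 1
        d1 <- hmean - g_mean
        g_mean <- g_mean + d1 / g_n
        d2 <- hmean - g_mean
        for (g in 1:2) g_m2[g, , ] <- g_m2[g, , ] + outer(d1[g, ], d2[g, ])
        if (g_n > 50 && it %% 25 == 0) {
          for (g in 1:2) {
            cv <- g_m2[g, , ] / (g_n - 1) + diag(1e-8, 4)
            ch <- try(chol(cv), silent = TRUE)
            if (!inherits(ch, "try-error")) g_chol[[g]] <- ch
          }
        }
      }
    }
    ## --- hierarchy updates
    if (hierarchical) {
      for (g in 1:2) {
        rows <- dat$block_group == g
        ng <- sum(rows)
        for (k in 1:4) {
          v0 <- prior$h_sd[k]^2; m0 <- prior$h_mean[g, k]
          vpost <- 1 / (1 / v0 + ng / hsd[k]^2)
          mpost <- vpost * (m0 / v0 + sum(th[rows, k]) / hsd[k]^2)
          hmean[g, k] <- rnorm(1, mpost, sqrt(vpost))
        }
      }
      hm <- hm_of()
      for (k in 1:4) {
        devs <- th[, k] - hm[, k]
        logf <- function(s)
          if (s <= 0) -Inf else
            sum(dnorm(devs, 0, s, log = TRUE)) + half_t_log(s, prior$sd_scale[k])
        hsd[k] <- slice_draw(hsd[k], logf, w = prior$sd_scale[k] / 2)
      }
      ## interweaved rescaling: jointly scale a hierarchy SD and all its
      ## deviations (non-centered move), which unsticks the SD near zero;
      ## run on alternate sweeps (fixed scan) to save likelihood passes
      if (it %% 2L == 0L) for (k in 1:4) {
        delta <- rnorm(1, 0, sqrt(s_scale2[k]))
        th_p <- th
        th_p[, k] <- hm[, k] + (th[, k] - hm[, k]) * exp(delta)
        ll_p <- blocks_loglik(th_p, dat)
        sd_p <- hsd[k] * exp(delta)
        a <- log(runif(1)) < (sum(ll_p) - sum(ll) +
                                half_t_log(sd_p, prior$sd_scale[k]) -
                                half_t_log(hsd[k], prior$sd_scale[k]) + delta)
        if (isTRUE(a) && all(is.finite(ll_p))) {
          th <- th_p; ll <- ll_p; hsd[k] <- sd_p
        }
        if (adapting)
          s_scale2[k] <- s_scale2[k] *
            exp(min(0.05, 5 / it) * (as.numeric(isTRUE(a)) - 0.234))
      }
      lp <- blocks_logprior(th, hm_of(), hsd)
    }
    ## --- record
    if (it > n_adapt + n_burn && (it - n_adapt - n_burn) %% thin == 0L) {
      ki <- ki + 1L
      vals <- c(exp(th[, 1]), th[, 2], exp(th[, 3]), exp(th[, 4]))
      if (hierarchical) vals <- c(vals, as.numeric(hmean), hsd)
      keep[ki, ] <- vals
    }
  }
  pn <- c("cc", "mu", "s1", "s2")
  nm <- character(0)
  for (p in pn) nm <- c(nm, if (C > 1L)
    sprintf("%s[%d,%d]", p, dat$block_country, dat$block_group2) else
    sprintf("%s[%d]", p, dat$block_group2))
  if (hierarchical)
    nm <- c(nm, sprintf("h_%s[%d]", rep(c("lc", "mu", "ls1", "ls2"), each = 2), 1:2),
            paste0("sd_", c("lc", "mu", "ls1", "ls2")))
  colnames(keep) <- nm
  keep
}

#' Fit the hierarchical Bayesian ASFR model
#'
#' Children counts of women in the fertile age range are modeled as Poisson
#' with mean equal to the cumulative ASFR of the woman's country x GRB
#' subgroup up to her age. The four curve parameters per country and
#' subgroup (eight per country) are drawn hierarchically around global
#' subgroup means - normal population distributions on `log(c)`, `mu`,
#' `log(s1)`, `log(s2)` - inducing shrinkage toward the average country.
#' Priors are weakly informative around typical human fertility schedules
#' (peak age 28 +- 5 years, peak height around 0.15 births/woman-year,
#' steepness around 5 and 9 years, half-t(3) hierarchy SDs).
#'
#' The posterior is sampled with an adaptive blocked Metropolis-within-Gibbs
#' sampler: one joint proposal per country-subgroup parameter quadruple with
#' per-block covariance adapted during warmup, conjugate normal updates for
#' the hierarchical means, and slice updates for the hierarchy SDs. Split
#' R-hat and effective sizes are computed for every stored parameter, with a
#' configurable convergence gate.
#'
#' @param data data frame of women with `age`, `n_children`, `country`, and
#'   either `grb_group` (levels low/high) or `grb` (split applied here).
#' @param split split value for [median_split()] when `grb_group` is absent
#'   (`"median"` = realized sample median).
#' @param support integer fertility-support ages (default 15:49; children
#'   reported at 18 reflect fertility before 18, so the support starts below
#'   the observed ages).
#' @param hierarchical force the hierarchical (`TRUE`) or single-country
#'   (`FALSE`) model; default: hierarchical iff more than one country.
#' @param n_chains,n_adapt,n_burn,n_iter,thin sampler settings.
#' @param seed RNG seed (chains use seeds derived from it).
#' @param rhat_warn,rhat_fail convergence gates on max split R-hat: warn
#'   above the first, abort above the second.
#' @return object of class `asfr_fit`: posterior draws (matrix), country and
#'   group labels, diagnostics, sampler settings.
#' @export
fit_asfr <- function(data, split = "median", support = 15:49,
                     hierarchical = NULL, n_chains = 3, n_adapt = 1500,
                     n_burn = 500, n_iter = 3000, thin = 3, seed = 1,
                     rhat_warn = 1.1, rhat_fail = 1.5) {
  check_cols(data, c("age", "n_children", "country"), "data")
  data <- data[!is.na(data$n_children) & !is.na(data$age), ]
  data <- data[data$age >= min(support) & data$age <= max(support), ]
  if (!"grb_group" %in% names(data)) {
    check_cols(data, "grb", "data")
    sv <- if (identical(split, "median")) median(data$grb, na.rm = TRUE) else split
    data$grb_group <- as.character(median_split(data$grb, sv))
  } else sv <- NA_real_
  data <- data[!is.na(data$grb_group), ]
  countries <- sort(unique(data$country))
  C <- length(countries)
  if (is.null(hierarchical)) hierarchical <- C > 1L
  ## aggregate: Poisson sums per country-group-age carry the full likelihood
  agg <- aggregate(cbind(n = rep(1, nrow(data)), y = data$n_children)
                   ~ country + grb_group + age, data, sum)
  ci <- match(agg$country, countries)
  gi <- match(agg$grb_group, c("low", "high"))
  block <- (ci - 1L) * 2L + gi
  B <- C * 2L
  dat <- list(B = B, C = C, support = support,
              A = matrix(support, B, length(support), byrow = TRUE),
              block = block, aidx = agg$age - min(support) + 1L,
              y = agg$y, n = agg$n,
              block_country = rep(seq_len(C), each = 2L),
              block_group = rep(1:2, times = C),
              block_group2 = rep(1:2, times = C))
  ## pooled per-group ML estimates for initialization
  pooled <- vapply(1:2, function(g) {
    sel <- gi == g
    op <- try(optim(c(log(0.15), 28, log(5), log(9)), function(t4) {
      lam <- cumulative_fertility(support[dat$aidx[sel]],
                                  c(exp(t4[1]), t4[2], exp(t4[3]), exp(t4[4])),
                                  support)
      -sum(agg$y[sel] * log(pmax(lam, 1e-12)) - agg$n[sel] * lam)
    }), silent = TRUE)
    if (inherits(op, "try-error")) c(log(0.15), 28, log(5), log(9)) else op$par
  }, numeric(4L))
  prior <- list(
    h_mean = t(pooled * 0 + c(log(0.15), 28, log(5), log(9))),   # 2 x 4
    h_sd = c(1, 5, 1, 1),
    sd_scale = c(0.5, 2.0, 0.5, 0.5),
    single_mean = t(matrix(c(log(0.15), 28, log(5), log(9)), 4, 2)),
    single_sd_mat = matrix(c(2, 5, 1, 1), C * 2L, 4, byrow = TRUE))
  chains <- lapply(seq_len(n_chains), function(ch) {
    set.seed(child_seed(seed, 300 + ch))
    init <- list(
      th = t(pooled)[dat$block_group, , drop = FALSE] +
        matrix(rnorm(B * 4, 0, rep(c(0.1, 0.5, 0.1, 0.1), each = B)), B, 4),
      hmean = t(pooled) + matrix(rnorm(8, 0, c(rep(0.1, 2), rep(0.5, 2),
                                               rep(0.1, 4))), 2, 4),
      hsd = c(0.2, 1, 0.2, 0.2))
    asfr_chain(dat, hierarchical, init, prior, n_adapt, n_burn, n_iter,
               thin, seed = child_seed(seed, 100 + ch))
  })
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  gd <- try(coda::gelman.diag(ml, multivariate = FALSE,
                              autoburnin = FALSE)$psrf[, 1], silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) rep(NA_real_, ncol(chains[[1]])) else gd
  mx <- suppressWarnings(max(rhat, na.rm = TRUE))
  if (is.finite(mx) && mx > rhat_fail)
    stop(sprintf("ASFR sampler did not converge (max R-hat %.2f)", mx))
  if (is.finite(mx) && mx > rhat_warn)
    warning(sprintf("ASFR sampler: max R-hat %.2f above %.2f", mx, rhat_warn))
  structure(list(draws = do.call(rbind, chains), countries = countries,
                 groups = c("low", "high"), hierarchical = hierarchical,
                 support = support, split_value = sv,
                 diagnostics = list(rhat = rhat,
                                    neff = coda::effectiveSize(ml)),
                 n_obs = nrow(data),
                 sampler = list(chains = n_chains, adapt = n_adapt,
                                burn = n_burn, iter = n_iter, thin = thin,
                                seed = seed)),
            class = "asfr_fit")
}

#' @export
print.asfr_fit <- function(x, ...) {
  cat("Hierarchical ASFR model:", length(x$countries), "countries x 2 GRB",
      "subgroups,", x$n_obs, "women\n")
  cat("  draws:", nrow(x$draws), " max R-hat:",
      round(suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)), 3), "\n")
  invisible(x)
}

#' @export
coef.asfr_fit <- function(object, ...) colMeans(object$draws)

## extract per-draw parameter array [draw, country, group, par]
asfr_par_array <- function(fit) {
  C <- length(fit$countries); D <- nrow(fit$draws)
  out <- array(NA_real_, c(D, C, 2L, 4L),
               dimnames = list(NULL, fit$countries, fit$groups,
                               c("c", "mu", "s1", "s2")))
  pn <- c("cc", "mu", "s1", "s2")
  for (p in 1:4) for (i in seq_len(C)) for (g in 1:2) {
    nm <- if (C > 1L) sprintf("%s[%d,%d]", pn[p], i, g) else
      sprintf("%s[%d]", pn[p], g)
    out[, i, g, p] <- fit$draws[, nm]
  }
  out
}

## hyper-level ("average country") parameter draws [draw, group, par]
asfr_hyper_array <- function(fit) {
  D <- nrow(fit$draws)
  out <- array(NA_real_, c(D, 2L, 4L),
               dimnames = list(NULL, fit$groups, c("c", "mu", "s1", "s2")))
  if (fit$hierarchical) {
    for (g in 1:2) {
      out[, g, 1] <- exp(fit$draws[, sprintf("h_lc[%d]", g)])
      out[, g, 2] <- fit$draws[, sprintf("h_mu[%d]", g)]
      out[, g, 3] <- exp(fit$draws[, sprintf("h_ls1[%d]", g)])
      out[, g, 4] <- exp(fit$draws[, sprintf("h_ls2[%d]", g)])
    }
  } else {
    pn <- c("cc", "mu", "s1", "s2")
    for (p in 1:4) for (g in 1:2)
      out[, g, p] <- fit$draws[, sprintf("%s[%d]", pn[p], g)]
  }
  out
}

## TFR and age at cumulative fertility 0.5 for one parameter vector
tfr_of <- function(pars, support) sum(asfr_curve(support, pars))

## vectorized over draws: P is D x 4 (c, mu, s1, s2)
curve_rows <- function(P, support) {
  D <- nrow(P); L <- length(support)
  A <- matrix(support, D, L, byrow = TRUE)
  Z <- A - P[, 2]
  S <- P[, 4] + (P[, 3] - P[, 4]) * (Z < 0)
  P[, 1] * exp(-(Z / S)^2)
}

cum_rows <- function(R) {
  for (a in 2:ncol(R)) R[, a] <- R[, a - 1L] + R[, a]
  R
}

aah_rows <- function(CUM, support, target = 0.5) {
  D <- nrow(CUM); L <- ncol(CUM)
  out <- rep(NA_real_, D)
  ok <- CUM[, L] >= target
  if (!any(ok)) return(out)
  idx <- max.col(CUM >= target, ties.method = "first")
  first <- ok & idx == 1L
  out[first] <- support[1]
  rest <- ok & idx > 1L
  if (any(rest)) {
    r <- which(rest)
    prev <- CUM[cbind(r, idx[r] - 1L)]
    out[r] <- support[idx[r] - 1L] +
      (target - prev) / (CUM[cbind(r, idx[r])] - prev)
  }
  out
}

age_at_half <- function(pars, support, target = 0.5) {
  cum <- cumsum(asfr_curve(support, pars))
  if (max(cum) < target) return(NA_real_)
  i <- which(cum >= target)[1]
  if (i == 1L) return(support[1])
  support[i - 1L] + (target - cum[i - 1L]) / (cum[i] - cum[i - 1L])
}

#' Fertility level and timing metrics from an ASFR fit
#'
#' Per posterior draw and per country x subgroup: the total fertility rate
#' (area under the ASFR schedule) and the age at which cumulative fertility
#' reaches 0.5 children per woman (linearly interpolated between integer
#' ages; undefined when the schedule never reaches 0.5 - such draws are
#' excluded with a count). At the average-country (hierarchical-mean) level
#' the low-minus-high TFR contrast and the high-minus-low timing contrast
#' are summarized; across countries, the per-draw proportion of countries in
#' which the low-GRB subpopulation has the higher TFR, and the younger age
#' at 0.5, are reported with 90% equal-tailed intervals.
#'
#' @param fit an [fit_asfr()] object.
#' @return object of class `fertility_metrics`.
#' @export
derive_metrics <- function(fit) {
  stopifnot(inherits(fit, "asfr_fit"))
  supp <- fit$support
  arr <- asfr_par_array(fit)
  D <- dim(arr)[1]; C <- dim(arr)[2]
  tfr <- array(NA_real_, c(D, C, 2L), dimnames = dimnames(arr)[1:3])
  aah <- tfr
  for (i in seq_len(C)) for (g in 1:2) {
    CUM <- cum_rows(curve_rows(arr[, i, g, , drop = TRUE], supp))
    tfr[, i, g] <- CUM[, ncol(CUM)]
    aah[, i, g] <- aah_rows(CUM, supp)
  }
  hyp <- asfr_hyper_array(fit)
  tfr_h <- matrix(NA_real_, D, 2L); aah_h <- tfr_h
  for (g in 1:2) {
    CUM <- cum_rows(curve_rows(hyp[, g, , drop = TRUE], supp))
    tfr_h[, g] <- CUM[, ncol(CUM)]
    aah_h[, g] <- aah_rows(CUM, supp)
  }
  tfr_diff <- tfr_h[, 1] - tfr_h[, 2]            # low - high, expected > 0
  aah_gap <- aah_h[, 2] - aah_h[, 1]             # high - low, expected > 0
  prop_higher <- rowMeans(tfr[, , 1, drop = FALSE][, , 1] >
                            tfr[, , 2, drop = FALSE][, , 1])
  ok <- !is.na(aah[, , 1]) & !is.na(aah[, , 2])
  prop_earlier <- rowSums((aah[, , 1] < aah[, , 2]) & ok, na.rm = TRUE) /
    pmax(rowSums(ok), 1L)
  summ <- function(x) c(mean = mean(x, na.rm = TRUE), eti(x))
  structure(list(
    tfr = tfr, age_at_half = aah,
    tfr_hyper = tfr_h, aah_hyper = aah_h,
    tfr_diff = tfr_diff, aah_gap = aah_gap,
    prop_low_higher_tfr = prop_higher,
    prop_low_earlier = prop_earlier,
    n_undefined_aah = sum(is.na(aah)),
    summary = rbind(tfr_diff = summ(tfr_diff), aah_gap = summ(aah_gap),
                    prop_low_higher_tfr = summ(prop_higher),
                    prop_low_earlier = summ(prop_earlier)),
    countries = fit$countries, support = supp),
    class = "fertility_metrics")
}

#' @export
print.fertility_metrics <- function(x, ...) {
  cat("Fertility metrics (posterior mean [90% ETI]):\n")
  s <- x$summary
  lab <- c("TFR difference (low - high)",
           "Age-at-0.5 gap (high - low, years)",
           "Prop. countries: low group higher TFR",
           "Prop. countries: low group earlier")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-38s %6.3f [%.3f, %.3f]\n", lab[i], s[i, 1], s[i, 2], s[i, 3]))
  if (x$n_undefined_aah > 0)
    cat("  (", x$n_undefined_aah, "draw-cells never reach 0.5 and were excluded)\n")
  invisible(x)
}
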