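#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from one master seed, so stages can be rerun in isolation and still
#' reproduce a full-pipeline run. Values stay below 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param k stage index (single non-negative integer).
#' @return an integer seed.
#' @export
child_seed <- function(seed, k) {
  stopifnot(length(seed) == 1L, length(k) == 1L, is.finite(seed), is.finite(k))
  as.integer((abs(as.double(seed)) * 7919 + as.double(k) * 104729) %% 2147483629)
}

#' Equal-tailed interval from draws
#'
#' 5th/95th (by default) percentiles computed with linear interpolation
#' between order statistics (the type-7 rule), so intervals are
#' bit-reproducible across platforms.
#'
#' @param x numeric vector of draws.
#' @param level interval mass (default 0.9).
#' @return named vector `c(lo, hi)`.
#' @export
eti <- function(x, level = 0.9) {
  a <- (1 - level) / 2
  q <- quantile(x, c(a, 1 - a), names = FALSE, na.rm = TRUE, type = 7)
  c(lo = q[1], hi = q[2])
}

## internal: stop unless all conditions hold, with a readable message
check_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
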