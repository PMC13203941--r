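#' Rescale an ordinal item response to 0-100
#'
#' Linear map taking the scale minimum to 0 and the maximum to 100. Missing
#' responses propagate; out-of-range responses are rejected.
#'
#' @param raw numeric vector of ordinal responses.
#' @param scale_min,scale_max response-scale endpoints (`scale_max` >
#'   `scale_min`).
#' @return numeric vector in \[0, 100\].
#' @examples
#' rescale_item(1:3, 1, 3)    # 0, 50, 100
#' rescale_item(3, 1, 4)      # 66.67
#' @export
rescale_item <- function(raw, scale_min, scale_max) {
  stopifnot(scale_max > scale_min)
  bad <- !is.na(raw) & (raw < scale_min | raw > scale_max)
  if (any(bad))
    stop(sprintf("%d response(s) outside [%s, %s]", sum(bad),
                 format(scale_min), format(scale_max)))
  (raw - scale_min) / (scale_max - scale_min) * 100
}

#' Composite GRB score from up to three rescaled items
#'
#' The composite is the arithmetic mean of the available rescaled items.
#' Rows with fewer than `min_items` non-missing items get `NA` (the study's
#' handling of partially answered items is not fixed by the measure itself,
#' so the threshold is configurable; default requires two of three).
#'
#' @param items numeric matrix (rows = respondents, columns = rescaled items
#'   on 0-100).
#' @param min_items minimum non-missing items per respondent.
#' @return numeric vector of composite scores in \[0, 100\]; higher is more
#'   egalitarian.
#' @export
composite_grb <- function(items, min_items = 2L) {
  items <- as.matrix(items)
  if (any(items < 0 | items > 100, na.rm = TRUE))
    stop("rescaled items must lie in [0, 100]")
  k <- rowSums(!is.na(items))
  out <- rowMeans(items, na.rm = TRUE)
  out[k < min_items | k == 0L] <- NA_real_
  out
}

#' Score a survey table: add the 0-100 composite GRB column
#'
#' Rescales `item1..item3` from their ordinal scales (lengths given by
#' `item_levels`, minimum response 1) and stores their mean as `grb`.
#'
#' @param survey data frame with `item1`, `item2`, `item3`.
#' @param item_levels integer scale lengths of the three items.
#' @param min_items passed to [composite_grb()].
#' @return `survey` with a `grb` column appended.
#' @export
score_survey <- function(survey, item_levels = c(2L, 3L, 4L), min_items = 2L) {
  check_cols(survey, c("item1", "item2", "item3"), "survey")
  m <- matrix(vapply(1:3, function(k)
    rescale_item(survey[[paste0("item", k)]], 1, item_levels[k]),
    numeric(nrow(survey))), nrow(survey), 3L)
  survey$grb <- composite_grb(m, min_items = min_items)
  survey
}

#' Cronbach's alpha of the item battery
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`, computed on
#' listwise-complete rows. Alpha can only exceed 0 when items covary
#' positively; zero total variance leaves alpha undefined (flagged).
#'
#' @param item_matrix numeric matrix, >= 2 columns, >= 3 complete rows.
#' @return object of class `reliability_report`: list with `alpha`,
#'   `n_respondents`, `item_variances`, `degenerate` flag.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  stopifnot(ncol(m) >= 2L)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete rows")
  k <- ncol(m)
  iv <- apply(m, 2L, var)
  tv <- var(rowSums(m))
  degenerate <- !is.finite(tv) || tv <= 0
  alpha <- if (degenerate) NA_real_ else k / (k - 1) * (1 - sum(iv) / tv)
  structure(list(alpha = alpha, n_respondents = nrow(m),
                 item_variances = iv, degenerate = degenerate),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  if (x$degenerate) {
    cat("Cronbach's alpha undefined (zero total variance), n =",
        x$n_respondents, "\n")
  } else {
    cat(sprintf("Cronbach's alpha = %.3f (n = %d, %d items)\n",
                x$alpha, x$n_respondents, length(x$item_variances)))
  }
  invisible(x)
}

#' Split respondents at a GRB score value
#'
#' Scores equal to or below the split go to `"low"` (the less egalitarian
#' group), scores above to `"high"`. The default split is the realized sample
#' median of the scores themselves.
#'
#' @param scores numeric GRB scores.
#' @param split_value split point in \[0, 100\] (default: realized median).
#' @return factor with levels `low`, `high` (`NA` scores stay `NA`).
#' @export
median_split <- function(scores, split_value = median(scores, na.rm = TRUE)) {
  stopifnot(split_value >= 0, split_value <= 100)
  factor(ifelse(scores <= split_value, "low", "high"),
         levels = c("low", "high"))
}

#' Religiosity index from four rescaled items
#'
#' Arithmetic mean of four ordinal items, each rescaled to 0-100.
#'
#' @param items numeric matrix with four columns of raw responses.
#' @param scales list of four `c(min, max)` response scales.
#' @param require_complete if `TRUE` (default) any missing item yields `NA`.
#' @return numeric vector in \[0, 100\].
#' @export
religiosity_index <- function(items,
                              scales = list(c(1, 4), c(1, 5), c(1, 7), c(1, 10)),
                              require_complete = TRUE) {
  m <- as.matrix(items)
  stopifnot(ncol(m) == 4L, length(scales) == 4L)
  r <- matrix(vapply(1:4, function(k) rescale_item(m[, k], scales[[k]][1],
                                                   scales[[k]][2]),
                     numeric(nrow(m))), nrow(m), 4L)
  out <- rowMeans(r, na.rm = !require_complete)
  out[is.nan(out)] <- NA_real_
  out
}
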