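#' Posterior draws of the annual percentage change
#'
#' For each posterior draw, the APC is the model-implied one-year gain in
#' coverage at baseline, in percentage points:
#' `100 * (inv_logit(alpha + beta) - inv_logit(alpha))`.
#'
#' @param fit A [fit_trend()] result.
#' @return Numeric vector of APC draws (pp/year).
#' @export
apc_draws <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  100 * (inv_logit(fit$alpha + fit$beta) - inv_logit(fit$alpha))
}

#' Annual percentage change summary
#'
#' Posterior mean and equal-tailed 95% credible interval of the APC
#' distribution (see [apc_draws()]).
#'
#' @param fit A [fit_trend()] result.
#' @return List of class `apc_summary`: `mean`, `cri_low`, `cri_high`
#'   (percentage points per year).
#' @export
apc <- function(fit) {
  d <- apc_draws(fit)
  q <- unname(quantile(d, c(0.025, 0.975), names = FALSE))
  structure(list(mean = mean(d), cri_low = q[1], cri_high = q[2],
                 unit = fit$unit, sex = fit$sex),
            class = "apc_summary")
}

#' @export
print.apc_summary <- function(x, ...) {
  cat(sprintf("<apc> %s / %s: %.2f (95%% CrI %.2f, %.2f) pp/year\n",
              x$unit, x$sex, x$mean, x$cri_low, x$cri_high))
  invisible(x)
}

#' Male-female difference in percentage points
#'
#' Positive values indicate a higher value among men.
#'
#' @param men,women Values in percent (0, 100).
#' @return `men - women`, percentage points.
#' @examples
#' sex_gap(47.5, 37.4)  # 10.1
#' @export
sex_gap <- function(men, women) {
  stopifnot(all(men > 0 & men < 100), all(women > 0 & women < 100))
  men - women
}

#' Count units meeting a coverage threshold
#'
#' Inclusive comparison (`>=`): a unit whose printed value equals the
#' threshold counts as meeting it.
#'
#' @param values Named numeric vector (percent), e.g. from
#'   [fixture_column()]; the nationwide row should already be excluded when
#'   counting prefectures.
#' @param threshold Threshold in percent.
#' @return List with `count` and `units` (names in table order).
#' @export
count_meeting_threshold <- function(values, threshold) {
  hit <- values >= threshold
  list(count = sum(hit), units = names(values)[hit])
}

#' Count units with a large male-female attainment-probability gap
#'
#' The gap is expressed in percentage points of probability:
#' `100 * (men - women)`. Inclusive comparison (`>=`).
#'
#' @param men_prob,women_prob Named probability vectors in \[0, 1\] with
#'   identical names.
#' @param cutoff Gap cutoff in percentage points (default 15).
#' @return List with `count`, `units`, and the named `gap_pp` vector.
#' @export
count_large_disparity <- function(men_prob, women_prob, cutoff = 15) {
  stopifnot(identical(names(men_prob), names(women_prob)))
  gap <- 100 * (men_prob - women_prob)
  hit <- gap >= cutoff
  list(count = sum(hit), units = names(men_prob)[hit], gap_pp = gap)
}

#' Extremes of a column with unit names
#'
#' Ties are broken by table order (first occurrence wins).
#'
#' @param values Named numeric vector.
#' @return List with `min_unit`, `min_value`, `max_unit`, `max_value`.
#' @export
range_summary <- function(values) {
  stopifnot(length(values) >= 1L)
  i <- which.min(values); j <- which.max(values)
  list(min_unit = names(values)[i], min_value = unname(values[i]),
       max_unit = names(values)[j], max_value = unname(values[j]))
}

#' Per-unit change between two columns
#'
#' @param col_a,col_b Named numeric vectors (percent) over the same units.
#' @return Named vector `col_b - col_a` in percentage points.
#' @export
change_summary <- function(col_a, col_b) {
  if (!identical(names(col_a), names(col_b)))
    stop("unit sets of the two columns do not match")
  col_b - col_a
}
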