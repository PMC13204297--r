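#' Posterior draws of projected coverage at a calendar year
#'
#' Evaluates `inv_logit(alpha + beta * (year - center_year))` for every
#' pooled posterior draw. By default only the linear predictor is projected
#' (trend uncertainty); `add_noise = TRUE` additionally adds one draw of
#' observation-level residual noise per posterior draw, as a sensitivity
#' variant (uses the current RNG stream).
#'
#' @param fit A [fit_trend()] result.
#' @param year Calendar year, at or after the centering year.
#' @param add_noise Add `N(0, sigma)` logit-scale noise per draw?
#' @return Numeric vector of coverage proportions, one per draw.
#' @export
coverage_draws <- function(fit, year, add_noise = FALSE) {
  stopifnot(inherits(fit, "trend_fit"))
  if (year < fit$center_year)
    stop("projection year precedes the centering year")
  eta <- fit$alpha + fit$beta * (year - fit$center_year)
  if (add_noise) eta <- eta + rnorm(length(eta), 0, fit$sigma)
  inv_logit(eta)
}

#' Project coverage to a calendar year
#'
#' Posterior summary of projected coverage: mean and equal-tailed 95%
#' credible interval (2.5th and 97.5th percentiles of the draws).
#'
#' @inheritParams coverage_draws
#' @return List of class `projection_summary`: `year`, `mean`, `cri_low`,
#'   `cri_high` (proportions).
#' @export
project_coverage <- function(fit, year, add_noise = FALSE) {
  d <- coverage_draws(fit, year, add_noise = add_noise)
  q <- unname(quantile(d, c(0.025, 0.975), names = FALSE))
  structure(list(year = year, mean = mean(d), cri_low = q[1], cri_high = q[2],
                 unit = fit$unit, sex = fit$sex),
            class = "projection_summary")
}

#' @export
print.projection_summary <- function(x, ...) {
  cat(sprintf("<projection> %s / %s @ %d: %.1f%% (95%% CrI %.1f, %.1f)\n",
              x$unit, x$sex, x$year, 100 * x$mean, 100 * x$cri_low,
              100 * x$cri_high))
  invisible(x)
}

#' Probability that projected coverage meets a benchmark
#'
#' Fraction of posterior draws whose projected coverage at `year` is at or
#' above `threshold` (a draw exactly at the benchmark counts as meeting it).
#'
#' @inheritParams coverage_draws
#' @param threshold Benchmark proportion in (0, 1); default 0.60.
#' @return Probability in \[0, 1\].
#' @export
exceedance_prob <- function(fit, year, threshold = 0.60, add_noise = FALSE) {
  stopifnot(threshold > 0, threshold < 1)
  mean(coverage_draws(fit, year, add_noise = add_noise) >= threshold)
}

#' First year the attainment probability reaches a given level
#'
#' Scans an annual grid from the centering year to `horizon_max` and returns
#' the smallest calendar year whose exceedance probability reaches
#' `prob_level` (`>=` by default; `strict = TRUE` uses `>`), or `"never"` if
#' no grid year qualifies.
#'
#' @inheritParams exceedance_prob
#' @param prob_level Required attainment probability (default 0.80).
#' @param horizon_max Last year scanned (default 2100).
#' @param strict Require strictly greater than `prob_level`?
#' @return Integer year, or the character sentinel `"never"`.
#' @export
target_year <- function(fit, threshold = 0.60, prob_level = 0.80,
                        horizon_max = 2100, strict = FALSE) {
  stopifnot(inherits(fit, "trend_fit"), prob_level > 0, prob_level < 1)
  lt <- logit(threshold)
  years <- seq.int(fit$center_year, horizon_max)
  for (y in years) {
    p <- mean(fit$alpha + fit$beta * (y - fit$center_year) >= lt)
    hit <- if (strict) p > prob_level else p >= prob_level
    if (hit) return(y)
  }
  "never"
}

#' Classify target attainment for one fitted series
#'
#' Combines the two published on-track conventions: the probability rule
#' (exceedance probability at the horizon year at or above `prob_level`) and
#' the year rule (target year at or before `on_track_by`). Both are reported
#' side by side because the published narrative uses the year rule while the
#' stated classification criterion is the probability rule.
#'
#' @inheritParams target_year
#' @param horizon Policy horizon year (default 2028).
#' @param on_track_by Latest target year counted as on track (default 2030).
#' @return List of class `target_attainment`: `prob_at_horizon`,
#'   `target_year`, `on_track_prob`, `on_track_year`.
#' @export
classify_attainment <- function(fit, horizon = 2028, threshold = 0.60,
                                prob_level = 0.80, horizon_max = 2100,
                                on_track_by = 2030, strict = FALSE) {
  p <- exceedance_prob(fit, horizon, threshold)
  ty <- target_year(fit, threshold, prob_level, horizon_max, strict = strict)
  on_prob <- if (strict) p > prob_level else p >= prob_level
  on_year <- !identical(ty, "never") && ty <= on_track_by
  structure(list(unit = fit$unit, sex = fit$sex,
                 prob_at_horizon = p, target_year = ty,
                 on_track_prob = on_prob, on_track_year = on_year,
                 horizon = horizon, threshold = threshold,
                 prob_level = prob_level),
            class = "target_attainment")
}

#' @export
print.target_attainment <- function(x, ...) {
  cat(sprintf(
    "<attainment> %s / %s: P(>=%.0f%% in %d) = %.3f; target year %s%s\n",
    x$unit, x$sex, 100 * x$threshold, x$horizon, x$prob_at_horizon,
    as.character(x$target_year),
    if (x$on_track_year) " (on track)" else ""))
  invisible(x)
}
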