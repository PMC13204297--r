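#' Forecast accuracy metrics on the percent scale
#'
#' Computes the five holdout accuracy metrics from observed and predicted
#' coverage, both in percent. Errors are `predicted - observed` in
#' percentage points, so positive bias means over-prediction.
#'
#' @param observed_pct,predicted_pct Numeric vectors in percent.
#' @param lo_pct,hi_pct Optional 95% interval bounds in percent for the
#'   empirical interval-coverage metric.
#' @return List of class `validation_metrics`: `mad`, `rmsd`, `bias` (pp),
#'   `mapd` (percent), `interval_coverage` (proportion, `NA` if no
#'   intervals supplied), `n_units`.
#' @examples
#' validation_metrics(c(50, 50), c(52, 46))  # mad 3, bias -1, rmsd sqrt(10)
#' @export
validation_metrics <- function(observed_pct, predicted_pct,
                               lo_pct = NULL, hi_pct = NULL) {
  stopifnot(length(observed_pct) == length(predicted_pct),
            length(observed_pct) >= 1L)
  e <- predicted_pct - observed_pct
  cover <- if (!is.null(lo_pct) && !is.null(hi_pct))
    mean(observed_pct >= lo_pct & observed_pct <= hi_pct) else NA_real_
  structure(list(mad = mean(abs(e)), rmsd = sqrt(mean(e^2)), bias = mean(e),
                 mapd = mean(abs(e) / observed_pct) * 100,
                 interval_coverage = cover, n_units = length(e)),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf(paste0("<validation_metrics> n = %d\n",
                     "  MAD  %.2f pp   RMSD %.2f pp   bias %+.2f pp\n",
                     "  MAPD %.2f %%   95%% interval coverage %s\n"),
              x$n_units, x$mad, x$rmsd, x$bias, x$mapd,
              ifelse(is.na(x$interval_coverage), "NA",
                     sprintf("%.3f", x$interval_coverage))))
  invisible(x)
}

#' Holdout forecast validation
#'
#' Trains the trend model on `train_years` for every series, projects the
#' held-out `test_year`, and aggregates accuracy over units. Series missing
#' any required wave are skipped with a warning and excluded from `n_units`.
#'
#' @param series_list List of [coverage_series].
#' @param train_years Training waves (default 2013, 2016, 2019).
#' @param test_year Held-out wave (default 2022).
#' @param priors,config Passed to [fit_trend()]; each series gets a distinct
#'   seed derived from `config$seed`.
#' @param point `"mean"` (default) or `"median"` posterior point prediction.
#' @param add_noise Include observation noise in the predictive draws?
#'   Default `FALSE`: intervals reflect trend uncertainty only, matching the
#'   projection convention.
#' @return List of class `holdout_validation`: `metrics`
#'   (a [validation_metrics()] object) and `residuals`, a per-unit
#'   data frame of observed/predicted values, interval bounds, errors and
#'   interval hits.
#' @export
holdout_validate <- function(series_list,
                             train_years = c(2013L, 2016L, 2019L),
                             test_year = 2022L,
                             priors = prior_spec(), config = mcmc_config(),
                             point = c("mean", "median"),
                             add_noise = FALSE) {
  point <- match.arg(point)
  train_years <- as.integer(train_years)
  rows <- list()
  skipped <- character()
  for (i in seq_along(series_list)) {
    s <- series_list[[i]]
    if (!all(train_years %in% s$years) || !(test_year %in% s$years)) {
      skipped <- c(skipped, paste(s$unit, s$sex, sep = "/"))
      next
    }
    keep <- s$years %in% train_years
    tr <- coverage_series(s$unit, s$sex, s$years[keep], s$coverage[keep])
    cfg <- config
    cfg$seed <- series_seed(config$seed, s$unit, s$sex)
    fit <- fit_trend(tr, priors, cfg)
    d <- coverage_draws(fit, test_year, add_noise = add_noise)
    pred <- if (point == "mean") mean(d) else median(d)
    q <- unname(quantile(d, c(0.025, 0.975), names = FALSE))
    obs <- s$coverage[s$years == test_year]
    rows[[length(rows) + 1L]] <- data.frame(
      unit = s$unit, sex = s$sex,
      observed_pct = 100 * obs, predicted_pct = 100 * pred,
      lo_pct = 100 * q[1], hi_pct = 100 * q[2],
      error_pp = 100 * (pred - obs),
      covered = obs >= q[1] & obs <= q[2],
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped series missing required waves: ",
            paste(skipped, collapse = ", "))
  if (!length(rows))
    stop("no series contained all training waves and the test wave")
  res <- do.call(rbind, rows)
  metrics <- validation_metrics(res$observed_pct, res$predicted_pct,
                                res$lo_pct, res$hi_pct)
  structure(list(metrics = metrics, residuals = res,
                 train_years = train_years, test_year = test_year),
            class = "holdout_validation")
}

#' @export
print.holdout_validation <- function(x, ...) {
  cat(sprintf("<holdout_validation> train %s -> test %d\n",
              paste(x$train_years, collapse = ","), x$test_year))
  print(x$metrics)
  invisible(x)
}
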