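#' Configuration for the synthetic survey-panel generator
#'
#' Describes a survey-like panel: 47 prefectures plus an optional nationwide
#' unit, three sex groups, triennial waves, and per-sex distributions of the
#' true logit-scale trend parameters. Defaults emulate the observed panel:
#' baseline (2013) coverage centered near 42% overall (lower for women,
#' higher for men), positive slopes with the female mean slope exceeding the
#' male mean, and residual logit-scale noise of 0.05 (about 1 pp of
#' wave-to-wave jitter at 50% coverage).
#'
#' @param n_prefectures Number of prefecture units (default 47).
#' @param include_nationwide Add a nationwide unit (default `TRUE`).
#' @param sexes Sex groups to generate (default all three).
#' @param survey_years Survey waves (default 2013, 2016, 2019, 2022).
#' @param alpha_mean,alpha_sd Per-sex mean (named vector) and common sd of
#'   the true baseline logit-coverage.
#' @param beta_mean,beta_sd Per-sex mean and common sd of the true slope
#'   (logit units/year).
#' @param sigma True residual sd (logit units, default 0.05).
#' @param positive_slopes Truncate true slopes at zero (default `TRUE`),
#'   matching the observed uniformly upward trends.
#' @param seed Master RNG seed; each unit gets a stable substream so adding
#'   units does not perturb existing ones.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_prefectures = 47L,
                             include_nationwide = TRUE,
                             sexes = c("total", "men", "women"),
                             survey_years = c(2013L, 2016L, 2019L, 2022L),
                             alpha_mean = c(total = -0.31, men = -0.10,
                                            women = -0.52),
                             alpha_sd = 0.30,
                             beta_mean = c(total = 0.033, men = 0.025,
                                           women = 0.041),
                             beta_sd = 0.012,
                             sigma = 0.05,
                             positive_slopes = TRUE,
                             seed = 1L) {
  sexes <- match.arg(sexes, SEX_LEVELS, several.ok = TRUE)
  survey_years <- sort(as.integer(survey_years))
  stopifnot(length(survey_years) >= 2L, n_prefectures >= 0L,
            sigma >= 0, alpha_sd >= 0, beta_sd >= 0,
            all(sexes %in% names(alpha_mean)),
            all(sexes %in% names(beta_mean)))
  structure(list(n_prefectures = as.integer(n_prefectures),
                 include_nationwide = isTRUE(include_nationwide),
                 sexes = sexes, survey_years = survey_years,
                 alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                 beta_mean = beta_mean, beta_sd = beta_sd,
                 sigma = sigma, positive_slopes = positive_slopes,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  while (any(bad <- out <= 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Generate a synthetic coverage panel with known ground truth
#'
#' Draws per-(unit, sex) true parameters from the configured distributions
#' and observations from the model
#' `coverage = inv_logit(alpha + beta * offset + N(0, sigma))`, offsets
#' centered on the first survey wave. Deterministic under the configured
#' seed; each unit uses its own substream, so the first `k` units are
#' identical regardless of `n_prefectures`.
#'
#' @param config A [synthetic_config()].
#' @return List with `series` (list of [coverage_series]) and `truth`
#'   (data frame of `unit`, `sex`, `alpha_true`, `beta_true`, `sigma_true`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  units <- character(0)
  if (config$n_prefectures > 0)
    units <- sprintf("P%02d", seq_len(config$n_prefectures))
  if (config$include_nationwide) units <- c("nationwide", units)
  offs <- config$survey_years - config$survey_years[1L]

  set.seed(config$seed)
  unit_seeds <- sample.int(.Machine$integer.max - 1L, length(units))

  series <- list()
  truth <- list()
  for (i in seq_along(units)) {
    set.seed(unit_seeds[i])
    for (sx in config$sexes) {
      a <- rnorm(1, config$alpha_mean[[sx]], config$alpha_sd)
      b <- if (config$positive_slopes)
        rtrunc_norm_pos(1, config$beta_mean[[sx]], config$beta_sd)
      else rnorm(1, config$beta_mean[[sx]], config$beta_sd)
      eps <- if (config$sigma > 0)
        rnorm(length(offs), 0, config$sigma) else numeric(length(offs))
      cov <- inv_logit(a + b * offs + eps)
      series[[length(series) + 1L]] <-
        coverage_series(units[i], sx, config$survey_years, cov)
      truth[[length(truth) + 1L]] <- data.frame(
        unit = units[i], sex = sx, alpha_true = a, beta_true = b,
        sigma_true = config$sigma, stringsAsFactors = FALSE)
    }
  }
  list(series = series, truth = do.call(rbind, truth))
}

#' Parameter-recovery experiment
#'
#' Generates replicate synthetic panels, fits the trend model to every
#' series, and records whether the true intercept and slope fall inside
#' their 95% posterior intervals, whether the posterior-mean slope has the
#' true sign, and whether the APC interval contains zero. This is the
#' calibration harness for the sampler.
#'
#' @param config A [synthetic_config()]; replicate `r` uses seed
#'   `config$seed + r - 1`.
#' @param priors,mcmc_config Passed to [fit_trend()] (seeds derived per
#'   series).
#' @param n_replicates Number of generated panels (default 1).
#' @param level Credible level (default 0.95).
#' @return List of class `recovery_report`: per-series `results` data frame
#'   and the aggregate rates `alpha_coverage`, `beta_coverage`,
#'   `sign_recovery`, `apc_includes_zero`.
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                priors = prior_spec(),
                                mcmc_config = screentrend::mcmc_config(),
                                n_replicates = 1L, level = 0.95) {
  stopifnot(n_replicates >= 1L)
  pr <- (1 - level) / 2
  rows <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + r - 1L)
    dat <- generate_dataset(cfg)
    for (i in seq_along(dat$series)) {
      s <- dat$series[[i]]
      tru <- dat$truth[i, ]
      mc <- mcmc_config
      mc$seed <- series_seed(mcmc_config$seed, s$unit, s$sex, salt = r)
      fit <- fit_trend(s, priors, mc)
      aq <- quantile(fit$alpha, c(pr, 1 - pr), names = FALSE)
      bq <- quantile(fit$beta, c(pr, 1 - pr), names = FALSE)
      av <- apc_draws(fit)
      apq <- quantile(av, c(pr, 1 - pr), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, unit = s$unit, sex = s$sex,
        alpha_true = tru$alpha_true, beta_true = tru$beta_true,
        alpha_mean = mean(fit$alpha), beta_mean = mean(fit$beta),
        alpha_lo = aq[1], alpha_hi = aq[2],
        beta_lo = bq[1], beta_hi = bq[2],
        apc_lo = apq[1], apc_hi = apq[2],
        alpha_covered = tru$alpha_true >= aq[1] & tru$alpha_true <= aq[2],
        beta_covered = tru$beta_true >= bq[1] & tru$beta_true <= bq[2],
        sign_ok = sign(mean(fit$beta)) == sign(tru$beta_true) |
          tru$beta_true == 0,
        apc_zero_in = apq[1] <= 0 & apq[2] >= 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  structure(list(results = res,
                 alpha_coverage = mean(res$alpha_covered),
                 beta_coverage = mean(res$beta_covered),
                 sign_recovery = mean(res$sign_ok),
                 apc_includes_zero = mean(res$apc_zero_in),
                 level = level, n_series = nrow(res)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf(paste0("<recovery_report> %d series, %.0f%% intervals\n",
                     "  alpha coverage %.3f   beta coverage %.3f\n",
                     "  slope-sign recovery %.3f   APC interval contains 0:",
                     " %.3f\n"),
              x$n_series, 100 * x$level, x$alpha_coverage, x$beta_coverage,
              x$sign_recovery, x$apc_includes_zero))
  invisible(x)
}
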