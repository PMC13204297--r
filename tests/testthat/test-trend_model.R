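test_that("logit and inverse-logit behave on and off the boundary", {
  expect_identical(logit(0.5), 0)
  expect_equal(logit(0.423), -0.3104701, tolerance = 1e-6)
  expect_equal(inv_logit(logit(0.697)), 0.697)
  expect_error(logit(0), "0 < p < 1")
  expect_error(logit(1), "0 < p < 1")
  expect_error(logit(c(0.5, 1.2)))
})

test_that("center_years anchors offsets on the baseline wave", {
  s4 <- nationwide_like_series()
  expect_equal(center_years(s4),
               list(offsets = c(0L, 3L, 6L, 9L), center_year = 2013L))
  s1 <- coverage_series("A", "total", 2013L, 0.5)
  expect_equal(center_years(s1)$offsets, 0L)
  s3 <- coverage_series("A", "total", c(2013L, 2016L, 2019L),
                        c(0.42, 0.45, 0.47))
  expect_equal(center_years(s3)$offsets, c(0L, 3L, 6L))
})

test_that("configuration objects validate their fields", {
  expect_error(mcmc_config(iterations = 100, burn_in = 100))
  expect_error(mcmc_config(chains = 0))
  expect_error(prior_spec(intercept_sd = 0))
  expect_error(nig_prior(shape = -1))
  cfg <- mcmc_config()
  expect_equal(cfg$chains * (cfg$iterations - cfg$burn_in), 30000L)
})

test_that("fit_trend is seed-deterministic and structurally sound", {
  s <- nationwide_like_series()
  f1 <- fit_trend(s, config = quick_config(seed = 11L))
  f2 <- fit_trend(s, config = quick_config(seed = 11L))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$sigma, f2$sigma)
  f3 <- fit_trend(s, config = quick_config(seed = 12L))
  expect_false(identical(f1$alpha, f3$alpha))
  expect_length(f1$alpha, 2L * 2000L)
  expect_true(all(f1$sigma > 0))
  expect_error(fit_trend(coverage_series("A", "total", 2013L, 0.5)),
               "at least 2")
})

test_that("shifting all years leaves the fit unchanged after centering", {
  s <- nationwide_like_series()
  shifted <- coverage_series(s$unit, s$sex, s$years + 300L, s$coverage)
  f1 <- fit_trend(s, config = quick_config(seed = 3L))
  f2 <- fit_trend(shifted, config = quick_config(seed = 3L))
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$beta, f2$beta)
  expect_equal(f2$center_year, 2313L)
})

test_that("a flat series yields posterior centered on no trend", {
  s <- coverage_series("flat", "total", c(2013, 2016, 2019, 2022),
                       rep(0.5, 4))
  f <- fit_trend(s, config = quick_config(seed = 5L))
  expect_lt(abs(mean(f$alpha)), 0.05)
  expect_lt(abs(mean(f$beta)), 0.02)
})

test_that("vague-prior MCMC matches the conjugate closed form", {
  np <- nig_prior(coef_precision = diag(1e-6, 2), shape = 3, rate = 0.1)
  series <- list(
    nationwide_like_series(),
    coverage_series("B", "women", c(2013, 2016, 2019, 2022),
                    c(0.374, 0.41, 0.44, 0.464)))
  for (i in seq_along(series)) {
    s <- series[[i]]
    fit <- fit_trend(s, np, quick_config(seed = 20L + i))
    ex <- conjugate_posterior(s, np)
    for (j in 1:2) {
      par <- c("alpha", "beta")[j]
      draws <- fit[[par]]
      expect_lt(abs(mean(draws) - ex$coef_mean[j]),
                3 * mcse_mean(fit, par))
      expect_lt(abs(sd(draws) - ex$coef_sd[j]), 3 * mcse_sd(fit, par))
    }
  }
})

test_that("conjugate_posterior reduces to least squares when vague", {
  s <- nationwide_like_series()
  cp <- conjugate_posterior(s, nig_prior(coef_precision = diag(1e-9, 2),
                                         shape = 1e-9, rate = 1e-9))
  ols <- lm(logit(s$coverage) ~ I(s$years - s$years[1]))
  expect_equal(unname(cp$coef_mean), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(unname(cp$coef_sd), unname(sqrt(diag(vcov(ols)))),
               tolerance = 1e-4)
})

test_that("posterior means under vague independent priors match OLS", {
  # the sigma prior cannot move the coefficient means when their own
  # priors are flat, whatever its family
  s <- nationwide_like_series()
  vague <- prior_spec(intercept_sd = 100, slope_sd = 100,
                      residual_sd_scale = 1)
  fit <- fit_trend(s, vague, quick_config(seed = 31L))
  ols <- coef(lm(logit(s$coverage) ~ I(s$years - s$years[1])))
  expect_lt(abs(mean(fit$alpha) - ols[[1]]), 3 * mcse_mean(fit, "alpha"))
  expect_lt(abs(mean(fit$beta) - ols[[2]]), 3 * mcse_mean(fit, "beta"))
})

test_that("split-chain diagnostic separates mixed from stuck chains", {
  set.seed(1)
  iid <- lapply(1:3, function(i)
    matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("a", "b"))))
  rep_ok <- check_convergence(iid)
  expect_true(all(rep_ok$rhat$rhat < 1.01))
  expect_false(rep_ok$flagged)
  # chains sampling different modes must be flagged, by direct formula
  bad <- list(matrix(rnorm(2000, 0), ncol = 1,
                     dimnames = list(NULL, "a")),
              matrix(rnorm(2000, 10), ncol = 1,
                     dimnames = list(NULL, "a")))
  rep_bad <- check_convergence(bad)
  expect_gt(rep_bad$rhat$rhat, 2)
  expect_true(rep_bad$flagged)
  expect_warning(one <- check_convergence(bad[1]), "2 chains")
  expect_true(is.na(one$flagged))
})

test_that("ess and mcse are sane for independent draws", {
  set.seed(2)
  x <- rnorm(10000)
  expect_gt(ess_mean(x), 5000)
  expect_lt(mcse_mean(x), 3 * sd(x) / sqrt(10000))
})
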