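# shared builders for the test suite

# a 4-wave series resembling the nationwide total trajectory
nationwide_like_series <- function(unit = "nationwide", sex = "total") {
  coverage_series(unit, sex, c(2013L, 2016L, 2019L, 2022L),
                  c(0.423, 0.450, 0.472, 0.497))
}

# a trend_fit stand-in with hand-set draw vectors, for exact projection math
make_fit <- function(alpha, beta, sigma = rep(0.05, length(alpha)),
                     center_year = 2013L, unit = "toy", sex = "total") {
  n <- max(length(alpha), length(beta))
  structure(list(alpha = rep_len(alpha, n), beta = rep_len(beta, n),
                 sigma = rep_len(sigma, n), chains = NULL,
                 center_year = as.integer(center_year),
                 unit = unit, sex = sex, acceptance = NA_real_,
                 convergence = NULL),
            class = "trend_fit")
}

# fast MCMC settings for unit tests (acceptance tests use the full config)
quick_config <- function(seed = 1L) {
  mcmc_config(chains = 2L, iterations = 2500L, burn_in = 500L, seed = seed)
}

# a small coverage CSV on disk; returns the path
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("unit,sex,year,coverage_pct", rows), path)
  path
}

# independent brute-force target-year scan used as the projection oracle
grid_scan_target_year <- function(fit, threshold, prob_level,
                                  horizon_max = 2100) {
  for (y in seq.int(fit$center_year, horizon_max)) {
    p <- mean(inv_logit(fit$alpha + fit$beta * (y - fit$center_year)) >=
                threshold)
    if (p >= prob_level) return(y)
  }
  "never"
}

# Monte Carlo standard error of a posterior sd: delta method with the
# empirical kurtosis (heavy-tailed t marginals make the Gaussian 1/sqrt(2n)
# rule too small)
mcse_sd <- function(fit, param) {
  chains <- lapply(fit$chains, function(m) m[, param])
  ess <- sum(vapply(chains, ess_mean, 0))
  x <- unlist(chains)
  kurt <- mean((x - mean(x))^4) / sd(x)^4
  sd(x) * sqrt(max(kurt - 1, 2) / (4 * ess))
}
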