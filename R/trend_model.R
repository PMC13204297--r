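#' Logit and inverse-logit transforms
#'
#' The trend model is linear on the logit scale: `logit(p) = log(p/(1-p))`.
#' `inv_logit()` is its inverse `1/(1+exp(-x))`.
#'
#' @param p Proportion(s) strictly inside (0, 1).
#' @param x Real number(s).
#' @return Numeric vector.
#' @examples
#' logit(0.5)              # 0
#' inv_logit(logit(0.697)) # 0.697
#' @export
logit <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("logit requires 0 < p < 1")
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Center survey years on the baseline wave
#'
#' Centering on the earliest training year makes the intercept the
#' logit-scale coverage at baseline and reduces intercept-slope correlation.
#'
#' @param series A [coverage_series].
#' @return List with `offsets` (years minus baseline) and `center_year`.
#' @examples
#' s <- coverage_series("A", "total", c(2013, 2016, 2019, 2022),
#'                      rep(0.5, 4))
#' center_years(s)  # offsets 0, 3, 6, 9; center 2013
#' @export
center_years <- function(series) {
  stopifnot(inherits(series, "coverage_series"), length(series$years) >= 1L)
  cy <- series$years[1L]
  list(offsets = series$years - cy, center_year = cy)
}

#' Weakly informative prior for the trend model
#'
#' Independent normal priors on the logit-scale intercept and slope and a
#' half-Normal prior on the residual standard deviation. The defaults span
#' baseline coverage of roughly 7-93% at one intercept prior sd and
#' implausibly steep annual trends at one slope prior sd.
#'
#' @param intercept_mean,intercept_sd Normal prior on the intercept
#'   (logit units). Defaults 0, 2.5.
#' @param slope_mean,slope_sd Normal prior on the slope (logit units per
#'   year). Defaults 0, 1.
#' @param residual_sd_scale Scale of the half-Normal prior on sigma.
#'   Default 1.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_mean = 0, intercept_sd = 2.5,
                       slope_mean = 0, slope_sd = 1,
                       residual_sd_scale = 1) {
  stopifnot(intercept_sd > 0, slope_sd > 0, residual_sd_scale > 0)
  structure(list(intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 residual_sd_scale = residual_sd_scale),
            class = "prior_spec")
}

#' Normal-inverse-gamma prior for the trend model
#'
#' Conjugate alternative to [prior_spec()]: coefficients are
#' `N(coef_mean, sigma2 * solve(coef_precision))` given the residual
#' variance, and `sigma2 ~ InvGamma(shape, rate)`. Under this prior the
#' posterior has a closed form ([conjugate_posterior()]), which serves as an
#' independent oracle for the MCMC sampler.
#'
#' @param coef_mean Length-2 prior mean (intercept, slope).
#' @param coef_precision 2x2 prior precision matrix (relative to sigma2).
#' @param shape,rate Inverse-gamma hyperparameters for sigma2.
#' @return An object of class `nig_prior`.
#' @export
nig_prior <- function(coef_mean = c(0, 0),
                      coef_precision = diag(1e-6, 2),
                      shape = 2, rate = 0.5) {
  stopifnot(length(coef_mean) == 2L, all(dim(coef_precision) == c(2L, 2L)),
            shape > 0, rate > 0)
  structure(list(coef_mean = as.numeric(coef_mean),
                 coef_precision = coef_precision,
                 shape = shape, rate = rate),
            class = "nig_prior")
}

#' MCMC sampler configuration
#'
#' @param chains Number of chains (default 3).
#' @param iterations Iterations per chain (default 12000).
#' @param burn_in Draws discarded per chain (default 2000), during which the
#'   proposal is adapted; with the defaults the pooled posterior sample has
#'   3 x 10000 = 30000 draws.
#' @param seed Integer RNG seed.
#' @param target_accept Target acceptance rate of the adaptive random-walk
#'   proposal (default 0.3).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iterations = 12000L, burn_in = 2000L,
                        seed = 1L, target_accept = 0.3) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  stopifnot(chains >= 1L, iterations > burn_in, burn_in >= 0L,
            target_accept > 0, target_accept < 1)
  structure(list(chains = chains, iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed), target_accept = target_accept),
            class = "mcmc_config")
}

# deterministic 31-bit hash of a series identity; used to derive per-series
# MCMC seeds that do not depend on the order series are processed in
series_seed <- function(base_seed, unit, sex, salt = 0L) {
  h <- Reduce(function(a, ch) (a * 31 + ch) %% 2147483647,
              utf8ToInt(paste(unit, sex, sep = "/")), 17)
  as.integer((base_seed * 7919 + h + salt * 104729) %% 2147483647)
}

prior_to_cpp <- function(priors) {
  if (inherits(priors, "prior_spec")) {
    list(type = 0L,
         par = c(priors$intercept_mean, priors$intercept_sd,
                 priors$slope_mean, priors$slope_sd,
                 priors$residual_sd_scale))
  } else if (inherits(priors, "nig_prior")) {
    P <- priors$coef_precision
    list(type = 1L,
         par = c(priors$coef_mean, P[1, 1], P[1, 2], P[2, 1], P[2, 2],
                 priors$shape, priors$rate))
  } else stop("priors must be a prior_spec or nig_prior")
}

#' Fit the Bayesian logit-linear trend model to one series
#'
#' Fits `logit(coverage) = alpha + beta * (year - center_year) + eps`,
#' `eps ~ N(0, sigma^2)`, by a collapsed adaptive Metropolis sampler: the
#' Gaussian coefficients are integrated out analytically, an adaptive
#' random walk targets the marginal posterior of `log(sigma)` (step size
#' adapted during burn-in only), and `(alpha, beta)` are drawn exactly from
#' their conditional bivariate normal at every kept iteration. Kept draws
#' are pooled across chains. Identical inputs and seed give bit-identical
#' draws.
#'
#' @param series A [coverage_series] with at least 2 observations.
#' @param priors A [prior_spec()] (default) or [nig_prior()].
#' @param config An [mcmc_config()].
#' @return An object of class `trend_fit` with pooled draw vectors `alpha`,
#'   `beta`, `sigma`, per-chain kept-draw matrices `chains`, `center_year`,
#'   `unit`, `sex`, per-chain `acceptance` rates and a `convergence` report
#'   (see [check_convergence()]).
#' @export
fit_trend <- function(series, priors = prior_spec(), config = mcmc_config()) {
  stopifnot(inherits(series, "coverage_series"),
            inherits(config, "mcmc_config"))
  if (length(series$years) < 2L)
    stop("at least 2 observations are required to fit a trend")
  cen <- center_years(series)
  x <- as.numeric(cen$offsets)
  y <- logit(series$coverage)
  if (any(!is.finite(y))) stop("non-finite logit-transformed coverage")
  pr <- prior_to_cpp(priors)

  # least-squares start, shared by all chains; dispersed by the adaptive
  # proposal within a few iterations
  # least-squares residual scale as the log-sigma starting point
  fit0 <- lm(y ~ x)
  res_sd <- sd(residuals(fit0))
  if (!is.finite(res_sd) || res_sd < 1e-4) res_sd <- 1e-2

  set.seed(config$seed)
  chains <- vector("list", config$chains)
  acc <- numeric(config$chains)
  for (k in seq_len(config$chains)) {
    out <- rw_chain(x, y, pr$type, pr$par, config$iterations, config$burn_in,
                    config$target_accept, log(res_sd), 1.0)
    m <- out$draws
    colnames(m) <- c("alpha", "beta", "sigma")
    chains[[k]] <- m
    acc[k] <- out$accept_rate
  }
  pooled <- do.call(rbind, chains)
  conv <- if (config$chains >= 2L) check_convergence(chains, acceptance = acc)
          else NULL
  structure(list(alpha = pooled[, "alpha"], beta = pooled[, "beta"],
                 sigma = pooled[, "sigma"], chains = chains,
                 center_year = cen$center_year,
                 unit = series$unit, sex = series$sex,
                 acceptance = acc, convergence = conv,
                 priors = priors, config = config),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s / %s  (center year %d, %d pooled draws)\n",
              x$unit, x$sex, x$center_year, length(x$alpha)))
  s <- rbind(alpha = c(mean(x$alpha), sd(x$alpha)),
             beta = c(mean(x$beta), sd(x$beta)),
             sigma = c(mean(x$sigma), sd(x$sigma)))
  colnames(s) <- c("mean", "sd")
  print(round(s, 4))
  if (!is.null(x$convergence) && x$convergence$flagged)
    cat("warning: split-chain diagnostic exceeds 1.01\n")
  invisible(x)
}

split_rhat <- function(mat_list, param) {
  halves <- list()
  for (m in mat_list) {
    v <- m[, param]
    n2 <- floor(length(v) / 2)
    halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  B <- n * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Split-chain convergence diagnostic
#'
#' Computes the split-chain potential scale reduction statistic for each
#' parameter: every chain is split in half and between/within-half variances
#' are compared. Values near 1 indicate the chains are mixing over the same
#' distribution; any value above 1.01 is flagged.
#'
#' @param chains List of per-chain draw matrices (columns = parameters), or a
#'   `trend_fit`.
#' @param acceptance Optional per-chain acceptance rates to carry along.
#' @param threshold Flagging threshold (default 1.01).
#' @return An object of class `convergence_report`: data frame `rhat` with
#'   one row per parameter, logical `flagged`, `acceptance`.
#' @export
check_convergence <- function(chains, acceptance = NULL, threshold = 1.01) {
  if (inherits(chains, "trend_fit")) {
    acceptance <- chains$acceptance
    chains <- chains$chains
  }
  stopifnot(is.list(chains), length(chains) >= 1L)
  if (length(chains) < 2L) {
    warning("split-chain diagnostic requires >= 2 chains; returning NA")
    params <- colnames(chains[[1L]])
    rh <- data.frame(param = params, rhat = NA_real_)
    return(structure(list(rhat = rh, flagged = NA, acceptance = acceptance,
                          threshold = threshold),
                     class = "convergence_report"))
  }
  params <- colnames(chains[[1L]])
  if (is.null(params)) params <- paste0("p", seq_len(ncol(chains[[1L]])))
  for (m in chains) stopifnot(ncol(m) == length(params))
  rh <- vapply(seq_along(params), function(j) split_rhat(chains, j), 0)
  rep <- data.frame(param = params, rhat = rh, stringsAsFactors = FALSE)
  structure(list(rhat = rep, flagged = any(rh > threshold),
                 acceptance = acceptance, threshold = threshold),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("<convergence_report> split-chain potential scale reduction\n")
  print(transform(x$rhat, rhat = round(rhat, 4)), row.names = FALSE)
  if (isTRUE(x$flagged)) cat(sprintf("FLAGGED: > %.2f\n", x$threshold))
  invisible(x)
}

#' Exact posterior under the normal-inverse-gamma prior
#'
#' Closed-form conjugate posterior for the trend model under a [nig_prior()]:
#' the coefficient marginals are Student-t. With a vague prior this reduces
#' to the classical least-squares solution, which makes it an independent
#' oracle for the MCMC sampler.
#'
#' @param series A [coverage_series].
#' @param prior A [nig_prior()].
#' @return List: `coef_mean` and `coef_sd` (intercept, slope), posterior
#'   precision `precision`, inverse-gamma `shape` and `rate` for sigma2,
#'   Student-t `df`, and `center_year`.
#' @export
conjugate_posterior <- function(series, prior = nig_prior()) {
  stopifnot(inherits(series, "coverage_series"), inherits(prior, "nig_prior"))
  cen <- center_years(series)
  X <- cbind(1, as.numeric(cen$offsets))
  y <- logit(series$coverage)
  n <- length(y)
  P0 <- prior$coef_precision
  m0 <- prior$coef_mean
  Pn <- P0 + crossprod(X)
  Vn <- solve(Pn)
  mn <- drop(Vn %*% (P0 %*% m0 + crossprod(X, y)))
  an <- prior$shape + n / 2
  bn <- prior$rate + 0.5 * (sum(y^2) + drop(t(m0) %*% P0 %*% m0) -
                              drop(t(mn) %*% Pn %*% mn))
  df <- 2 * an
  scale2 <- (bn / an) * diag(Vn)
  coef_sd <- if (df > 2) sqrt(scale2 * df / (df - 2)) else rep(Inf, 2)
  list(coef_mean = setNames(mn, c("alpha", "beta")),
       coef_sd = setNames(coef_sd, c("alpha", "beta")),
       precision = Pn, shape = an, rate = bn, df = df,
       center_year = cen$center_year)
}

#' Effective sample size and Monte Carlo standard error
#'
#' `ess_mean()` estimates the effective sample size of a single chain via
#' Geyer's initial positive sequence on the empirical autocorrelations;
#' `mcse_mean()` turns it into a Monte Carlo standard error for a posterior
#' mean, summing ESS across chains when given a list.
#'
#' @param x Numeric vector (one chain) for `ess_mean`; a vector, a list of
#'   chain vectors, or a `trend_fit` plus parameter name for `mcse_mean`.
#' @param param Parameter name when `x` is a `trend_fit`.
#' @return Scalar ESS or MCSE.
#' @export
ess_mean <- function(x) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  lag_max <- min(n - 1L, 2000L)
  rho <- drop(acf(x, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)[-1L]
  # Geyer: sum consecutive-pair autocorrelations while positive
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    s <- s + g
  }
  ess <- n / (1 + 2 * s)
  max(1, min(ess, n))
}

#' @rdname ess_mean
#' @export
mcse_mean <- function(x, param = NULL) {
  if (inherits(x, "trend_fit")) {
    stopifnot(!is.null(param))
    chains <- lapply(x$chains, function(m) m[, param])
  } else if (is.list(x)) chains <- x else chains <- list(x)
  pooled <- unlist(chains, use.names = FALSE)
  ess <- sum(vapply(chains, ess_mean, 0))
  sd(pooled) / sqrt(ess)
}
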