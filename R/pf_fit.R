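#' Aggregate trial-level data to binomial counts per stimulus value
#'
#' @param trials Data frame with columns `stimulus` and `response`
#'   (logical or 0/1). Rows flagged `is_practice` are dropped.
#' @return Data frame `x`, `n`, `k` (trials and correct counts per
#'   unique stimulus value).
#' @export
pf_trials_aggregate <- function(trials) {
  if ("is_practice" %in% names(trials))
    trials <- trials[!trials$is_practice, , drop = FALSE]
  if (nrow(trials) == 0)
    return(data.frame(x = 0, n = 0L, k = 0L))
  x <- trials$stimulus
  r <- as.integer(trials$response)
  ux <- sort(unique(x))
  data.frame(x = ux,
             n = as.integer(tapply(r, factor(x, levels = ux), length)),
             k = as.integer(tapply(r, factor(x, levels = ux), sum)))
}

#' Maximum-likelihood psychometric fit (midpoint and slope)
#'
#' Quick two-parameter fit used to centre priors: the lapse rate is held
#' at a small fixed value for stability and the guess rate at its known
#' value; midpoint and log-slope are optimized by `optim`.
#'
#' @param trials Trial data frame (see [pf_trials_aggregate]).
#' @param guess Fixed guess rate.
#' @param lapse_fixed Fixed lapse rate (default 0.02).
#' @param start Optional starting values `c(midpoint, slope)`.
#' @return Named vector `c(midpoint, slope)`.
#' @export
pf_ml_fit <- function(trials, guess, lapse_fixed = 0.02, start = NULL) {
  agg <- pf_trials_aggregate(trials)
  if (sum(agg$n) == 0) stop("no trials to fit")
  if (sum(agg$k) == 0 || sum(agg$k) == sum(agg$n))
    stop("degenerate track: all responses identical")
  if (is.null(start)) {
    start <- c(stats::weighted.mean(agg$x, agg$n),
               2 / max(diff(range(agg$x)), 1e-3))
  }
  nll <- function(par) {
    a <- par[1]
    b <- exp(par[2])
    F <- stats::plogis(b * (agg$x - a))
    p <- guess + (1 - guess - lapse_fixed) * F
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log1p(-p))
  }
  opt <- stats::optim(c(start[1], log(start[2])), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 500))
  c(midpoint = opt$par[1], slope = exp(opt$par[2]))
}

#' Empirical prior centres from preliminary ML fits
#'
#' Fits each track by maximum likelihood (lapse fixed) and averages the
#' midpoint and slope estimates across tracks. Tracks with all-correct
#' or all-incorrect responses carry no information about either
#' parameter and are excluded with a warning.
#'
#' @param tracks List of trial data frames for one condition (>= 2).
#' @param guess Fixed guess rate.
#' @param lapse_fixed Fixed lapse used in the ML fits.
#' @return Named vector `c(midpoint, slope)` of across-track averages.
#' @export
empirical_prior_centers <- function(tracks, guess, lapse_fixed = 0.02) {
  stopifnot(is.list(tracks), length(tracks) >= 2)
  fits <- lapply(tracks, function(tr)
    tryCatch(pf_ml_fit(tr, guess, lapse_fixed),
             error = function(e) NULL))
  bad <- vapply(fits, is.null, logical(1))
  if (any(bad))
    warning(sum(bad), " degenerate track(s) excluded from prior centring")
  fits <- fits[!bad]
  if (length(fits) == 0)
    stop("all tracks degenerate; cannot centre priors")
  m <- do.call(rbind, fits)
  c(midpoint = mean(m[, "midpoint"]), slope = mean(m[, "slope"]))
}

#' Prior specification for a psychometric-function fit
#'
#' Normal prior on the midpoint (on the task's linear or log stimulus
#' axis), gamma priors on the slope and on the lapse rate, the latter
#' truncated above (default 0.2) to prevent lapse/midpoint confounding
#' on short tracks; the guess rate is fixed, never sampled.
#'
#' @param midpoint_mean,midpoint_sd Normal prior on the midpoint.
#' @param slope_shape,slope_rate Gamma prior on the slope.
#' @param lapse_shape,lapse_rate Gamma prior on the lapse rate.
#' @param lapse_upper Upper truncation of the lapse prior.
#' @param guess Fixed guess rate.
#' @return Object of class `pf_prior`.
#' @export
pf_prior_spec <- function(midpoint_mean, midpoint_sd,
                          slope_shape = 2, slope_rate = 2,
                          lapse_shape = 1.2, lapse_rate = 12,
                          lapse_upper = 0.2, guess = 0.5) {
  stopifnot(midpoint_sd > 0, slope_shape > 0, slope_rate > 0,
            lapse_shape > 0, lapse_rate > 0,
            lapse_upper > 0, lapse_upper < 1,
            guess >= 0, guess < 1)
  structure(list(midpoint_mean = midpoint_mean,
                 midpoint_sd = midpoint_sd,
                 slope_shape = slope_shape, slope_rate = slope_rate,
                 lapse_shape = lapse_shape, lapse_rate = lapse_rate,
                 lapse_upper = lapse_upper, guess = guess),
            class = "pf_prior")
}

#' MCMC settings for psychometric-function fits
#'
#' The default effective-sample-size floor of 10,000 matches the
#' convention used for the main parameters of interest in the analyses
#' this package implements; validation suites lower it for speed.
#'
#' @param n_chains,n_adapt,n_burn,n_iter,thin Standard MCMC controls
#'   (`n_iter` is post-burn iterations per chain).
#' @param ess_floor Minimum effective sample size per parameter.
#' @param rhat_max Maximum split Gelman-Rubin statistic.
#' @param max_retries Times to double `n_iter` on failed diagnostics.
#' @return List of settings.
#' @export
pf_fit_settings <- function(n_chains = 4, n_adapt = 500, n_burn = 500,
                            n_iter = 10000, thin = 1,
                            ess_floor = 10000, rhat_max = 1.01,
                            max_retries = 2) {
  list(n_chains = n_chains, n_adapt = n_adapt, n_burn = n_burn,
       n_iter = n_iter, thin = thin, ess_floor = ess_floor,
       rhat_max = rhat_max, max_retries = max_retries)
}

.pf_jags_model <- "model {
  for (j in 1:J) {
    F[j] <- 1 / (1 + exp(-beta * (x[j] - alpha)))
    p[j] <- guess + (1 - guess - lambda) * F[j]
    k[j] ~ dbin(p[j], n[j])
  }
  alpha ~ dnorm(a_mean, pow(a_sd, -2))
  beta ~ dgamma(b_shape, b_rate)
  lambda ~ dgamma(l_shape, l_rate) T(0, l_upper)
}"

#' Bayesian psychometric-function refit by MCMC
#'
#' Post-hoc refit of an adaptive track (typically the pooled 160
#' responses of two 80-trial blocks): joint posterior over midpoint,
#' slope and lapse rate under a Bernoulli likelihood with the guess rate
#' fixed, sampled with JAGS. Convergence is checked with the
#' Gelman-Rubin statistic and the effective sample size; on failure the
#' chain length is doubled up to `max_retries` times, after which the
#' fit is flagged unconverged (downstream consumers exclude flagged
#' fits). Fitted midpoints may fall beyond the physically presentable
#' stimulus range (e.g. AM depths above 100%); they are reported
#' untruncated, since listeners genuinely unable to do the task are
#' informative about the analysis scale.
#'
#' @param trials Trial data frame with `stimulus`, `response` (practice
#'   rows dropped).
#' @param priors A [pf_prior_spec].
#' @param settings See [pf_fit_settings].
#' @param seed Integer seed for the JAGS RNGs.
#' @return Object of class `pf_fit`: `draws` (a `coda::mcmc.list` over
#'   `alpha`, `beta`, `lambda`), `rhat`, `ess`, `converged`, `priors`,
#'   and the aggregated data.
#' @export
fit_pf <- function(trials, priors, settings = pf_fit_settings(),
                   seed = 1) {
  stopifnot(inherits(priors, "pf_prior"))
  agg <- pf_trials_aggregate(trials)
  dat <- list(J = nrow(agg), x = agg$x, n = agg$n, k = agg$k,
              guess = priors$guess,
              a_mean = priors$midpoint_mean, a_sd = priors$midpoint_sd,
              b_shape = priors$slope_shape, b_rate = priors$slope_rate,
              l_shape = priors$lapse_shape, l_rate = priors$lapse_rate,
              l_upper = priors$lapse_upper)
  n_iter <- settings$n_iter
  for (attempt in 0:settings$max_retries) {
    inits <- lapply(seq_len(settings$n_chains), function(i)
      list(alpha = priors$midpoint_mean +
             priors$midpoint_sd * (i - (settings$n_chains + 1) / 2) / 2,
           beta = priors$slope_shape / priors$slope_rate,
           lambda = min(0.02, priors$lapse_upper / 2),
           .RNG.name = "base::Mersenne-Twister",
           .RNG.seed = seed + i + 1000L * attempt))
    m <- rjags::jags.model(textConnection(.pf_jags_model), data = dat,
                           inits = inits,
                           n.chains = settings$n_chains,
                           n.adapt = settings$n_adapt, quiet = TRUE)
    if (settings$n_burn > 0)
      update(m, settings$n_burn, progress.bar = "none")
    draws <- rjags::coda.samples(m, c("alpha", "beta", "lambda"),
                                 n.iter = n_iter,
                                 thin = settings$thin,
                                 progress.bar = "none")
    diag <- .mcmc_diagnostics(draws)
    ok <- (is.na(diag$rhat_max) || diag$rhat_max < settings$rhat_max) &&
      diag$ess_min >= settings$ess_floor
    if (ok || attempt == settings$max_retries) {
      return(structure(list(draws = draws, rhat = diag$rhat,
                            ess = diag$ess, converged = ok,
                            priors = priors, data = agg,
                            settings = settings),
                       class = "pf_fit"))
    }
    n_iter <- n_iter * 2L
  }
}

# main_vars restricts the convergence gates (effective-sample-size
# floor and Gelman-Rubin cutoff) to the main parameters of interest
# (e.g. regression coefficients); diagnostics are still reported for
# every monitored parameter.
.mcmc_diagnostics <- function(draws, main_vars = NULL) {
  ess <- coda::effectiveSize(draws)
  rhat <- if (coda::nchain(draws) >= 2) {
    coda::gelman.diag(draws, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1]
  } else rep(NA_real_, coda::nvar(draws))
  pick <- function(x) if (is.null(main_vars)) x else
    x[intersect(main_vars, names(x))]
  ess_main <- pick(ess)
  rhat_main <- pick(rhat)
  list(ess = ess, ess_min = min(ess_main), rhat = rhat,
       rhat_max = if (all(is.na(rhat_main))) NA_real_ else
         max(rhat_main, na.rm = TRUE))
}

#' Threshold posterior from a psychometric fit
#'
#' Transforms the joint posterior draws into draws of the stimulus value
#' at a requested fraction of the psychometric function's dynamic range
#' (`0.5` = the midpoint; `0.25` = the "1/4 point" used in
#' speech-reception re-analyses) and summarizes them with a central
#' credibility interval.
#'
#' @param fit A [fit_pf] result.
#' @param fraction Fraction of dynamic range (default 0.5).
#' @param level Credibility level (default 0.99).
#' @return List with `draws`, `median`, `lo`, `hi`, `fraction`, `level`.
#' @export
pf_threshold <- function(fit, fraction = 0.5, level = 0.99) {
  stopifnot(inherits(fit, "pf_fit"), fraction > 0, fraction < 1)
  d <- as.matrix(fit$draws)
  th <- d[, "alpha"] + stats::qlogis(fraction) / d[, "beta"]
  qs <- stats::quantile(th, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(draws = th, median = stats::median(th), lo = qs[1], hi = qs[2],
       fraction = fraction, level = level)
}

#' @export
print.pf_fit <- function(x, ...) {
  med <- apply(as.matrix(x$draws), 2, stats::median)
  cat(sprintf(
    "Psychometric MCMC fit (%s): midpoint %.4g, slope %.4g, lapse %.3g\n",
    if (x$converged) "converged" else "NOT CONVERGED",
    med["alpha"], med["beta"], med["lambda"]))
  cat(sprintf("  max Rhat %.4f, min ESS %.0f\n",
              if (all(is.na(x$rhat))) NA else max(x$rhat, na.rm = TRUE),
              min(x$ess)))
  invisible(x)
}
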