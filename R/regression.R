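#' Standardize a continuous predictor
#'
#' Centring and scaling by the sample standard deviation (n-1
#' denominator). Interaction terms are always formed as products of
#' already-standardized parents (the Friedrich convention), never by
#' standardizing a raw product; the stored mean and sd allow
#' unstandardized coefficients to be recovered by scaling.
#'
#' @param x Numeric vector with positive spread.
#' @return List with `z`, `mean`, `sd`.
#' @export
standardize <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  s <- stats::sd(x)
  if (s == 0) stop("cannot standardize a zero-variance column")
  list(z = (x - mean(x)) / s, mean = mean(x), sd = s)
}

#' Unweighted effect coding of a categorical predictor
#'
#' Codes a k-level factor as k-1 columns of {1, -1, 0}: each non-reference
#' level gets an indicator column, and the reference level is coded -1 in
#' every column. Under this coding the intercept is the unweighted grand
#' mean of the level means, and each coefficient is the deviation of one
#' level from that grand mean; the implied deviations over all k levels
#' sum to zero.
#'
#' @param f Vector coercible to factor with at least 2 levels.
#' @param reference Reference level (default: the last level).
#' @return Matrix with one column per non-reference level (named
#'   `<level>`), with attributes `levels`, `reference` and `codes` (the
#'   k x (k-1) matrix of level codes).
#' @export
effect_code <- function(f, reference = NULL) {
  f <- as.factor(f)
  lev <- levels(f)
  if (length(lev) < 2) stop("effect coding requires >= 2 levels")
  if (is.null(reference)) reference <- lev[length(lev)]
  if (!reference %in% lev) stop("unknown reference level")
  keep <- setdiff(lev, reference)
  codes <- matrix(0, nrow = length(lev), ncol = length(keep),
                  dimnames = list(lev, keep))
  for (j in seq_along(keep)) codes[keep[j], j] <- 1
  codes[reference, ] <- -1
  X <- codes[as.character(f), , drop = FALSE]
  rownames(X) <- NULL
  attr(X, "levels") <- lev
  attr(X, "reference") <- reference
  attr(X, "codes") <- codes
  X
}

#' Build a regression design with effect coding and standardization
#'
#' Assembles the design matrix for the robust mixed-effects models: the
#' (optionally log-transformed) outcome in sd units, standardized
#' continuous predictors, unweighted effect codes for categorical
#' predictors, and interaction columns formed as products of the coded /
#' standardized parent columns. Each column is assigned a prior class:
#' `shrinkage` for continuous covariate main effects and for any
#' interaction involving a continuous covariate (the terms of analytical
#' interest), `broad` for the intercept, categorical main effects and
#' factor-by-factor interactions (nuisance structure expected to affect
#' the outcome).
#'
#' @param data Data frame in long format (one row per subject x
#'   condition).
#' @param outcome Name of the outcome column.
#' @param continuous Character vector of continuous predictor columns.
#' @param factors Character vector of categorical predictor columns.
#' @param interactions List of length-2 character vectors naming parent
#'   variables (continuous or factor).
#' @param subject Name of the subject identifier column, or `NULL` for a
#'   model without random effects.
#' @param outcome_transform `"identity"` or `"log"` (natural log applied
#'   before standardization, for ratio-scale thresholds).
#' @param standardize_outcome Standardize the (transformed) outcome
#'   (default `TRUE`, the convention in these models).
#' @param prior_class Optional named character vector overriding the
#'   prior class (`"shrinkage"`/`"broad"`) of specific design columns.
#' @return Object of class `regression_design`: `X`, `y`, `subject`
#'   (integer index or `NULL`), `col_class`, `scaling` (outcome and
#'   predictor means/sds), `factor_codes`, and `meta` describing each
#'   column.
#' @export
build_design <- function(data, outcome, continuous = character(),
                         factors = character(), interactions = list(),
                         subject = "subject",
                         outcome_transform = c("identity", "log"),
                         standardize_outcome = TRUE,
                         prior_class = NULL) {
  outcome_transform <- match.arg(outcome_transform)
  for (v in c(outcome, continuous, factors,
              if (!is.null(subject)) subject))
    if (!v %in% names(data)) stop("column not found in data: ", v)
  y_raw <- data[[outcome]]
  if (outcome_transform == "log") {
    if (any(y_raw <= 0))
      stop("log outcome transform requires positive values")
    y_raw <- log(y_raw)
  }
  if (standardize_outcome) {
    ys <- standardize(y_raw)
    y <- ys$z
    y_scale <- c(mean = ys$mean, sd = ys$sd)
  } else {
    y <- y_raw
    y_scale <- c(mean = 0, sd = 1)
  }

  cols <- list(`(Intercept)` = rep(1, nrow(data)))
  col_class <- c(`(Intercept)` = "broad")
  meta <- list(`(Intercept)` = list(kind = "intercept"))
  x_scale <- list()
  for (v in continuous) {
    s <- standardize(data[[v]])
    cols[[v]] <- s$z
    x_scale[[v]] <- c(mean = s$mean, sd = s$sd)
    col_class[v] <- "shrinkage"
    meta[[v]] <- list(kind = "continuous", var = v)
  }
  factor_codes <- list()
  for (f in factors) {
    X <- effect_code(data[[f]])
    factor_codes[[f]] <- attr(X, "codes")
    for (j in seq_len(ncol(X))) {
      nm <- paste0(f, ".", colnames(X)[j])
      cols[[nm]] <- X[, j]
      col_class[nm] <- "broad"
      meta[[nm]] <- list(kind = "factor", var = f,
                         level = colnames(X)[j])
    }
  }
  expand <- function(v) {
    # names of the design columns representing variable v
    if (v %in% continuous) return(v)
    if (v %in% factors)
      return(paste0(v, ".", colnames(factor_codes[[v]])))
    stop("interaction parent not among predictors: ", v)
  }
  for (ia in interactions) {
    stopifnot(length(ia) == 2)
    for (ca in expand(ia[1])) for (cb in expand(ia[2])) {
      nm <- paste0(ca, ":", cb)
      cols[[nm]] <- cols[[ca]] * cols[[cb]]
      both_factor <- ia[1] %in% factors && ia[2] %in% factors
      col_class[nm] <- if (both_factor) "broad" else "shrinkage"
      meta[[nm]] <- list(kind = "interaction", vars = ia,
                         parent_cols = c(ca, cb))
    }
  }
  if (!is.null(prior_class)) {
    bad <- setdiff(names(prior_class), names(cols))
    if (length(bad)) stop("prior_class names not in design: ",
                          paste(bad, collapse = ", "))
    col_class[names(prior_class)] <- prior_class
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    drop_idx <- qd$pivot[(qd$rank + 1):ncol(X)]
    stop("design is rank deficient; collinear column(s): ",
         paste(colnames(X)[drop_idx], collapse = ", "))
  }
  subj <- NULL
  subj_levels <- NULL
  if (!is.null(subject)) {
    sf <- factor(data[[subject]])
    subj <- as.integer(sf)
    subj_levels <- levels(sf)
  }
  structure(list(X = X, y = y, subject = subj,
                 subject_levels = subj_levels,
                 col_class = col_class,
                 scaling = list(y = y_scale, x = x_scale,
                                outcome_transform = outcome_transform),
                 factor_codes = factor_codes, meta = meta),
            class = "regression_design")
}

#' Prior configuration for the robust regression models
#'
#' Coefficients of analytical interest get the heavy-tailed shrinkage
#' prior: a t distribution centred at zero with 1 degree of freedom and
#' scale 0.1 on the standardized scale — mass concentrated near zero, but
#' tails heavy enough to accommodate clearly-supported large effects.
#' Nuisance coefficients get a very broad prior on the scale of the data
#' (Normal with sd 100, realized as a t with large df). Residuals are
#' Student-t with unknown scale and normality parameter `nu` (shifted
#' exponential prior, `nu >= 1`); the subject random-intercept sd has a
#' half-t prior.
#'
#' @param shrinkage_scale,shrinkage_df Shrinkage-prior t scale and df.
#' @param broad_sd Sd of the broad nuisance prior.
#' @param broad_df Degrees of freedom used to realize the broad prior as
#'   a t (large = effectively Normal).
#' @param sigma_max Upper bound of the uniform prior on the residual
#'   scale (outcome is in sd units).
#' @param nu_rate Rate of the exponential prior on `nu - 1` (default
#'   1/29, prior mean `nu` = 30).
#' @param ranef_scale,ranef_df Half-t prior on the random-intercept sd.
#' @return List of class `prior_config`.
#' @export
prior_config <- function(shrinkage_scale = 0.1, shrinkage_df = 1,
                         broad_sd = 100, broad_df = 1000,
                         sigma_max = 10, nu_rate = 1 / 29,
                         ranef_scale = 1, ranef_df = 3) {
  structure(list(shrinkage_scale = shrinkage_scale,
                 shrinkage_df = shrinkage_df, broad_sd = broad_sd,
                 broad_df = broad_df, sigma_max = sigma_max,
                 nu_rate = nu_rate, ranef_scale = ranef_scale,
                 ranef_df = ranef_df),
            class = "prior_config")
}

#' MCMC settings for regression fits
#'
#' @inheritParams pf_fit_settings
#' @return List of settings.
#' @export
regression_settings <- function(n_chains = 4, n_adapt = 500,
                                n_burn = 500, n_iter = 10000, thin = 1,
                                ess_floor = 10000, rhat_max = 1.01,
                                max_retries = 2) {
  pf_fit_settings(n_chains, n_adapt, n_burn, n_iter, thin, ess_floor,
                  rhat_max, max_retries)
}

# Student-t residuals and t-distributed coefficient priors are written
# as scale mixtures of normals so that, with the JAGS "glm" module
# loaded, the coefficient and random-effect updates are conjugate block
# updates rather than slice sweeps (orders of magnitude faster mixing
# per second on these designs). The marginal model is unchanged:
# integrating w[i] out gives t_nu residuals, integrating g[j] out gives
# the t(b_df, 0, b_scale) coefficient prior.
.regression_jags_model <- function(ranef, student) {
  lik <- if (student)
    "y[i] ~ dnorm(mu[i], tau * w[i])
    w[i] ~ dgamma(nu / 2, nu / 2)" else
      "y[i] ~ dnorm(mu[i], tau)"
  mu <- if (ranef) "mu[i] <- eta[i] + u[subj[i]]" else
    "mu[i] <- eta[i]"
  paste0("model {
  eta <- X %*% b
  for (i in 1:N) {
    ", mu, "
    ", lik, "
  }
  for (j in 1:P) {
    b[j] ~ dnorm(0, g[j] / pow(b_scale[j], 2))
    g[j] ~ dgamma(b_df[j] / 2, b_df[j] / 2)
  }
", if (ranef) "  for (s in 1:S) { u[s] ~ dnorm(0, pow(sigma_u, -2)) }
  sigma_u ~ dt(0, pow(u_scale, -2), u_df) T(0,)
" else "", "  sigma ~ dunif(0, sigma_max)
  tau <- pow(sigma, -2)
", if (student) "  nuMinusOne ~ dexp(nu_rate)
  nu <- 1 + nuMinusOne
" else "", "}")
}

#' Fit a robust Bayesian mixed-effects regression
#'
#' Samples the posterior of the model: outcome (in sd units) described
#' by a Student-t distribution around a linear predictor built from the
#' design of [build_design], with per-subject random intercepts.
#' Shrinkage-class coefficients get the t(df, 0, scale) prior of
#' [prior_config]; broad-class coefficients the wide nuisance prior.
#' Convergence (Gelman-Rubin < `rhat_max`, effective sample size >=
#' `ess_floor` for every monitored coefficient) is enforced with a
#' retry-and-double policy; an unconverged fit is returned flagged.
#'
#' @param design A [build_design] result.
#' @param priors A [prior_config].
#' @param settings See [regression_settings].
#' @param residuals `"student_t"` (robust, the default) or `"normal"`
#'   (for sensitivity comparisons; equivalent to fixing `nu` large).
#' @param seed Integer seed for the JAGS RNGs.
#' @return Object of class `robust_fit`: `draws` (`coda::mcmc.list`
#'   with columns named after design columns plus `sigma`, `nu`,
#'   `sigma_u`), `design`, `rhat`, `ess`, `converged`, `residuals`.
#' @export
fit_robust <- function(design, priors = prior_config(),
                       settings = regression_settings(),
                       residuals = c("student_t", "normal"),
                       seed = 1) {
  stopifnot(inherits(design, "regression_design"),
            inherits(priors, "prior_config"))
  residuals <- match.arg(residuals)
  student <- residuals == "student_t"
  ranef <- !is.null(design$subject)
  P <- ncol(design$X)
  b_scale <- ifelse(design$col_class == "shrinkage",
                    priors$shrinkage_scale, priors$broad_sd)
  b_df <- ifelse(design$col_class == "shrinkage",
                 priors$shrinkage_df, priors$broad_df)
  dat <- list(y = design$y, X = design$X, N = nrow(design$X), P = P,
              b_scale = unname(b_scale), b_df = unname(b_df),
              sigma_max = priors$sigma_max)
  if (student) dat$nu_rate <- priors$nu_rate
  if (ranef) {
    dat$subj <- design$subject
    dat$S <- max(design$subject)
    dat$u_scale <- priors$ranef_scale
    dat$u_df <- priors$ranef_df
  }
  model_str <- .regression_jags_model(ranef, student)
  monitors <- c("b", "sigma", if (student) "nu",
                if (ranef) "sigma_u")
  ls_fit <- stats::lm.fit(design$X, design$y)
  n_iter <- settings$n_iter
  for (attempt in 0:settings$max_retries) {
    inits <- lapply(seq_len(settings$n_chains), function(i) {
      ini <- list(b = ls_fit$coefficients *
                    (1 + 0.1 * (i - (settings$n_chains + 1) / 2)),
                  g = rep(1, P),
                  sigma = min(max(stats::sd(ls_fit$residuals), 0.05),
                              priors$sigma_max * 0.9),
                  .RNG.name = "base::Mersenne-Twister",
                  .RNG.seed = seed + i + 1000L * attempt)
      if (student) {
        ini$nuMinusOne <- 9
        ini$w <- rep(1, nrow(design$X))
      }
      if (ranef) {
        ini$sigma_u <- 0.3
        ini$u <- rep(0, dat$S)
      }
      ini
    })
    .load_glm_module()
    m <- rjags::jags.model(textConnection(model_str), data = dat,
                           inits = inits,
                           n.chains = settings$n_chains,
                           n.adapt = settings$n_adapt, quiet = TRUE)
    if (settings$n_burn > 0)
      update(m, settings$n_burn, progress.bar = "none")
    draws <- rjags::coda.samples(m, monitors, n.iter = n_iter,
                                 thin = settings$thin,
                                 progress.bar = "none")
    draws <- .rename_b(draws, colnames(design$X))
    diag <- .mcmc_diagnostics(draws, main_vars = colnames(design$X))
    ok <- (is.na(diag$rhat_max) || diag$rhat_max < settings$rhat_max) &&
      diag$ess_min >= settings$ess_floor
    if (ok || attempt == settings$max_retries)
      return(structure(list(draws = draws, design = design,
                            rhat = diag$rhat, ess = diag$ess,
                            converged = ok, residuals = residuals,
                            priors = priors, settings = settings),
                       class = "robust_fit"))
    n_iter <- n_iter * 2L
  }
}

.load_glm_module <- function() {
  if (!"glm" %in% rjags::list.modules())
    try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
}

.rename_b <- function(draws, xnames) {
  vn <- coda::varnames(draws)
  idx <- grepl("^b\\[", vn)
  j <- as.integer(sub("^b\\[(\\d+)\\]$", "\\1", vn[idx]))
  vn[idx] <- xnames[j]
  for (c in seq_along(draws)) colnames(draws[[c]]) <- vn
  draws
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf(
    "Robust Bayesian regression (%s residuals, %s): %d coefficients, %s random intercepts\n",
    x$residuals, if (x$converged) "converged" else "NOT CONVERGED",
    ncol(x$design$X),
    if (is.null(x$design$subject)) "no" else
      length(x$design$subject_levels)))
  print(utils::head(summarize_ci(x), 12))
  invisible(x)
}

#' Credibility-interval summary of a fit
#'
#' Central posterior intervals (default 99%) for every monitored
#' parameter; a coefficient whose interval excludes zero is flagged
#' `credible`.
#'
#' @param fit A [fit_robust] (or any object with an `mcmc.list` in
#'   `$draws`).
#' @param level Credibility level (default 0.99).
#' @return Data frame `term`, `median`, `lo`, `hi`, `credible`.
#' @export
summarize_ci <- function(fit, level = 0.99) {
  d <- as.matrix(fit$draws)
  qs <- t(apply(d, 2, stats::quantile,
                probs = c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)))
  out <- data.frame(term = rownames(qs), median = qs[, 2],
                    lo = qs[, 1], hi = qs[, 3])
  out$credible <- out$lo > 0 | out$hi < 0
  rownames(out) <- NULL
  out
}

#' Per-condition covariate slopes and differential contrasts
#'
#' Under unweighted effect coding, the slope of a continuous covariate
#' at a given level of a condition factor is the covariate's main-effect
#' coefficient plus the code-weighted sum of its interaction
#' coefficients with that factor; differences between conditions (e.g.
#' high minus low stimulus level — the differential measure motivated by
#' the hypothesis of level-specific deficits, or colocated minus offset
#' — spatial release from masking) are posterior contrasts of those
#' slopes. Slopes are rescaled from standardized units to outcome units
#' per `per_unit` raw covariate units (e.g. per decade of age, per 10 dB
#' of audiometric shift); for log-transformed outcomes
#' `exponentiate = TRUE` converts them to factor changes.
#'
#' @param fit A [fit_robust] result.
#' @param covariate Name of a standardized continuous predictor.
#' @param factors Character vector of condition factors over whose level
#'   combinations the slope is evaluated (may be empty: overall slope).
#' @param per_unit Raw covariate units per reported slope unit (default
#'   10: per decade / per 10 dB).
#' @param exponentiate Report `exp(slope)` factor changes (log outcomes).
#' @param level Credibility level (default 0.99).
#' @return Data frame with one row per condition and per condition
#'   difference: `contrast`, `median`, `lo`, `hi`, `credible`.
#' @export
derived_contrasts <- function(fit, covariate, factors = character(),
                              per_unit = 10, exponentiate = FALSE,
                              level = 0.99) {
  stopifnot(inherits(fit, "robust_fit"))
  design <- fit$design
  d <- as.matrix(fit$draws)
  if (!covariate %in% colnames(d))
    stop("covariate not in fit: ", covariate)
  for (f in factors)
    if (!f %in% names(design$factor_codes))
      stop("factor not in design: ", f)
  y_sd <- design$scaling$y[["sd"]]
  x_sd <- design$scaling$x[[covariate]][["sd"]]
  unit <- y_sd / x_sd * per_unit
  combos <- if (length(factors) == 0) {
    data.frame(row.names = 1)
  } else {
    do.call(expand.grid, c(lapply(factors, function(f)
      rownames(design$factor_codes[[f]])), list(stringsAsFactors = FALSE,
                                                KEEP.OUT.ATTRS = FALSE)))
  }
  if (length(factors)) names(combos) <- factors
  slope_draws <- list()
  for (i in seq_len(max(nrow(combos), 1))) {
    s <- d[, covariate]
    for (f in factors) {
      codes <- design$factor_codes[[f]]
      lv <- combos[i, f]
      for (cc in colnames(codes)) {
        nm1 <- paste0(covariate, ":", f, ".", cc)
        nm2 <- paste0(f, ".", cc, ":", covariate)
        nm <- if (nm1 %in% colnames(d)) nm1 else nm2
        if (!nm %in% colnames(d))
          stop("no interaction term between ", covariate, " and ", f,
               " in the fit")
        s <- s + codes[lv, cc] * d[, nm]
      }
    }
    lab <- if (length(factors))
      paste(paste(factors, unlist(combos[i, , drop = TRUE]), sep = "="),
            collapse = ", ") else "overall"
    slope_draws[[lab]] <- s * unit
  }
  # condition differences (all ordered pairs, later minus earlier)
  labs <- names(slope_draws)
  if (length(labs) > 1) {
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (j <= i) next
      lab <- paste0("(", labs[j], ") - (", labs[i], ")")
      slope_draws[[lab]] <- slope_draws[[labs[j]]] -
        slope_draws[[labs[i]]]
    }
  }
  summ <- lapply(names(slope_draws), function(lab) {
    s <- slope_draws[[lab]]
    if (exponentiate) s <- exp(s)
    qs <- stats::quantile(s, c((1 - level) / 2, 0.5,
                               1 - (1 - level) / 2), names = FALSE)
    null_value <- if (exponentiate) 1 else 0
    data.frame(contrast = lab, median = qs[2], lo = qs[1], hi = qs[3],
               credible = qs[1] > null_value | qs[3] < null_value)
  })
  out <- do.call(rbind, summ)
  rownames(out) <- NULL
  attr(out, "draws") <- slope_draws
  out
}
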