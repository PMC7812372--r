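# Shared fixtures and independent oracles for the test suite.

# Reduced MCMC settings: coverage/recovery suites use lowered ESS floors
# and short chains so the whole suite stays fast.
quick_pf_settings <- function(n_iter = 1000, n_chains = 2)
  pf_fit_settings(n_chains = n_chains, n_adapt = 200, n_burn = 200,
                  n_iter = n_iter, ess_floor = 150, max_retries = 0)

quick_reg_settings <- function(n_iter = 700, n_chains = 2,
                               max_retries = 0)
  regression_settings(n_chains = n_chains, n_adapt = 200, n_burn = 200,
                      n_iter = n_iter, ess_floor = 150,
                      max_retries = max_retries)

# Independent brute-force posterior for a UML history: recomputes the
# full grid posterior in one pass as prior x product of all trial
# likelihoods, with plain loops over grid cells (no reuse of the
# package's update path).
brute_force_posterior <- function(prior_log, grids, guess, history) {
  na <- length(grids$alpha)
  nb <- length(grids$beta)
  nl <- length(grids$lambda)
  lp <- prior_log
  for (i in seq_len(na)) for (j in seq_len(nb)) for (k in seq_len(nl)) {
    a <- grids$alpha[i]; b <- grids$beta[j]; l <- grids$lambda[k]
    for (t in seq_len(nrow(history))) {
      F <- 1 / (1 + exp(-b * (history$stimulus[t] - a)))
      p <- guess + (1 - guess - l) * F
      lp[i, j, k] <- lp[i, j, k] +
        if (history$response[t]) log(p) else log(1 - p)
    }
  }
  m <- max(lp)
  lp - (m + log(sum(exp(lp - m))))
}

# A design object built directly from a plain numeric matrix (no
# standardization), for regression tests on raw coefficients.
matrix_design <- function(X, y, prior_class = "broad",
                          subject = NULL) {
  Xd <- cbind(`(Intercept)` = 1, X)
  cls <- c("broad", rep(prior_class, ncol(X)))
  names(cls) <- colnames(Xd)
  subj <- subj_levels <- NULL
  if (!is.null(subject)) {
    sf <- factor(subject)
    subj <- as.integer(sf)
    subj_levels <- levels(sf)
  }
  xs <- lapply(colnames(Xd)[-1], function(v) c(mean = 0, sd = 1))
  names(xs) <- colnames(Xd)[-1]
  structure(list(X = Xd, y = y, subject = subj,
                 subject_levels = subj_levels, col_class = cls,
                 scaling = list(y = c(mean = 0, sd = 1), x = xs,
                                outcome_transform = "identity"),
                 factor_codes = list(), meta = list()),
            class = "regression_design")
}

# A fake converged fit with known draws, for summary/contrast oracles.
fake_fit <- function(draws_matrix, design = NULL) {
  ml <- coda::mcmc.list(coda::mcmc(draws_matrix))
  structure(list(draws = ml, design = design,
                 rhat = rep(1, ncol(draws_matrix)),
                 ess = rep(1e4, ncol(draws_matrix)),
                 converged = TRUE, residuals = "student_t"),
            class = "robust_fit")
}
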