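test_that("trial aggregation produces binomial counts", {
  tr <- data.frame(stimulus = c(1, 1, 2, 2, 2),
                   response = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                   is_practice = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  agg <- pf_trials_aggregate(tr)
  expect_equal(agg$x, c(1, 2))
  expect_equal(agg$n, c(1L, 3L))
  expect_equal(agg$k, c(0L, 2L))
})

test_that("preliminary ML fits recover and centre the priors", {
  set.seed(21)
  obs <- psyfun(-10, 0.6, guess = 0.5, lapse = 0.02)
  x <- rep(seq(-20, 0, by = 2), 60)
  mk_track <- function() data.frame(stimulus = x,
                                    response = simulate_response(obs, x))
  ml <- pf_ml_fit(mk_track(), guess = 0.5)
  expect_lt(abs(ml[["midpoint"]] + 10), 0.6)
  expect_lt(abs(ml[["slope"]] - 0.6), 0.15)

  # identical tracks: centres equal the single-track estimate
  tr <- mk_track()
  ctr <- empirical_prior_centers(list(tr, tr), guess = 0.5)
  expect_equal(unname(ctr), unname(pf_ml_fit(tr, guess = 0.5)),
               tolerance = 1e-8)

  # degenerate all-correct tracks are excluded with a warning
  good <- replicate(4, mk_track(), simplify = FALSE)
  bad <- data.frame(stimulus = x, response = TRUE)
  expect_warning(
    ctr2 <- empirical_prior_centers(c(good, list(bad)), guess = 0.5),
    "degenerate")
  fits <- sapply(good, function(t) pf_ml_fit(t, guess = 0.5))
  expect_equal(ctr2[["midpoint"]], mean(fits["midpoint", ]),
               tolerance = 1e-8)
  expect_error(suppressWarnings(
    empirical_prior_centers(list(bad, bad), guess = 0.5)),
    "all tracks degenerate")
})

test_that("with no data the posterior reproduces the priors", {
  pri <- pf_prior_spec(midpoint_mean = -15, midpoint_sd = 8,
                       slope_shape = 2, slope_rate = 5, guess = 1 / 3)
  fit <- fit_pf(data.frame(stimulus = numeric(0),
                           response = logical(0)),
                pri, quick_pf_settings(n_iter = 10000), seed = 2)
  d <- as.matrix(fit$draws)
  # quantile match within 2 points of probability mass
  for (q in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_lt(abs(mean(d[, "alpha"] < qnorm(q, -15, 8)) - q), 0.02)
    expect_lt(abs(mean(d[, "beta"] < qgamma(q, 2, 5)) - q), 0.02)
  }
  expect_lt(max(d[, "lambda"]), pri$lapse_upper)
})

test_that("a long informative track pins the midpoint", {
  set.seed(22)
  obs <- psyfun(0, 2, guess = 0.5, lapse = 0)
  # trials concentrated near threshold, with a high-performance tail
  # that identifies the lapse rate
  x <- c(rep(seq(-1, 1, length.out = 20), 450), rep(4, 600))
  tr <- data.frame(stimulus = x, response = simulate_response(obs, x))
  fit <- fit_pf(tr, pf_prior_spec(0.5, 2, 2, 1, guess = 0.5),
                quick_pf_settings(n_iter = 2000), seed = 1)
  expect_lt(abs(median(as.matrix(fit$draws)[, "alpha"])), 0.05)
})

test_that("modelling the lapse rate removes midpoint bias", {
  sp <- task_spec("am")
  cfg <- c(sp$uml, list(bounds = sp$bounds, start = sp$start))
  pri_free <- pf_prior_spec(-15, 10, 2, 5, guess = sp$guess)
  # fixed-at-zero comparison: lapse prior collapsed onto ~0
  pri_fix0 <- pf_prior_spec(-15, 10, 2, 5, lapse_shape = 1,
                            lapse_rate = 5000, lapse_upper = 0.002,
                            guess = sp$guess)
  set.seed(15)
  nrep <- 40
  bias_free <- bias_fix <- numeric(nrep)
  for (r in 1:nrep) {
    obs <- psyfun(-18, 0.5, guess = sp$guess, lapse = 0.08)
    run <- uml_run(obs, cfg, n_trials = 160)
    st <- quick_pf_settings(n_iter = 800)
    ff <- fit_pf(run$log, pri_free, st, seed = r)
    f0 <- fit_pf(run$log, pri_fix0, st, seed = r)
    bias_free[r] <- median(as.matrix(ff$draws)[, "alpha"]) + 18
    bias_fix[r] <- median(as.matrix(f0$draws)[, "alpha"]) + 18
  }
  expect_lt(abs(mean(bias_free)), abs(mean(bias_fix)))
  # ignoring lapses inflates apparent thresholds
  expect_gt(mean(bias_fix), 0.4)
})

test_that("out-of-range thresholds pass through untruncated", {
  # an observer who cannot do the task even at the 100%-depth cap
  sp <- task_spec("am")
  cfg <- c(sp$uml, list(bounds = sp$bounds, start = sp$start))
  set.seed(23)
  obs <- psyfun(5, 0.4, guess = sp$guess, lapse = 0.02)
  run <- uml_run(obs, cfg, n_trials = 160)
  fit <- fit_pf(run$log, pf_prior_spec(-10, 12, 2, 5,
                                       guess = sp$guess),
                quick_pf_settings(), seed = 3)
  th <- pf_threshold(fit)
  expect_gt(th$median, 0)  # beyond the physical stimulus range
})

test_that("threshold posteriors support fractional performance points", {
  set.seed(24)
  obs <- psyfun(0, 1, guess = 0.5, lapse = 0)
  x <- rep(seq(-3, 3, length.out = 15), 40)
  tr <- data.frame(stimulus = x, response = simulate_response(obs, x))
  fit <- fit_pf(tr, pf_prior_spec(0, 3, 2, 2, guess = 0.5),
                quick_pf_settings(), seed = 4)
  t50 <- pf_threshold(fit, 0.5)
  t25 <- pf_threshold(fit, 0.25)
  expect_lt(t25$median, t50$median)
  d <- as.matrix(fit$draws)
  # quarter point equals the draw-wise closed form
  expect_equal(t25$median,
               median(d[, "alpha"] + qlogis(0.25) / d[, "beta"]),
               tolerance = 1e-10)
})
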