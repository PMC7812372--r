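test_that("initialization reproduces the prior and the start stimulus", {
  # uniform prior on a 3x3x1 grid: every cell 1/9
  grids <- list(alpha = 1:3, beta = c(0.5, 1, 2), lambda = 0)
  st <- uml_init(list(alpha = rep(1, 3), beta = rep(1, 3), lambda = 1),
                 grids, bounds = c(0, 5), start = 5, guess = 0.5)
  expect_equal(exp(st$log_post), array(1 / 9, dim = c(3, 3, 1)),
               tolerance = 1e-12)
  expect_equal(uml_next_stimulus(st), 5)

  # AM task: first stimulus at 100% depth (0 dB)
  sp <- task_spec("am")
  st_am <- uml_init(sp$uml$prior, sp$uml$grids, sp$bounds, sp$start,
                    sp$guess)
  expect_equal(uml_next_stimulus(st_am), 0)
  expect_equal(sum(exp(st_am$log_post)), 1, tolerance = 1e-10)

  expect_error(uml_init(list(alpha = c(0, 0), beta = 1, lambda = 1),
                        list(alpha = 1:2, beta = 1, lambda = 0),
                        c(0, 1), 0.5, 0.5), "zero mass")
  expect_error(uml_init(sp$uml$prior,
                        list(alpha = c(2, 1), beta = 1, lambda = 0),
                        c(0, 1), 0.5, 0.5), "strictly increasing")
})

test_that("a single update is a hand-checkable Bayes step", {
  # two midpoint cells whose correct-response probabilities at x = 0
  # are 0.9 and 0.6; prior (0.5, 0.5); correct response
  # => posterior (0.9, 0.6)/1.5 = (0.6, 0.4)
  grids <- list(alpha = c(-qlogis(0.9), -qlogis(0.6)), beta = 1,
                lambda = 0)
  st <- uml_init(list(alpha = c(1, 1), beta = 1, lambda = 1), grids,
                 bounds = c(-10, 10), start = 0, guess = 0)
  st <- uml_update(st, 0, TRUE)
  expect_equal(as.numeric(exp(st$log_post)), c(0.6, 0.4),
               tolerance = 1e-12)
})

test_that("sequential posterior equals the batch brute-force posterior", {
  set.seed(11)
  grids <- list(alpha = seq(-10, 10, length.out = 12),
                beta = seq(0.1, 2, length.out = 7),
                lambda = seq(0, 0.2, length.out = 3))
  prior <- list(midpoint = c(mean = 0, sd = 5),
                slope = c(shape = 2, rate = 2),
                lapse = c(shape = 1.2, rate = 12))
  for (r in 1:20) {
    st <- uml_init(prior, grids, bounds = c(-10, 10), start = 0,
                   guess = 0.5)
    prior_log <- st$log_post
    for (t in 1:10)
      st <- uml_update(st, runif(1, -10, 10), runif(1) < 0.7)
    brute <- brute_force_posterior(prior_log, grids, 0.5, st$history)
    expect_lt(max(abs(exp(st$log_post) - exp(brute))), 1e-12)
    expect_equal(sum(exp(st$log_post)), 1, tolerance = 1e-10)
  }
})

test_that("responses at a fixed stimulus concentrate mass at p ~ 0.5", {
  # alternating correct/incorrect at x = 0: the posterior-mean
  # parameters should predict ~chance-of-the-dynamic-range there
  sp <- list(grids = list(alpha = seq(-5, 5, length.out = 41),
                          beta = seq(0.2, 3, length.out = 21),
                          lambda = 0),
             prior = list(midpoint = c(mean = 0, sd = 3),
                          slope = c(shape = 2, rate = 2),
                          lapse = c(shape = 1, rate = 1)))
  st <- uml_init(sp$prior, sp$grids, c(-5, 5), 0, guess = 0)
  for (t in 1:60) st <- uml_update(st, 0, t %% 2 == 0)
  est <- uml_estimate(st)
  p0 <- prob_correct(psyfun(est[["alpha"]], est[["beta"]], guess = 0),
                     0)
  expect_lt(abs(p0 - 0.5), 0.1)
})

test_that("sweetpoints minimize the per-parameter variance proxies", {
  sp <- task_spec("am")
  st <- uml_init(sp$uml$prior, sp$uml$grids, sp$bounds, sp$start,
                 sp$guess)
  set.seed(3)
  obs <- psyfun(-18, 0.4, guess = sp$guess, lapse = 0.02)
  for (t in 1:30) {
    x <- uml_next_stimulus(st)
    st <- uml_update(st, x, simulate_response(obs, x))
  }
  sw <- uml_sweetpoints(st)
  expect_length(sw, 4)
  expect_true(!is.unsorted(sw))
  expect_true(all(sw >= sp$bounds[1] & sw <= sp$bounds[2]))

  # independent continuous minimization of the asymptotic variance
  # proxy p(1-p)/(dp/dtheta)^2 at the current estimate
  est <- uml_estimate(st)
  g <- sp$guess
  a <- est[["alpha"]]; b <- est[["beta"]]; l <- est[["lambda"]]
  psi <- function(x) g + (1 - g - l) * plogis(b * (x - a))
  vproxy <- function(x, dpd) psi(x) * (1 - psi(x)) / dpd(x)^2
  dF <- function(x) plogis(b * (x - a)) * (1 - plogis(b * (x - a)))
  o_alpha <- optimize(function(x)
    vproxy(x, function(z) (1 - g - l) * b * dF(z)),
    interval = sp$bounds)$minimum
  o_beta_lo <- optimize(function(x)
    vproxy(x, function(z) (1 - g - l) * (z - a) * dF(z)),
    interval = c(sp$bounds[1], a - 1e-6))$minimum
  o_beta_hi <- optimize(function(x)
    vproxy(x, function(z) (1 - g - l) * (z - a) * dF(z)),
    interval = c(a + 1e-6, sp$bounds[2]))$minimum
  lattice_step <- diff(sp$bounds) / 1000
  expect_equal(sw[2], o_alpha, tolerance = 2 * lattice_step)
  expect_equal(sw[1], o_beta_lo, tolerance = 2 * lattice_step)
  expect_equal(sw[3], o_beta_hi, tolerance = 2 * lattice_step)
  # lapse sweetpoint: the high-performance end of the stimulus range
  expect_equal(sw[4], sp$bounds[2])

  # symmetric 2AFC function with no lapse: the midpoint sweetpoint sits
  # at the midpoint estimate
  grids0 <- sp$uml$grids
  grids0$lambda <- 0
  st0 <- uml_init(sp$uml$prior, grids0, sp$bounds, sp$start,
                  guess = 0.5)
  set.seed(4)
  obs0 <- psyfun(-20, 0.4, guess = 0.5)
  for (t in 1:40) {
    x <- uml_next_stimulus(st0)
    st0 <- uml_update(st0, x, simulate_response(obs0, x))
  }
  est0 <- uml_estimate(st0)
  sw0 <- uml_sweetpoints(st0)
  expect_equal(sw0[2], est0[["alpha"]], tolerance = 0.1)
})

test_that("the 2-down 1-up sweetpoint selection rule moves correctly", {
  grids <- list(alpha = seq(-5, 5, length.out = 11), beta = c(1),
                lambda = 0)
  prior <- list(alpha = rep(1, 11), beta = 1, lambda = 1)
  st <- uml_init(prior, grids, c(-5, 5), 0, guess = 0.5)
  expect_equal(st$sweet_index, 4L)
  # one incorrect at the top index: clamped
  st <- uml_update(st, 0, FALSE)
  expect_equal(st$sweet_index, 4L)
  # two consecutive correct: move one sweetpoint down
  st <- uml_update(st, 0, TRUE)
  st <- uml_update(st, 0, TRUE)
  expect_equal(st$sweet_index, 3L)
  st <- uml_update(st, 0, TRUE)
  st <- uml_update(st, 0, TRUE)
  expect_equal(st$sweet_index, 2L)
  # an error moves one up and resets the counter
  st <- uml_update(st, 0, FALSE)
  expect_equal(st$sweet_index, 3L)
  st <- uml_update(st, 0, TRUE)
  st <- uml_update(st, 0, FALSE)
  expect_equal(st$sweet_index, 4L)
})

test_that("UML tracks sample near the 70.7% level and stay in bounds", {
  sp <- task_spec("am")
  cfg <- c(sp$uml, list(bounds = sp$bounds, start = sp$start))
  obs <- psyfun(-18, 0.4, guess = sp$guess, lapse = 0.02)
  set.seed(9)
  run <- uml_run(obs, cfg, n_trials = 1200)
  expect_true(all(run$log$stimulus >= sp$bounds[1] &
                    run$log$stimulus <= sp$bounds[2]))
  # 2-down 1-up selection equilibrates near 70.7% correct
  late <- run$log[run$log$trial_index > 200, ]
  expect_lt(abs(mean(late$response) - 2^-0.5), 0.04)
})

test_that("the posterior-mean midpoint converges within a grid cell", {
  # grid resolution matched to the information in a 160-trial track
  # (2-dB cells); generating parameters drawn from the prior's bulk
  sp <- task_spec("am")
  cfg <- c(sp$uml, list(bounds = sp$bounds, start = sp$start))
  cfg$grids$alpha <- seq(-40, 0, length.out = 21)
  cell <- diff(cfg$grids$alpha[1:2])
  set.seed(78)
  hits <- replicate(100, {
    a <- rnorm(1, -15, 5)
    obs <- psyfun(a, runif(1, 0.3, 0.6), guess = sp$guess,
                  lapse = runif(1, 0, 0.05))
    run <- uml_run(obs, cfg, n_trials = 160)
    abs(uml_estimate(run$state)[["alpha"]] - a) <= cell
  })
  expect_gte(mean(hits), 0.9)
})

test_that("practice trials are flagged and kept out of the main state", {
  sp <- task_spec("dtt")
  cfg <- c(sp$uml, list(bounds = sp$bounds, start = sp$start))
  obs <- psyfun(-6, 0.5, guess = sp$guess, lapse = 0.02)
  set.seed(12)
  run <- uml_run(obs, cfg, n_trials = 30, n_practice = 10)
  expect_equal(sum(run$log$is_practice), 10)
  expect_equal(nrow(run$log), 40)
  # the returned posterior reflects only the 30 main trials
  expect_equal(nrow(run$state$history), 30)
})
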