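test_that("standardization is Friedrich-style: parents first, then products", {
  set.seed(1)
  a <- rexp(200)^2          # strongly skewed
  b <- rexp(200)
  s <- standardize(a)
  expect_equal(mean(s$z), 0, tolerance = 1e-12)
  expect_equal(sd(s$z), 1, tolerance = 1e-12)
  expect_error(standardize(rep(2, 5)), "zero-variance")

  d <- data.frame(y = rnorm(200), a = a, b = b, subject = "s1")
  des <- build_design(d, "y", continuous = c("a", "b"),
                      interactions = list(c("a", "b")))
  za <- standardize(a)$z
  zb <- standardize(b)$z
  expect_equal(unname(des$X[, "a:b"]), za * zb)
  # products of standardized parents differ from standardized products
  expect_gt(max(abs(za * zb - standardize(a * b)$z)), 0.1)
})

test_that("unweighted effect coding recovers level deviations", {
  f <- rep(c("lo", "mid", "hi"), each = 4)
  X <- effect_code(f)
  expect_equal(ncol(X), 2)
  codes <- attr(X, "codes")
  # implied effects over all levels sum to zero in each column
  expect_equal(colSums(codes), c(hi = 0, lo = 0))
  # reference level coded -1 everywhere
  expect_equal(unname(codes[attr(X, "reference"), ]), c(-1, -1))

  # two-level factor: a single +/-1 column
  X2 <- effect_code(c("a", "b", "a"))
  expect_equal(dim(X2), c(3L, 1L))
  expect_setequal(unique(as.vector(X2)), c(1, -1))
  expect_error(effect_code(rep("a", 3)), "2 levels")

  # balanced noiseless data: solve the normal equations by hand;
  # intercept = unweighted grand mean, coefficients = deviations
  mu <- c(lo = 2, mid = 5, hi = 11)
  y <- mu[f]
  M <- cbind(1, X)
  beta <- solve(crossprod(M), crossprod(M, y))
  expect_equal(unname(beta[1, 1]), mean(mu), tolerance = 1e-12)
  expect_equal(unname(beta["hi", 1]), mu[["hi"]] - mean(mu),
               tolerance = 1e-12)
  expect_equal(unname(beta["lo", 1]), mu[["lo"]] - mean(mu),
               tolerance = 1e-12)
})

test_that("standardized slopes back-transform to raw-scale slopes", {
  set.seed(2)
  x <- rnorm(60, 10, 3)
  y <- 4 + 1.7 * x            # noiseless line
  d <- data.frame(y = y, x = x, subject = "s")
  des <- build_design(d, "y", continuous = "x")
  # closed-form OLS on the standardized design
  b_std <- solve(crossprod(des$X), crossprod(des$X, des$y))["x", 1]
  b_raw <- b_std * des$scaling$y[["sd"]] / des$scaling$x$x[["sd"]]
  expect_equal(unname(b_raw), 1.7, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  d <- data.frame(y = rnorm(30), a = rnorm(30), subject = "s")
  d$b <- 2 * d$a
  expect_error(
    build_design(d, "y", continuous = c("a", "b")),
    "rank deficient.*\\bb\\b")
})

test_that("noiseless data identify the coefficients", {
  set.seed(3)
  X <- matrix(rnorm(240), 80, 3)
  colnames(X) <- paste0("x", 1:3)
  truth <- c(0.8, -0.5, 0.25)
  y <- drop(X %*% truth) + rnorm(80, 0, 1e-3)
  des <- matrix_design(X, y)
  fit <- fit_robust(des, settings = quick_reg_settings(),
                    residuals = "normal", seed = 1)
  ci <- summarize_ci(fit)
  est <- ci$median[match(colnames(X), ci$term)]
  expect_lt(max(abs(est - truth)), 0.01)
})

test_that("credibility summaries match a sort-based quantile oracle", {
  set.seed(4)
  dr <- cbind(b1 = rnorm(4000, 0, 1), b2 = rnorm(4000, 5, 0.5),
              b3 = -abs(rnorm(4000)))
  fit <- fake_fit(dr)
  ci <- summarize_ci(fit, level = 0.99)
  expect_equal(ci$credible, c(FALSE, TRUE, TRUE))
  for (j in 1:3) {
    s <- sort(dr[, j])
    # endpoints must sit between neighbouring order statistics
    klo <- floor(0.005 * 4000)
    khi <- ceiling(0.995 * 4000)
    expect_gte(ci$lo[j], s[klo])
    expect_lte(ci$lo[j], s[klo + 2])
    expect_gte(ci$hi[j], s[khi - 2])
    expect_lte(ci$hi[j], s[min(khi + 1, 4000)])
  }
})

test_that("per-condition slopes and differentials follow the coding", {
  # fabricate a fit with known draws: slope at level '80' must be
  # b_age + b_int, at '40' b_age - b_int, differential 2 * b_int
  n <- 2000
  set.seed(5)
  d <- data.frame(y = rnorm(40), age = rnorm(40),
                  level = factor(rep(c(40, 80), 20)),
                  subject = rep(sprintf("s%d", 1:20), 2))
  des <- build_design(d, "y", continuous = "age", factors = "level",
                      interactions = list(c("age", "level")))
  dr <- cbind(`(Intercept)` = rnorm(n), age = rnorm(n, 0.5, 0.01),
              `level.40` = rnorm(n), `age:level.40` = rnorm(n, 0.2,
                                                            0.01))
  fit <- fake_fit(dr, design = des)
  ct <- derived_contrasts(fit, "age", factors = "level", per_unit = 10)
  unit <- des$scaling$y[["sd"]] / des$scaling$x$age[["sd"]] * 10
  m40 <- ct$median[ct$contrast == "level=40"]
  m80 <- ct$median[ct$contrast == "level=80"]
  expect_equal(m40, 0.7 * unit, tolerance = 0.01 * unit)
  expect_equal(m80, 0.3 * unit, tolerance = 0.01 * unit)
  diff_row <- ct$median[grepl("-", ct$contrast)]
  expect_equal(diff_row, -0.4 * unit, tolerance = 0.02 * unit)

  # an exactly-zero interaction: equal slopes, differential CI at 0
  dr0 <- dr
  dr0[, "age:level.40"] <- 0
  ct0 <- derived_contrasts(fake_fit(dr0, design = des), "age",
                           factors = "level")
  expect_equal(ct0$median[1], ct0$median[2], tolerance = 1e-9)
  expect_false(ct0$credible[grepl("-", ct0$contrast)])

  # log-outcome contrasts exponentiate to factor changes
  des_log <- des
  des_log$scaling$y <- c(mean = 0, sd = 1)
  des_log$scaling$x$age <- c(mean = 50, sd = 10)
  drl <- cbind(`(Intercept)` = rnorm(n), age = rep(log(1.1), n),
               `level.40` = rnorm(n),
               `age:level.40` = rep(0, n))
  ctl <- derived_contrasts(fake_fit(drl, design = des_log), "age",
                           factors = "level", per_unit = 10,
                           exponentiate = TRUE)
  expect_equal(ctl$median[ctl$contrast == "level=80"], 1.1,
               tolerance = 1e-9)

  expect_error(derived_contrasts(fit, "age", factors = "nope"),
               "factor not in design")
})

test_that("robust fits match mixed-model ML estimates in the Normal limit", {
  library(lme4)
  co <- generate_cohort(102, seed = 11)
  th <- generate_thresholds(co, tasks = "dtt", seed = 11)
  fam <- model_families()$dtt
  d <- prepare_family_data(fam, co, th)
  des <- do.call(build_design, c(list(data = d),
                                 attr(d, "design_args")))
  des$col_class[] <- "broad"
  fit <- fit_robust(des, settings = quick_reg_settings(n_iter = 2000,
                                                       max_retries = 1),
                    residuals = "normal", seed = 9)
  ci <- summarize_ci(fit)
  dd <- data.frame(y = des$y, des$X[, -1], subj = d$subject)
  names(dd) <- c("y", paste0("c", seq_len(ncol(des$X) - 1)), "subj")
  lf <- lmer(y ~ . - subj + (1 | subj), data = dd, REML = FALSE)
  fe <- fixef(lf)[-1]
  med <- ci$median[match(colnames(des$X)[-1], ci$term)]
  expect_lt(max(abs(med - unname(fe))), 0.02)
})

test_that("derived contrasts are invariant to the coding reference level", {
  co <- generate_cohort(51, seed = 13)
  th <- generate_thresholds(co, tasks = "dtt", seed = 13)
  fam <- model_families()$dtt
  d <- prepare_family_data(fam, co, th)
  args <- attr(d, "design_args")
  d2 <- d
  d2$level <- factor(d2$level, levels = rev(levels(d$level)))
  fit1 <- fit_robust(do.call(build_design, c(list(data = d), args)),
                     settings = quick_reg_settings(n_iter = 1500),
                     seed = 7)
  fit2 <- fit_robust(do.call(build_design, c(list(data = d2), args)),
                     settings = quick_reg_settings(n_iter = 1500),
                     seed = 7)
  c1 <- derived_contrasts(fit1, "age", factors = "level")
  c2 <- derived_contrasts(fit2, "age", factors = "level")
  for (lv in c("level=45", "level=80")) {
    expect_lt(abs(c1$median[c1$contrast == lv] -
                    c2$median[c2$contrast == lv]), 0.25)
  }
})

test_that("a planted differential age effect is recovered", {
  # age slope +1 dB/decade at the high level, +0.3 at the low level
  tr <- cohort_truth()
  tr$tasks$dtt$covariates$age <- list(
    per = 10, slope = 0.65,
    extras = list(level = c(`45` = -0.35, `80` = 0.35)))
  co <- generate_cohort(102, seed = 21, truth = tr)
  th <- generate_thresholds(co, tasks = "dtt", truth = tr, seed = 21)
  fit <- fit_family("dtt", co, thresholds = th,
                    settings = quick_reg_settings(n_iter = 1500,
                                                  max_retries = 1),
                    seed = 5)
  ct <- derived_contrasts(fit, "age", factors = "level", per_unit = 10)
  dif <- ct[ct$contrast == "(level=80) - (level=45)", ]
  expect_true(dif$lo <= 0.7 && dif$hi >= 0.7)
  expect_lt(abs(dif$median - 0.7), 0.6)
})
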