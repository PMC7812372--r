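test_that("noise-exposure units follow the equal-energy definition", {
  # the reference exposure: 8 h/day, 5 d/wk, 52 wk, 1 y at 90 dBA
  expect_equal(tcne_units(90, 8, 5, 52, 1), 1)
  # +10 dBA is a tenfold energy increase
  expect_equal(tcne_units(100, 8, 5, 52, 1), 10)
  # additive across activities
  expect_equal(tcne_units(c(90, 90), c(4, 4), c(5, 5), c(52, 52),
                          c(1, 1)), 1)
  # additivity over arbitrary partitions and dB scaling, jointly
  set.seed(1)
  for (r in 1:10) {
    lv <- runif(3, 70, 110)
    h <- runif(3, 0.5, 10)
    total <- tcne_units(lv, h, rep(5, 3), rep(50, 3), rep(2, 3))
    parts <- sum(sapply(1:3, function(i)
      tcne_units(lv[i], h[i], 5, 50, 2)))
    expect_equal(total, parts, tolerance = 1e-12)
    expect_equal(tcne_units(lv + 10, h, rep(5, 3), rep(50, 3),
                            rep(2, 3)), 10 * total, tolerance = 1e-9)
  }
  expect_error(tcne_units(90, -1, 5, 52, 1), "non-negative")
})

test_that("log noise exposure is base 10", {
  expect_equal(log_tcne(1), 0)
  expect_equal(log_tcne(1000), 3)
  # a unit difference on the log scale is a tenfold energy difference
  u <- c(0.3, 7, 42)
  expect_equal(log_tcne(10 * u) - log_tcne(u), rep(1, 3))
  expect_error(log_tcne(0), "positive")
})

test_that("equal-temperament steps are 2^(1/12) per 100 cents", {
  expect_equal(et_frequency(146.83, 0), 146.83)
  # D3 up seven semitones reaches A3
  expect_equal(et_frequency(146.83, 7), 220, tolerance = 0.05)
  expect_equal(et_frequency(146.83, 12), 2 * 146.83, tolerance = 1e-9)
})

test_that("consonance preference is a within-listener z contrast", {
  roots <- et_frequency(146.83, 0:7)
  grid <- expand.grid(interval = c("P5", "TT"), dyad_level = c(40, 80),
                      root_f0 = roots, stringsAsFactors = FALSE)
  # every dyad rated identically except the fifth at 80 dB rated higher
  r1 <- grid
  r1$subject <- "s1"
  r1$rating <- ifelse(r1$interval == "P5" & r1$dyad_level == 80, 2, 0)
  pr <- consonance_preference(r1)$preference
  expect_equal(pr$preference[pr$dyad_level == 40], 0, tolerance = 1e-10)
  expect_gt(pr$preference[pr$dyad_level == 80], 0)

  # invariance to affine rescaling of a listener's ratings
  set.seed(2)
  r2 <- grid
  r2$subject <- "s2"
  r2$rating <- rnorm(nrow(r2))
  r3 <- r2
  r3$rating <- 1.7 * r2$rating + 0.4
  p2 <- consonance_preference(r2)$preference$preference
  p3 <- consonance_preference(r3)$preference$preference
  expect_equal(p2, p3, tolerance = 1e-10)

  # a listener with zero rating spread is flagged, not silently scored
  r4 <- grid
  r4$subject <- "s4"
  r4$rating <- 1
  expect_warning(p4 <- consonance_preference(r4), "zero rating variance")
  expect_true(all(is.na(p4$preference$preference)))
})

test_that("the rating generator round-trips its target preference", {
  tr <- cohort_truth()
  tr$consonance$pref <- c(`40` = 0.8, `80` = 0.8)
  for (cv in names(tr$consonance$covariates))
    tr$consonance$covariates[[cv]]$slope[] <- 0
  co <- generate_cohort(60, seed = 8, truth = tr)
  rat <- generate_ratings(co, tr, seed = 8)
  pr <- consonance_preference(rat)$preference
  rec <- tapply(pr$preference, pr$dyad_level, mean)
  expect_lt(max(abs(rec - 0.8)), 0.1)
})

test_that("cognitive PCA has orthonormal structure and captures shared variance", {
  set.seed(3)
  n <- 400
  shared <- rnorm(n)
  scores <- cbind(a = shared + rnorm(n, 0, 0.05),
                  b = shared + rnorm(n, 0, 0.05),
                  c = rnorm(n), d = rnorm(n))
  p <- cognitive_pca(scores)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # PC1 captures the correlated pair
  expect_gt(abs(p$loadings["a", 1]), 0.6)
  expect_gt(abs(p$loadings["b", 1]), 0.6)
  expect_lt(p$variance_fraction[1], 0.65)
  expect_gt(p$variance_fraction[1], 0.4)
  # loadings orthogonal; reconstruction exact with all components
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  Z <- scale(scores)
  expect_equal(p$scores %*% t(p$loadings), Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  # sign convention: the dominant loading of each component is positive
  for (j in 1:4)
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)

  # exactly orthogonal mean-zero columns: isotropic fractions
  Q <- qr.Q(qr(scale(matrix(rnorm(200 * 4), 200, 4), scale = FALSE)))
  p2 <- cognitive_pca(Q)
  expect_equal(p2$variance_fraction, rep(0.25, 4), tolerance = 1e-8)

  expect_error(cognitive_pca(cbind(a = rep(1, 10), b = rnorm(10))),
               "constant")
})

test_that("musical practice and questionnaire transforms are elementwise", {
  expect_equal(music_transform(8), 2)
  expect_equal(music_transform(0), 0)
  expect_equal(music_transform(27), 3)
  expect_error(music_transform(-1), "non-negative")
  expect_equal(ssq_mean(rep(6, 12)), 6)
  m <- matrix(1:24, nrow = 2, byrow = TRUE)
  expect_equal(ssq_mean(m), rowMeans(m))
  expect_error(ssq_mean(1:5))
})
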