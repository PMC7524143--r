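test_that("standard errors are recovered from ratio-scale CIs", {
  # unit-SE construction
  expect_equal(se_from_ci(1, exp(-qnorm(0.975)), exp(qnorm(0.975))), 1,
               tolerance = 1e-12)
  expect_equal(se_from_ci(0.87, 0.79, 0.95), 0.04705, tolerance = 1e-4)
  expect_error(se_from_ci(0.5, 0.6, 0.9), "low < point < high")
  expect_warning(se_from_ci(0.5, 0.45, 0.9), "asymmetric")
})

test_that("fixed-effect pooling matches closed forms and the direct oracle", {
  # two identical studies: pooled = b, se = s / sqrt(2)
  m <- fixed_effect_meta(c(-0.4, -0.4), c(0.1, 0.1))
  expect_equal(m$pooled_estimate, -0.4, tolerance = 1e-12)
  expect_equal(m$pooled_se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$q_statistic, 0)
  expect_equal(m$i2, 0)

  set.seed(37)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    b <- rnorm(k); s <- runif(k, 0.05, 0.6)
    m <- fixed_effect_meta(b, s)
    w <- 1 / s^2
    expect_equal(m$pooled_estimate, sum(w * b) / sum(w), tolerance = 1e-12)
    expect_equal(m$pooled_se, sqrt(1 / sum(w)), tolerance = 1e-12)
    # pooled estimate lies inside the range of inputs, se below the best
    expect_gte(m$pooled_estimate, min(b) - 1e-12)
    expect_lte(m$pooled_estimate, max(b) + 1e-12)
    expect_lte(m$pooled_se, min(s))
  }
  expect_error(fixed_effect_meta(0.2, 0.1), "nothing to pool")
})

test_that("fixed-effect results agree with the metafor reference", {
  skip_if_not_installed("metafor")
  set.seed(41)
  b <- rnorm(4); s <- runif(4, 0.1, 0.5)
  m <- fixed_effect_meta(b, s)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(m$pooled_estimate, as.numeric(ref$beta), tolerance = 1e-9)
  expect_equal(m$pooled_se, ref$se, tolerance = 1e-9)
  expect_equal(m$fe_p, ref$pval, tolerance = 1e-9)
  expect_equal(m$q_statistic, ref$QE, tolerance = 1e-9)
})

test_that("rescaling studies rescales the pooled estimate, not its p-value", {
  b <- c(-0.3, -0.1, -0.5); s <- c(0.1, 0.2, 0.15)
  m1 <- fixed_effect_meta(b, s)
  m2 <- fixed_effect_meta(3 * b, 3 * s)
  expect_equal(m2$pooled_estimate, 3 * m1$pooled_estimate,
               tolerance = 1e-12)
  expect_equal(m2$fe_p, m1$fe_p, tolerance = 1e-12)
})

test_that("RE2 statistic dominates the fixed-effect z on homogeneous input", {
  b <- c(-0.30, -0.31, -0.29); s <- c(0.1, 0.11, 0.1)
  m <- han_eskin_re2(b, s)
  z2 <- (m$pooled_estimate / m$pooled_se)^2
  expect_gte(m$re2_statistic, z2 - 1e-6)
  # nested-model property at a modest signal: with tau2_hat = 0 the RE2
  # statistic equals the FE z^2 and the mixture p stays within a factor
  # of 2 of the FE p (the chi2(2) tail pulls further ahead only for very
  # large statistics)
  bw <- c(-0.10, -0.11, -0.10)
  mw <- han_eskin_re2(bw, s)
  expect_gte(mw$re2_statistic, (mw$pooled_estimate / mw$pooled_se)^2 - 1e-6)
  expect_lt(mw$re2_p, 2 * mw$fe_p)
  expect_gt(mw$re2_p, mw$fe_p / 2)
})

test_that("RE2 degenerates gracefully and stays non-negative", {
  m0 <- han_eskin_re2(c(0, 0), c(0.2, 0.3))
  expect_equal(m0$re2_statistic, 0)
  expect_equal(m0$re2_p, 1)
  set.seed(43)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    m <- han_eskin_re2(rnorm(k, sd = 0.5), runif(k, 0.05, 0.5))
    expect_gte(m$re2_statistic, 0)
    expect_gte(m$re2_tau2, 0)
    expect_true(m$re2_p > 0 && m$re2_p <= 1)
  }
})

test_that("RE2 detects heterogeneous effects the FE model averages away", {
  # two well-measured studies with opposite effects: FE pools towards 0,
  # RE2 keeps power through the heterogeneity component
  m <- han_eskin_re2(c(0.8, -0.8), c(0.1, 0.1))
  expect_lt(m$re2_p, 0.01)
  expect_gt(m$fe_p, 0.5)
})

test_that("printed-CI pooling wrapper matches its pieces", {
  studies <- list(c(0.31, 0.11, 0.90), c(0.87, 0.79, 0.95))
  m <- meta_from_ratio_ci(studies)
  b <- log(c(0.31, 0.87))
  s <- c(se_from_ci(0.31, 0.11, 0.90), se_from_ci(0.87, 0.79, 0.95))
  expect_equal(m$pooled_estimate,
               fixed_effect_meta(b, s)$pooled_estimate, tolerance = 1e-12)
})
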