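test_that("the published model reproduces its printed arithmetic", {
  m <- published_mmd_model()
  expect_length(m$coefficients, 6L)
  expect_equal(m$provenance, "published")
  expect_equal(apply_score(m, published_zero_matrix()), -0.0476306)
  expect_equal(apply_score(m, published_zero_matrix() + 1), 0.2769962)
  one <- published_zero_matrix()
  one[, "indolepropionate"] <- 1
  expect_equal(apply_score(m, one), -0.0476306 + 0.0683178)
})

test_that("analyte aliases resolve to canonical slugs", {
  r <- resolve_analyte(c("IPA", "indolepropionate", "indole propionate"))
  expect_true(all(r == "indolepropionate"))
  expect_equal(unname(resolve_analyte("Glutarate (pentanedioate)")),
               "glutarate")
  expect_equal(unname(resolve_analyte(
    "5alphapregnan_3beta,20alpha_diolmonosulfate2")),
    "pregnanediol_monosulfate")
  expect_true(is.na(resolve_analyte("caffeine")))
})

test_that("apply_score errors name the missing column", {
  m <- published_mmd_model()
  x <- published_zero_matrix()[, -3, drop = FALSE]
  expect_error(apply_score(m, x), "cinnamoylglycine")
})

test_that("a perfect single predictor is fit exactly", {
  set.seed(2)
  d <- rnorm(60)
  X <- matrix(d, 60, 1, dimnames = list(NULL, "m"))
  fit <- fit_score(d, X)
  expect_equal(unname(fit$coefficients["m"]), 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(attr(fit, "r_squared"), 1, tolerance = 1e-9)
})

test_that("fitted coefficients are permutation invariant and r2 consistent", {
  set.seed(12)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  d <- X %*% c(0.4, -0.3, 0.2, 0.1) + rnorm(n)
  f1 <- fit_score(d[, 1], X)
  perm <- sample(n)
  f2 <- fit_score(d[perm, 1], X[perm, ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  # in-sample r2 from the fit equals evaluate_score on the training data
  ev <- evaluate_score(apply_score(f1, X), d[, 1], X)
  expect_equal(ev$r2, attr(f1, "r_squared"), tolerance = 1e-9)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_score(rnorm(20), X), "dup")
})

test_that("score recovery: six-term generating model at moderate n", {
  set.seed(8)
  n <- 2000
  beta <- c(0.5, -0.4, 0.45, 0.5, -0.45, 0.35)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("m", 1:6)))
  d <- as.numeric(X %*% beta + rnorm(n))
  fit <- fit_score(d, X)
  se_approx <- 1 / sqrt(n)  # unit-variance orthogonal design
  expect_true(all(abs(fit$coefficients - beta) < 3 * se_approx))
})

test_that("out-of-sample fit does not beat in-sample fit on average", {
  # the overfitting direction: the discovery-set r2 exceeds the held-out
  # r2 in expectation (any single split can flip by sampling noise)
  set.seed(15)
  beta <- c(0.4, -0.3, 0.35, -0.25)
  gap <- replicate(30, {
    X <- matrix(rnorm(300 * 4), 300, 4,
                dimnames = list(NULL, paste0("m", 1:4)))
    d <- as.numeric(X %*% beta + rnorm(300))
    train <- 1:100
    fit <- fit_score(d[train], X[train, ])
    ins <- attr(fit, "r_squared")
    oos <- evaluate_score(apply_score(fit, X[-train, ]), d[-train])$r2
    ins - oos
  })
  expect_gt(mean(gap), 0)
})

test_that("apply_score is affine in its inputs", {
  m <- published_mmd_model()
  set.seed(5)
  x <- matrix(rnorm(18), 3, 6, dimnames = list(NULL, published_slugs()))
  y <- matrix(rnorm(18), 3, 6, dimnames = list(NULL, published_slugs()))
  for (a in c(0.2, 0.5, 0.9)) {
    lhs <- apply_score(m, a * x + (1 - a) * y)
    rhs <- a * apply_score(m, x) + (1 - a) * apply_score(m, y)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("evaluate_score reports identity and orthogonality exactly", {
  set.seed(6)
  d <- rnorm(200)
  ev <- evaluate_score(d, d)
  expect_equal(ev$r2, 1, tolerance = 1e-12)
  expect_equal(ev$beta, 1, tolerance = 1e-12)
  # two design columns orthogonal to each other and the intercept: VIF 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(400), 200, 2))))[, 2:3]
  colnames(X) <- c("u", "v")
  ev2 <- evaluate_score(rnorm(200), rnorm(200), X)
  expect_equal(unname(ev2$vif), c(1, 1), tolerance = 1e-9)
  expect_error(evaluate_score(rep(1, 10), rnorm(10)), "zero-variance")
})
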