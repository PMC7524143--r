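test_that("closed-form indices match hand-computed values", {
  expect_equal(shannon(c(25, 25, 25, 25)), 2)
  expect_equal(shannon(c(100)), 0)
  expect_equal(shannon(c(50, 25, 25)), 1.5)  # -(0.5 log2 0.5 + 2*0.25 log2 0.25)
  expect_equal(shannon(c(1, 1), base = exp(1)), log(2))

  expect_equal(simpson(c(100)), 0)
  expect_equal(simpson(c(50, 50)), 0.5)
  expect_equal(simpson(c(50, 25, 25)), 0.625)

  # no singletons: chao1 collapses to observed richness
  expect_equal(chao1(c(5, 3, 2)), 3)
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/6
  v <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  expect_equal(chao1(v), 12)
  expect_equal(chao1(v, bias_corrected = FALSE), 10 + 16 / 4)
})

test_that("degenerate communities are rejected", {
  expect_error(shannon(c(0, 0, 0)), "empty community")
  expect_error(simpson(numeric(0)), "empty community")
  expect_error(chao1(c(0, 0)), "empty community")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("chao1 never falls below observed richness", {
  set.seed(42)
  for (i in 1:25) {
    v <- rpois(30, 2)
    if (sum(v) == 0) next
    expect_gte(chao1(v), sum(v > 0))
  }
})

test_that("adding an equally-abundant taxon increases every index", {
  for (k in c(2, 5, 10)) {
    a <- rep(20, k); b <- rep(20, k + 1)
    expect_gt(shannon(b), shannon(a))
    expect_gt(simpson(b), simpson(a))
    expect_gt(chao1(b), chao1(a))
  }
})

test_that("indices agree with the vegan reference on random vectors", {
  skip_if_not_installed("vegan")
  set.seed(7)
  for (i in 1:50) {
    v <- rpois(40, exp(runif(1, 0, 3)))
    if (sum(v) == 0) v[1] <- 5
    expect_equal(shannon(v), vegan::diversity(v, "shannon", base = 2),
                 tolerance = 1e-9)
    expect_equal(simpson(v), vegan::diversity(v, "simpson"),
                 tolerance = 1e-9)
    expect_equal(chao1(v), unname(vegan::estimateR(v)["S.chao1"]),
                 tolerance = 1e-9)
  }
})

test_that("standardize centres and scales with n-1 denominator", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)  # idempotent
  expect_error(standardize(rep(4, 10)), "zero variance")
})

test_that("rarefied subsamples conserve depth and composition support", {
  set.seed(3)
  cnt <- rpois(30, 40)
  for (i in 1:20) {
    r <- mmdscore:::rarefy_counts(cnt, 200)
    expect_equal(sum(r), 200)
    expect_true(all(r <= cnt))  # without replacement
  }
})

test_that("single-OTU subjects have zero diversity at any depth", {
  tab <- matrix(c(5000L, 0L, 0L, 2000L, 2000L, 2000L), 2, 3, byrow = TRUE,
                dimnames = list(c("mono", "even"), paste0("o", 1:3)))
  a <- rarefied_alpha(tab, depth = 500, reps = 5, seed = 1)
  expect_equal(a$shannon[a$subject_id == "mono"], 0)
  expect_equal(a$simpson[a$subject_id == "mono"], 0)
  expect_gt(a$shannon[a$subject_id == "even"], 1)
})

test_that("shallow subjects are dropped and counted", {
  tab <- matrix(c(50L, 50L, 5000L, 5000L), 2, 2, byrow = TRUE,
                dimnames = list(c("shallow", "deep"), c("o1", "o2")))
  a <- rarefied_alpha(tab, depth = 1000, reps = 3, seed = 1)
  expect_equal(nrow(a), 1L)
  expect_equal(attr(a, "n_dropped"), 1L)
  expect_equal(attr(a, "dropped_ids"), "shallow")
  expect_error(rarefied_alpha(tab, depth = 1e6, reps = 2), "below")
})

test_that("rarefaction mean matches a brute-force oracle on a toy table", {
  set.seed(11)
  cnt <- rpois(20, 60)
  tab <- matrix(as.integer(cnt), 1, 20,
                dimnames = list("s1", paste0("o", 1:20)))
  a <- rarefied_alpha(tab, depth = 300, reps = 50, seed = 5)
  oracle <- replicate(1000, {
    r <- oracle_rarefy(cnt, 300)
    p <- r[r > 0] / 300
    -sum(p * log2(p))
  })
  mc_se <- sd(oracle) * sqrt(1 / 50 + 1 / 1000)
  expect_lt(abs(a$shannon - mean(oracle)), 3 * mc_se)
})

test_that("between-subject spread of rarefied Shannon shrinks with reps", {
  cnt <- as.integer(rmultinom(1, 5000, prob = rep(1, 25))[, 1])
  tab <- matrix(rep(cnt, 12), 12, 25, byrow = TRUE,
                dimnames = list(paste0("s", 1:12), paste0("o", 1:25)))
  a5 <- rarefied_alpha(tab, depth = 500, reps = 5, seed = 2)
  a200 <- rarefied_alpha(tab, depth = 500, reps = 200, seed = 2)
  expect_lt(sd(a200$shannon), sd(a5$shannon))
})

test_that("standardized diversity columns have mean 0 and unit SD", {
  a <- small_alpha()
  for (m in c("shannon", "simpson", "observed_otus", "chao1")) {
    expect_lt(abs(mean(a[[paste0(m, "_std")]])), 1e-9)
    expect_equal(sd(a[[paste0(m, "_std")]]), 1, tolerance = 1e-9)
  }
  # chao1 >= observed OTUs on the same rarefied samples
  expect_true(all(a$chao1 >= a$observed_otus - 1e-9))
})

test_that("log relative abundance applies the pseudocount transform", {
  tab <- matrix(c(9L, 1L, 0L), 1, 3)
  lr <- log_relative_abundance(tab)
  expect_equal(lr[1, 3], log10(1e-6))
  expect_equal(lr[1, 1], log10(0.9 + 1e-6))
})
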