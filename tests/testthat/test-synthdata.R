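test_that("invalid configurations are rejected with the field name", {
  expect_error(sim_config(twin_fraction = 1.4), "twin_fraction")
  expect_error(sim_config(family_icc = 1), "family_icc")
  expect_error(sim_config(n_causal = 700), "n_causal")
  expect_error(sim_config(causal_loadings = c(0.2, 0.3)), "causal_loadings")
  expect_error(sim_config(or_per_score_unit = -2), "or_per_score_unit")
  expect_error(sim_config(baseline_hazard = 0), "baseline_hazard")
})

test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- small_sim_config(seed = 303)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  r1 <- simulate_replication_cohort(cfg)
  r2 <- simulate_replication_cohort(cfg)
  expect_identical(r1, r2)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); x <- rnorm(1)
  set.seed(1); invisible(simulate_cohort(cfg)); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("cohort tables are internally consistent", {
  co <- small_cohort()
  ph <- co$phenotypes
  expect_setequal(rownames(co$otu_counts), ph$subject_id)
  expect_setequal(rownames(co$metabolites$values), ph$subject_id)
  expect_true(all(co$truth$causal_ids %in% colnames(co$metabolites$values)))
  expect_true(all(co$otu_counts >= 0))
  expect_true(all(rowSums(co$otu_counts) > 0))
  # prevalent cases carry no follow-up and are never incident
  expect_true(all(is.na(ph$followup_time[ph$t2d_prevalent == 1])))
  expect_true(all(ph$t2d_incident[ph$t2d_prevalent == 1] == 0))
  expect_true(all(ph$followup_time[ph$t2d_prevalent == 0] > 0))
  # left-censored missingness never removes a whole run-day column
  expect_error(impute_runday_min(co$metabolites), NA)
})

test_that("replication cohort has no OTU table but keeps the latent truth", {
  rep_co <- simulate_replication_cohort(small_sim_config(seed = 77))
  expect_null(rep_co$otu_counts)
  expect_length(rep_co$truth$latent_diversity, nrow(rep_co$phenotypes))
  expect_gt(length(unique(rep_co$phenotypes$sex)), 1L)
  expect_gt(length(unique(rep_co$phenotypes$center)), 1L)
  # unrelated: every family is a singleton
  expect_equal(anyDuplicated(rep_co$phenotypes$family_id), 0L)
})

test_that("within-pair correlation of latent diversity matches the ICC", {
  # enough pairs that the +-0.05 band sits several sampling SDs out
  cfg <- sim_config(n_subjects = 4000, twin_fraction = 1, family_icc = 0.4,
                    n_otus = 20, n_metabolites = 10, n_causal = 2,
                    causal_loadings = c(0.3, -0.3), depth_mean = 1500,
                    seed = 505)
  co <- simulate_cohort(cfg)
  d <- co$truth$latent_diversity
  fam <- co$phenotypes$family_id
  pairs <- split(seq_along(d), fam)
  pairs <- pairs[lengths(pairs) == 2L]
  m <- t(vapply(pairs, function(i) d[i], numeric(2)))
  expect_gt(nrow(m), 500)
  expect_lt(abs(cor(m[, 1], m[, 2]) - 0.4), 0.05)
})

test_that("realized Shannon diversity tracks the latent scale", {
  co <- small_cohort()
  a <- small_alpha()
  d <- co$truth$latent_diversity[a$subject_id]
  expect_gt(cor(a$shannon, d, method = "spearman"), 0.5)
})

test_that("observed prevalence matches the logistic model's implied rate", {
  cfg <- sim_config(n_subjects = 5000, n_otus = 20, n_metabolites = 12,
                    n_causal = 2, causal_loadings = c(0.4, -0.4),
                    depth_mean = 1500, seed = 909)
  rep_co <- simulate_replication_cohort(cfg)
  implied <- mean(plogis(rep_co$truth$prevalence_linear_predictor))
  observed <- mean(rep_co$phenotypes$t2d_prevalent)
  mc_se <- sqrt(implied * (1 - implied) / 5000)
  expect_lt(abs(observed - implied), 2 * mc_se + 1e-9)
})

test_that("null loadings produce calibrated screening p-values", {
  cfg <- sim_config(n_subjects = 150, n_otus = 40, n_metabolites = 250,
                    n_causal = 2, causal_loadings = c(0, 0),
                    missing_rate = 0, depth_mean = 2000, seed = 61)
  co <- simulate_cohort(cfg)
  a <- rarefied_alpha(co$otu_counts, depth = 800, reps = 5, seed = 3)
  idx <- match(a$subject_id, co$phenotypes$subject_id)
  prepped <- prep_metabolites(co$metabolites)
  scr <- screen_all(a$shannon_std, prepped$values[idx, , drop = FALSE],
                    co$phenotypes[idx, c("age", "bmi")],
                    co$phenotypes$family_id[idx],
                    screen_config(0.1, 250))
  frac <- mean(scr$results$p_value < 0.05)
  # all metabolites are null here; rejection at 0.05 within 3 binomial SEs
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 250))
})

test_that("cohort files round-trip as plain text", {
  dir <- withr::local_tempdir()
  co <- small_cohort()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("phenotypes.tsv", "metabolites.tsv", "otu_counts.tsv", "truth.json")))))
  ph <- read.delim(file.path(dir, "phenotypes.tsv"))
  expect_equal(nrow(ph), nrow(co$phenotypes))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(tr$causal_ids), co$truth$causal_ids,
               ignore_attr = TRUE)
  otu <- read.delim(file.path(dir, "otu_counts.tsv"), check.names = FALSE)
  expect_equal(as.integer(as.matrix(otu[, -1])),
               as.integer(co$otu_counts), ignore_attr = TRUE)
})
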