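# Shared fixtures, built in code. Small cohorts are memoized so several
# test files can reuse the same simulated data without regenerating it.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a small but complete twin cohort: 240 subjects, 60 OTUs, 80 metabolites
# (4 causal), modest sequencing depth so rarefaction at 1000 reads is fast
small_sim_config <- function(seed = 101, ...) {
  sim_config(n_subjects = 240, n_otus = 60, n_metabolites = 80,
             n_causal = 4, causal_loadings = c(0.5, -0.45, 0.5, -0.4),
             batch_count = 4, missing_rate = 0.05,
             depth_mean = 4000, seed = seed, ...)
}

small_cohort <- function() memo("small_cohort",
                                simulate_cohort(small_sim_config()))

small_alpha <- function() memo("small_alpha", {
  rarefied_alpha(small_cohort()$otu_counts, depth = 1000, reps = 10,
                 seed = 7)
})

small_prepped <- function() memo("small_prepped",
                                 prep_metabolites(small_cohort()$metabolites))

# independent brute-force rarefaction: expand to read level and subsample
oracle_rarefy <- function(counts, depth) {
  reads <- rep(seq_along(counts), counts)
  tabulate(sample(reads, depth), nbins = length(counts))
}

# published analyte slugs in model order
published_slugs <- function() names(published_mmd_model()$coefficients)

# a zero metabolite matrix carrying the published analyte columns
published_zero_matrix <- function(n = 1) {
  matrix(0, n, 6, dimnames = list(NULL, published_slugs()))
}
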