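---
title: "Methods: the Microbial Metabolite Diversity score, from OTU counts to mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Microbial Metabolite Diversity score, from OTU counts to mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdscore)
```

## The scientific problem

Reduced gut microbiome alpha diversity is a reproducible correlate of type 2
diabetes (T2D), but stool microbiome profiling is rarely available in large
epidemiological cohorts. Serum metabolites of microbial origin offer a
work-around: if a small set of circulating metabolites predicts microbiome
diversity, a blood-based *Microbial Metabolite Diversity* (MMD) score can
stand in for diversity in cohorts without 16S data, and mediation analysis
can ask how much of the diversity–T2D relationship travels through those
metabolites.

`mmdscore` implements that full analysis chain: alpha diversity from OTU
counts, metabolite preprocessing, a per-metabolite mixed-model screen,
score construction and out-of-sample evaluation, logistic/Cox outcome
models, two-cohort meta-analysis and potential-outcomes mediation. Because
the motivating cohort data (twin registries, replication cohorts) are
access-restricted, the package also ships a synthetic-cohort generator
that reproduces the statistical structure those analyses assume, so every
stage is exercised and validated end to end by the test suite.

## Alpha diversity

Diversity is computed on the OTU count table by repeated rarefaction:
each subject's counts are subsampled **without replacement** to a common
depth (default 10,000 reads, 50 repetitions) and the per-subsample
indices are averaged. Subjects under the depth are dropped, not scaled —
the standard semantics of rarefaction. Indices:

* **Shannon** \(H = -\sum_i p_i \log_2 p_i\) — log base 2 by default,
  which is the QIIME 1.9 convention and puts a typical gut community in
  the 3–6 bit range; `base` is an argument for users who prefer nats.
* **Simpson** \(D = 1 - \sum_i p_i^2\).
* **Observed OTUs** — the mean number of nonzero OTUs across rarefied
  replicates (fractional values are expected under averaging).
* **Chao1** — bias-corrected form
  \(S_{obs} + F_1(F_1-1)/(2(F_2+1))\) by default, which stays finite when
  doubletons are absent; the classic form is available by flag.

Each index is also standardized to mean 0, SD 1 across subjects
(denominator \(n-1\)), which is the scale the screen, the score and the
outcome models use. A pseudocount log-relative-abundance utility
(`log_relative_abundance()`, zero proportions replaced at \(10^{-6}\)) is
provided for taxon-level analyses but deliberately *not* used in the
diversity path: pseudocounted proportions would corrupt richness.

## Metabolite preprocessing

Mass-spectrometry metabolite panels are missing-not-at-random: values
below the detection limit vanish, and detection limits drift by run day.
The pipeline therefore:

1. **imputes** each missing cell with the *minimum observed value of that
   metabolite within the same run day* (`impute_runday_min()`), the
   natural fill under left-censoring; and then
2. **inverse-normal transforms** each metabolite column
   (`inverse_normal()`), the rank-based map
   \(\Phi^{-1}((r - 3/8)/(n + 1/4))\) with the Blom offset and average
   ranks for ties.

Imputation must precede the transform — ranks are undefined on incomplete
columns — and a state flag (`raw → imputed → inverse_normalized`)
enforces that order at the API level. The transform is equivariant to any
strictly monotone distortion of the raw values, so the choice of raw
intensity scale is immaterial downstream.

## Screening and score construction

Each transformed metabolite is tested against standardized Shannon
diversity with a **random-intercept linear mixed model**
(`diversity ~ metabolite + age + BMI + (1 | family)`, REML, Wald z test
on the metabolite effect) — the family intercept absorbs twin
relatedness. Fits that fail are refit without the random effect and
flagged. Selection uses a Bonferroni threshold, by default
\(0.1/596 = 1.68\times10^{-4}\); the denominator is configurable (the
count of named metabolites differs slightly between panel descriptions,
592 vs 596, so both are legal configurations and the threshold follows
the configured denominator).

Sex is *not* a default screening covariate because the motivating
discovery cohort is all-female; the pipeline adds sex and center to
outcome models automatically whenever the column actually varies.

The screen runs in a **discovery subset** (default one third of
subjects). The split is at the *family* level — both twins of a pair land
on the same side — to prevent leakage of the shared family effect into
the held-out evaluation. Whether the original analysis preserved pairs
this way is not documented; the family-level split is this package's
design choice.

The MMD score itself is ordinary least squares of standardized Shannon on
the selected metabolites jointly, **without covariates**: the published
formula contains only metabolite terms, and covariate adjustment belongs
to the outcome models. Collinearity is summarized by per-term variance
inflation factors; the published single "VIF = 1.38" figure does not say
whether it is a mean or a maximum, so `evaluate_score()` reports the
per-term values plus both summaries. The shipped
`published_mmd_model()` carries the published six-analyte coefficients
verbatim with an alias table (Metabolon-style names, abbreviations like
"IPA") so the constant model can be applied to external files by name.

## Outcome models and meta-analysis

Prevalent T2D uses maximum-likelihood logistic regression, incident T2D a
Cox model with Efron ties, baseline prevalent cases excluded from the
risk set, and a Schoenfeld-residual proportional-hazards p-value
attached. Follow-up time starts at study baseline; age enters as a
covariate, not as the timescale. Exposures are reported both in native
score units and per SD — cross-cohort score scales differ, and the per-SD
effect is what the pipeline pools. Family clustering is *not* modelled in
the outcome stage (mirroring the screening-only use of random intercepts
in the motivating analysis); a sensitivity adjustment for baseline
fasting glucose is a config toggle.

Two pooling methods are implemented by hand and cross-checked against
`metafor` in the tests:

* **Inverse-variance fixed effect**: weights \(1/se^2\), with Cochran's
  Q, \(I^2\) and a DerSimonian–Laird \(\tau^2\) for description.
* **Han–Eskin RE2**: the likelihood-ratio test of \(H_0: \mu = 0,
  \tau^2 = 0\) under \(b_k \sim N(\mu, se_k^2 + \tau^2)\), referred to
  the asymptotic \(\tfrac12\chi^2_1 + \tfrac12\chi^2_2\) mixture. The
  \(\tau^2\) profile is maximized by a coarse grid plus golden-section
  refinement (tolerance \(10^{-8}\)), constrained to \(\tau^2 \ge 0\).

A limitation stated openly: with only two studies the mixture null is
mildly **conservative** (simulated type-I ≈ 0.03 at nominal 0.05),
because \(\hat\tau^2\) lands on the boundary more than half the time at
\(K = 2\). The tabulated small-sample corrections that address this in
the metasoft software are out of scope here; p-values are labelled
asymptotic. `se_from_ci()` recovers log-scale SEs from printed ratio
CIs using \(z = 1.959964\) by default, with a 1.96 "printed convention"
flag — pooled results are insensitive to the choice at 2 decimal places.

## Mediation

The mediation stage asks how much of the effect of *high vs low
diversity* (dichotomized at the median; ties to LOW, a deterministic
rule) on T2D flows through the MMD score. Following the conventions of
probit-outcome mediation software:

1. mediator model: linear \(M \sim T + X\);
2. outcome model: **probit** \(Y \sim T + M + X\) (logit by flag);
3. quasi-Bayesian inference: `n_draws` (default 1000) parameter vectors
   drawn from each model's asymptotic normal sampling distribution (the
   residual variance from its scaled inverse-\(\chi^2\));
4. per draw, subject-level potential-outcome probabilities are averaged;
   the mediator residual integrates out analytically under the probit
   link via \(\Phi\big((\eta + \gamma_M \mu_M)/\sqrt{1 +
   \gamma_M^2\sigma^2}\big)\), so no mediator simulation is needed;
5. ACME and ADE are averaged over the two treatment regimes and reported
   on the **probability (risk-difference) scale**; total = ACME + ADE
   holds exactly draw by draw; intervals are 2.5/97.5 percentiles.

The proportion mediated (VAF) is the ratio of indirect to total effect:
point estimate from the point effects, interval from per-draw ratios.
The ratio is ill-behaved when the total effect is near zero, so draws
with \(|total| < 0.05\,\mathrm{sd}(total)\) are excluded and counted,
with a warning past 20% — that instability is also why VAF intervals are
characteristically wide.

## The synthetic-cohort generator

`simulate_cohort()` emulates the *structure* the analyses assume, not any
real dataset:

* **Twin families.** Latent diversity \(d_i = \sqrt{\rho}\,f_{fam} +
  \sqrt{1-\rho}\,e_i\) with intra-class correlation `family_icc`
  (default 0.4); 80% of subjects sit in complete pairs.
* **OTU counts.** Dirichlet-multinomial with a fixed lognormal base
  composition and total concentration \(40\,e^{0.8 d_i}\); sequencing
  depth lognormal with mean 30,000 (3× the default rarefaction depth,
  CV 0.25). This is the simplest mechanism that makes realized,
  rarefied Shannon diversity track a latent scalar; at the defaults the
  realized index averages ≈ 4.3 bits (SD ≈ 0.7) and correlates ≈ 0.85
  with \(d_i\) — calibrated once at design time and not revisited.
* **Metabolites.** 596 columns; six causal ones load on standardized
  \(d_i\) with signed loadings (defaults 0.35–0.5 SD, four positive and
  two negative, echoing the published sign pattern); all columns get a
  run-day batch shift (SD 0.3 across 10 run-days) and unit noise; raw
  intensities are lognormal. Missingness is **left-censored**: within
  each run-day the lowest 5% of each metabolite falls below detection —
  which is exactly the regime where run-day-minimum imputation is the
  right fill. No generative details for the metabolite–diversity links
  exist in the motivating work (only associations are reported), so the
  loadings are free configuration, not published values.
* **Outcomes.** The "true score" is the realized causal-metabolite
  combination (signal + measurement noise, batch excluded),
  standardized. Prevalent T2D is Bernoulli with
  \(\text{logit}^{-1}(-3.75 + \log(0.22)\,s_i)\) — intercept chosen for
  ≈ 5% marginal prevalence under the protective default effect; incident
  times are exponential with hazard \(0.006 \times 0.31^{s_i}\)/year,
  censored administratively at Normal(8.16, 1.3) years truncated at 1.
  Outcomes depend on diversity *only through the score* — full mediation
  by construction — so end-to-end VAF estimates concentrate around 1.
* **Causal positions** are evenly spaced over the panel rather than
  drawn per cohort: a score fitted in one cohort must transfer to the
  replication cohort by metabolite ID, which requires the causal
  identities to be shared across cohorts.
* `simulate_replication_cohort()` drops the OTU table (the replication
  setting has no 16S data), mixes sexes, adds a center label and removes
  family structure; the latent diversity that drives its metabolites is
  kept in the `truth` record.

Age, BMI and the metabolic traits are independent of latent diversity in
the generator (the traits correlate mildly with the score only), which
keeps the null-calibration properties of the screen and outcome models
clean. Real cohorts are messier: covariate–diversity confounding,
non-lognormal abundance profiles, phylogenetic structure, diet. Passing
tests on these cohorts therefore validate the *statistical machinery*,
not the biology of any particular dataset.

The `truth` record (latent diversity, causal IDs and loadings, the true
score, outcome parameters) is always emitted; it is a test fixture for
parameter-recovery checks, never an input to the pipeline.

## Numerical and interface choices

* Rarefaction subsamples are drawn by index inversion
  (`sample.int` + `findInterval` on cumulative counts), exact sampling
  without replacement at \(O(N)\) per replicate.
* All stage seeds derive deterministically from one master seed; RNG
  state is saved and restored around every seeded operation, so
  simulations never disturb the caller's stream and a fixed
  configuration reproduces the full study report identically.
* Degenerate inputs error early with the offending field or column
  named: empty communities, constant columns, rank-deficient score
  designs, run-day×metabolite cells with no observed values, separation
  in the logistic/probit fits.
* Non-converged mixed models fall back to OLS and are flagged rather
  than aborting a 596-metabolite sweep.
* The exported functions and `run_study()` are the interface; stage
  artifacts (TSV tables, JSON models and effects) are written by
  `run_study(..., out_dir = )` and `write_cohort()` for use outside R.

## Problem sizes used in validation

The automated suite validates at reduced but fully-powered scales chosen
as a deliberate design point: module tests use cohorts of 240–330
subjects with 60–80 metabolites and rarefaction at 1,000 reads; the
calibration checks use 500 null replicates (mixed-model type-I), 2,000
replicates (RE2 null) and 50 seeds at n = 5,000 (mediation coverage
against a counterfactual oracle with the true parameters); the
end-to-end reproducibility check runs the default-scale study
(1,000/1,500 subjects, 596 metabolites, 10,000×50 rarefaction) twice and
requires identical reports. `scripts/acceptance.R` re-runs the
printed-value reproductions and a full default-scale study from a single
command-line seed.

## Known limitations

* The RE2 p-value is asymptotic and conservative for two studies (above).
* Mediation assumes sequential ignorability; no sensitivity analysis for
  unmeasured mediator–outcome confounding is provided.
* The published six-metabolite coefficients cannot be re-derived without
  the restricted cohort data; they are shipped as a constant and
  validated arithmetically.
* Beta diversity, phylogenetic metrics (UniFrac, Faith's PD) and
  upstream read processing are out of scope — the pipeline starts at the
  OTU count table.
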