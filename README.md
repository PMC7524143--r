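# mmdscore

Serum metabolite scores for gut microbiome diversity and type 2 diabetes
risk.

Low gut microbiome alpha diversity accompanies type 2 diabetes (T2D), but
stool 16S profiling is missing from most large cohorts. A small set of
circulating microbial metabolites can stand in for it: a **Microbial
Metabolite Diversity (MMD) score** — a linear combination of six serum
metabolites — predicts Shannon diversity, associates with prevalent and
incident T2D, and lets mediation analysis ask how much of the
diversity→T2D effect travels through microbial metabolites.

`mmdscore` implements that analysis chain for biostatisticians and
microbiome epidemiologists:

* **Alpha diversity** from an OTU count table by repeated rarefaction
  (default 10,000 reads × 50 subsamples, averaged): Shannon
  (H = −Σ pᵢ log₂ pᵢ), Simpson (1 − Σ pᵢ²), observed OTUs and
  bias-corrected Chao1 (S + F₁(F₁−1)/(2(F₂+1))), plus standardization.
* **Metabolite preprocessing**: run-day-minimum imputation for
  left-censored missingness, then rank-based inverse-normal
  transformation (Blom offset, Φ⁻¹((r − 3/8)/(n + ¼))).
* **Screening**: per-metabolite random-intercept mixed models
  (`diversity ~ metabolite + age + BMI + (1 | family)`) with Bonferroni
  selection (default 0.1/596 = 1.68×10⁻⁴).
* **Score construction**: OLS of standardized Shannon on the selected
  metabolites in a family-level discovery split, evaluated out of sample
  (R², Pearson r, per-term VIF). The published six-metabolite model ships
  as a constant with an alias table for external application.
* **Outcome models**: logistic (prevalent T2D) and Cox (incident T2D,
  Efron ties, prevalent cases excluded, Schoenfeld PH diagnostic), plus
  covariate-adjusted partial-correlation matrices for metabolic traits.
* **Meta-analysis**: inverse-variance fixed effect and the Han–Eskin RE2
  likelihood-ratio test (H₀: μ = 0, τ² = 0 under bₖ ~ N(μ, seₖ² + τ²),
  ½χ²₁ + ½χ²₂ mixture null).
* **Mediation**: potential-outcomes ACME/ADE/total on the risk-difference
  scale for a median-dichotomized treatment, linear mediator and probit
  outcome, quasi-Bayesian intervals, and the proportion mediated (VAF).
* A **synthetic-cohort generator** (twin families, Dirichlet-multinomial
  OTU counts linked to a latent diversity scale, a 596-metabolite panel
  with six causal metabolites, run-day batches with left-censored
  missingness, score-driven T2D outcomes) so the whole chain runs and
  validates without access-restricted data.

## Worked example

The published score model is a shipped constant:

```r
library(mmdscore)
published_mmd_model()
#> <score_model> (published) 6 terms
#>   intercept: -0.0476306
#>   +0.1746576 * three_phenylpropionate
#>   -0.0867652 * imidazole_propionate
#>   +0.1461903 * cinnamoylglycine
#>   +0.1674953 * pregnanediol_monosulfate
#>   -0.145269 * glutarate
#>   +0.0683178 * indolepropionate
```

Applied to all-zero (i.e. panel-average, on the inverse-normal scale)
inputs it returns its intercept, −0.0476306; higher 3-phenylpropionate,
indolepropionate, cinnamoylglycine and pregnanediol monosulfate push the
score (and predicted diversity) up, imidazole propionate and glutarate
push it down.

Pooling two printed incident-T2D hazard ratios (0.31 [0.11, 0.90] and
0.87 [0.79, 0.95]) recovers their meta-analytic summary:

```r
meta_from_ratio_ci(list(c(0.31, 0.11, 0.90), c(0.87, 0.79, 0.95)))
#> <meta_result> k = 2: pooled = -0.1471 (SE 0.0469), FE P = 0.00169
#>   Q = 3.675, I2 = 72.8%, tau2 = 0.3876
#>   RE2 stat = 9.857, P = 0.00447 (tau2_hat = 0)
```

`exp(-0.1471)` = **0.86**: a 14% lower incident-T2D hazard per score SD,
significant under both the fixed-effect and RE2 tests despite the
between-cohort heterogeneity (I² = 73%).

A complete synthetic study — two cohorts, rarefaction, preprocessing,
screen, score, outcome models, meta-analysis, mediation — runs from one
seed (about 80 s at the default 1018/1522-subject scale):

```r
report <- run_study(study_config(seed = 42))
report
#> <mmd_study_report>
#>   n: discovery 339, test 679, replication 1522 (0 dropped at rarefaction)
#>   screen: 6 / 596 metabolites selected (threshold 0.000168)
#>   score R2: discovery 0.462, test 0.427
#>   prevalent T2D OR/SD: twins 0.235, replication 0.254, pooled 0.246 (FE P = 7.98e-38)
#>   incident T2D HR/SD: twins 0.335, replication 0.314, pooled 0.322 (FE P = 9.99e-41)
#>   mediation: ACME -0.0804, ADE 0.0080, VAF 1.110 [0.722, 1.969]
```

Reading it: the screen found exactly the six causal metabolites planted
by the generator among 596; the score fitted on 339 discovery subjects
explains 43% of Shannon variance out of sample; the fitted odds ratio
0.235 per score SD recovers the generating protective effect (true OR
0.22); and because the generator routes the entire diversity effect
through the metabolites, the mediated proportion (VAF) concentrates
around 1 — the direct effect's interval covers zero. `run_study(cfg,
out_dir = "...")` additionally writes every stage artifact (cohort TSVs,
screen table, score-model and effects JSON, the adjusted correlation
matrix) as plain text.

The methods vignette (`vignettes/mmd-methods.Rmd`) documents the models,
the generator's assumptions and what the validation does and does not
show about real data.

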