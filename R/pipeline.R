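# End-to-end study replica: simulate a twin discovery cohort and an
# unrelated replication cohort, compute rarefied diversity, preprocess
# metabolites, split families, screen, fit and evaluate the score, run
# outcome models in both cohorts, meta-analyse, and mediate.

#' Study configuration
#'
#' Bundles the generator settings for both cohorts with the analysis
#' parameters. Stage seeds are derived deterministically from `seed`.
#'
#' @param sim [sim_config()] for the twin discovery cohort.
#' @param sim_replication [sim_config()] for the unrelated replication
#'   cohort (metabolites + outcomes, no microbiome).
#' @param discovery_fraction fraction of subjects (whole families) in the
#'   discovery split, default 1/3.
#' @param screen a [screen_config()].
#' @param rarefaction_depth,rarefaction_reps rarefaction parameters
#'   (defaults 10000 reads, 50 repetitions).
#' @param mediation_draws quasi-Bayesian draws for the mediation stage.
#' @param adjust_fasting_glucose also fit outcome models additionally
#'   adjusted for baseline fasting glucose (sensitivity analysis).
#' @param seed master seed.
#' @return object of class `study_config`.
#' @export
study_config <- function(sim = sim_config(),
                         sim_replication = sim_config(n_subjects = 1522),
                         discovery_fraction = 1 / 3,
                         screen = screen_config(),
                         rarefaction_depth = 10000,
                         rarefaction_reps = 50,
                         mediation_draws = 1000,
                         adjust_fasting_glucose = FALSE,
                         seed = 1L) {
  if (discovery_fraction <= 0 || discovery_fraction >= 1)
    stop_field("discovery_fraction", "must be in (0, 1)")
  structure(list(sim = sim, sim_replication = sim_replication,
                 discovery_fraction = discovery_fraction,
                 screen = screen,
                 rarefaction_depth = rarefaction_depth,
                 rarefaction_reps = rarefaction_reps,
                 mediation_draws = mediation_draws,
                 adjust_fasting_glucose = adjust_fasting_glucose,
                 seed = as.integer(seed)),
            class = "study_config")
}

# deterministic stage seeds, kept well inside 32-bit range
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 101L + stage
}

outcome_covariates <- function(ph, extra_glucose = FALSE) {
  cov <- ph[, c("age", "bmi"), drop = FALSE]
  if (length(unique(ph$sex)) > 1L) cov$sex <- ph$sex
  if (length(unique(ph$center)) > 1L) cov$center <- ph$center
  if (extra_glucose) cov$fasting_glucose <- ph$fasting_glucose
  cov
}

cohort_outcome_models <- function(ph, score, extra_glucose = FALSE) {
  cov <- outcome_covariates(ph, extra_glucose)
  score_sd <- score / stats::sd(score)
  list(
    prevalent = logistic_association(ph$t2d_prevalent, score, cov),
    prevalent_per_sd = logistic_association(ph$t2d_prevalent, score_sd, cov),
    incident = cox_association(ph$followup_time, ph$t2d_incident, score,
                               cov, prevalent = ph$t2d_prevalent),
    incident_per_sd = cox_association(ph$followup_time, ph$t2d_incident,
                                      score_sd, cov,
                                      prevalent = ph$t2d_prevalent)
  )
}

#' Run the full study replica
#'
#' Executes simulate (both cohorts) -> rarefied diversity -> metabolite
#' preprocessing -> family-level discovery/test split -> mixed-model screen
#' (discovery) -> OLS score fit (discovery) -> score evaluation (discovery
#' in-sample and test out-of-sample) -> logistic/Cox outcome models in both
#' cohorts (the replication cohort always uses the discovery-fitted model,
#' never a refit) -> fixed-effect and RE2 meta-analysis across cohorts ->
#' mediation of dichotomized diversity through the score (discovery cohort
#' only, where microbiome data exist). All randomness derives from
#' `cfg$seed`, so a fixed configuration reproduces the report exactly.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; when given, stage artifacts
#'   (cohort TSVs, screen table, score model JSON, effects JSON) are
#'   written there.
#' @return object of class `mmd_study_report`.
#' @export
run_study <- function(cfg = study_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim_cfg <- cfg$sim; sim_cfg$seed <- stage_seed(cfg$seed, 1L)
  rep_cfg <- cfg$sim_replication; rep_cfg$seed <- stage_seed(cfg$seed, 2L)
  twins <- stage("simulate_discovery", simulate_cohort(sim_cfg))
  repl_cohort <- stage("simulate_replication",
                simulate_replication_cohort(rep_cfg))

  alpha <- stage("diversity",
                 rarefied_alpha(twins$otu_counts,
                                depth = cfg$rarefaction_depth,
                                reps = cfg$rarefaction_reps,
                                seed = stage_seed(cfg$seed, 3L)))
  # align the twin cohort to subjects retained after rarefaction
  keep <- match(alpha$subject_id, twins$phenotypes$subject_id)
  ph <- twins$phenotypes[keep, , drop = FALSE]

  metab <- stage("prep_metabolites", prep_metabolites(twins$metabolites))
  mvals <- metab$values[keep, , drop = FALSE]
  metab_rep <- stage("prep_metabolites_replication",
                     prep_metabolites(repl_cohort$metabolites))

  shannon_std <- alpha$shannon_std
  is_disc <- stage("split",
                   family_split(ph$family_id, cfg$discovery_fraction,
                                seed = stage_seed(cfg$seed, 4L)))

  cov_screen <- ph[, cfg$screen$covariates, drop = FALSE]
  scr <- stage("screen",
               screen_all(shannon_std[is_disc],
                          mvals[is_disc, , drop = FALSE],
                          cov_screen[is_disc, , drop = FALSE],
                          ph$family_id[is_disc], cfg$screen))
  if (!length(scr$selected))
    stop("stage 'screen' failed: no metabolite passed the Bonferroni ",
         "threshold; cannot build a score", call. = FALSE)

  model <- stage("fit_score",
                 fit_score(shannon_std[is_disc],
                           mvals[is_disc, scr$selected, drop = FALSE]))
  score_disc <- apply_score(model, mvals[is_disc, , drop = FALSE])
  score_test <- apply_score(model, mvals[!is_disc, , drop = FALSE])
  score_all <- apply_score(model, mvals)
  eval_disc <- evaluate_score(score_disc, shannon_std[is_disc],
                              mvals[is_disc, scr$selected, drop = FALSE])
  eval_test <- evaluate_score(score_test, shannon_std[!is_disc])

  effects_twins <- stage("outcomes_discovery",
                         cohort_outcome_models(ph, score_all,
                                               cfg$adjust_fasting_glucose))
  score_rep <- apply_score(model, metab_rep$values)
  effects_rep <- stage("outcomes_replication",
                       cohort_outcome_models(repl_cohort$phenotypes, score_rep,
                                             cfg$adjust_fasting_glucose))

  meta_prev <- stage("meta", han_eskin_re2(
    c(effects_twins$prevalent_per_sd$estimate,
      effects_rep$prevalent_per_sd$estimate),
    c(effects_twins$prevalent_per_sd$se,
      effects_rep$prevalent_per_sd$se)))
  meta_inc <- stage("meta", han_eskin_re2(
    c(effects_twins$incident_per_sd$estimate,
      effects_rep$incident_per_sd$estimate),
    c(effects_twins$incident_per_sd$se,
      effects_rep$incident_per_sd$se)))

  med <- stage("mediation", mediate(
    treatment = dichotomize_diversity(shannon_std),
    mediator = score_all,
    outcome = ph$t2d_prevalent,
    covariates = ph[, c("age", "bmi")],
    n_draws = cfg$mediation_draws,
    seed = stage_seed(cfg$seed, 5L)))

  # Fig 2-style adjusted correlation matrix in the full twin cohort
  traits <- cbind(bmi = ph$bmi, vfat = ph$visceral_fat,
                  homa2_ir = ph$homa2_ir, glucose = ph$fasting_glucose)
  micro <- cbind(mmd_score = score_all, shannon = alpha$shannon_std,
                 observed_otus = alpha$observed_otus_std,
                 simpson = alpha$simpson_std, chao1 = alpha$chao1_std)
  corr <- stage("correlations",
                adjusted_correlation_matrix(traits, micro,
                                            ph[, c("age", "bmi")]))

  report <- structure(list(
    config = cfg,
    n = list(discovery = sum(is_disc), test = sum(!is_disc),
             replication = nrow(repl_cohort$phenotypes),
             dropped_rarefaction = attr(alpha, "n_dropped")),
    alpha = alpha,
    screen = scr,
    score_model = model,
    score_eval = list(discovery = eval_disc, test = eval_test),
    effects = list(twins = effects_twins, replication = effects_rep),
    meta = list(prevalent = meta_prev, incident = meta_inc),
    mediation = med,
    correlations = corr,
    truth = list(twins = twins$truth, replication = repl_cohort$truth),
    provenance = list(seed = cfg$seed,
                      package_version =
                        as.character(utils::packageVersion("mmdscore")))),
    class = "mmd_study_report")
  if (!is.null(out_dir)) write_report(report, twins, repl_cohort, out_dir)
  report
}

write_report <- function(report, twins, repl_cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(twins, file.path(out_dir, "cohort_twins"))
  write_cohort(repl_cohort, file.path(out_dir, "cohort_replication"))
  utils::write.table(report$screen$results,
                     file.path(out_dir, "screen_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$alpha, file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(intercept = report$score_model$intercept,
                            coefficients =
                              as.list(report$score_model$coefficients),
                            provenance = report$score_model$provenance),
                       file.path(out_dir, "score_model.json"),
                       auto_unbox = TRUE, digits = NA)
  flatten_effect <- function(e) e[c("scale", "estimate", "se", "ci_low",
                                    "ci_high", "p_value", "n", "n_events")]
  jsonlite::write_json(
    lapply(report$effects, function(ch) lapply(ch, flatten_effect)),
    file.path(out_dir, "effects.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(pair = outer(rownames(report$correlations$r),
                            colnames(report$correlations$r),
                            paste, sep = " x ") |> as.vector(),
               r = as.vector(report$correlations$r),
               p = as.vector(report$correlations$p)),
    file.path(out_dir, "figure2_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.mmd_study_report <- function(x, ...) {
  cat("<mmd_study_report>\n")
  cat(sprintf("  n: discovery %d, test %d, replication %d (%d dropped at rarefaction)\n",
              x$n$discovery, x$n$test, x$n$replication,
              x$n$dropped_rarefaction))
  cat(sprintf("  screen: %d / %d metabolites selected (threshold %.3g)\n",
              length(x$screen$selected), nrow(x$screen$results),
              x$screen$threshold))
  cat(sprintf("  score R2: discovery %.3f, test %.3f\n",
              x$score_eval$discovery$r2, x$score_eval$test$r2))
  cat(sprintf("  prevalent T2D OR/SD: twins %.3f, replication %.3f, pooled %.3f (FE P = %.3g)\n",
              exp(x$effects$twins$prevalent_per_sd$estimate),
              exp(x$effects$replication$prevalent_per_sd$estimate),
              exp(x$meta$prevalent$pooled_estimate), x$meta$prevalent$fe_p))
  cat(sprintf("  incident T2D HR/SD: twins %.3f, replication %.3f, pooled %.3f (FE P = %.3g)\n",
              exp(x$effects$twins$incident_per_sd$estimate),
              exp(x$effects$replication$incident_per_sd$estimate),
              exp(x$meta$incident$pooled_estimate), x$meta$incident$fe_p))
  cat(sprintf("  mediation: ACME %.4f, ADE %.4f, VAF %.3f [%.3f, %.3f]\n",
              x$mediation$acme$estimate, x$mediation$ade$estimate,
              x$mediation$vaf$estimate, x$mediation$vaf$ci_low,
              x$mediation$vaf$ci_high))
  invisible(x)
}

#' Apply the published score to a metabolite file
#'
#' Reads a tab-separated metabolite table (subjects in rows), resolves
#' column names against the published-analyte alias table (Metabolon-style
#' names and abbreviations such as `"IPA"` both work), applies the shipped
#' published model and returns per-subject scores with a distribution
#' summary.
#'
#' @param metabolites a file path to a TSV, or a numeric matrix / data
#'   frame with metabolite columns.
#' @return list with `scores` (named numeric vector) and `summary`
#'   (mean, sd, quantiles).
#' @export
published_score_report <- function(metabolites) {
  if (is.character(metabolites)) {
    df <- utils::read.delim(metabolites, check.names = FALSE)
    idcol <- which(tolower(colnames(df)) %in% c("subject_id", "id", "sample"))
    ids <- if (length(idcol)) as.character(df[[idcol[1]]])
           else sprintf("S%04d", seq_len(nrow(df)))
    if (length(idcol)) df <- df[, -idcol[1], drop = FALSE]
    metabolites <- as.matrix(df[vapply(df, is.numeric, logical(1))])
    rownames(metabolites) <- ids
  } else {
    metabolites <- as.matrix(metabolites)
  }
  model <- published_mmd_model()
  slugs <- resolve_analyte(colnames(metabolites))
  resolved <- !is.na(slugs) & !duplicated(slugs)
  mat <- metabolites[, resolved, drop = FALSE]
  colnames(mat) <- slugs[resolved]
  missing_slugs <- setdiff(names(model$coefficients), colnames(mat))
  if (length(missing_slugs)) {
    an <- published_analytes()
    msg <- vapply(missing_slugs, function(s)
      sprintf("%s (aliases tried: %s)", an[[s]]$display,
              paste(an[[s]]$aliases, collapse = "; ")), character(1))
    stop("unresolvable analyte column(s): ", paste(msg, collapse = " | "),
         call. = FALSE)
  }
  scores <- apply_score(model, mat)
  names(scores) <- rownames(mat)
  list(scores = scores,
       summary = c(n = length(scores), mean = mean(scores),
                   sd = stats::sd(scores),
                   stats::quantile(scores, c(0.025, 0.25, 0.5, 0.75, 0.975))))
}
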