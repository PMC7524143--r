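# The Microbial Metabolite Diversity (MMD) score: an ordinary
# least-squares combination of the metabolites selected by the screen,
# plus the published six-metabolite model shipped as a constant.

#' Construct a score model
#'
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector: score units per (transformed)
#'   metabolite unit.
#' @param provenance `"fitted"` or `"published"`.
#' @return object of class `score_model`.
#' @export
score_model <- function(intercept, coefficients,
                        provenance = c("fitted", "published")) {
  provenance <- match.arg(provenance)
  if (length(coefficients) < 1L || is.null(names(coefficients)))
    stop("coefficients must be a named vector with >= 1 term", call. = FALSE)
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 provenance = provenance),
            class = "score_model")
}

#' @export
print.score_model <- function(x, digits = 7, ...) {
  cat(sprintf("<score_model> (%s) %d terms\n", x$provenance,
              length(x$coefficients)))
  cat(sprintf("  intercept: %.*g\n", digits, x$intercept))
  for (nm in names(x$coefficients))
    cat(sprintf("  %+.*g * %s\n", digits, x$coefficients[[nm]], nm))
  invisible(x)
}

# Canonical slugs and display names for the six published analytes, with
# aliases covering Metabolon-style names and common abbreviations.
published_analytes <- function() {
  list(
    three_phenylpropionate = list(
      display = "3-phenylpropionate (hydrocinnamate)",
      aliases = c("3-phenylpropionate (hydrocinnamate)", "3-phenylpropionate",
                  "hydrocinnamate", "phenylpropionate", "phenylp",
                  "3-phenylpropionatehydrocinnamate")),
    imidazole_propionate = list(
      display = "imidazole propionate",
      aliases = c("imidazole propionate", "imidazolepropionate",
                  "imidazolep", "4-imidazoleacetate propionate")),
    cinnamoylglycine = list(
      display = "cinnamoylglycine",
      aliases = c("cinnamoylglycine", "cinnamoylgl", "cinnamoyl glycine")),
    pregnanediol_monosulfate = list(
      display = "5alpha-pregnan-3beta,20alpha-diol monosulfate (2)",
      aliases = c("5alpha-pregnan-3beta,20alpha-diol monosulfate (2)",
                  "5alphapregnan_3beta,20alpha_diolmonosulfate2",
                  "pregnanediol monosulfate", "alphapregan",
                  "5alpha-pregnan-3beta-20alpha-diol-monosulfate-2")),
    glutarate = list(
      display = "glutarate (pentanedioate)",
      aliases = c("glutarate (pentanedioate)", "glutarate", "pentanedioate",
                  "glutaratepentanedioate")),
    indolepropionate = list(
      display = "indolepropionate",
      aliases = c("indolepropionate", "ipa", "indole propionate",
                  "3-indolepropionate", "indole-3-propionate"))
  )
}

normalize_analyte_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Resolve metabolite names to canonical score-analyte slugs
#'
#' Matches names case-insensitively after stripping punctuation against an
#' alias table covering Metabolon-style names and common abbreviations
#' (e.g. both `"indolepropionate"` and `"IPA"` map to the same analyte).
#'
#' @param names character vector of metabolite names.
#' @return character vector of canonical slugs, `NA` where unresolved.
#' @export
resolve_analyte <- function(names) {
  an <- published_analytes()
  lut <- unlist(lapply(names(an), function(slug) {
    stats::setNames(rep(slug, length(an[[slug]]$aliases) + 1L),
                    normalize_analyte_name(c(slug, an[[slug]]$aliases)))
  }))
  out <- lut[normalize_analyte_name(names)]
  stats::setNames(unname(out), names)
}

#' The published six-metabolite MMD score
#'
#' The serum metabolite combination reported to predict gut microbiome
#' Shannon diversity: an intercept of -0.0476306 with positive weights on
#' 3-phenylpropionate, cinnamoylglycine, pregnanediol monosulfate and
#' indolepropionate and negative weights on imidazole propionate and
#' glutarate. Inputs are expected on the inverse-normalized scale.
#'
#' @return a `score_model` with `provenance = "published"`.
#' @examples
#' m <- published_mmd_model()
#' apply_score(m, matrix(0, 1, 6, dimnames = list(NULL,
#'   names(m$coefficients))))  # the intercept, -0.0476306
#' @export
published_mmd_model <- function() {
  score_model(
    intercept = -0.0476306,
    coefficients = c(
      three_phenylpropionate   =  0.1746576,
      imidazole_propionate     = -0.0867652,
      cinnamoylglycine         =  0.1461903,
      pregnanediol_monosulfate =  0.1674953,
      glutarate                = -0.145269,
      indolepropionate         =  0.0683178),
    provenance = "published")
}

#' Fit a diversity-prediction score by ordinary least squares
#'
#' Regresses standardized diversity jointly on the selected (transformed)
#' metabolites, without covariates: the score is a pure metabolite
#' combination; covariate adjustment happens later in the outcome models.
#'
#' @param diversity standardized diversity vector.
#' @param metabolites numeric matrix of the selected metabolites (colnames
#'   = metabolite IDs), aligned with `diversity`.
#' @return a `score_model` with `provenance = "fitted"`; attributes
#'   `r_squared` (in-sample) and `sigma`.
#' @export
fit_score <- function(diversity, metabolites) {
  stopifnot(is.matrix(metabolites), !is.null(colnames(metabolites)))
  n <- length(diversity)
  if (nrow(metabolites) != n) stop("misaligned inputs", call. = FALSE)
  if (n <= ncol(metabolites) + 1L)
    stop("need n > terms + 1", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, metabolites)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, diversity)
  cf <- fit$coefficients
  r2 <- 1 - sum(fit$residuals^2) / sum((diversity - mean(diversity))^2)
  out <- score_model(cf[1L], cf[-1L], provenance = "fitted")
  attr(out, "r_squared") <- r2
  attr(out, "sigma") <- sqrt(sum(fit$residuals^2) / (n - ncol(X)))
  out
}

#' Apply a score model to a metabolite matrix
#'
#' `score_i = intercept + sum_m coef_m * value_im`. All model metabolites
#' must be present as columns (use [resolve_analyte()] / the pipeline's
#' alias resolution for published-name matching).
#'
#' @param model a `score_model`.
#' @param metabolites numeric matrix with the model's metabolite IDs among
#'   its colnames.
#' @return numeric vector of per-subject scores.
#' @export
apply_score <- function(model, metabolites) {
  stopifnot(inherits(model, "score_model"), is.matrix(metabolites))
  need <- names(model$coefficients)
  missing_cols <- setdiff(need, colnames(metabolites))
  if (length(missing_cols))
    stop("missing metabolite column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  as.numeric(model$intercept +
               metabolites[, need, drop = FALSE] %*% model$coefficients)
}

#' Evaluate a score against a diversity metric
#'
#' Univariate regression `diversity ~ score`: R-squared, Pearson r, slope
#' and its standard error. When the metabolite design behind the score is
#' supplied, per-term variance inflation factors `1 / (1 - R^2_{m|others})`
#' and their mean and max are also reported (a mean VIF near 1 indicates
#' the score terms are nearly uncorrelated).
#'
#' @param score numeric score vector.
#' @param diversity_metric aligned diversity vector.
#' @param metabolite_design optional numeric matrix of the score's input
#'   metabolites for VIF computation.
#' @return list with `r2`, `pearson_r`, `beta`, `se`, `n`, and when a
#'   design is given `vif` (named), `vif_mean`, `vif_max`.
#' @export
evaluate_score <- function(score, diversity_metric,
                           metabolite_design = NULL) {
  n <- length(score)
  stopifnot(length(diversity_metric) == n)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(score) == 0) stop("zero-variance score", call. = FALSE)
  fit <- stats::lm(diversity_metric ~ score)
  sm <- summary(fit)
  out <- list(r2 = sm$r.squared,
              pearson_r = stats::cor(score, diversity_metric),
              beta = unname(stats::coef(fit)["score"]),
              se = sm$coefficients["score", 2],
              n = n)
  if (!is.null(metabolite_design)) {
    stopifnot(is.matrix(metabolite_design),
              nrow(metabolite_design) == n)
    vif <- vapply(seq_len(ncol(metabolite_design)), function(j) {
      if (ncol(metabolite_design) == 1L) return(1)
      r2j <- summary(stats::lm(metabolite_design[, j] ~
                                 metabolite_design[, -j, drop = FALSE]
                               ))$r.squared
      1 / (1 - r2j)
    }, numeric(1))
    names(vif) <- colnames(metabolite_design)
    out$vif <- vif
    out$vif_mean <- mean(vif)
    out$vif_max <- max(vif)
  }
  out
}
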