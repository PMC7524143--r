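# Per-metabolite association screen: standardized Shannon diversity
# regressed on each transformed metabolite with a family random intercept,
# Bonferroni selection across the panel.

#' Screening configuration
#'
#' @param alpha_total family-wise significance level (default 0.1).
#' @param n_tests Bonferroni denominator: the number of metabolites tested
#'   (default 596).
#' @param covariates names of fixed-effect covariates to adjust for
#'   (default age and BMI; sex is added automatically by the pipeline only
#'   when it varies within the cohort).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(alpha_total = 0.1, n_tests = 596,
                          covariates = c("age", "bmi")) {
  if (!is.finite(alpha_total) || alpha_total <= 0 || alpha_total > 1)
    stop_field("alpha_total", "must be in (0, 1]")
  if (!is.numeric(n_tests) || n_tests < 1)
    stop_field("n_tests", "must be a positive count")
  structure(list(alpha_total = alpha_total, n_tests = as.integer(n_tests),
                 covariates = covariates),
            class = "screen_config")
}

#' Bonferroni per-test threshold
#'
#' @param cfg a [screen_config()], or a numeric `alpha_total` when
#'   `n_tests` is given.
#' @param n_tests number of tests (used when `cfg` is numeric).
#' @return the per-test significance threshold `alpha_total / n_tests`.
#' @examples
#' bonferroni_threshold(screen_config())  # 0.1 / 596 = 1.678e-4
#' @export
bonferroni_threshold <- function(cfg, n_tests = NULL) {
  if (is.numeric(cfg)) cfg <- screen_config(cfg, n_tests)
  cfg$alpha_total / cfg$n_tests
}

#' Single-metabolite mixed-model association
#'
#' Fits `diversity ~ metabolite + covariates + (1 | family)` by REML and
#' reports the metabolite fixed effect with a Wald z test. Families of
#' size 1 are permitted. If the mixed-model fit fails, the model is refit
#' without the random intercept (ordinary least squares) and flagged
#' `converged = FALSE`.
#'
#' @param diversity standardized diversity vector.
#' @param metabolite transformed metabolite vector.
#' @param covariates data.frame (or NULL) of fixed-effect covariates.
#' @param family_ids family identifier per subject.
#' @return one-row data.frame: `beta`, `se`, `p_value`, `n`, `converged`.
#' @export
lmm_association <- function(diversity, metabolite, covariates = NULL,
                            family_ids) {
  n <- length(diversity)
  stopifnot(length(metabolite) == n, length(family_ids) == n)
  dat <- data.frame(.div = diversity, .met = metabolite,
                    .fam = as.character(family_ids))
  rhs <- ".met"
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
    rhs <- paste(c(".met", colnames(covariates)), collapse = " + ")
  }
  if (length(unique(dat$.fam)) < 2L)
    stop("need at least 2 families", call. = FALSE)
  fml <- stats::as.formula(paste(".div ~", rhs, "+ (1 | .fam)"))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = dat, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- tryCatch({
      b <- lme4::fixef(fit)[".met"]
      s <- sqrt(diag(as.matrix(stats::vcov(fit)))[".met"])
      c(b, s)
    }, error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf)) && cf[2] > 0) {
      z <- cf[1] / cf[2]
      return(data.frame(beta = unname(cf[1]), se = unname(cf[2]),
                        p_value = 2 * stats::pnorm(-abs(z)),
                        n = n, converged = TRUE))
    }
  }
  # fallback: simplified model without the random intercept
  ols <- tryCatch(stats::lm(stats::as.formula(paste(".div ~", rhs)),
                            data = dat),
                  error = function(e) NULL)
  if (is.null(ols))
    return(data.frame(beta = NA_real_, se = NA_real_, p_value = 1,
                      n = n, converged = FALSE))
  sm <- summary(ols)$coefficients
  data.frame(beta = sm[".met", 1], se = sm[".met", 2],
             p_value = sm[".met", 4], n = n, converged = FALSE)
}

#' Screen a metabolite panel against diversity
#'
#' Runs [lmm_association()] for every metabolite column and selects those
#' with p below the Bonferroni per-test threshold. Results are returned in
#' metabolite-ID order regardless of column order, so selection is
#' invariant to how the panel is arranged.
#'
#' @param diversity standardized diversity vector.
#' @param metabolites numeric matrix, subjects x metabolites (colnames =
#'   metabolite IDs), already imputed and inverse-normalized.
#' @param covariates data.frame of covariates or NULL.
#' @param family_ids family identifier per subject.
#' @param cfg a [screen_config()].
#' @return list with `results` (data.frame, one row per metabolite,
#'   ordered by ID), `selected` (character vector of metabolite IDs) and
#'   `threshold`.
#' @export
screen_all <- function(diversity, metabolites, covariates = NULL,
                       family_ids, cfg = screen_config()) {
  stopifnot(is.matrix(metabolites))
  thr0 <- bonferroni_threshold(cfg)
  if (ncol(metabolites) == 0L)
    return(list(results = data.frame(metabolite = character(0),
                                     beta = numeric(0), se = numeric(0),
                                     p_value = numeric(0), n = integer(0),
                                     converged = logical(0),
                                     selected = logical(0)),
                selected = character(0), threshold = thr0))
  ids <- colnames(metabolites)
  if (is.null(ids)) stop("metabolites must have colnames", call. = FALSE)
  ord <- order(ids)
  rows <- lapply(ord, function(j) {
    r <- tryCatch(
      lmm_association(diversity, metabolites[, j], covariates, family_ids),
      error = function(e) data.frame(beta = NA_real_, se = NA_real_,
                                     p_value = 1, n = length(diversity),
                                     converged = FALSE))
    cbind(metabolite = ids[j], r)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  thr <- bonferroni_threshold(cfg)
  res$selected <- res$p_value < thr
  list(results = res, selected = res$metabolite[res$selected],
       threshold = thr)
}

#' Family-level discovery/test split
#'
#' Assigns whole families to the discovery or test side so twins never
#' straddle the split (preventing leakage of the family effect).
#'
#' @param family_ids family identifier per subject.
#' @param discovery_fraction target fraction of subjects in discovery
#'   (default 1/3).
#' @param seed RNG seed.
#' @return logical vector, TRUE = discovery.
#' @export
family_split <- function(family_ids, discovery_fraction = 1 / 3,
                         seed = NULL) {
  if (discovery_fraction <= 0 || discovery_fraction >= 1)
    stop_field("discovery_fraction", "must be in (0, 1)")
  fams <- unique(family_ids)
  with_seed(seed, {
    fams <- sample(fams)
    sizes <- table(family_ids)[fams]
    cum <- cumsum(as.numeric(sizes))
    target <- discovery_fraction * length(family_ids)
    k <- which.min(abs(cum - target))
    family_ids %in% fams[seq_len(k)]
  })
}
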