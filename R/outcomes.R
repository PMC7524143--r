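# Outcome models: logistic regression for prevalent disease, Cox
# proportional hazards for incident disease, and covariate-adjusted
# (partial) correlations for continuous traits.

effect_estimate <- function(scale, estimate, se, p_value, n, n_events,
                            extra = list()) {
  z <- stats::qnorm(0.975)
  ratio <- scale %in% c("logOR", "logHR")
  ci <- estimate + c(-1, 1) * z * se
  if (ratio) ci <- exp(ci)
  structure(c(list(scale = scale, estimate = estimate, se = se,
                   ci_low = ci[1], ci_high = ci[2], p_value = p_value,
                   n = n, n_events = n_events), extra),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  lab <- switch(x$scale, logOR = "OR", logHR = "HR", "beta")
  pt <- if (x$scale %in% c("logOR", "logHR")) exp(x$estimate) else x$estimate
  cat(sprintf("<effect_estimate> %s = %.3f [%.3f, %.3f], P = %.3g (n = %d, events = %d)\n",
              lab, pt, x$ci_low, x$ci_high, x$p_value, x$n, x$n_events))
  invisible(x)
}

#' Logistic association with a binary outcome
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' exposure plus covariates; the estimate is the log odds ratio per unit
#' exposure with a Wald confidence interval and p-value.
#'
#' @param outcome 0/1 vector.
#' @param exposure numeric exposure vector.
#' @param covariates data.frame of adjustment covariates, or NULL.
#'   Constant columns (e.g. sex in a single-sex cohort) are dropped.
#' @return an `effect_estimate` with `scale = "logOR"`.
#' @export
logistic_association <- function(outcome, exposure, covariates = NULL) {
  dat <- build_model_frame(outcome, exposure, covariates)
  if (stats::sd(dat$.exp) == 0)
    stop("zero variance exposure", call. = FALSE)
  n_events <- sum(dat$.out)
  if (n_events < 10)
    warning("fewer than 10 cases; estimates may be unstable", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(.out ~ ., data = dat, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  b <- sm[".exp", 1]; s <- sm[".exp", 2]
  if (!is.finite(b) || abs(b) > 15 || s > 100)
    stop("complete separation suspected: |logOR| = ",
         format(abs(b), digits = 3), ", SE = ", format(s, digits = 3),
         call. = FALSE)
  effect_estimate("logOR", b, s, sm[".exp", 4], nrow(dat), n_events)
}

#' Cox proportional-hazards association with an incident outcome
#'
#' Partial-likelihood Cox regression (Efron tie handling) of time-to-event
#' on an exposure plus covariates, with baseline prevalent cases optionally
#' excluded from the risk set. A Schoenfeld-residual proportional-hazards
#' diagnostic p-value for the exposure is attached.
#'
#' @param time follow-up time in years (> 0).
#' @param event 0/1 incident-event indicator.
#' @param exposure numeric exposure vector.
#' @param covariates data.frame of adjustment covariates, or NULL.
#' @param prevalent optional 0/1 vector of baseline cases.
#' @param exclude_prevalent drop subjects with `prevalent == 1` (default
#'   TRUE when `prevalent` is supplied).
#' @return an `effect_estimate` with `scale = "logHR"` and an extra
#'   `ph_test_p` element.
#' @export
cox_association <- function(time, event, exposure, covariates = NULL,
                            prevalent = NULL,
                            exclude_prevalent = !is.null(prevalent)) {
  keep <- rep(TRUE, length(time))
  if (isTRUE(exclude_prevalent) && !is.null(prevalent))
    keep <- prevalent == 0
  keep <- keep & !is.na(time) & time > 0
  dat <- build_model_frame(event[keep], exposure[keep],
                           if (is.null(covariates)) NULL
                           else as.data.frame(covariates)[keep, ,
                                                          drop = FALSE])
  dat$.time <- time[keep]
  if (stats::sd(dat$.exp) == 0)
    stop("zero variance exposure", call. = FALSE)
  n_events <- sum(dat$.out)
  if (n_events == 0) stop("no events", call. = FALSE)
  if (n_events < 10)
    warning("fewer than 10 events; estimates may be unstable",
            call. = FALSE)
  rhs <- setdiff(names(dat), c(".out", ".time"))
  fml <- stats::as.formula(paste("survival::Surv(.time, .out) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  sm <- summary(fit)$coefficients
  b <- sm[".exp", "coef"]; s <- sm[".exp", "se(coef)"]
  ph_p <- tryCatch({
    z <- survival::cox.zph(fit)
    unname(z$table[".exp", "p"])
  }, error = function(e) NA_real_)
  effect_estimate("logHR", b, s, sm[".exp", "Pr(>|z|)"], nrow(dat),
                  n_events, extra = list(ph_test_p = ph_p))
}

build_model_frame <- function(outcome, exposure, covariates) {
  n <- length(outcome)
  stopifnot(length(exposure) == n)
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  dat <- data.frame(.out = as.numeric(outcome), .exp = as.numeric(exposure))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    varying <- vapply(covariates,
                      function(x) length(unique(x)) > 1L, logical(1))
    if (any(varying)) dat <- cbind(dat, covariates[, varying, drop = FALSE])
  }
  stats::na.omit(dat)
}

#' Covariate-adjusted correlation matrix
#'
#' Partial Pearson correlation of every (microbial variable, trait) pair
#' given the covariates, computed by correlating the residuals of each
#' variable after regression on the covariates. Two-sided p-values use the
#' t distribution with `n - 2 - k` degrees of freedom (`k` covariates).
#'
#' @param traits numeric matrix of metabolic traits (columns named).
#' @param microbial_vars numeric matrix of microbial variables (columns
#'   named).
#' @param covariates data.frame or matrix of covariates.
#' @return list of matrices `r` and `p` (microbial vars x traits).
#' @export
adjusted_correlation_matrix <- function(traits, microbial_vars,
                                        covariates) {
  traits <- as.matrix(traits); microbial_vars <- as.matrix(microbial_vars)
  Xc <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  n <- nrow(traits)
  k <- ncol(Xc) - 1L
  stopifnot(nrow(microbial_vars) == n, nrow(Xc) == n)
  if (n <= k + 3L) stop("too few subjects for adjustment", call. = FALSE)
  resid_on <- function(M) as.matrix(stats::lm.fit(Xc, M)$residuals)
  rt <- resid_on(traits); rm_ <- resid_on(microbial_vars)
  r <- stats::cor(rm_, rt)
  df <- n - 2L - k
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  dimnames(r) <- dimnames(p) <- list(colnames(microbial_vars),
                                     colnames(traits))
  list(r = r, p = p, df = df)
}
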