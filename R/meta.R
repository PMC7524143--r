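# Two-cohort meta-analysis: inverse-variance fixed effect, with
# heterogeneity statistics, and the Han-Eskin random-effects (RE2)
# likelihood-ratio test.

#' Log-scale standard error from a ratio-scale confidence interval
#'
#' Recovers the Wald standard error of a log odds/hazard ratio from the
#' printed ratio-scale 95% CI: `se = (ln high - ln low) / (2 z)`. A
#' warning is raised when the CI is markedly asymmetric on the log scale
#' (more than 10% imbalance), which suggests it is not a plain Wald
#' interval.
#'
#' @param point,low,high ratio-scale estimate and 95% CI bounds,
#'   `0 < low < point < high`.
#' @param z normal quantile used to build the CI; `qnorm(0.975)` =
#'   1.959964 by default, `conventional = TRUE` uses 1.96 (the rounding
#'   convention of printed tables).
#' @param conventional use 1.96 instead of 1.959964.
#' @return standard error on the log scale.
#' @examples
#' se_from_ci(0.87, 0.79, 0.95)
#' @export
se_from_ci <- function(point, low, high, z = stats::qnorm(0.975),
                       conventional = FALSE) {
  if (conventional) z <- 1.96
  if (!(0 < low && low < point && point < high))
    stop("need 0 < low < point < high", call. = FALSE)
  lo_gap <- log(point) - log(low)
  hi_gap <- log(high) - log(point)
  if (abs(lo_gap - hi_gap) > 0.1 * max(lo_gap, hi_gap))
    warning("CI asymmetric on the log scale; not a plain Wald interval?",
            call. = FALSE)
  (log(high) - log(low)) / (2 * z)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools log-scale study estimates with weights `1/se^2`. Reports the
#' pooled estimate and SE, Wald p-value, Cochran's Q, I-squared, and the
#' DerSimonian-Laird between-study variance (for description; the pooled
#' estimate itself is fixed-effect).
#'
#' @param estimates numeric vector of log-scale study estimates.
#' @param se numeric vector of their standard errors (> 0).
#' @return object of class `meta_result`.
#' @export
fixed_effect_meta <- function(estimates, se) {
  k <- length(estimates)
  if (k < 2L) stop("nothing to pool: need >= 2 studies", call. = FALSE)
  stopifnot(length(se) == k, all(se > 0))
  w <- 1 / se^2
  pooled <- sum(w * estimates) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- pooled / pooled_se
  q <- sum(w * (estimates - pooled)^2)
  df <- k - 1L
  i2 <- max(0, (q - df) / q) * 100
  if (!is.finite(i2)) i2 <- 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  zq <- stats::qnorm(0.975)
  structure(list(pooled_estimate = pooled, pooled_se = pooled_se,
                 ci_low = pooled - zq * pooled_se,
                 ci_high = pooled + zq * pooled_se,
                 fe_p = 2 * stats::pnorm(-abs(z)),
                 q_statistic = q, i2 = i2, tau2 = tau2,
                 k = k, estimates = estimates, se = se),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d: pooled = %.4f (SE %.4f), FE P = %.3g\n",
              x$k, x$pooled_estimate, x$pooled_se, x$fe_p))
  cat(sprintf("  Q = %.3f, I2 = %.1f%%, tau2 = %.4g\n",
              x$q_statistic, x$i2, x$tau2))
  if (!is.null(x$re2_p))
    cat(sprintf("  RE2 stat = %.3f, P = %.3g (tau2_hat = %.4g)\n",
                x$re2_statistic, x$re2_p, x$re2_tau2))
  invisible(x)
}

# Profile log-likelihood of the random-effects normal marginal model
# b_k ~ N(mu, se_k^2 + tau2), maximized over mu for fixed tau2.
re_profile_ll <- function(tau2, estimates, se) {
  v <- se^2 + tau2
  w <- 1 / v
  mu <- sum(w * estimates) / sum(w)
  sum(stats::dnorm(estimates, mu, sqrt(v), log = TRUE))
}

#' Han-Eskin random-effects (RE2) meta-analysis
#'
#' Likelihood-ratio test of `H0: mu = 0, tau2 = 0` against a free mean and
#' non-negative between-study variance under the normal marginal model
#' `b_k ~ N(mu, se_k^2 + tau2)`. The statistic is referred to the
#' asymptotic equal-mixture null `0.5 chi2(1) + 0.5 chi2(2)`; tabulated
#' small-sample corrections are not applied. The tau2 maximization is a
#' bounded 1-D profile search (coarse grid, then golden-section refinement
#' to 1e-8).
#'
#' @inheritParams fixed_effect_meta
#' @return a `meta_result` with `re2_statistic`, `re2_p` and `re2_tau2`
#'   alongside the fixed-effect fields.
#' @export
han_eskin_re2 <- function(estimates, se) {
  out <- fixed_effect_meta(estimates, se)
  l0 <- sum(stats::dnorm(estimates, 0, se, log = TRUE))
  upper <- max(4 * stats::var(estimates), max(se)^2, 1e-6) * 10
  grid <- seq(0, upper, length.out = 64L)
  ll <- vapply(grid, re_profile_ll, numeric(1),
               estimates = estimates, se = se)
  j <- which.max(ll)
  lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(re_profile_ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8, estimates = estimates, se = se)
  best_ll <- max(opt$objective, ll[j], re_profile_ll(0, estimates, se))
  tau2_hat <- if (opt$objective >= ll[j]) opt$maximum else grid[j]
  if (re_profile_ll(0, estimates, se) >= best_ll) tau2_hat <- 0
  stat <- max(0, 2 * (best_ll - l0))
  out$re2_statistic <- stat
  out$re2_tau2 <- tau2_hat
  out$re2_p <- if (stat == 0) 1 else
    0.5 * stats::pchisq(stat, 1, lower.tail = FALSE) +
    0.5 * stats::pchisq(stat, 2, lower.tail = FALSE)
  out
}

#' Meta-analyse printed ratio-scale estimates
#'
#' Convenience wrapper pooling studies given as ratio-scale (OR/HR)
#' triplets `(point, low, high)`: converts to log estimates and SEs via
#' [se_from_ci()], then runs both [fixed_effect_meta()] and
#' [han_eskin_re2()].
#'
#' @param studies list of numeric length-3 vectors `(point, low, high)`.
#' @param conventional passed to [se_from_ci()] (1.96 vs 1.959964).
#' @return a `meta_result`; the pooled ratio is `exp(pooled_estimate)`.
#' @export
meta_from_ratio_ci <- function(studies, conventional = FALSE) {
  b <- vapply(studies, function(s) log(s[1]), numeric(1))
  s <- vapply(studies, function(x) se_from_ci(x[1], x[2], x[3],
                                              conventional = conventional),
              numeric(1))
  han_eskin_re2(b, s)
}
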