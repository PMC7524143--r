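# Potential-outcomes mediation of a binary treatment (high vs low
# diversity) on a binary outcome (T2D) through a continuous mediator (the
# MMD score): linear mediator model, probit outcome model, quasi-Bayesian
# (parametric-bootstrap) draws, effects on the probability scale.

#' Dichotomize a diversity vector at its median
#'
#' High = strictly above the median; values equal to the median are
#' assigned to the LOW group (deterministic tie rule).
#'
#' @param shannon numeric vector, not constant, n >= 2.
#' @return integer 0/1 vector (1 = high diversity).
#' @export
dichotomize_diversity <- function(shannon) {
  if (length(shannon) < 2L) stop("need n >= 2", call. = FALSE)
  if (stats::sd(shannon) == 0) stop("constant vector", call. = FALSE)
  as.integer(shannon > stats::median(shannon))
}

# Probability that Y = 1 under the probit outcome model after integrating
# out the mediator-model residual: with M | T = t' ~ N(mu, sigma2) and
# Y* = g0 + g1 T + g2 M + Xg + e, e ~ N(0, 1),
# P(Y = 1 | T = t, M ~ regime t') = Phi((eta_t + g2 * mu_{t'}) /
#                                       sqrt(1 + g2^2 sigma2)).
probit_po_prob <- function(eta_out_base, g_treat, g_med, mu_med, sigma2,
                           t_out) {
  stats::pnorm((eta_out_base + g_treat * t_out + g_med * mu_med) /
                 sqrt(1 + g_med^2 * sigma2))
}

#' Causal mediation analysis (binary treatment, continuous mediator,
#' binary outcome)
#'
#' Fits a linear mediator model `M ~ T + covariates` and a probit outcome
#' model `Y ~ T + M + covariates`, then draws `n_draws` parameter vectors
#' from each model's asymptotic sampling distribution. For every draw the
#' average causal mediation effect (ACME), average direct effect (ADE) and
#' total effect are computed on the outcome probability scale by averaging
#' subject-level potential-outcome probabilities (the mediator residual is
#' integrated out analytically under the probit link). Reported effects
#' average the two treatment regimes; intervals are 2.5/97.5 percentiles
#' of the draws; the proportion mediated (VAF) comes from [vaf()].
#'
#' @param treatment 0/1 vector (e.g. high vs low Shannon diversity).
#' @param mediator continuous mediator (e.g. MMD score).
#' @param outcome 0/1 vector.
#' @param covariates data.frame of covariates or NULL.
#' @param n_draws number of quasi-Bayesian draws (>= 100, default 1000).
#' @param seed RNG seed (fixed seed gives identical results).
#' @param link outcome link, `"probit"` (default) or `"logit"` (the logit
#'   variant integrates the mediator residual by Gauss-Hermite-free
#'   normal approximation: probability averaged over 32 mediator
#'   quantiles).
#' @return object of class `mediation_result` with elements `acme`, `ade`,
#'   `total`, `vaf` (each a list: `estimate`, `ci_low`, `ci_high`),
#'   `n_draws`, `vaf_excluded`, `mediator_model`, `outcome_model`.
#' @export
mediate <- function(treatment, mediator, outcome, covariates = NULL,
                    n_draws = 1000, seed = NULL, link = c("probit", "logit")) {
  link <- match.arg(link)
  n <- length(treatment)
  stopifnot(length(mediator) == n, length(outcome) == n)
  if (!all(treatment %in% c(0, 1)))
    stop("treatment must be binary 0/1", call. = FALSE)
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (n_draws < 100) stop("n_draws must be >= 100", call. = FALSE)

  dat <- data.frame(.t = as.numeric(treatment), .m = as.numeric(mediator),
                    .y = as.numeric(outcome))
  has_cov <- !is.null(covariates) && ncol(as.data.frame(covariates)) > 0L
  if (has_cov) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == n)
    dat <- cbind(dat, covariates)
  }
  cov_terms <- if (has_cov) paste("+", paste(colnames(covariates),
                                             collapse = " + ")) else ""
  med_fit <- stats::lm(stats::as.formula(paste(".m ~ .t", cov_terms)),
                       data = dat)
  out_fit <- suppressWarnings(stats::glm(
    stats::as.formula(paste(".y ~ .t + .m", cov_terms)),
    family = stats::binomial(link = link), data = dat))
  oc <- stats::coef(out_fit)
  if (any(!is.finite(oc)) || any(abs(oc) > 15))
    stop("outcome model separation suspected", call. = FALSE)

  # design matrices for the subject-level averages
  Xm <- stats::model.matrix(med_fit)     # mediator model: (1, T, X)
  Xo <- stats::model.matrix(out_fit)     # outcome model: (1, T, M, X)
  t_col_m <- match(".t", colnames(Xm))
  t_col_o <- match(".t", colnames(Xo))
  m_col_o <- match(".m", colnames(Xo))
  sigma2_hat <- summary(med_fit)$sigma^2
  df_m <- med_fit$df.residual

  draws <- with_seed(seed, {
    a_draws <- MASS::mvrnorm(n_draws, stats::coef(med_fit),
                             stats::vcov(med_fit))
    s2_draws <- sigma2_hat * df_m / stats::rchisq(n_draws, df_m)
    g_draws <- MASS::mvrnorm(n_draws, oc, stats::vcov(out_fit))
    acme <- ade <- numeric(n_draws)
    Xm0 <- Xm; Xm0[, t_col_m] <- 0
    Xo_base <- Xo; Xo_base[, t_col_o] <- 0; Xo_base[, m_col_o] <- 0
    for (b in seq_len(n_draws)) {
      a <- a_draws[b, ]; g <- g_draws[b, ]; s2 <- s2_draws[b]
      mu0 <- as.numeric(Xm0 %*% a)          # E[M | T = 0, X]
      mu1 <- mu0 + a[t_col_m]               # E[M | T = 1, X]
      eta_base <- as.numeric(Xo_base %*% g) # outcome LP at T = 0, M = 0
      g_t <- g[t_col_o]; g_m <- g[m_col_o]
      pr <- function(t_out, mu) {
        if (link == "probit")
          mean(probit_po_prob(eta_base, g_t, g_m, mu, s2, t_out))
        else {
          # logit link: integrate mediator residual by quadrature over
          # normal quantiles
          qs <- stats::qnorm(seq(0.5, 31.5) / 32)
          mean(vapply(qs, function(q)
            mean(stats::plogis(eta_base + g_t * t_out +
                                 g_m * (mu + sqrt(s2) * q))),
            numeric(1)))
        }
      }
      p11 <- pr(1, mu1); p10 <- pr(1, mu0)
      p01 <- pr(0, mu1); p00 <- pr(0, mu0)
      acme[b] <- ((p11 - p10) + (p01 - p00)) / 2
      ade[b] <- ((p11 - p01) + (p10 - p00)) / 2
    }
    list(acme = acme, ade = ade)
  })
  total <- draws$acme + draws$ade
  pe <- function(x) list(estimate = mean(x),
                         ci_low = unname(stats::quantile(x, 0.025)),
                         ci_high = unname(stats::quantile(x, 0.975)))
  v <- vaf(draws$acme, draws$ade)
  structure(list(acme = pe(draws$acme), ade = pe(draws$ade),
                 total = pe(total), vaf = v,
                 acme_draws = draws$acme, ade_draws = draws$ade,
                 n_draws = n_draws, vaf_excluded = attr(v, "n_excluded"),
                 mediator_model = summary(med_fit)$coefficients,
                 outcome_model = summary(out_fit)$coefficients,
                 link = link),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  f <- function(e) sprintf("%.4f [%.4f, %.4f]", e$estimate, e$ci_low,
                           e$ci_high)
  cat("<mediation_result> (", x$link, " outcome link, ", x$n_draws,
      " draws)\n", sep = "")
  cat("  ACME (indirect):", f(x$acme), "\n")
  cat("  ADE  (direct):  ", f(x$ade), "\n")
  cat("  Total effect:   ", f(x$total), "\n")
  cat("  VAF (prop. mediated):", f(x$vaf), "\n")
  invisible(x)
}

#' Proportion mediated (variance accounted for)
#'
#' Ratio of the indirect to the total effect. The point estimate is the
#' ratio of the point estimates; the interval is the 2.5/97.5 percentile
#' of the per-draw ratios `acme / (acme + ade)`. Draws whose total effect
#' is within a relative tolerance of zero make the ratio unstable and are
#' excluded (their count is reported; more than 20% exclusions triggers a
#' warning).
#'
#' @param acme_draws,ade_draws aligned numeric vectors of per-draw
#'   effects.
#' @param rel_tol draws with `|total| < rel_tol * sd(total)` are excluded.
#' @return list `estimate`, `ci_low`, `ci_high` with attribute
#'   `n_excluded`.
#' @export
vaf <- function(acme_draws, ade_draws, rel_tol = 0.05) {
  stopifnot(length(acme_draws) == length(ade_draws))
  total <- acme_draws + ade_draws
  thr <- rel_tol * max(stats::sd(total), .Machine$double.eps)
  ok <- abs(total) >= thr
  if (mean(!ok) > 0.2)
    warning("unstable VAF: ", sum(!ok), " of ", length(ok),
            " draws have total effect near zero", call. = FALSE)
  ratios <- acme_draws[ok] / total[ok]
  point <- mean(acme_draws) / mean(total)
  if (!length(ratios)) {
    out <- list(estimate = point, ci_low = NA_real_, ci_high = NA_real_)
    attr(out, "n_excluded") <- sum(!ok)
    return(out)
  }
  out <- list(estimate = point,
              ci_low = unname(stats::quantile(ratios, 0.025)),
              ci_high = unname(stats::quantile(ratios, 0.975)))
  attr(out, "n_excluded") <- sum(!ok)
  out
}
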