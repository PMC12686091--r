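# Inverse-variance-weighted mixed model comparing the measures:
#   proportion ~ 1 + measure + (1 | domain), weights = 1/variance
# Measure is a fixed, exhaustive factor; domain is a random intercept
# (domains are a sample of possible attitude domains). Weights are
# treated as known relative error variances with a residual scale
# estimated, the standard weighted-LMM reading. When the domain variance
# estimate collapses to zero the fit reduces to weighted least squares
# and is flagged as such.

#' Validate a meta-analysis dataset
#'
#' @param data Data frame with columns `y` (proportion outcome),
#'   `variance` (> 0), `measure`, `domain`.
#' @return The data with `measure` and `domain` as factors.
#' @export
meta_dataset <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("y", "variance", "measure", "domain") %in% names(data)))
  if (any(!is.finite(data$variance)) || any(data$variance <= 0)) {
    stop("every row needs a positive finite variance", call. = FALSE)
  }
  data$measure <- as.factor(data$measure)
  data$domain <- as.factor(data$domain)
  empty <- levels(data$measure)[!levels(data$measure) %in% data$measure]
  if (length(empty) > 0L) {
    stop("measure level(s) with no rows: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  data
}

#' Fit the inverse-variance-weighted mixed model
#'
#' Fits `y ~ measure + (1 | domain)` by REML with `weights =
#' 1/variance`. With fewer than two domain levels, or when the estimated
#' domain variance tau^2 falls at (or numerically below) zero, the model
#' reduces to weighted least squares on the fixed effects and the fit is
#' recorded as `"WLS-fallback"`.
#'
#' @param data A [meta_dataset()]-valid data frame.
#' @return A `meta_fit`: coefficients, their covariance, `tau2_domain`,
#'   `sigma2`, `fit_method` (`"REML"` or `"WLS-fallback"`),
#'   `converged`, the measure levels, and the model frame.
#' @export
fit_weighted_lmm <- function(data) {
  data <- meta_dataset(data)
  w <- 1 / data$variance
  fallback <- function(converged) {
    fit <- stats::lm(y ~ measure, data = data, weights = w)
    s2 <- sum(w * stats::residuals(fit)^2) / fit$df.residual
    Xw <- stats::model.matrix(fit) * sqrt(w)
    structure(list(coefficients = stats::coef(fit),
                   vcov = s2 * solve(crossprod(Xw)),
                   tau2_domain = 0,
                   sigma2 = s2,
                   fit_method = "WLS-fallback", converged = converged,
                   measure_levels = levels(data$measure), data = data),
              class = "meta_fit")
  }
  if (nlevels(data$domain) < 2L) return(fallback(TRUE))
  fit <- suppressMessages(
    lme4::lmer(y ~ measure + (1 | domain), data = data, weights = w,
               REML = TRUE,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular =
                                             lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4))))
  tau2 <- as.numeric(lme4::VarCorr(fit)$domain[1])
  converged <- length(fit@optinfo$conv$lme4$messages) == 0L
  if (!is.finite(tau2) || tau2 <= 1e-10) return(fallback(converged))
  structure(list(coefficients = lme4::fixef(fit),
                 vcov = as.matrix(stats::vcov(fit)),
                 tau2_domain = tau2,
                 sigma2 = stats::sigma(fit)^2,
                 fit_method = "REML", converged = converged,
                 measure_levels = levels(data$measure), data = data),
            class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  cat(sprintf("Weighted mixed meta-model (%s%s)\n", x$fit_method,
              if (x$converged) "" else ", convergence warning"))
  cat(sprintf("  domain random-intercept variance tau^2 = %.6g\n",
              x$tau2_domain))
  emm <- estimated_marginal_means(x)
  for (i in seq_len(nrow(emm))) {
    cat(sprintf("  %-8s EMM = %.4f (SE %.4f)\n", emm$measure[i],
                emm$emmean[i], emm$se[i]))
  }
  invisible(x)
}

#' Estimated marginal means per measure
#'
#' With a single fixed factor and a domain random intercept, the EMM of
#' measure m is the population-level prediction intercept + beta_m
#' (the random intercept averages to zero); its SE comes from the
#' fixed-effect covariance.
#'
#' @param fit A `meta_fit`.
#' @return Data frame: measure, emmean, se.
#' @export
estimated_marginal_means <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  lv <- fit$measure_levels
  k <- length(lv)
  L <- matrix(0, k, length(fit$coefficients),
              dimnames = list(lv, names(fit$coefficients)))
  L[, "(Intercept)"] <- 1
  for (m in lv[-1]) L[m, paste0("measure", m)] <- 1
  est <- as.numeric(L %*% fit$coefficients)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  data.frame(measure = lv, emmean = est, se = unname(se),
             stringsAsFactors = FALSE)
}

#' Holm-corrected pairwise contrasts of the estimated marginal means
#'
#' All unordered pairs of measure EMMs, each difference tested against a
#' standard-normal reference (difference / SE from the full fixed-effect
#' covariance), with Holm step-down adjustment of the p-values.
#'
#' @param fit A `meta_fit`.
#' @param alpha Significance level for the contrast CIs.
#' @return Data frame with one row per pair: measure_1, measure_2,
#'   emm_difference, ci_lower, ci_upper, p_value, p_holm.
#' @export
pairwise_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "meta_fit"))
  lv <- fit$measure_levels
  if (length(lv) < 2L) stop("contrasts need >= 2 measures", call. = FALSE)
  cf <- fit$coefficients
  V <- fit$vcov
  cvec <- function(m) {
    v <- stats::setNames(numeric(length(cf)), names(cf))
    if (m != lv[1]) v[paste0("measure", m)] <- 1
    v
  }
  pairs <- utils::combn(lv, 2)
  z975 <- stats::qnorm(1 - alpha / 2)
  rows <- apply(pairs, 2, function(pr) {
    cc <- cvec(pr[1]) - cvec(pr[2])
    diff <- sum(cc * cf)
    se <- sqrt(drop(t(cc) %*% V %*% cc))
    z <- if (se > 0) diff / se else 0
    data.frame(measure_1 = pr[1], measure_2 = pr[2],
               emm_difference = diff,
               ci_lower = diff - z975 * se, ci_upper = diff + z975 * se,
               p_value = if (se > 0) 2 * stats::pnorm(-abs(z)) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Holm step-down p-value adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "holm")
}
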