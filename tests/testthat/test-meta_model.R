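test_that("single-domain data fall back to weighted least squares", {
  d <- data.frame(y = c(0.2, 0.4, 0.6, 0.8),
                  variance = 0.01,
                  measure = c("IAT", "IAT", "AMP", "AMP"),
                  domain = "race")
  fit <- fit_weighted_lmm(d)
  expect_equal(fit$fit_method, "WLS-fallback")
  emm <- estimated_marginal_means(fit)
  expect_equal(emm$emmean[emm$measure == "IAT"], 0.3)
  expect_equal(emm$emmean[emm$measure == "AMP"], 0.7)
})

test_that("weights act as inverse variances in the fallback fit", {
  # closed form: (1 * 0.4 + 3 * 0.6) / 4 = 0.55
  d <- data.frame(y = c(0.4, 0.6, 0.5),
                  variance = c(1, 1 / 3, 1),
                  measure = c("M1", "M1", "M2"),
                  domain = "d1")
  fit <- fit_weighted_lmm(d)
  emm <- estimated_marginal_means(fit)
  expect_equal(emm$emmean[emm$measure == "M1"], 0.55)
})

test_that("REML fixed effects match a known-variance GLS solve on a balanced grid", {
  set.seed(23)
  measures <- paste0("M", 1:6)
  domains <- paste0("D", 1:3)
  grid <- expand.grid(measure = measures, domain = domains,
                      stringsAsFactors = TRUE)
  beta <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  tau2 <- 0.04
  s2 <- 0.01
  grid$y <- 0.3 + beta[as.integer(grid$measure)] +
    rep(rnorm(3, 0, sqrt(tau2)), each = 6) + rnorm(18, 0, sqrt(s2))
  grid$variance <- 0.01
  fit <- fit_weighted_lmm(grid)
  X <- model.matrix(~measure, grid)
  Z <- model.matrix(~ 0 + domain, grid)
  V <- s2 * diag(nrow(grid)) + tau2 * Z %*% t(Z)
  gls <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% grid$y)
  expect_equal(unname(fit$coefficients), unname(drop(gls)),
               tolerance = 1e-6)
})

test_that("zero domain variance with equal weights reduces to OLS", {
  # identical domain profiles force tau^2 to the boundary
  d <- expand.grid(measure = paste0("M", 1:4), domain = paste0("D", 1:3))
  d$y <- rep(c(0.2, 0.35, 0.5, 0.8), 3)
  d$variance <- 1
  fit <- fit_weighted_lmm(d)
  expect_equal(fit$fit_method, "WLS-fallback")
  ols <- lm(y ~ measure, data = d)
  expect_equal(unname(fit$coefficients), unname(coef(ols)),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(fit$vcov)),
               unname(suppressWarnings(vcov(ols))), tolerance = 1e-12)
})

test_that("meta dataset validation names the offending level", {
  d <- data.frame(y = 0.5, variance = 0.01,
                  measure = factor("IAT", levels = c("IAT", "GNAT")),
                  domain = "race")
  expect_error(fit_weighted_lmm(d), "GNAT")
  d2 <- data.frame(y = c(0.4, 0.5), variance = c(0.01, 0),
                   measure = c("A", "B"), domain = "race")
  expect_error(fit_weighted_lmm(d2), "variance")
})

test_that("EMMs are translation-equivariant and match emmeans", {
  set.seed(29)
  d <- expand.grid(measure = paste0("M", 1:5), domain = paste0("D", 1:3))
  d$y <- runif(nrow(d), 0.2, 0.8)
  d$variance <- runif(nrow(d), 0.005, 0.02)
  fit <- fit_weighted_lmm(d)
  emm <- estimated_marginal_means(fit)
  d_shift <- d
  d_shift$y <- d$y + 0.1
  emm_shift <- estimated_marginal_means(fit_weighted_lmm(d_shift))
  expect_equal(emm_shift$emmean, emm$emmean + 0.1, tolerance = 1e-6)
  # independent route: emmeans on the same lme4 fit
  library(emmeans)
  lfit <- lme4::lmer(y ~ measure + (1 | domain), data = d,
                     weights = 1 / d$variance, REML = TRUE)
  ref <- as.data.frame(emmeans(lfit, "measure",
                               lmer.df = "asymptotic"))
  expect_equal(emm$emmean, ref$emmean, tolerance = 1e-6)
  expect_equal(emm$se, ref$SE, tolerance = 1e-6)
})

test_that("EMM ordering recovers the generating measure means", {
  set.seed(37)
  truth <- c(M1 = 0.2, M2 = 0.4, M3 = 0.6, M4 = 0.8)
  d <- expand.grid(measure = names(truth), domain = paste0("D", 1:3))
  d$y <- truth[as.character(d$measure)] + rnorm(nrow(d), 0, 0.01)
  d$variance <- 0.01
  emm <- estimated_marginal_means(fit_weighted_lmm(d))
  expect_equal(order(emm$emmean), order(truth[emm$measure]))
})

test_that("pairwise contrasts enumerate all pairs with antisymmetric signs", {
  set.seed(41)
  d <- expand.grid(measure = paste0("M", 1:6), domain = paste0("D", 1:3))
  d$y <- runif(18)
  d$variance <- runif(18, 0.005, 0.02)
  fit <- fit_weighted_lmm(d)
  ct <- pairwise_contrasts(fit)
  expect_equal(nrow(ct), choose(6, 2))
  emm <- estimated_marginal_means(fit)
  for (k in seq_len(nrow(ct))) {
    expect_equal(ct$emm_difference[k],
                 emm$emmean[emm$measure == ct$measure_1[k]] -
                   emm$emmean[emm$measure == ct$measure_2[k]],
                 tolerance = 1e-10)
  }
  expect_true(all(ct$p_holm >= ct$p_value))
  # outcomes varying only by domain: all measure differences zero, p = 1
  d$y <- rep(c(0.4, 0.5, 0.6), each = 6)
  d$variance <- 0.01
  ct0 <- pairwise_contrasts(fit_weighted_lmm(d))
  expect_true(all(abs(ct0$emm_difference) < 1e-10))
  expect_true(all(ct0$p_value > 1 - 1e-6))
})

test_that("holm_adjust reproduces hand step-down enumeration", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  for (i in 1:20) {
    p <- runif(sample(1:6, 1))
    expect_equal(holm_adjust(p), holm_hand(p))
    expect_true(all(holm_adjust(p) >= p))
    expect_true(all(holm_adjust(p) <= 1))
    # never more rejections than unadjusted testing
    expect_lte(sum(holm_adjust(p) < 0.05), sum(p < 0.05))
  }
})

test_that("REML recovers generating parameters on average", {
  set.seed(47)
  measures <- paste0("M", 1:6)
  beta <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  mu <- 0.25
  tau2 <- 0.02
  s2 <- 0.005
  est <- replicate(100, {
    d <- expand.grid(measure = measures, domain = paste0("D", 1:3))
    d$y <- mu + beta[as.integer(d$measure)] +
      rep(rnorm(3, 0, sqrt(tau2)), each = 6) +
      rnorm(18, 0, sqrt(s2))
    d$variance <- 1
    fit <- fit_weighted_lmm(d)
    fit$coefficients
  })
  bias <- rowMeans(est) - c(mu, beta[-1])
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias) < 4 * mc_se + 1e-8))
})
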