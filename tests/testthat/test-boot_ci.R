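test_that("resampling constant data collapses to the point estimate", {
  spec <- bootstrap_spec(n_resamples = 100, seed = 1)
  res <- bootstrap_participant_ci(rep(3, 5), rep(3, 7), spec)
  expect_true(all(res$replicates$replicates == 0.5))
  expect_equal(res$interval$lower, 0.5)
  expect_equal(res$interval$upper, 0.5)
  expect_equal(res$interval$width, 0)
})

test_that("bootstrap is deterministic under a fixed seed", {
  spec <- bootstrap_spec(n_resamples = 200, seed = 77)
  a <- rnorm(30, 600, 80)
  b <- rnorm(30, 680, 80)
  r1 <- bootstrap_participant_ci(a, b, spec)
  r2 <- bootstrap_participant_ci(a, b, spec)
  expect_identical(r1, r2)
  r3 <- bootstrap_participant_ci(a, b, bootstrap_spec(200, seed = 78))
  expect_false(identical(r1$replicates$replicates,
                         r3$replicates$replicates))
})

test_that("the basic interval is the reverse-percentile transform", {
  # direct formula: theta = 0.6, Q(.025) = 0.5, Q(.975) = 0.8 -> (0.4, 0.7)
  reps <- seq(0.5, 0.8, length.out = 41)  # type-7 quantiles hit ends
  ci <- basic_interval(0.6, reps, alpha = 0.05)
  expect_equal(ci$lower, 2 * 0.6 - quantile7(reps, 0.975))
  expect_equal(ci$upper, 2 * 0.6 - quantile7(reps, 0.025))
  # reverse-percentile identity against the independent quantile oracle
  set.seed(5)
  for (i in 1:20) {
    reps <- runif(sample(50:500, 1))
    th <- runif(1)
    ci <- basic_interval(th, reps)
    expect_equal(ci$lower + ci$upper,
                 4 * th - (quantile7(reps, 0.975) + quantile7(reps, 0.025)))
  }
  # bounds may leave [0, 1] and are preserved unclipped
  reps <- c(rep(0.95, 99), 0.2)
  ci <- basic_interval(0.99, reps)
  expect_gt(ci$upper, 1)
})

test_that("replicate means track the estimate on smooth data", {
  spec <- bootstrap_spec(n_resamples = 2000, seed = 3)
  set.seed(4)
  a <- rnorm(100, 600, 90)
  b <- rnorm(100, 660, 90)
  res <- bootstrap_participant_ci(a, b, spec)
  reps <- res$replicates$replicates
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - res$replicates$estimate), 3 * se + 0.002)
})

test_that("interval width shrinks with trial count", {
  widths <- sapply(c(20, 80, 320), function(n_tr) {
    tpl <- task_template("SIM", "latency", n_tr, n_tr)
    sim <- simulate_task_data(tpl, population_spec(10, 60, 0, seed = 12))
    sc <- score_participants(sim$trials)
    bt <- implicitprecision:::bootstrap_cohort(
      sim$trials, sc, score_spec("PI"), bootstrap_spec(400), seed = 12)
    median(bt$intervals$width)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("a strongly shifted participant's PI interval excludes 0.5", {
  tpl <- task_template("SIM", "latency", 200, 200)
  delta <- delta_for_pi(0.9, tpl$latency_sd_ms, tpl$latency_exp_tail_ms)
  sim <- simulate_task_data(tpl, population_spec(1, 0, 0, seed = 6),
                            delta_fixed = delta)
  v <- sim$trials$response_value
  res <- bootstrap_participant_ci(v[sim$trials$block_role == "A"],
                                  v[sim$trials$block_role == "B"],
                                  bootstrap_spec(2000, seed = 6))
  expect_gt(res$interval$lower, 0.5)
})

test_that("pairwise difference intervals behave under identity and swap", {
  set.seed(9)
  spec <- bootstrap_spec(500, seed = 9)
  ra <- bootstrap_participant_ci(rnorm(50, 600, 80),
                                 rnorm(50, 630, 80), spec)$replicates
  rb <- bootstrap_participant_ci(rnorm(50, 600, 80),
                                 rnorm(50, 720, 80),
                                 bootstrap_spec(500, seed = 10))$replicates
  # same participant paired with itself: all-zero differences
  self <- pairwise_difference_ci(ra, ra)
  expect_equal(self$lower, 0)
  expect_equal(self$upper, 0)
  # swapping the pair flips the interval
  ij <- pairwise_difference_ci(ra, rb)
  ji <- pairwise_difference_ci(rb, ra)
  expect_equal(ij$lower, -ji$upper)
  expect_equal(ij$upper, -ji$lower)
  mismatched <- fake_replicates(0.5, runif(123))
  expect_error(pairwise_difference_ci(ra, mismatched), "equal length")
})

test_that("well-separated participants are discriminable", {
  tpl <- task_template("SIM", "latency", 200, 200)
  deltas <- delta_for_pi(c(0.3, 0.7), tpl$latency_sd_ms,
                         tpl$latency_exp_tail_ms)
  sim <- simulate_task_data(tpl, population_spec(2, 0, 0, seed = 15),
                            delta_fixed = deltas)
  sc <- score_participants(sim$trials)
  bt <- implicitprecision:::bootstrap_cohort(
    sim$trials, sc, score_spec("PI"), bootstrap_spec(2000), seed = 15)
  reps <- bt$cache[[1]]
  ci <- pairwise_difference_ci(reps[[1]], reps[[2]])
  expect_true(ci$lower > 0 || ci$upper < 0)
})

test_that("degenerate resamples are redrawn and hard failures surface", {
  # D score on nearly-constant data: some resamples hit zero SD and are
  # redrawn; fully constant data cannot be rescued
  spec <- bootstrap_spec(50, seed = 2)
  dfun <- function(a, b) implicitprecision:::d_score_values(a, b)
  set.seed(2)
  res <- replicate_scores(c(500, 500, 500, 501), c(500, 500, 500, 502),
                          spec, score_fn = dfun)
  expect_true(all(is.finite(res$replicates)))
  expect_error(
    suppressWarnings(
      replicate_scores(rep(5, 4), rep(5, 4), spec, score_fn = dfun)),
    "degenerate")
})
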