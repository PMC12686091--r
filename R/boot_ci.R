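# Per-participant bootstrap: each participant's own trials are the
# distribution resampled. Basic (reverse-percentile) intervals are the
# primary method; percentile intervals are kept for comparison. Bounds
# are deliberately NOT clipped to the metric's range — an interval
# escaping [0, 1] for a PI is information about the resampling
# distribution, and clipping is left to an explicit opt-in post-step.

#' Bootstrap specification
#'
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param method `"basic"` (reverse percentile, default) or
#'   `"percentile"`.
#' @param alpha Significance level (default 0.05 for 95% intervals).
#' @param seed Integer seed (per-participant substreams are derived from
#'   it in pipeline use).
#' @param stratified Resample within each block role, preserving the two
#'   pool sizes (default TRUE; unstratified resampling of the pooled
#'   trials can produce an empty pool).
#' @param max_redraws How often an invalid resample (one that breaks the
#'   scoring preconditions) is redrawn before the replicate is dropped.
#' @return A `bootstrap_spec` object.
#' @export
bootstrap_spec <- function(n_resamples = 2000L,
                           method = c("basic", "percentile"),
                           alpha = 0.05, seed = 1L, stratified = TRUE,
                           max_redraws = 100L) {
  method <- match.arg(method)
  stopifnot(n_resamples >= 1, alpha > 0, alpha < 1, max_redraws >= 0)
  structure(list(n_resamples = as.integer(n_resamples), method = method,
                 alpha = alpha, seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 max_redraws = as.integer(max_redraws)),
            class = "bootstrap_spec")
}

#' Bootstrap replicate scores for one participant
#'
#' Draws `spec$n_resamples` with-replacement resamples of the
#' participant's two response pools (within-role when stratified) and
#' scores each. Resamples that break the scoring preconditions (e.g. an
#' all-constant pool for the D score) are redrawn up to
#' `spec$max_redraws` times, then dropped with a warning.
#'
#' @param values_A,values_B The participant's role-A and role-B response
#'   values.
#' @param spec A [bootstrap_spec()]. The caller is responsible for
#'   seeding (see [bootstrap_participant_ci()]).
#' @param score_fn Function of `(a, b)` returning a scalar score;
#'   defaults to [pi_score()].
#' @return A `replicate_set`: list with `replicates` (numeric vector,
#'   dropped replicates removed), `estimate` (score of the original
#'   data), `n_redraws`, `n_dropped`.
#' @export
replicate_scores <- function(values_A, values_B, spec,
                             score_fn = pi_score) {
  nA <- length(values_A)
  nB <- length(values_B)
  estimate <- score_fn(values_A, values_B)
  reps <- numeric(spec$n_resamples)
  n_redraws <- 0L
  dropped <- logical(spec$n_resamples)
  pooled <- c(values_A, values_B)
  n <- nA + nB
  for (b in seq_len(spec$n_resamples)) {
    val <- NA_real_
    for (try in seq_len(spec$max_redraws + 1L)) {
      if (spec$stratified) {
        a <- values_A[sample.int(nA, nA, replace = TRUE)]
        bb <- values_B[sample.int(nB, nB, replace = TRUE)]
      } else {
        idx <- sample.int(n, n, replace = TRUE)
        a <- pooled[idx[idx <= nA]]
        bb <- pooled[idx[idx > nA]]
      }
      val <- tryCatch(score_fn(a, bb), error = function(e) NA_real_)
      if (is.finite(val)) break
      n_redraws <- n_redraws + 1L
    }
    if (!is.finite(val)) dropped[b] <- TRUE
    reps[b] <- val
  }
  if (any(dropped)) {
    warning(sum(dropped), " replicate(s) dropped after ",
            spec$max_redraws, " redraws", call. = FALSE)
    if (all(dropped)) {
      stop("degenerate data: no valid bootstrap resample could be drawn",
           call. = FALSE)
    }
  }
  structure(list(replicates = reps[!dropped], estimate = estimate,
                 n_redraws = n_redraws, n_dropped = sum(dropped)),
            class = "replicate_set")
}

interval_estimate <- function(estimate, lower, upper, method,
                              n_resamples) {
  structure(list(estimate = estimate, lower = lower, upper = upper,
                 width = upper - lower, method = method,
                 n_resamples = n_resamples),
            class = "interval_estimate")
}

#' Basic (reverse-percentile) bootstrap interval
#'
#' `(2 * estimate - Q(1 - alpha/2), 2 * estimate - Q(alpha/2))` where Q
#' is the empirical quantile of the replicates (type-7 interpolation).
#' Bounds are not clipped to the metric's range.
#'
#' @param estimate The point estimate from the original data.
#' @param replicates Numeric vector of bootstrap replicate scores.
#' @param alpha Significance level.
#' @return An `interval_estimate`.
#' @export
basic_interval <- function(estimate, replicates, alpha = 0.05) {
  stopifnot(length(replicates) >= 1, alpha > 0, alpha < 1)
  q <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2),
                       type = 7, names = FALSE)
  interval_estimate(estimate, 2 * estimate - q[2], 2 * estimate - q[1],
                    "basic", length(replicates))
}

#' Percentile bootstrap interval
#' @inheritParams basic_interval
#' @return An `interval_estimate`.
#' @export
percentile_interval <- function(estimate, replicates, alpha = 0.05) {
  stopifnot(length(replicates) >= 1, alpha > 0, alpha < 1)
  q <- stats::quantile(replicates, c(alpha / 2, 1 - alpha / 2),
                       type = 7, names = FALSE)
  interval_estimate(estimate, q[1], q[2], "percentile",
                    length(replicates))
}

#' Bootstrap confidence interval for one participant
#'
#' Seeds the generator from `spec$seed`, draws the replicate set and
#' forms the interval with the spec's method. Deterministic under a
#' fixed seed.
#'
#' @inheritParams replicate_scores
#' @return List with `interval` (an `interval_estimate`) and
#'   `replicates` (the `replicate_set`, reusable for pairwise
#'   difference intervals).
#' @export
bootstrap_participant_ci <- function(values_A, values_B, spec,
                                     score_fn = pi_score) {
  set.seed(spec$seed)
  rs <- replicate_scores(values_A, values_B, spec, score_fn)
  int <- if (spec$method == "basic") {
    basic_interval(rs$estimate, rs$replicates, spec$alpha)
  } else {
    percentile_interval(rs$estimate, rs$replicates, spec$alpha)
  }
  list(interval = int, replicates = rs)
}

#' Bootstrap interval for the difference between two participants
#'
#' Pairs the two participants' cached replicate vectors index by index
#' (statistically valid for independently generated streams), forms the
#' difference replicates, and wraps a basic interval around the point
#' difference. Downstream, "discriminable" means this interval excludes
#' zero.
#'
#' @param rep_i,rep_j `replicate_set`s with equal replicate counts.
#' @param alpha Significance level.
#' @return An `interval_estimate` for `estimate_i - estimate_j`.
#' @export
pairwise_difference_ci <- function(rep_i, rep_j, alpha = 0.05) {
  stopifnot(inherits(rep_i, "replicate_set"),
            inherits(rep_j, "replicate_set"))
  if (length(rep_i$replicates) != length(rep_j$replicates)) {
    stop("replicate sets must have equal length", call. = FALSE)
  }
  d <- rep_i$replicates - rep_j$replicates
  basic_interval(rep_i$estimate - rep_j$estimate, d, alpha)
}

#' Interval table for a cohort of interval estimates
#' @param intervals List of `interval_estimate`s.
#' @param ids Optional identifiers (recycled into the first column).
#' @return Tidy data frame: id, estimate, lower, upper, width, method.
#' @export
intervals_df <- function(intervals, ids = seq_along(intervals)) {
  data.frame(id = ids,
             estimate = vapply(intervals, `[[`, numeric(1), "estimate"),
             lower = vapply(intervals, `[[`, numeric(1), "lower"),
             upper = vapply(intervals, `[[`, numeric(1), "upper"),
             width = vapply(intervals, `[[`, numeric(1), "width"),
             method = vapply(intervals, `[[`, character(1), "method"),
             stringsAsFactors = FALSE)
}
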