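# Per-participant point estimates. The probabilistic index (PI) is the
# primary metric because it puts latency- and evaluation-based tasks on
# one scale; native scores (IAT-style D, proportion difference, latency
# difference) are provided for task-specific analyses.

#' Scoring specification
#'
#' @param metric One of `"PI"` (probabilistic index), `"D"` (IAT-family
#'   D score), `"prop_diff"` (difference of response proportions,
#'   AMP-style), `"latency_diff"` (mean latency difference, ms).
#' @param orientation `"B_minus_A"` (default: PI > 0.5 and D > 0 both
#'   read as the role-B pool being larger/slower) or `"A_minus_B"`.
#' @param min_trials_per_role Minimum trials required in each pool.
#' @param use_error_trials Keep error-trial latencies (default TRUE; the
#'   scoring contrast is between block types, and tasks administered with
#'   built-in error correction fold the penalty into the latency).
#' @return A `score_spec` object.
#' @export
score_spec <- function(metric = c("PI", "D", "prop_diff", "latency_diff"),
                       orientation = c("B_minus_A", "A_minus_B"),
                       min_trials_per_role = 2L,
                       use_error_trials = TRUE) {
  metric <- match.arg(metric)
  orientation <- match.arg(orientation)
  stopifnot(min_trials_per_role >= 2)
  structure(list(metric = metric, orientation = orientation,
                 min_trials_per_role = as.integer(min_trials_per_role),
                 use_error_trials = isTRUE(use_error_trials)),
            class = "score_spec")
}

#' Probabilistic index of two response pools
#'
#' Probability that a randomly selected role-B response exceeds a
#' randomly selected role-A response, ties counted half:
#' `(#\{b > a\} + 0.5 #\{b = a\}) / (nA * nB)`. Equals the Mann-Whitney
#' U statistic (with half ties) divided by `nA * nB`, and is computed
#' through midranks in O(n log n); the brute-force pair enumeration is
#' kept as an oracle in the test suite.
#'
#' @param values_A,values_B Non-empty numeric vectors (latencies or 0/1
#'   evaluations).
#' @return Probability in \[0, 1\].
#' @export
#' @examples
#' pi_score(c(400, 500, 600), c(500, 600, 700))  # 7/9
pi_score <- function(values_A, values_B) {
  nA <- length(values_A)
  nB <- length(values_B)
  if (nA == 0L || nB == 0L) {
    stop("both response pools must be non-empty", call. = FALSE)
  }
  if (anyNA(values_A) || anyNA(values_B)) {
    stop("response values must not be missing", call. = FALSE)
  }
  r <- rank(c(values_A, values_B))
  u <- sum(r[(nA + 1L):(nA + nB)]) - nB * (nB + 1) / 2
  u / (nA * nB)
}

# inclusive-SD D score on raw latency vectors; shared by d_score and the
# bootstrap fast path
d_score_values <- function(lat_A, lat_B) {
  s <- stats::sd(c(lat_A, lat_B))
  if (!is.finite(s) || s == 0) {
    stop("degenerate data: pooled latency SD is zero", call. = FALSE)
  }
  (mean(lat_B) - mean(lat_A)) / s
}

#' IAT-family D score for one participant
#'
#' Mean latency difference between the two critical block types divided
#' by the inclusive standard deviation of all critical-trial latencies
#' (both pools, n - 1 denominator). No error-penalty replacement is
#' applied; the variant hook is the `use_error_trials` flag of
#' [score_spec()].
#'
#' @param trials One participant's role-assigned critical trials.
#' @param spec A [score_spec()].
#' @return The D score (sign follows `spec$orientation`).
#' @export
d_score <- function(trials, spec = score_spec("D")) {
  v <- role_values(trials, spec, field = "latency_ms")
  d <- d_score_values(v$A, v$B)
  if (spec$orientation == "A_minus_B") d <- -d
  d
}

#' Native (task-specific) scores
#'
#' `prop_diff`: difference in mean response value (e.g. proportion of
#' pleasant judgements) between role B and role A. `latency_diff`:
#' difference in mean latency (ms).
#'
#' @inheritParams d_score
#' @return The native score.
#' @export
native_score <- function(trials, spec) {
  stopifnot(spec$metric %in% c("prop_diff", "latency_diff"))
  field <- if (spec$metric == "prop_diff") "response_value" else "latency_ms"
  v <- role_values(trials, spec, field = field)
  est <- mean(v$B) - mean(v$A)
  if (spec$orientation == "A_minus_B") est <- -est
  est
}

# split one participant's trials into role pools, honouring the spec's
# error-trial and minimum-count rules
role_values <- function(trials, spec, field) {
  if (!spec$use_error_trials) {
    keep <- is.na(trials$accuracy) | trials$accuracy == 1
    trials <- trials[keep, , drop = FALSE]
  }
  a <- trials[[field]][trials$block_role == "A"]
  b <- trials[[field]][trials$block_role == "B"]
  if (length(a) < spec$min_trials_per_role ||
      length(b) < spec$min_trials_per_role) {
    stop(sprintf("insufficient data: need >= %d trials per role (have %d A, %d B)",
                 spec$min_trials_per_role, length(a), length(b)),
         call. = FALSE)
  }
  list(A = a, B = b)
}

# metric dispatch on pre-split pools (used by the bootstrap)
score_pools <- function(values_A, values_B, spec) {
  est <- switch(spec$metric,
                PI = pi_score(values_A, values_B),
                D = d_score_values(values_A, values_B),
                prop_diff = ,
                latency_diff = mean(values_B) - mean(values_A))
  if (spec$orientation == "A_minus_B") {
    est <- if (spec$metric == "PI") 1 - est else -est
  }
  est
}

# which trial field a metric compares
metric_field <- function(spec) {
  switch(spec$metric,
         PI = "response_value",
         D = "latency_ms",
         prop_diff = "response_value",
         latency_diff = "latency_ms")
}

#' Score every participant in a trial table
#'
#' One row per participant x measure x domain. Participants whose data
#' fail the metric's preconditions (a missing role pool, too few trials,
#' zero pooled SD for D) are skipped; skips are recorded in the
#' `"skipped"` attribute with their reason, never silently dropped.
#'
#' @param trials A role-assigned [trial_table()] with exclusions applied.
#' @param spec A [score_spec()].
#' @return Data frame with columns participant_id, measure, domain,
#'   metric, estimate, n_A, n_B; attribute `"skipped"` holds a data frame
#'   of skipped units and reasons.
#' @export
score_participants <- function(trials, spec = score_spec("PI")) {
  trials <- trial_table(trials)
  stopifnot(inherits(spec, "score_spec"))
  if (any(is.na(trials$block_role))) {
    stop("block roles must be assigned before scoring", call. = FALSE)
  }
  unit <- interaction(trials$participant_id, trials$measure,
                      trials$domain, drop = TRUE, sep = "\r")
  groups <- split(trials, unit)
  rows <- vector("list", length(groups))
  skipped <- list()
  field <- metric_field(spec)
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    est <- tryCatch({
      v <- role_values(g, spec, field = field)
      list(value = score_pools(v$A, v$B, spec),
           n_A = length(v$A), n_B = length(v$B))
    }, error = function(e) e)
    if (inherits(est, "error")) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        participant_id = g$participant_id[1], measure = g$measure[1],
        domain = g$domain[1], reason = conditionMessage(est),
        stringsAsFactors = FALSE)
      next
    }
    rows[[k]] <- data.frame(participant_id = g$participant_id[1],
                            measure = g$measure[1], domain = g$domain[1],
                            metric = spec$metric, estimate = est$value,
                            n_A = est$n_A, n_B = est$n_B,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), measure = character(),
                      domain = character(), metric = character(),
                      estimate = numeric(), n_A = integer(),
                      n_B = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(participant_id = character(),
                                          measure = character(),
                                          domain = character(),
                                          reason = character())
  out
}
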