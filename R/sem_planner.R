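# Standard-error-of-measurement utilities and precision planning: how
# wide may an individual's CI be before adjacent feedback categories
# (the Project Implicit D-score cut-offs) become indistinguishable, and
# what error rates follow from a given per-score measurement SD.

#' Standard error of measurement
#'
#' `SEm = SD * sqrt(1 - r)`, with `SD` the score standard deviation and
#' `r` the test-retest reliability.
#'
#' @param sd Score standard deviation (> 0).
#' @param r Reliability in \[0, 1\].
#' @return The SEm.
#' @export
sem <- function(sd, r) {
  if (any(sd <= 0)) stop("sd must be positive", call. = FALSE)
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]", call. = FALSE)
  sd * sqrt(1 - r)
}

#' SEm-based interval around an individual score
#'
#' `(score - z * SEm, score + z * SEm)`; with z = 1.96 this is the
#' conventional 95% interval.
#'
#' @param score Observed score.
#' @param sem_value SEm (>= 0).
#' @param z Critical value (default 1.96).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
sem_interval <- function(score, sem_value, z = 1.96) {
  if (any(sem_value < 0)) stop("sem_value must be >= 0", call. = FALSE)
  c(lower = score - z * sem_value, upper = score + z * sem_value)
}

#' Project Implicit-style cut-off scheme
#'
#' @param cutoffs Named, strictly increasing numeric vector; defaults to
#'   the Project Implicit IAT D-score feedback cut-offs.
#' @return A `cutoff_scheme` object.
#' @export
cutoff_scheme <- function(cutoffs = c(no_bias = 0, weak = 0.15,
                                      moderate = 0.35, strong = 0.65)) {
  if (any(diff(cutoffs) <= 0)) {
    stop("cut-offs must be strictly increasing", call. = FALSE)
  }
  structure(cutoffs, class = "cutoff_scheme")
}

#' Maximal CI width that still separates two cut-offs
#'
#' A score sitting exactly at one cut-off with a symmetric interval of
#' width `w` excludes the other cut-off iff `w/2 < cutoff_high -
#' cutoff_low`; the maximal such width is `2 * (cutoff_high -
#' cutoff_low)`. E.g. separating the moderate (0.35) and strong (0.65)
#' D-score cut-offs requires intervals no wider than 0.6.
#'
#' @param cutoff_low,cutoff_high The two cut-offs (`cutoff_high >
#'   cutoff_low`).
#' @return The required width, in score units.
#' @export
required_ci_width <- function(cutoff_low, cutoff_high) {
  if (any(cutoff_high <= cutoff_low)) {
    stop("cutoff_high must exceed cutoff_low", call. = FALSE)
  }
  2 * (cutoff_high - cutoff_low)
}

#' Required widths between adjacent cut-offs of a scheme
#'
#' @param scheme A [cutoff_scheme()].
#' @return Data frame: from, to, cutoff_low, cutoff_high,
#'   required_width.
#' @export
required_widths <- function(scheme = cutoff_scheme()) {
  stopifnot(inherits(scheme, "cutoff_scheme"))
  k <- length(scheme)
  data.frame(from = names(scheme)[-k], to = names(scheme)[-1],
             cutoff_low = unname(scheme[-k]),
             cutoff_high = unname(scheme[-1]),
             required_width = required_ci_width(unname(scheme[-k]),
                                                unname(scheme[-1])),
             stringsAsFactors = FALSE)
}

#' Simulated error rates for comparing two individuals' scores
#'
#' Draws `n_sims` pairs of observed scores — true scores separated by
#' `true_difference`, each perturbed by independent Normal(0,
#' measurement_sd^2) error — and declares a difference when the absolute
#' observed difference exceeds `z * sqrt(2) * measurement_sd` (the sqrt(2)
#' reflecting the error variance of a difference of two noisy scores).
#' With `true_difference = 0` the declaration rate is the false-positive
#' rate; otherwise the non-declaration rate is the false-negative rate.
#'
#' @param true_difference Latent score difference between the pair.
#' @param measurement_sd Per-score measurement error SD (>= 0).
#' @param alpha Nominal significance level (sets z).
#' @param n_sims Number of simulated pairs.
#' @param seed Integer seed.
#' @return List with `false_positive_rate`, `false_negative_rate` (the
#'   one not addressed by `true_difference` is `NA`), and the
#'   declaration threshold used.
#' @export
simulate_error_rates <- function(true_difference, measurement_sd,
                                 alpha = 0.05, n_sims = 1e5L,
                                 seed = 1L) {
  stopifnot(measurement_sd >= 0, n_sims >= 1, alpha > 0, alpha < 1)
  set.seed(as.integer(seed))
  z <- stats::qnorm(1 - alpha / 2)
  s1 <- stats::rnorm(n_sims, 0, measurement_sd)
  s2 <- stats::rnorm(n_sims, true_difference, measurement_sd)
  threshold <- z * sqrt(2) * measurement_sd
  declared <- abs(s2 - s1) > threshold
  if (true_difference == 0) {
    list(false_positive_rate = mean(declared),
         false_negative_rate = NA_real_, threshold = threshold)
  } else {
    list(false_positive_rate = NA_real_,
         false_negative_rate = mean(!declared), threshold = threshold)
  }
}

#' Summarize bootstrap D-score intervals at feedback cut-offs
#'
#' For each cut-off, collects the participants whose D estimate lies
#' within `tolerance` of it and summarizes their interval bounds
#' (median by default). A cut-off with an empty neighborhood yields a
#' flagged missing row rather than an error.
#'
#' @param intervals Data frame with columns `estimate`, `lower`,
#'   `upper` for D-metric interval estimates.
#' @param scheme A [cutoff_scheme()].
#' @param tolerance Half-width of the estimate neighborhood around each
#'   cut-off.
#' @param summary_fn Summary functional for the bounds (default
#'   [stats::median()]).
#' @return Data frame: cutoff_label, cutoff, lower, upper, n, missing.
#' @export
dscore_cutoff_intervals <- function(intervals, scheme = cutoff_scheme(),
                                    tolerance = 0.05,
                                    summary_fn = stats::median) {
  stopifnot(inherits(scheme, "cutoff_scheme"),
            all(c("estimate", "lower", "upper") %in% names(intervals)))
  rows <- lapply(seq_along(scheme), function(i) {
    sel <- abs(intervals$estimate - scheme[i]) <= tolerance
    if (!any(sel)) {
      data.frame(cutoff_label = names(scheme)[i],
                 cutoff = unname(scheme[i]), lower = NA_real_,
                 upper = NA_real_, n = 0L, missing = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cutoff_label = names(scheme)[i],
                 cutoff = unname(scheme[i]),
                 lower = summary_fn(intervals$lower[sel]),
                 upper = summary_fn(intervals$upper[sel]),
                 n = sum(sel), missing = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
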