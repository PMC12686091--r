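# The three per-cell precision statistics (a "cell" is one measure x
# domain combination):
#   detectability    — does a participant's CI exclude the metric's
#                      neutral point (PI = 0.5)?
#   discriminability — from what proportion of the other participants in
#                      the cell is a participant's score detectably
#                      different (pairwise difference CI excludes 0)?
#   coverage         — what fraction of the observed score range does a
#                      participant's CI span?
# Cell proportions of exactly 0 or 1 and variances of exactly 0 are
# nudged by 0.001 so every row can carry an inverse-variance weight in
# the meta-analysis.

#' Nudge boundary proportions and zero variances for meta-analysis
#'
#' Proportions of exactly 0 become 0.001, of exactly 1 become 0.999;
#' variances of exactly 0 become 0.001.
#'
#' @param p Proportion(s).
#' @param variance Variance(s).
#' @return List with offset `p` and `variance`.
#' @export
offset_for_meta <- function(p, variance) {
  p[p == 0] <- 0.001
  p[p == 1] <- 0.999
  variance[variance == 0] <- 0.001
  list(p = p, variance = variance)
}

#' Is an individual's effect detectable from the neutral point?
#'
#' TRUE iff the interval excludes `null_value`; a bound exactly on the
#' null does not count as detection.
#'
#' @param interval An `interval_estimate` (or anything with `lower` and
#'   `upper`).
#' @param null_value The neutral point (0.5 for the PI, 0 for difference
#'   metrics).
#' @return Logical flag.
#' @export
detectable_from_zero <- function(interval, null_value = 0.5) {
  interval$lower > null_value || interval$upper < null_value
}

#' Cell-level proportion of detectable effects (with variance)
#'
#' @param flags Logical vector, one flag per participant in the cell.
#' @param measure,domain Cell labels.
#' @return One-row data frame: measure, domain, statistic, proportion,
#'   variance, n_units — the meta-analysis row unit.
#' @export
cell_proportion_detectable <- function(flags, measure = NA_character_,
                                       domain = NA_character_) {
  if (length(flags) == 0L) stop("empty cell", call. = FALSE)
  n <- length(flags)
  p <- mean(flags)
  v <- p * (1 - p) / n
  o <- offset_for_meta(p, v)
  data.frame(measure = measure, domain = domain,
             statistic = "prop_diff_zero", proportion = o$p,
             variance = o$variance, n_units = n,
             stringsAsFactors = FALSE)
}

#' Per-participant discriminability proportions for one cell
#'
#' For every unordered pair in the cell, the bootstrap difference CI is
#' computed from the cached replicate sets; a pair is discriminable when
#' that interval excludes zero (a symmetric relation). Each participant's
#' proportion is their discriminable-pair count over `n - 1`, with a
#' binomial variance `p(1-p)/(n-1)`, both offset for meta-analysis.
#'
#' @param replicate_sets Named list of `replicate_set`s, one per
#'   participant in the cell.
#' @param alpha Significance level for the difference intervals.
#' @param measure,domain Cell labels.
#' @return Data frame with one row per participant: participant_id,
#'   measure, domain, statistic, proportion, variance, n_units.
#' @export
discriminability_proportions <- function(replicate_sets, alpha = 0.05,
                                         measure = NA_character_,
                                         domain = NA_character_) {
  n <- length(replicate_sets)
  if (n < 2L) {
    stop("discriminability needs at least 2 participants in the cell",
         call. = FALSE)
  }
  ids <- names(replicate_sets)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  counts <- integer(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ci <- pairwise_difference_ci(replicate_sets[[i]],
                                   replicate_sets[[j]], alpha)
      if (ci$lower > 0 || ci$upper < 0) {
        counts[i] <- counts[i] + 1L
        counts[j] <- counts[j] + 1L
      }
    }
  }
  p <- counts / (n - 1L)
  v <- p * (1 - p) / (n - 1L)
  o <- offset_for_meta(p, v)
  data.frame(participant_id = ids, measure = measure, domain = domain,
             statistic = "prop_discriminable", proportion = o$p,
             variance = o$variance, n_units = n,
             stringsAsFactors = FALSE)
}

#' Confidence-interval coverage of the observed score range in a cell
#'
#' The observed range is the spread of the point estimates in the cell;
#' each participant's interval width is divided by it. Width proportions
#' above 1 are legal (an interval wider than the score range) and are
#' preserved. The cell summary is their mean with the variance of the
#' mean (sample variance / n), offset for meta-analysis.
#'
#' @param estimates Point estimates of the participants in the cell.
#' @param widths Their interval widths.
#' @param measure,domain Cell labels.
#' @return List with `participants` (per-participant width proportions)
#'   and `cell` (one CellSummary row).
#' @export
coverage_proportion <- function(estimates, widths,
                                measure = NA_character_,
                                domain = NA_character_) {
  stopifnot(length(estimates) == length(widths))
  if (length(estimates) < 2L) {
    stop("coverage needs at least 2 participants in the cell",
         call. = FALSE)
  }
  rng <- max(estimates) - min(estimates)
  if (rng <= 0) {
    stop("degenerate cell: observed score range is zero", call. = FALSE)
  }
  wp <- widths / rng
  m <- mean(wp)
  v <- stats::var(wp) / length(wp)
  o <- offset_for_meta(m, v)
  list(participants = data.frame(width_proportion = wp,
                                 measure = measure, domain = domain,
                                 stringsAsFactors = FALSE),
       cell = data.frame(measure = measure, domain = domain,
                         statistic = "ci_width_proportion_mean",
                         proportion = o$p, variance = o$variance,
                         n_units = length(wp), stringsAsFactors = FALSE))
}

#' Modal confidence-interval width (MAP estimate)
#'
#' Mode of a Gaussian kernel density estimate over the widths (Silverman
#' bandwidth, 2048-point grid between the sample extremes). For an
#' effectively constant sample the common value is returned directly.
#'
#' @param widths Interval widths (>= 1 value).
#' @return The modal width.
#' @export
map_width <- function(widths) {
  stopifnot(length(widths) >= 1)
  if (diff(range(widths)) < .Machine$double.eps^0.5) return(widths[1])
  d <- stats::density(widths, bw = "nrd0", n = 2048,
                      from = min(widths), to = max(widths))
  d$x[which.max(d$y)]
}
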