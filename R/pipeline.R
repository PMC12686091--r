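# End-to-end orchestration: simulate (or ingest) trials -> assign roles
# -> exclusions -> scores -> per-participant bootstrap CIs -> the three
# precision statistics -> weighted meta-models with Holm-corrected
# contrasts. Per-participant bootstrap seeds are substreams of the
# global seed keyed by (participant, measure, domain), so results do not
# depend on row order.

#' Study configuration
#'
#' @param trials Optional [trial_table()] with roles assigned; when
#'   `NULL`, a synthetic study is simulated from `templates` and the
#'   population parameters.
#' @param templates Named list of [task_template()]s for simulation.
#' @param domains Domain labels for simulation.
#' @param n_participants Participants per measure x domain cell.
#' @param mu_delta_ms,tau_delta_ms,mu_delta_logit,tau_delta_logit
#'   Population shift parameters passed to [simulate_study()].
#' @param policy An [exclusion_policy()].
#' @param score A [score_spec()].
#' @param bootstrap A [bootstrap_spec()] (its `seed` field is ignored;
#'   `seed` below governs all randomness).
#' @param rqs Which precision statistics to run (subset of 1:3).
#' @param run_dscore_cutoffs Also bootstrap D scores for the latency
#'   measures and summarize them at the feedback cut-offs?
#' @param seed Global integer seed.
#' @return A `study_config` object.
#' @export
study_config <- function(trials = NULL,
                         templates = default_task_templates(),
                         domains = c("politics", "race", "self"),
                         n_participants = 50,
                         mu_delta_ms = 60, tau_delta_ms = 40,
                         mu_delta_logit = 0.8, tau_delta_logit = 0.6,
                         policy = exclusion_policy(),
                         score = score_spec("PI"),
                         bootstrap = bootstrap_spec(),
                         rqs = 1:3,
                         run_dscore_cutoffs = FALSE,
                         seed = 1L) {
  stopifnot(all(rqs %in% 1:3))
  structure(list(trials = trials, templates = templates,
                 domains = domains, n_participants = n_participants,
                 mu_delta_ms = mu_delta_ms, tau_delta_ms = tau_delta_ms,
                 mu_delta_logit = mu_delta_logit,
                 tau_delta_logit = tau_delta_logit,
                 policy = policy, score = score, bootstrap = bootstrap,
                 rqs = sort(unique(rqs)),
                 run_dscore_cutoffs = isTRUE(run_dscore_cutoffs),
                 seed = as.integer(seed)),
            class = "study_config")
}

# bootstrap every scored participant; returns the intervals table plus
# the replicate cache keyed by cell
bootstrap_cohort <- function(trials, scores, spec, boot, seed,
                             score_fn_field = NULL) {
  field <- if (is.null(score_fn_field)) metric_field(spec) else
    score_fn_field
  cells <- split(seq_len(nrow(scores)),
                 paste(scores$measure, scores$domain, sep = "\r"))
  key_all <- paste(trials$participant_id, trials$measure, trials$domain,
                   sep = "\r")
  rows <- vector("list", nrow(scores))
  cache <- list()
  for (cell in names(cells)) {
    cell_reps <- list()
    for (i in cells[[cell]]) {
      pid <- scores$participant_id[i]
      key <- paste(pid, scores$measure[i], scores$domain[i], sep = "\r")
      g <- trials[key_all == key, , drop = FALSE]
      v <- role_values(g, spec, field = field)
      bspec <- boot
      bspec$seed <- substream_seed(seed, paste("boot", spec$metric, key,
                                               sep = "|"))
      res <- bootstrap_participant_ci(
        v$A, v$B, bspec, score_fn = function(a, b) score_pools(a, b, spec))
      int <- res$interval
      rows[[i]] <- data.frame(participant_id = pid,
                              measure = scores$measure[i],
                              domain = scores$domain[i],
                              metric = spec$metric,
                              estimate = int$estimate, lower = int$lower,
                              upper = int$upper, width = int$width,
                              method = int$method,
                              n_resamples = int$n_resamples,
                              stringsAsFactors = FALSE)
      cell_reps[[pid]] <- res$replicates
    }
    cache[[cell]] <- cell_reps
  }
  list(intervals = do.call(rbind, rows), cache = cache)
}

#' Run an end-to-end precision study
#'
#' Executes the full pipeline and returns a report bundle whose tables
#' back caterpillar/forest-style summaries: per-participant scores and
#' intervals, the per-cell precision statistics, the three weighted
#' meta-model fits with Holm-corrected contrasts, and modal CI widths
#' per cell. Deterministic under a fixed `config$seed`.
#'
#' @param config A [study_config()].
#' @return A `report_bundle` list: `scores`, `intervals`,
#'   `participant_precision`, `cell_summaries`, `meta_fits`,
#'   `contrasts`, `emms`, `map_widths`, `dscore_cutoffs` (optional),
#'   `exclusions`, `ground_truth` (when simulated), `manifest`.
#' @export
run_precision_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  ground_truth <- NULL
  if (is.null(config$trials)) {
    sim <- simulate_study(config$templates, config$domains,
                          config$n_participants, config$mu_delta_ms,
                          config$tau_delta_ms, config$mu_delta_logit,
                          config$tau_delta_logit, config$seed)
    trials <- sim$trials
    ground_truth <- sim$ground_truth
  } else {
    trials <- trial_table(config$trials)
  }
  excl <- apply_exclusions(trials, config$policy)
  trials <- excl$trials
  scores <- score_participants(trials, config$score)
  if (nrow(scores) == 0L) {
    stop("pipeline stage 'scoring': no participant could be scored",
         call. = FALSE)
  }
  bt <- bootstrap_cohort(trials, scores, config$score, config$bootstrap,
                         config$seed)
  intervals <- bt$intervals
  alpha <- config$bootstrap$alpha

  cell_summaries <- list()
  participant_precision <- list()
  cells <- split(seq_len(nrow(intervals)),
                 paste(intervals$measure, intervals$domain, sep = "\r"))
  for (cell in names(cells)) {
    idx <- cells[[cell]]
    m <- intervals$measure[idx[1]]
    d <- intervals$domain[idx[1]]
    null_value <- if (config$score$metric == "PI") 0.5 else 0
    flags <- intervals$lower[idx] > null_value |
      intervals$upper[idx] < null_value
    if (1 %in% config$rqs) {
      cell_summaries[[paste0(cell, "\r1")]] <-
        cell_proportion_detectable(flags, m, d)
    }
    if (2 %in% config$rqs) {
      if (length(idx) < 2L) {
        stop("pipeline stage 'RQ2 discriminability': cell ", m, " x ", d,
             " has fewer than 2 participants", call. = FALSE)
      }
      disc <- discriminability_proportions(bt$cache[[cell]], alpha, m, d)
      participant_precision[[paste0(cell, "\r2")]] <- disc
    }
    if (3 %in% config$rqs) {
      cov <- coverage_proportion(intervals$estimate[idx],
                                 intervals$width[idx], m, d)
      cell_summaries[[paste0(cell, "\r3")]] <- cov$cell
    }
    participant_precision[[paste0(cell, "\rdet")]] <-
      data.frame(participant_id = intervals$participant_id[idx],
                 measure = m, domain = d, statistic = "detectable_zero",
                 proportion = as.numeric(flags),
                 variance = NA_real_, n_units = length(idx),
                 stringsAsFactors = FALSE)
  }
  cell_summaries <- do.call(rbind, cell_summaries)
  participant_precision <- do.call(rbind, participant_precision)
  rownames(cell_summaries) <- rownames(participant_precision) <- NULL

  meta_fits <- list()
  contrasts <- list()
  emms <- list()
  fit_one <- function(df) {
    dat <- data.frame(y = df$proportion, variance = df$variance,
                      measure = df$measure, domain = df$domain)
    fit <- fit_weighted_lmm(dat)
    list(fit = fit, emm = estimated_marginal_means(fit),
         contrast = pairwise_contrasts(fit, alpha))
  }
  if (1 %in% config$rqs) {
    r <- fit_one(cell_summaries[cell_summaries$statistic ==
                                  "prop_diff_zero", ])
    meta_fits$rq1 <- r$fit; emms$rq1 <- r$emm; contrasts$rq1 <- r$contrast
  }
  if (2 %in% config$rqs) {
    r <- fit_one(participant_precision[participant_precision$statistic ==
                                         "prop_discriminable", ])
    meta_fits$rq2 <- r$fit; emms$rq2 <- r$emm; contrasts$rq2 <- r$contrast
  }
  if (3 %in% config$rqs) {
    r <- fit_one(cell_summaries[cell_summaries$statistic ==
                                  "ci_width_proportion_mean", ])
    meta_fits$rq3 <- r$fit; emms$rq3 <- r$emm; contrasts$rq3 <- r$contrast
  }

  map_widths <- do.call(rbind, lapply(cells, function(idx) {
    data.frame(measure = intervals$measure[idx[1]],
               domain = intervals$domain[idx[1]],
               map_width = map_width(intervals$width[idx]),
               n = length(idx), stringsAsFactors = FALSE)
  }))
  rownames(map_widths) <- NULL

  dscore_cutoffs <- NULL
  if (config$run_dscore_cutoffs) {
    lat_measures <- names(Filter(function(t) t$response_kind == "latency",
                                 config$templates))
    dtrials <- trials[trials$measure %in% lat_measures, , drop = FALSE]
    dspec <- score_spec("D", min_trials_per_role =
                          config$score$min_trials_per_role)
    dscores <- score_participants(dtrials, dspec)
    dbt <- bootstrap_cohort(dtrials, dscores, dspec, config$bootstrap,
                            config$seed)
    dscore_cutoffs <- dscore_cutoff_intervals(dbt$intervals)
  }

  # strip the fitted-model frames down to plain numbers so bundles from
  # identical seeds compare identical()
  meta_fits <- lapply(meta_fits, function(f) {
    f$data <- NULL
    f
  })
  bundle <- structure(list(
    scores = scores,
    intervals = intervals,
    participant_precision = participant_precision,
    cell_summaries = cell_summaries,
    meta_fits = meta_fits,
    emms = emms,
    contrasts = contrasts,
    map_widths = map_widths,
    dscore_cutoffs = dscore_cutoffs,
    exclusions = exclusion_report_df(excl$report),
    ground_truth = ground_truth,
    manifest = list(seed = config$seed, metric = config$score$metric,
                    n_resamples = config$bootstrap$n_resamples,
                    method = config$bootstrap$method,
                    alpha = alpha, rqs = config$rqs,
                    package_version =
                      as.character(utils::packageVersion("implicitprecision")))),
    class = "report_bundle")
  bundle
}

#' Human-readable summary of a report bundle
#'
#' @param bundle A `report_bundle`.
#' @param digits Digits for printed proportions.
#' @return Invisibly, a tidy per-measure summary data frame (modal
#'   width and the available precision statistics, averaged over
#'   domains); the text form is printed.
#' @export
summarize_report <- function(bundle, digits = 3) {
  stopifnot(inherits(bundle, "report_bundle"))
  measures <- sort(unique(bundle$scores$measure))
  per_measure <- lapply(measures, function(m) {
    row <- list(measure = m,
                map_width = mean(bundle$map_widths$map_width[
                  bundle$map_widths$measure == m]))
    for (rq in c("rq1", "rq2", "rq3")) {
      emm <- bundle$emms[[rq]]
      row[[paste0(rq, "_emm")]] <-
        if (is.null(emm)) NA_real_ else emm$emmean[emm$measure == m]
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_measure)
  cat("Precision study summary (seed ", bundle$manifest$seed, ", ",
      bundle$manifest$n_resamples, " resamples, metric ",
      bundle$manifest$metric, ")\n", sep = "")
  skipped <- setdiff(1:3, bundle$manifest$rqs)
  if (length(skipped)) {
    cat("  skipped: RQ", paste(skipped, collapse = ", RQ"),
        " (not requested in config)\n", sep = "")
  }
  for (i in seq_len(nrow(out))) {
    cat(sprintf("  %-6s modal CI width %.3f | detectable %s | discriminable %s | coverage %s\n",
                out$measure[i], out$map_width[i],
                fmt_or_na(out$rq1_emm[i], digits),
                fmt_or_na(out$rq2_emm[i], digits),
                fmt_or_na(out$rq3_emm[i], digits)))
  }
  top <- bundle$contrasts$rq1
  if (!is.null(top)) {
    top <- top[order(top$p_holm, -abs(top$emm_difference)), ]
    cat("  largest detectability contrast: ", top$measure_1[1], " - ",
        top$measure_2[1], " = ",
        format(round(top$emm_difference[1], digits)), " (Holm p = ",
        format.pval(top$p_holm[1], digits = 3), ")\n", sep = "")
  }
  invisible(out)
}

fmt_or_na <- function(x, digits) {
  if (is.na(x)) "--" else format(round(x, digits), nsmall = digits)
}

#' Write a report bundle's tables as CSV files
#'
#' @param bundle A `report_bundle`.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(bundle$scores, "scores")
  wr(bundle$intervals, "intervals")
  wr(bundle$participant_precision, "participant_precision")
  wr(bundle$cell_summaries, "cell_summaries")
  wr(bundle$map_widths, "map_widths")
  wr(bundle$dscore_cutoffs, "dscore_cutoffs")
  wr(bundle$exclusions, "exclusions")
  wr(bundle$ground_truth, "ground_truth")
  for (rq in names(bundle$contrasts)) {
    wr(bundle$contrasts[[rq]], paste0("contrasts_", rq))
    wr(bundle$emms[[rq]], paste0("emms_", rq))
  }
  manifest <- bundle$manifest
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x)
                     paste(x, collapse = ","), character(1)),
                   sep = "="),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
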