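#' @keywords internal
"_PACKAGE"

TRIAL_COLUMNS <- c(
  "participant_id", "measure", "domain", "block_label", "block_role",
  "trial_index", "latency_ms", "accuracy", "response_value"
)

REQUIRED_INPUT_COLUMNS <- c(
  "participant_id", "measure", "domain", "block_label",
  "trial_index", "latency_ms"
)

#' Construct and validate a trial table
#'
#' A trial table is a long-format data frame with one row per task trial,
#' the single input currency of the pipeline. Columns: `participant_id`,
#' `measure` (task name, e.g. IAT, BIAT, STIAT, AMP, GNAT, EPT), `domain`
#' (attitude domain, e.g. politics, race, self), `block_label` (raw block
#' string), `block_role` (`"A"`/`"B"` once roles are assigned, otherwise
#' `NA`), `trial_index` (1-based, unique within participant x measure x
#' domain), `latency_ms` (positive), `accuracy` (0/1/`NA`), and
#' `response_value` (the value the probabilistic index compares: the
#' latency for latency-scored tasks, a 0/1 evaluation for binary tasks).
#'
#' @param df A data frame containing at least the required columns.
#' @return The validated trial table (class `trial_table`).
#' @export
trial_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_INPUT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"block_role" %in% names(df)) df$block_role <- NA_character_
  if (!"accuracy" %in% names(df)) df$accuracy <- NA_real_
  if (!"response_value" %in% names(df)) df$response_value <- df$latency_ms
  df$trial_index <- as.integer(df$trial_index)
  df$latency_ms <- as.numeric(df$latency_ms)
  df$accuracy <- as.numeric(df$accuracy)
  df$response_value <- as.numeric(df$response_value)
  df <- df[TRIAL_COLUMNS]
  bad_lat <- !is.na(df$latency_ms) & df$latency_ms <= 0
  if (any(bad_lat)) {
    stop("latency_ms must be positive; ", sum(bad_lat),
         " non-positive value(s) found", call. = FALSE)
  }
  bad_role <- !is.na(df$block_role) & !df$block_role %in% c("A", "B")
  if (any(bad_role)) {
    stop("block_role must be 'A', 'B' or NA", call. = FALSE)
  }
  key <- paste(df$participant_id, df$measure, df$domain, df$trial_index,
               sep = "\r")
  if (anyDuplicated(key)) {
    stop("(participant_id, measure, domain, trial_index) must be unique",
         call. = FALSE)
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read trial-level data from a long-format CSV
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema_map Optional named character vector mapping canonical
#'   column names to the names used in the file, e.g.
#'   `c(participant_id = "subject", latency_ms = "rt")`. Unmapped columns
#'   are looked up under their canonical names.
#' @return A [trial_table()]. Latency or accuracy entries that fail to
#'   parse as numbers become `NA` and a warning reports how many.
#' @export
read_trials <- function(path, schema_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty input: ", path, call. = FALSE)
  wanted <- stats::setNames(TRIAL_COLUMNS, TRIAL_COLUMNS)
  if (!is.null(schema_map)) wanted[names(schema_map)] <- schema_map
  missing_req <- REQUIRED_INPUT_COLUMNS[
    !wanted[REQUIRED_INPUT_COLUMNS] %in% names(raw)]
  if (length(missing_req) > 0L) {
    stop("input lacks required column(s): ",
         paste(sprintf("%s (looked for '%s')", missing_req,
                       wanted[missing_req]), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(participant_id = raw[[wanted["participant_id"]]],
                    measure = raw[[wanted["measure"]]],
                    domain = raw[[wanted["domain"]]],
                    block_label = raw[[wanted["block_label"]]],
                    stringsAsFactors = FALSE)
  num_field <- function(col) {
    if (!wanted[col] %in% names(raw)) return(NULL)
    x <- raw[[wanted[col]]]
    v <- suppressWarnings(as.numeric(x))
    is_blank <- is.na(x) | !nzchar(trimws(x)) | trimws(x) %in% c("NA", "NaN")
    n_bad <- sum(is.na(v) & !is_blank)
    if (n_bad > 0L) {
      warning(sprintf("%d unparseable value(s) in column '%s' set to NA",
                      n_bad, col), call. = FALSE)
    }
    v
  }
  out$trial_index <- num_field("trial_index")
  out$latency_ms <- num_field("latency_ms")
  acc <- num_field("accuracy")
  out$accuracy <- if (is.null(acc)) NA_real_ else acc
  resp <- num_field("response_value")
  out$response_value <- if (is.null(resp)) out$latency_ms else resp
  if (wanted["block_role"] %in% names(raw)) {
    br <- raw[[wanted["block_role"]]]
    br[!br %in% c("A", "B")] <- NA_character_
    out$block_role <- br
  }
  trial_table(out)
}

#' Write a trial table to CSV
#'
#' @param trials A [trial_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Assign score-defining condition roles to blocks
#'
#' Every measure's score contrasts two pools of trials (e.g. the IAT's
#' compatible vs incompatible critical blocks, an AMP's two prime types).
#' `role_map` states, per measure, which raw block labels feed pool A and
#' which feed pool B; labels in neither set are treated as practice and
#' dropped. The map is explicit rather than inferred from block order
#' because block numbering differs across task variants and
#' counterbalancing schemes.
#'
#' @param trials A [trial_table()].
#' @param role_map Named list, one entry per measure, each a
#'   `list(A = <labels>, B = <labels>)`.
#' @return A [trial_table()] with `block_role` filled in and non-critical
#'   trials removed.
#' @export
#' @examples
#' tt <- trial_table(data.frame(
#'   participant_id = "p1", measure = "IAT", domain = "race",
#'   block_label = as.character(c(3, 4, 6, 7, 1)), trial_index = 1:5,
#'   latency_ms = c(500, 600, 700, 800, 400)))
#' assign_condition_roles(tt, list(IAT = list(A = c("3", "4"),
#'                                            B = c("6", "7"))))
assign_condition_roles <- function(trials, role_map) {
  trials <- trial_table(trials)
  measures <- unique(trials$measure)
  for (m in measures) {
    entry <- role_map[[m]]
    if (is.null(entry) || (length(entry$A) + length(entry$B)) == 0L) {
      stop("role_map has no block labels for measure '", m, "'",
           call. = FALSE)
    }
    overlap <- intersect(entry$A, entry$B)
    if (length(overlap) > 0L) {
      stop("block label(s) mapped to both roles for measure '", m, "': ",
           paste(overlap, collapse = ", "), call. = FALSE)
    }
    rows <- trials$measure == m
    lab <- trials$block_label[rows]
    role <- rep(NA_character_, length(lab))
    role[lab %in% as.character(entry$A)] <- "A"
    role[lab %in% as.character(entry$B)] <- "B"
    trials$block_role[rows] <- role
  }
  out <- trials[!is.na(trials$block_role), , drop = FALSE]
  rownames(out) <- NULL
  trial_table(out)
}

#' Performance-based exclusion policy
#'
#' Defaults follow common IAT-family practice: retain trials with
#' latencies in \[300, 10000\] ms; drop a participant's whole
#' measure-by-domain unit when more than 10% of their latencies are under
#' 300 ms, when mean accuracy over non-missing trials falls below 0.80
#' (tasks with no correct answer, such as the AMP, record accuracy as
#' missing and are untouched by this rule), or when either role pool
#' retains fewer than `min_trials_per_role` trials.
#'
#' @param min_latency_ms,max_latency_ms Retained-trial latency window.
#' @param fast_trial_threshold_ms Latency under which a trial counts as
#'   anticipatory ("fast").
#' @param max_fast_trial_proportion Participant-level cap on the fast-trial
#'   proportion.
#' @param min_accuracy_proportion Participant-level accuracy floor.
#' @param min_trials_per_role Minimum retained trials per role pool.
#' @return An `exclusion_policy` object.
#' @export
exclusion_policy <- function(min_latency_ms = 300,
                             max_latency_ms = 10000,
                             fast_trial_threshold_ms = 300,
                             max_fast_trial_proportion = 0.10,
                             min_accuracy_proportion = 0.80,
                             min_trials_per_role = 2L) {
  stopifnot(min_latency_ms < max_latency_ms,
            max_fast_trial_proportion >= 0, max_fast_trial_proportion <= 1,
            min_accuracy_proportion >= 0, min_accuracy_proportion <= 1,
            min_trials_per_role >= 2)
  structure(list(min_latency_ms = min_latency_ms,
                 max_latency_ms = max_latency_ms,
                 fast_trial_threshold_ms = fast_trial_threshold_ms,
                 max_fast_trial_proportion = max_fast_trial_proportion,
                 min_accuracy_proportion = min_accuracy_proportion,
                 min_trials_per_role = as.integer(min_trials_per_role)),
            class = "exclusion_policy")
}

#' A policy that removes nothing (useful for validation runs)
#' @return An `exclusion_policy` with infinite bounds and zero thresholds.
#' @export
identity_exclusion_policy <- function() {
  p <- exclusion_policy()
  p$min_latency_ms <- -Inf
  p$max_latency_ms <- Inf
  p$fast_trial_threshold_ms <- -Inf
  p$max_fast_trial_proportion <- 1
  p$min_accuracy_proportion <- 0
  p$min_trials_per_role <- 2L
  p
}

#' Apply an exclusion policy
#'
#' Trial-level removal (the latency window) happens first; participant
#' units (participant x measure x domain) are then dropped wholesale by
#' the fast-trial rule (evaluated on the incoming trials, before window
#' trimming, so anticipatory responses are counted), the accuracy rule
#' (non-missing trials only), and the minimum-trials-per-role rule
#' (evaluated after window trimming). The report reconciles every count:
#' `n_trials_in` equals trials retained plus all removals.
#'
#' @param trials A role-assigned [trial_table()].
#' @param policy An [exclusion_policy()].
#' @return A list with `trials` (the retained table) and `report` (an
#'   `exclusion_report` list of counts by rule).
#' @export
apply_exclusions <- function(trials, policy = exclusion_policy()) {
  trials <- trial_table(trials)
  stopifnot(inherits(policy, "exclusion_policy"))
  if (any(is.na(trials$block_role))) {
    stop("block roles must be assigned before applying exclusions",
         call. = FALSE)
  }
  unit <- paste(trials$participant_id, trials$measure, trials$domain,
                sep = "\r")
  n_in <- nrow(trials)
  units_in <- unique(unit)

  # participant-level fast-trial rule, on incoming trials
  fast <- trials$latency_ms < policy$fast_trial_threshold_ms
  fast_prop <- tapply(fast, unit, mean)
  drop_fast <- names(fast_prop)[fast_prop > policy$max_fast_trial_proportion]

  # trial-level latency window
  in_window <- trials$latency_ms >= policy$min_latency_ms &
    trials$latency_ms <= policy$max_latency_ms
  n_window_removed <- sum(!in_window & !(unit %in% drop_fast))
  kept <- trials[in_window & !(unit %in% drop_fast), , drop = FALSE]
  kept_unit <- paste(kept$participant_id, kept$measure, kept$domain,
                     sep = "\r")

  # accuracy rule over non-missing accuracies of retained trials
  acc_mean <- tapply(kept$accuracy, kept_unit,
                     function(a) if (all(is.na(a))) NA_real_
                                 else mean(a, na.rm = TRUE))
  drop_acc <- names(acc_mean)[!is.na(acc_mean) &
                                acc_mean < policy$min_accuracy_proportion]
  # minimum trials per role
  nA <- tapply(kept$block_role == "A", kept_unit, sum)
  nB <- tapply(kept$block_role == "B", kept_unit, sum)
  drop_few <- names(nA)[nA < policy$min_trials_per_role |
                          nB < policy$min_trials_per_role]
  drop_few <- setdiff(drop_few, drop_acc)

  trials_fast <- sum(unit %in% drop_fast)
  trials_acc <- sum(kept_unit %in% drop_acc)
  trials_few <- sum(kept_unit %in% drop_few)
  out <- kept[!(kept_unit %in% c(drop_acc, drop_few)), , drop = FALSE]
  rownames(out) <- NULL

  report <- structure(list(
    n_trials_in = n_in,
    n_trials_retained = nrow(out),
    n_trials_removed_by_rule = c(
      fast_participant = trials_fast,
      latency_window = n_window_removed,
      low_accuracy_participant = trials_acc,
      too_few_trials_participant = trials_few),
    n_participants_in = length(units_in),
    n_participants_retained = length(unique(
      paste(out$participant_id, out$measure, out$domain, sep = "\r"))),
    n_participants_removed_by_rule = c(
      fast_trials = length(drop_fast),
      low_accuracy = length(drop_acc),
      too_few_trials = length(drop_few))),
    class = "exclusion_report")
  list(trials = trial_table(out), report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  cat(sprintf("  trials: %d in, %d retained\n",
              x$n_trials_in, x$n_trials_retained))
  for (r in names(x$n_trials_removed_by_rule)) {
    cat(sprintf("    removed by %s: %d\n", r,
                x$n_trials_removed_by_rule[[r]]))
  }
  cat(sprintf("  participant units: %d in, %d retained\n",
              x$n_participants_in, x$n_participants_retained))
  for (r in names(x$n_participants_removed_by_rule)) {
    cat(sprintf("    removed by %s: %d\n", r,
                x$n_participants_removed_by_rule[[r]]))
  }
  invisible(x)
}

#' Exclusion report as a tidy data frame
#' @param report An `exclusion_report`.
#' @return Data frame with columns `level`, `rule`, `count`.
#' @export
exclusion_report_df <- function(report) {
  stopifnot(inherits(report, "exclusion_report"))
  rbind(
    data.frame(level = "trial", rule = c("input", "retained",
                                         names(report$n_trials_removed_by_rule)),
               count = c(report$n_trials_in, report$n_trials_retained,
                         unname(report$n_trials_removed_by_rule))),
    data.frame(level = "participant_unit",
               rule = c("input", "retained",
                        names(report$n_participants_removed_by_rule)),
               count = c(report$n_participants_in,
                         report$n_participants_retained,
                         unname(report$n_participants_removed_by_rule))))
}
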