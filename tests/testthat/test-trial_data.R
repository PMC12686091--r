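test_that("trial CSVs round-trip exactly through write and read", {
  tt <- make_trials(c(400, 500, 600), c(500, 700))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(tt, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(tt))
})

test_that("read_trials reports schema problems and respects column maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject = "p1", measure = "IAT", domain = "race",
                   block_label = "A", trial_index = 1, rt = 500)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_trials(path), "latency_ms")
  mapped <- read_trials(path, schema_map = c(participant_id = "subject",
                                             latency_ms = "rt"))
  expect_equal(mapped$latency_ms, 500)
  # unparseable latency becomes NA with a warning
  df$rt <- "oops"
  df$latency <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_warning(
    out <- read_trials(path, schema_map = c(participant_id = "subject",
                                            latency_ms = "rt")),
    "unparseable")
  expect_true(is.na(out$latency_ms))
  # empty file
  write.csv(df[0, ], path, row.names = FALSE)
  expect_error(read_trials(path, schema_map = c(participant_id = "subject",
                                                latency_ms = "rt")),
               "empty")
})

test_that("trial table invariants are enforced", {
  base <- data.frame(participant_id = "p1", measure = "IAT",
                     domain = "race", block_label = "A", trial_index = 1,
                     latency_ms = 500)
  expect_error(trial_table(transform(base, latency_ms = -1)), "positive")
  expect_error(trial_table(base[, -6]), "latency_ms")
  dup <- rbind(base, base)
  expect_error(trial_table(dup), "unique")
})

test_that("condition roles follow the explicit per-measure map", {
  tt <- trial_table(data.frame(
    participant_id = "p1", measure = "IAT", domain = "race",
    block_label = as.character(c(1, 2, 3, 4, 5, 6, 7)),
    trial_index = 1:7, latency_ms = 400 + 50 * (1:7)))
  out <- assign_condition_roles(
    tt, list(IAT = list(A = c("3", "4"), B = c("6", "7"))))
  expect_equal(nrow(out), 4L)  # practice blocks 1, 2, 5 dropped
  expect_setequal(out$block_role[out$block_label %in% c("3", "4")], "A")
  expect_setequal(out$block_role[out$block_label %in% c("6", "7")], "B")
  expect_error(
    assign_condition_roles(tt, list(IAT = list(A = "3", B = "3"))),
    "both roles")
  expect_error(
    assign_condition_roles(tt, list(IAT = list(A = character(),
                                               B = character()))),
    "no block labels")
  expect_error(assign_condition_roles(tt, list(AMP = list(A = "1", B = "2"))),
               "IAT")
})

test_that("exclusion rules remove what the policy says and nothing else", {
  # slow trial beyond the window is removed
  tt <- make_trials(c(500, 600, 11000), c(550, 650))
  res <- apply_exclusions(tt, exclusion_policy())
  expect_equal(nrow(res$trials), 4L)
  expect_equal(res$report$n_trials_removed_by_rule[["latency_window"]], 1L)
  # participant with > 10% anticipatory trials is dropped wholesale
  fast <- make_trials(c(100, 100, 600, 700, 800, 900),
                      c(600, 700, 800, 900, 1000, 1100, 1200, 1300),
                      participant_id = "p2")
  both <- trial_table(rbind(as.data.frame(tt), as.data.frame(fast)))
  res2 <- apply_exclusions(both, exclusion_policy())
  expect_false("p2" %in% res2$trials$participant_id)
  expect_equal(res2$report$n_participants_removed_by_rule[["fast_trials"]], 1L)
  # low-accuracy participant dropped; AMP-style all-NA accuracy is exempt
  lowacc <- make_trials(600 + 1:5, 700 + 1:5, participant_id = "p3",
                        accuracy = c(rep(0, 6), rep(1, 4)))
  amp <- make_trials(c(0, 1, 0, 1), c(1, 1, 0, 1), participant_id = "p4",
                     measure = "AMP", accuracy = NA_real_)
  amp$latency_ms <- 500 + seq_len(8)
  res3 <- apply_exclusions(trial_table(rbind(as.data.frame(lowacc),
                                             as.data.frame(amp))),
                           exclusion_policy())
  expect_false("p3" %in% res3$trials$participant_id)
  expect_true("p4" %in% res3$trials$participant_id)
})

test_that("exclusion accounting is conservative, idempotent and value-preserving", {
  set.seed(11)
  sim <- simulate_study(n_participants = 5, domains = "race", seed = 5)
  res <- apply_exclusions(sim$trials, exclusion_policy())
  rep <- res$report
  expect_equal(rep$n_trials_in,
               rep$n_trials_retained + sum(rep$n_trials_removed_by_rule))
  again <- apply_exclusions(res$trials, exclusion_policy())
  expect_equal(as.data.frame(again$trials), as.data.frame(res$trials))
  # retained rows are untouched copies of input rows
  key <- function(d) paste(d$participant_id, d$measure, d$domain,
                           d$trial_index)
  orig <- as.data.frame(sim$trials)
  kept <- as.data.frame(res$trials)
  expect_equal(kept, orig[match(key(kept), key(orig)), ],
               ignore_attr = TRUE)
  # the identity policy passes everything through
  ident <- apply_exclusions(sim$trials, identity_exclusion_policy())
  expect_equal(as.data.frame(ident$trials), as.data.frame(sim$trials))
  expect_equal(ident$report$n_trials_retained, ident$report$n_trials_in)
})
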