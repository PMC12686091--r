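#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# Six implicit measures x three attitude domains x 50 participants per
# cell, with per-participant condition shifts drawn from a population
# distribution so that every participant has a known true probabilistic
# index. Writes the trial table, the ground truth, and the exclusion
# report under results/.

library(implicitprecision)

seed <- 20260929
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(n_participants = 50, seed = seed)
cat(sprintf("simulated %d trials for %d participant units\n",
            nrow(sim$trials),
            nrow(unique(sim$trials[c("participant_id", "measure",
                                     "domain")]))))

excl <- apply_exclusions(sim$trials, exclusion_policy())
print(excl$report)

write_trials(excl$trials, file.path(out_dir, "trials.csv"))
write.csv(sim$ground_truth, file.path(out_dir, "ground_truth.csv"),
          row.names = FALSE)
write.csv(exclusion_report_df(excl$report),
          file.path(out_dir, "exclusions.csv"), row.names = FALSE)
cat("wrote trials.csv, ground_truth.csv, exclusions.csv to", out_dir, "\n")
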