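#!/usr/bin/env Rscript
# Step 3: precision planning on the D-score scale.
#
# Three questions a practitioner can answer without new data:
#   (a) how narrow must an individual's CI be to separate adjacent
#       Project Implicit feedback categories?
#   (b) what does a published SEm imply for an individual's interval?
#   (c) what error rates follow from a given per-score measurement SD
#       when comparing two people?
# Writes planner tables under results/.

library(implicitprecision)

dir.create("results", showWarnings = FALSE)

# (a) required widths between adjacent cut-offs
rw <- required_widths(cutoff_scheme())
print(rw)
write.csv(rw, "results/planner_required_widths.csv", row.names = FALSE)

# published reference intervals at the cut-offs: the narrowest observed
# interval is wider than every requirement above
ref <- read.csv(system.file("extdata", "iat_dscore_cutoff_reference.csv",
                            package = "implicitprecision"))
ref$width <- ref$upper - ref$lower
cat(sprintf("narrowest published cut-off interval: %.2f (%s)\n",
            min(ref$width), ref$label[which.min(ref$width)]))

# (b) the SEm worked example: a D score of .30 under SEm back-solved
# from its published interval
sem_value <- (1.11 - 0.30) / 1.96
ci <- sem_interval(0.30, sem_value)
cat(sprintf("SEm example: D = 0.30, SEm = %.3f -> CI (%.2f, %.2f)\n",
            sem_value, ci[["lower"]], ci[["upper"]]))

# (c) error rates when comparing two individuals, across plausible
# measurement SDs and true differences
grid <- expand.grid(true_difference = c(0, 0.15, 0.3, 0.5),
                    measurement_sd = c(0.1, 0.2, 0.3))
rates <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  r <- simulate_error_rates(grid$true_difference[i],
                            grid$measurement_sd[i],
                            n_sims = 1e5, seed = 100 + i)
  data.frame(grid[i, ], fpr = r$false_positive_rate,
             fnr = r$false_negative_rate)
}))
print(rates, row.names = FALSE)
write.csv(rates, "results/planner_error_rates.csv", row.names = FALSE)
cat("wrote planner tables to results/\n")
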