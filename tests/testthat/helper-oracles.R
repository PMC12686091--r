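# Independent oracles the implementation is checked against.

# brute-force probabilistic index: enumerate all pairs
pi_brute <- function(a, b) {
  cnt <- 0
  ties <- 0
  for (x in a) {
    cnt <- cnt + sum(b > x)
    ties <- ties + sum(b == x)
  }
  (cnt + 0.5 * ties) / (length(a) * length(b))
}

# hand step-down Holm adjustment
holm_hand <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running <- max(running, val)
    adj[ord[i]] <- running
  }
  adj
}

# type-7 empirical quantile, written out from the interpolation rule
quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# minimal role-assigned trial table for one or more participants
make_trials <- function(values_A, values_B, participant_id = "p1",
                        measure = "IAT", domain = "race",
                        accuracy = 1) {
  n <- length(values_A) + length(values_B)
  vals <- c(values_A, values_B)
  lat <- if (all(vals > 0)) vals else 500 + seq_len(n)
  trial_table(data.frame(
    participant_id = participant_id, measure = measure, domain = domain,
    block_label = c(rep("A", length(values_A)),
                    rep("B", length(values_B))),
    block_role = c(rep("A", length(values_A)),
                   rep("B", length(values_B))),
    trial_index = seq_len(n),
    latency_ms = lat,
    accuracy = accuracy,
    response_value = vals,
    stringsAsFactors = FALSE))
}

# replicate_set with fully controlled replicates, for discriminability
# fixtures
fake_replicates <- function(estimate, replicates) {
  structure(list(replicates = replicates, estimate = estimate,
                 n_redraws = 0L, n_dropped = 0L),
            class = "replicate_set")
}
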