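# Small in-code fixtures shared across test files.

# A tiny balanced CRT with all four observed (D, S) groups present.
make_toy_data <- function(n_clusters = 8, size = 6, seed = 11,
                          config = sim_config(m = size,
                                              n_clusters = n_clusters)) {
  simulate_crt(config, seed = seed)$data
}

# Hand-built dataset: explicit rows, no randomness.
make_manual_data <- function(df) {
  crt_data(df, covariates = setdiff(names(df), c("cluster", "D", "S", "Y")))
}

# Default benchmark membership coefficients used throughout the tests.
bench_beta <- c(-1, 0.3, 0.5)
bench_gamma <- c(-0.8, 0.6, 0.4)

# Membership labels that satisfy the monotonicity table for a dataset.
admissible_labels <- function(data, seed = 1) {
  set.seed(seed)
  g <- character(data$n)
  g[data$D == 1 & data$S == 0] <- "00"
  g[data$D == 0 & data$S == 1] <- "11"
  ts <- data$D == 1 & data$S == 1
  g[ts] <- sample(c("10", "11"), sum(ts), replace = TRUE)
  cd <- data$D == 0 & data$S == 0
  g[cd] <- sample(c("00", "10"), sum(cd), replace = TRUE)
  g
}

# Check the monotonicity constraints of a membership vector.
memberships_admissible <- function(data, g) {
  all(g[data$D == 1 & data$S == 0] == "00") &&
    all(g[data$D == 0 & data$S == 1] == "11") &&
    all(g[data$D == 1 & data$S == 1] %in% c("10", "11")) &&
    all(g[data$D == 0 & data$S == 0] %in% c("00", "10"))
}
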