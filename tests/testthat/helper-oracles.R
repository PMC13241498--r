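# Independent brute-force oracles used across tests.

# O(n) PLV straight from the definition at one timepoint
plv_brute <- function(phases) {
  phases <- phases[!is.na(phases)]
  Mod(mean(exp(1i * phases)))
}

# O(n^2) pairwise phase consistency straight from the pairwise sum
ppc_brute <- function(phases) {
  phases <- phases[!is.na(phases)]
  n <- length(phases)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in seq_len(n - 1)) {
    s <- s + sum(cos(phases[i] - phases[(i + 1):n]))
  }
  2 * s / (n * (n - 1))
}

# build an epoch_set directly from a phase matrix (events x time)
epochs_from_matrix <- function(m, fs = 100) {
  structure(
    list(data = m,
         time_s = (seq_len(ncol(m)) - 1) / fs,
         event_times = seq_len(nrow(m)),
         dropped = 0L, kind = "phase"),
    class = "epoch_set"
  )
}

# closed-form paired t statistic
paired_t_brute <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# tiny deterministic study used by several preprocessing tests
small_study_config <- function(seed = 42, ...) {
  sim_config(n_participants = 2, n_trials = 2, seed = seed, ...)
}
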