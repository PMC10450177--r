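# Independent oracles kept deliberately naive: scalar loops over the printed
# formulas, no shared code with the package internals.

# depletion score for one PAM, as a scalar evaluation of the printed formula
oracle_depletion_score <- function(ctrl_counts, trg_counts, i,
                                   pseudocount = 0, proportion_ratio = FALSE) {
  total_control <- 0
  total_targeting <- 0
  for (j in seq_along(ctrl_counts)) {
    total_control <- total_control + ctrl_counts[j]
    total_targeting <- total_targeting + trg_counts[j]
  }
  depth <- if (proportion_ratio) total_targeting / total_control
           else total_control / total_targeting
  depth * (ctrl_counts[i] + pseudocount) / (trg_counts[i] + pseudocount)
}

# expected marginal percent depletion of base b at position p under a
# multiplicative survival truth, by brute-force summation over all 1024 PAMs
oracle_marginal_depletion <- function(effects, p, b) {
  bases <- c("A", "C", "G", "T")
  total_w <- 0
  sel_w <- 0
  n_sel <- 0
  for (i1 in bases) for (i2 in bases) for (i3 in bases)
    for (i4 in bases) for (i5 in bases) {
      pam <- c(i1, i2, i3, i4, i5)
      w <- 1
      for (pos in 1:5) w <- w * effects[pos, pam[pos]]
      total_w <- total_w + w
      if (pam[p] == b) {
        sel_w <- sel_w + w
        n_sel <- n_sel + 1
      }
    }
  trg_freq <- sel_w / total_w        # marginal freq of b at p, targeting arm
  ctrl_freq <- n_sel / 1024          # uniform control
  100 * (1 - trg_freq / ctrl_freq)
}

# quick small simulated run shared across pipeline tests
small_run <- function(n_reads = 400, seed = 42, error_rate = 0, ...) {
  truth <- library_truth(n_reads_per_sample = n_reads, seed = seed,
                         error_rate = error_rate, ...)
  simulate_pam_library(truth, gzip = FALSE)
}
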