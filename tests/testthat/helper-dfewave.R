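# Shared fixtures and small oracles used across test files.

# the standard simulation conditions used throughout: N = 1e4, L = 100,
# genomic mutation rate mu*L = 0.05, f_in = 0.2, half-normal intrinsic DFE
# with mean s_av = 0.05
std_params <- function(generations = 10, n_replicates = 20, seed = 101) {
  sim_params(N = 1e4, L = 100, mu = 5e-4, f_in = 0.2,
             generations = generations, n_replicates = n_replicates,
             seed = seed)
}

std_profile <- function(L = 100, seed = 3) {
  sample_selection_profile(L, intrinsic_dfe(0.05), seed = seed)
}

# CDF of the half-normal parameterized by its mean (for KS tests)
phalfnorm_mean <- function(q, mean) {
  sigma <- mean * sqrt(pi / 2)
  2 * stats::pnorm(q / sigma) - 1
}

# build a timepoint_alignment whose minority frequencies are exact:
# n sequences per timepoint, each site carrying round(n * f) minority
# residues ("G"), consensus "A"
alignment_from_frequencies <- function(freq_list, n = 1000) {
  mats <- lapply(freq_list, function(f) {
    m <- matrix("A", nrow = n, ncol = length(f))
    for (j in seq_along(f)) {
      k <- round(n * f[j])
      if (k > 0) m[seq_len(k), j] <- "G"
    }
    m
  })
  timepoint_alignment(mats, times = seq_along(freq_list) * 10)
}

# a tiny deterministic ensemble_freq built from a closed-form frequency
# surface f(s, t); used by the stats tests
synthetic_ensemble <- function(s, times, f_fun, n_replicates = 1) {
  mean_f <- t(vapply(times, function(t) f_fun(s, t), numeric(length(s))))
  structure(list(times = as.integer(times), s_values = s, mean_f = mean_f,
                 n_replicates = n_replicates),
            class = "ensemble_freq")
}
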