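# Shared fixtures, generated in code at test time.

# Small simulated data set + SNV table + split, reused across tests.
tiny_sim <- function(n_per_stage = 5, seed = 11, ...) {
  simulate_samples(sim_config(n_per_stage = n_per_stage, seed = seed, ...))
}

# A deliberately simple spectra tibble on an arbitrary grid.
toy_spectra <- function(m, wl) {
  as_spectra_tibble(m, wl, sprintf("T%02d", seq_len(nrow(m))))
}

# Spectrum that is a fixed point of SNV (mean 0, population sd 1) with
# zeros at the given band indices.
snv_fixed_point_with_zeros <- function(n_bands, zero_idx) {
  x <- numeric(n_bands)
  free <- setdiff(seq_len(n_bands), zero_idx)
  stopifnot(length(free) >= 2)
  half <- length(free) %/% 2
  x[free[seq_len(half)]] <- 1
  x[free[(half + 1):length(free)]] <- -half / (length(free) - half)
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}
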