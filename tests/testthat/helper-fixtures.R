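# Shared fixture builders. Everything is generated in code; no stored data.

# Small random community matrix (samples x taxa) with no all-zero sample.
random_counts <- function(n_samples, n_taxa, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("t%03d", seq_len(n_taxa))))
  empty <- rowSums(m) == 0
  m[empty, 1] <- 1L
  m
}

# Wrap a counts matrix in a community_table with a single group.
as_ct <- function(counts, group = "G1") {
  community_table(counts, data.frame(sample_id = rownames(counts),
                                     group = group))
}

# A short synthetic forcing series (no noise unless asked).
quick_forcing <- function(n_days = 200, seed = 1, noise = FALSE) {
  nd <- if (noise) list(temperature = 0.8, moisture = 0.02, litter = 4e-4)
        else list(temperature = 0, moisture = 0, litter = 0)
  gen_forcing(forcing_design(n_days = n_days, noise_sd = nd, seed = seed))
}

# Random valid MEND parameter draw over the default calibration bounds.
random_params <- function(seed) {
  set.seed(seed)
  b <- default_param_bounds()
  draw <- stats::setNames(stats::runif(nrow(b), b[, 1], b[, 2]), rownames(b))
  mend_params(as.list(draw))
}
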