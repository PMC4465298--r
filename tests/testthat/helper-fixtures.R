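# Shared fixture builders; everything is generated in code under fixed seeds.

toy_counts <- function(n_transcripts = 12, n_samples = 8, seed = 100,
                       mu = 30, size = 4) {
  set.seed(seed)
  matrix(rnbinom(n_transcripts * n_samples, mu = mu, size = size),
         n_transcripts, n_samples,
         dimnames = list(paste0("t", seq_len(n_transcripts)),
                         paste0("s", seq_len(n_samples))))
}

toy_design <- function(n_samples = 8) {
  half <- n_samples / 2
  de_design(paste0("s", seq_len(half)), paste0("s", half + seq_len(half)))
}

# Independent brute-force GP pmf straight from the formula (no log tricks);
# valid for the small x used in tests.
ref_gp_pmf <- function(x, theta, lambda) {
  v <- theta * (theta + x * lambda)^(x - 1) * exp(-theta - x * lambda) /
    factorial(x)
  v[theta + x * lambda <= 0] <- 0
  v
}
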