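# Shared fixture builders. Everything is generated in code; no files
# ship with the tests.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_sequence <- function(n) paste(sample(aa20, n, TRUE), collapse = "")

# A random row-normalized 96 x 3 probability matrix.
random_probs <- function(n = 96L) {
  p <- matrix(runif(n * 3L), n, 3L)
  p / rowSums(p)
}

# Probability matrix with the S channel pinned to `s` (a length-96
# vector); the remainder is split evenly between T and N.
probs_with_s <- function(s) {
  cbind(S = s, T = (1 - s) / 2, N = (1 - s) / 2)
}

# Tiny architecture for fast training/gradient tests.
tiny_config <- function(...) {
  network_config(m = 4L, n = 4L, depth = 2L, kernel_size = 3L,
                 convs_per_level = 1L, ...)
}

# Small labeled synthetic sample set.
tiny_samples <- function(n_sp = 8L, n_tm = 6L, n_other = 6L, seed = 5L) {
  encode_records(generate_dataset(
    synthetic_spec(n_sp, n_tm, n_other, seed = seed)))
}

# Independent per-sample cross entropy used as an oracle against the
# package's loss.
reference_loss <- function(y, h) {
  -sum(y * log(pmin(pmax(h, 1e-7), 1)))
}
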