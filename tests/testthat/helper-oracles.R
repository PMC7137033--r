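# Shared helpers: independent oracles and small data builders.

# Random valid site windows (uniform composition, center C).
random_windows <- function(n, L = 41L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(sample(c("A", "C", "G", "U"), n * L, replace = TRUE), n, L)
    m[, (L + 1L) %/% 2L] <- "C"
    apply(m, 1, paste0, collapse = "")
  })
}

# Independent k-mer frequency oracle via Biostrings.
oracle_kmer_spectrum <- function(seq, k) {
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::RNAString(seq), k)
  counts / (nchar(seq) - k + 1)
}

# Textbook one-way ANOVA F via stats::lm / stats::anova.
oracle_anova_f <- function(x, g) {
  stats::anova(stats::lm(x ~ g))$`F value`[1]
}

# Two-Gaussian toy classification problem.
toy_gaussians <- function(n_per = 30L, d = 4L, delta = 3, seed = 1L) {
  withr::with_seed(seed, {
    X <- rbind(matrix(stats::rnorm(n_per * d), n_per, d),
               matrix(stats::rnorm(n_per * d, mean = delta), n_per, d))
  })
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, labels = rep(c("negative", "positive"), each = n_per))
}
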