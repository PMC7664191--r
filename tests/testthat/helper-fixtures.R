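# Shared fixtures: small PWMs and sequences built in code.

# near-indicator PWM spelling a consensus word (dominant prob d)
indicator_pwm <- function(word, id = "ind", d = 0.997) {
  bases <- strsplit(word, "")[[1]]
  cons <- match(bases, c("A", "C", "G", "T"))
  L <- length(cons)
  probs <- matrix((1 - d) / 3, nrow = 4, ncol = L)
  probs[cbind(cons, seq_len(L))] <- d
  new_pwm(id, probs)
}

# random Dirichlet-ish PWM
random_pwm <- function(L, id = "rand", shape = 1) {
  m <- matrix(stats::rgamma(4 * L, shape), nrow = 4)
  new_pwm(id, sweep(m, 2, colSums(m), "/"))
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
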