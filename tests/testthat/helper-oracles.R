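# Independent brute-force oracles, kept free of the code paths they check.

# All 4^L words as an integer matrix (rows = words)
all_words <- function(L) {
  as.matrix(expand.grid(rep(list(1:4), L)))
}

# Exact tail P(score >= s) by enumerating every word and weighting by the
# background; scores use the package's scoring matrix (the p-value is
# defined with respect to that score function), but the tail itself is
# computed by direct summation, independently of the DP convolution.
enum_pvalue <- function(pwm, s, step = 1e-4) {
  lo <- pwm_logodds(pwm, step = step)
  L <- ncol(lo)
  w <- all_words(L)
  sc <- numeric(nrow(w))
  for (j in seq_len(L)) sc <- sc + lo[w[, j], j]
  wt <- apply(matrix(pwm$background[w], nrow(w)), 1, prod)
  vapply(s, function(si) sum(wt[sc >= si - 1e-9]), numeric(1))
}

# Scores of every possible word under the package's scoring matrix; p-value
# queries are made at these achievable scores, as the scanner produces them
word_scores <- function(pwm, step = 1e-4) {
  lo <- pwm_logodds(pwm, step = step)
  L <- ncol(lo)
  w <- all_words(L)
  sc <- numeric(nrow(w))
  for (j in seq_len(L)) sc <- sc + lo[w[, j], j]
  unname(sort(sc))
}

# Hypergeometric upper tail by explicit summation of the pmf
enum_hyper_ge <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  x <- max(k, 0):min(K, n)
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# Binomial upper tail by explicit summation
enum_binom_ge <- function(k, n, p) {
  if (k > n) return(0)
  x <- max(k, 0):n
  sum(choose(n, x) * p^x * (1 - p)^(n - x))
}
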