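# Fixtures built in code; no data files.

# A universe of per-gene sign pairs whose concordance indicator is
# Bernoulli(rate): mouse sign a fair coin, human sign matching with the
# given probability. Returns the logical concordance flags.
make_concordance_universe <- function(n, rate, seed) {
  set.seed(seed)
  mouse <- sample(c(-1L, 1L), n, replace = TRUE)
  agree <- rbinom(n, 1L, rate) == 1L
  human <- ifelse(agree, mouse, -mouse)
  setNames(mouse == human, sprintf("g%05d", seq_len(n)))
}

# Small deterministic counts matrix with dimnames.
make_counts <- function(n_genes, n_samples, seed = 1, mu_range = c(20, 2000)) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples,
                      mu = exp(runif(n_genes * n_samples,
                                     log(mu_range[1]), log(mu_range[2]))),
                      size = 20),
              n_genes, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  m
}

# Brute-force BH step-up: q(i) = min over j >= i of m * p_(j) / j.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of a
# universe of size N and count those overlapping the K-set in >= k genes.
hyper_brute_force <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  mean(colSums(sets <= K) >= k)
}
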