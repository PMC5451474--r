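# Independent oracles used across the suite.  All are deliberately naive
# (direct summation, brute-force search, sliding windows) and share no code
# with the implementation paths they check.

# Conditional point mass by direct factorial evaluation (log factorials so
# the long upper-tail summation does not overflow)
oracle_pointmass <- function(x, y, N1, N2) {
  r <- N2 / N1
  exp(y * log(r) + lfactorial(x + y) - lfactorial(x) - lfactorial(y) -
        (x + y + 1) * log(1 + r))
}

# Tails and two-sided p by direct summation of the conditional pmf
oracle_tails <- function(x, y, N1, N2, kmax = 2000) {
  ks <- 0:kmax
  pm <- oracle_pointmass(x, ks, N1, N2)
  C <- sum(pm[ks <= y])
  D <- sum(pm[ks >= y])
  list(C = C, D = D)
}

oracle_pvalue <- function(x, y, N1, N2) {
  t <- oracle_tails(x, y, N1, N2)
  min(1, 2 * min(t$C, t$D))
}

# Literal rank-based FDR, element by element
oracle_fdr_literal <- function(p) {
  m <- length(p)
  vapply(p, function(pi) min(1, pi * m / sum(p <= pi)), numeric(1))
}

# Monotone step-up: each element takes the smallest literal value among
# elements with p at least as large
oracle_fdr_monotone <- function(p) {
  lit <- oracle_fdr_literal(p)
  vapply(p, function(pi) min(lit[p >= pi]), numeric(1))
}

# Sliding-window seed-site scan on the DNA sense strand
oracle_scan <- function(motif, utr) {
  L <- nchar(utr)
  w <- nchar(motif)
  starts <- integer(0)
  for (i in seq_len(L - w + 1))
    if (substr(utr, i, i + w - 1) == motif) starts <- c(starts, i)
  starts
}

# Hypergeometric upper tail by direct summation of choose() terms
oracle_hyper <- function(overlap, term, universe, selection) {
  ks <- overlap:min(term, selection)
  sum(choose(term, ks) * choose(universe - term, selection - ks)) /
    choose(universe, selection)
}

# Binomial upper tail by direct summation
oracle_binom_tail <- function(obs, n, prob) {
  ks <- obs:n
  sum(choose(n, ks) * prob^ks * (1 - prob)^(n - ks))
}

random_dna <- function(n, len = 500) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# Small count matrix used by several tests
toy_counts <- function(seed = 42, n = 50) {
  cfg <- sim_config(n_mirnas = n, n_genes = 10, seed = seed)
  gen_count_libraries(cfg)$counts
}
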