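# Shared fixtures and independent oracles used across test files.

# Adjusted Rand index, computed directly from the contingency-table
# formula; independent of any clustering code in the package.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(n)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Brute-force colocalization posteriors by explicit enumeration of every
# single-causal-variant configuration, in plain (non-log) arithmetic.
# Only safe for small |z|; that is the point of the oracle.
coloc_enumerate <- function(bf1, bf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  m <- length(bf1)
  l0 <- 1
  l1 <- sum(p1 * bf1)
  l2 <- sum(p2 * bf2)
  l3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) l3 <- l3 + p1 * p2 * bf1[i] * bf2[j]
  }
  l4 <- sum(p12 * bf1 * bf2)
  tot <- l0 + l1 + l2 + l3 + l4
  c(PP0 = l0, PP1 = l1, PP2 = l2, PP3 = l3, PP4 = l4) / tot
}

# Small deterministic genotype panel for regression-level tests.
toy_genotypes <- function(n_individuals = 50, n_variants = 30, seed = 11,
                          ld_rho = 0, pos_step = 1000) {
  simulate_genotypes(n_individuals, n_variants, maf_range = c(0.2, 0.5),
                     ld_block_size = 10, ld_rho = ld_rho, seed = seed,
                     pos_step = pos_step)
}

# Binary matrix with k planted blocks of identical rows.
planted_block_matrix <- function(n_rows = 400, n_cols = 40, k = 4,
                                 seed = 5) {
  withr::with_seed(seed, {
    proto <- matrix(rbinom(k * n_cols, 1, 0.5), k, n_cols)
    # ensure prototypes are distinct and non-empty
    for (i in seq_len(k)) proto[i, ((i - 1) * floor(n_cols / k)) + 1] <- 1
    labels <- rep(seq_len(k), length.out = n_rows)
    mat <- proto[labels, , drop = FALSE]
    rownames(mat) <- sprintf("are%04d", seq_len(n_rows))
    list(mat = mat, labels = labels)
  })
}
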