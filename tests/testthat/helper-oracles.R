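# Independent oracles used to cross-check the vectorized implementations.
# These deliberately use naive enumeration, not the package's kernels.

# Mean pairwise difference per site within a haplotype matrix (rows = sites,
# cols = chromosomes), by explicit O(n^2) pair enumeration.
oracle_pi_within <- function(H, callable_bp) {
  n <- ncol(H)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + sum(H[, i] != H[, j])
    }
  }
  tot / choose(n, 2) / callable_bp
}

# Mean cross-population pairwise difference per site by O(nA * nB)
# enumeration.
oracle_pi_between <- function(HA, HB, callable_bp) {
  tot <- 0
  for (i in seq_len(ncol(HA))) {
    for (j in seq_len(ncol(HB))) {
      tot <- tot + sum(HA[, i] != HB[, j])
    }
  }
  tot / (ncol(HA) * ncol(HB)) / callable_bp
}

# Tajima's D assembled constant-by-constant from the 1989 definitions,
# written independently of the package's formula.
oracle_tajimas_d <- function(H) {
  n <- ncol(H)
  freqs <- rowSums(H)
  seg <- freqs > 0 & freqs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k_hat <- 0
  npairs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k_hat <- k_hat + sum(H[, i] != H[, j])
      npairs <- npairs + 1
    }
  }
  k_hat <- k_hat / npairs
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n^2 + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Hand-coded Benjamini-Hochberg step-up (no p.adjust).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(N, n) draws from a population with K successes.
oracle_hyper_tail <- function(k, K, N, n) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  mean(colSums(matrix(pop[draws], nrow = n)) >= k)
}

# Random haplotype matrix and the corresponding site-count table.
random_sites <- function(n_sites, n_a, n_b, contig = "chr1",
                         span = 1000) {
  pos <- sort(sample(0:(span - 1), n_sites))
  HA <- matrix(rbinom(n_sites * n_a, 1, runif(1, 0.1, 0.9)), n_sites, n_a)
  HB <- matrix(rbinom(n_sites * n_b, 1, runif(1, 0.1, 0.9)), n_sites, n_b)
  list(
    sites = tibble::tibble(
      contig = contig, pos = pos,
      n_popA = rowSums(HA), n_popB = rowSums(HB)
    ),
    HA = HA, HB = HB
  )
}

# Minimal VCF writer for hand-constructed genotype layouts.
write_toy_vcf <- function(path, rows,
                          samples = c("dog1", "dog2", "boxer", "wolf1",
                                      "wolf2", "wolf3", "jackal")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows
  ), path)
  path
}

toy_spec <- function() sweepfdr::default_pop_spec()
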