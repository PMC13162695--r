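# Independent brute-force oracles, deliberately naive: per-site loops and
# exhaustive pair enumeration, kept free of any package internals.

# Patterson's D by exhaustive per-haplotype ABBA/BABA pattern counting over
# all haplotype quadruples; outgroup fixes the ancestral allele per site.
oracle_dstat_counts <- function(g1, g2, g3, go) {
  abba <- 0
  baba <- 0
  for (s in seq_len(ncol(g1))) {
    og <- go[, s]
    if (length(unique(og)) != 1) next
    anc <- og[1]
    for (i in seq_len(nrow(g1))) for (j in seq_len(nrow(g2)))
      for (k in seq_len(nrow(g3))) {
        a <- g1[i, s] != anc
        b <- g2[j, s] != anc
        c <- g3[k, s] != anc
        if (!a && b && c) abba <- abba + 1
        if (a && !b && c) baba <- baba + 1
      }
  }
  n <- nrow(g1) * nrow(g2) * nrow(g3)
  list(abba = abba / n, baba = baba / n)
}

# Nucleotide diversity by O(n^2) pairwise difference counting.
oracle_pi <- function(g, length_bp) {
  n <- nrow(g)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(g[i, ] != g[j, ])
  tot / choose(n, 2) / length_bp
}

# Weir & Cockerham (1984) per-site theta components, transcribed
# independently: genotypes as two-row pairs per individual.
oracle_wc_fst <- function(gA, gB) {
  per <- function(g) {
    n <- nrow(g) / 2
    geno <- g[seq(1, nrow(g), 2), , drop = FALSE] +
      g[seq(2, nrow(g), 2), , drop = FALSE]
    list(n = n, p = colMeans(geno) / 2, h = colMeans(geno == 1))
  }
  A <- per(gA)
  B <- per(gB)
  r <- 2
  S <- ncol(gA)
  a <- b <- cc <- numeric(S)
  for (s in seq_len(S)) {
    nbar <- (A$n + B$n) / 2
    nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
    pbar <- (A$n * A$p[s] + B$n * B$p[s]) / (r * nbar)
    s2 <- (A$n * (A$p[s] - pbar)^2 + B$n * (B$p[s] - pbar)^2) /
      ((r - 1) * nbar)
    hbar <- (A$n * A$h[s] + B$n * B$h[s]) / (r * nbar)
    a[s] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b[s] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[s] <- hbar / 2
  }
  sum(a) / sum(a + b + cc)
}

# EHH by exhaustive haplotype-pair comparison over the extended window
# (EHH at the core itself is 1 by definition).
oracle_ehh <- function(g, core, x) {
  n <- nrow(g)
  if (x == core) return(1)
  idx <- if (x > core) (core + 1):x else x:(core - 1)
  same <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(g[i, idx] == g[j, idx])) same <- same + 1
  }
  same / choose(n, 2)
}

# Single-population SFS projection by exhaustive enumeration of all
# subsamples of size m out of n haplotypes.
oracle_project_1pop <- function(sfs_counts, m) {
  n <- length(sfs_counts) - 1
  out <- numeric(m + 1)
  for (d in 0:n) {
    if (sfs_counts[d + 1] == 0) next
    combos <- utils::combn(n, m)
    picked <- numeric(m + 1)
    for (cmb in seq_len(ncol(combos))) {
      hap <- c(rep(1, d), rep(0, n - d))[combos[, cmb]]
      picked[sum(hap) + 1] <- picked[sum(hap) + 1] + 1
    }
    out <- out + sfs_counts[d + 1] * picked / ncol(combos)
  }
  out
}

# A small deterministic genotype container for toy tests.
toy_geno <- function(G, pops_per_sample, pos = NULL, chrom = NULL, ...) {
  ns <- length(pops_per_sample)
  S <- ncol(G)
  geno_matrix(G, sample_ids = paste0("s", seq_len(ns)),
              pops = pops_per_sample,
              chrom = chrom %||% rep("1", S),
              pos = pos %||% ((seq_len(S) - 1L) * 10L), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
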