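# A deterministic quartet matrix where each population is fixed for the
# frequencies in `p1/p2/p3` (one diploid per population, both haplotypes
# equal) and the outgroup is fixed ancestral.
fixed_freq_geno <- function(p1, p2, p3, block = 1e6) {
  S <- length(p1)
  mk <- function(p) rbind(as.integer(p), as.integer(p))
  G <- rbind(mk(p1), mk(p2), mk(p3), mk(rep(0, S)))
  toy_geno(G, c("P1", "P2", "P3", "O"),
           pos = as.integer(seq(0, by = block / 4, length.out = S)))
}

test_that("the four-site hand example gives ABBA = 2, BABA = 1, D = 1/3", {
  x <- fixed_freq_geno(p1 = c(0, 0, 1, 0), p2 = c(1, 1, 0, 0),
                       p3 = c(1, 1, 1, 0))
  d <- dstat(x, "P1", "P2", "P3", "O", block_size_bp = 250000)
  expect_equal(d$abba, 2)
  expect_equal(d$baba, 1)
  expect_equal(d$D, 1 / 3, tolerance = 1e-12)
})

test_that("D vanishes when P2 and P3 have identical frequencies and flips sign when P1 and P2 swap", {
  fx <- make_fixture("geneflow_quartet", seed = 12, n_loci = 60,
                     locus_length = 2e4)
  x <- fx$geno
  d12 <- dstat(x, "P1", "P2", "P3", "OUT", block_size_bp = 2e4)
  d21 <- dstat(x, "P2", "P1", "P3", "OUT", block_size_bp = 2e4)
  expect_equal(d21$D, -d12$D, tolerance = 1e-12)
  expect_equal(d21$abba, d12$baba)
  # p1 = p2 at every site -> D = 0 exactly (the symmetry D tests)
  G <- rbind(c(0L, 1L), c(1L, 1L),
             c(0L, 1L), c(1L, 1L),
             c(0L, 1L), c(1L, 0L),
             c(0L, 0L), c(0L, 0L))
  y <- toy_geno(G, c("P1", "P2", "P3", "O"), pos = c(0L, 500000L))
  sf <- coalscan:::abba_site_freqs(y, c("P1", "P2", "P3"), "O")
  abba <- sum((1 - sf$freqs[, 1]) * sf$freqs[, 2] * sf$freqs[, 3])
  baba <- sum(sf$freqs[, 1] * (1 - sf$freqs[, 2]) * sf$freqs[, 3])
  expect_equal(abba, baba)
})

test_that("frequency-based D equals exhaustive haplotype pattern counting", {
  set.seed(5)
  G <- matrix(sample(c(0L, 1L), 10 * 50, replace = TRUE), nrow = 10)
  x <- toy_geno(G, c("P1", "P2", "P3", "P3", "O"),
                pos = as.integer(seq(0, by = 4000, length.out = 50)))
  d <- dstat(x, "P1", "P2", "P3", "O", block_size_bp = 50000)
  orc <- oracle_dstat_counts(G[1:2, , drop = FALSE], G[3:4, , drop = FALSE],
                             G[5:8, , drop = FALSE], G[9:10, , drop = FALSE])
  expect_equal(d$abba, orc$abba, tolerance = 1e-12)
  expect_equal(d$baba, orc$baba, tolerance = 1e-12)
  expect_equal(d$D, (orc$abba - orc$baba) / (orc$abba + orc$baba),
               tolerance = 1e-12)
})

test_that("jackknife SE shrinks roughly like 1/sqrt(blocks) on homogeneous data", {
  ratios <- vapply(1:6, function(s) {
    fx <- make_fixture("no_geneflow_quartet", seed = 50 + s, n_loci = 160,
                       locus_length = 2e4)
    d_all <- dstat(fx$geno, "P1", "P2", "P3", "OUT", block_size_bp = 2e4)
    quarter <- subset_geno(fx$geno,
                           sites = which(fx$geno$pos < 40 * 2e4))
    d_q <- dstat(quarter, "P1", "P2", "P3", "OUT", block_size_bp = 2e4)
    d_q$se / d_all$se
  }, numeric(1))
  # 40 vs 160 blocks: expect roughly a doubling of the SE on average
  expect_gt(median(ratios), 1.2)
  expect_lt(median(ratios), 4)
})

test_that("outgroup f3 reflects shared drift and its degenerate bounds", {
  # pO = pA at every site -> f3 = 0
  G <- rbind(c(0L, 1L), c(1L, 0L),
             c(0L, 0L), c(1L, 1L),
             c(0L, 1L), c(1L, 0L))
  x <- toy_geno(G, c("A", "B", "O"), pos = c(0L, 2000000L))
  expect_error(f3_outgroup(x, "A", "B", "O"), "3 non-empty blocks")
  fx <- make_fixture("no_geneflow_quartet", seed = 19, n_loci = 100,
                     locus_length = 2e4)
  # P1 and P2 are sisters; P3 is the more distant lineage
  f_sis <- f3_outgroup(fx$geno, "P1", "P2", "OUT", block_size_bp = 2e4)
  f_far <- f3_outgroup(fx$geno, "P1", "P3", "OUT", block_size_bp = 2e4)
  expect_gt(f_sis$f3, f_far$f3)
  # self-comparison dominates any cross-pair
  f_self <- f3_outgroup(fx$geno, "P1", "P1", "OUT", block_size_bp = 2e4)
  expect_gt(f_self$f3, f_sis$f3)
})

test_that("sister pairs out-share distant pairs in nearly all replicates", {
  wins <- 0
  for (s in 1:25) {
    fx <- make_fixture("no_geneflow_quartet", seed = 400 + s, n_loci = 50,
                       locus_length = 2e4)
    f_sis <- f3_outgroup(fx$geno, "P1", "P2", "OUT", block_size_bp = 2e4)
    f_far <- f3_outgroup(fx$geno, "P1", "P3", "OUT", block_size_bp = 2e4)
    wins <- wins + (f_sis$f3 > f_far$f3)
  }
  expect_gte(wins, 24)
})

test_that("fd windows: tiling arithmetic, zero cases and bounds", {
  fx <- make_fixture("geneflow_quartet", seed = 8, n_loci = 80,
                     locus_length = 2e4)
  tr <- fd_windows(fx$geno, "P1", "P2", "P3", "OUT", window_snps = 50,
                   step_snps = 50)
  sf <- coalscan:::abba_site_freqs(fx$geno, c("P1", "P2", "P3"), "OUT")
  expect_equal(nrow(tr), floor(sum(sf$use) / 50))
  expect_true(all(tr$value >= 0 & tr$value <= 1))
  expect_true(all(tr$end > tr$start))
  ov <- fd_windows(fx$geno, "P1", "P2", "P3", "OUT", window_snps = 50,
                   step_snps = 25)
  expect_gt(nrow(ov), nrow(tr))
  expect_error(fd_windows(fx$geno, "P1", "P2", "P3", "OUT",
                          window_snps = 1e6), "no complete window")
})

test_that("fd is elevated inside a known introgressed tract", {
  fx <- make_fixture("introgressed_tract", seed = 3, n_loci = 200,
                     locus_length = 2e4)
  tr <- fd_windows(fx$geno, "P1", "P2", "P3", "OUT")
  inside <- tr$start < fx$meta$tract_end & tr$end > fx$meta$tract_start
  expect_gt(mean(tr$value[inside]), mean(tr$value[!inside]))
})

test_that("top-fraction selection and window overlap behave at the edges", {
  tr <- tibble::tibble(chrom = "1", start = seq(0, 1990, 10),
                       end = seq(10, 2000, 10), stat = "fd",
                       value = seq_len(200), n_sites = 1)
  top <- top_fraction_windows(tr, 0.01)
  expect_identical(nrow(top), 2L)            # ceiling(0.01 * 200)
  expect_setequal(top$value, c(199, 200))
  expect_equal(window_overlap(top, top), 1.0)
  other <- tibble::tibble(chrom = "1", start = 5000, end = 6000)
  expect_equal(window_overlap(top, other), 0.0)
  expect_error(top_fraction_windows(tr, 0), "q must be")
})

test_that("topology weights sum to one per locus and recover the species tree", {
  fx <- make_fixture("no_geneflow_quartet", seed = 21, n_loci = 40,
                     locus_length = 1e4)
  tw <- topology_weights(fx$genealogies,
                         groups = list(P1 = "P1", P2 = "P2", P3 = "P3"),
                         outgroup = "OUT", n_samples = 40, seed = 2)
  sums <- tw$per_locus |>
    dplyr::group_by(locus) |>
    dplyr::summarise(s = sum(weight))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_equal(sum(tw$weights$weight), 1, tolerance = 1e-12)
  # concordant topology (P1,P2 cherry) carries the highest weight
  best <- tw$weights$topology[which.max(tw$weights$weight)]
  expect_identical(best, "((P1,P2),P3)")
  expect_error(topology_weights(fx$genealogies,
                                groups = list(P1 = "P1", P2 = "P2",
                                              P3 = "OUT"),
                                outgroup = "OUT"),
               "outgroup cannot")
})

test_that("gene flow raises the weight of the donor-recipient topology", {
  fx0 <- make_fixture("no_geneflow_quartet", seed = 33, n_loci = 60,
                      locus_length = 1e4)
  fx1 <- make_fixture("geneflow_quartet", seed = 33, n_loci = 60,
                      locus_length = 1e4)
  gr <- list(P1 = "P1", P2 = "P2", P3 = "P3")
  w0 <- topology_weights(fx0$genealogies, gr, "OUT", n_samples = 50,
                         seed = 4)$weights
  w1 <- topology_weights(fx1$genealogies, gr, "OUT", n_samples = 50,
                         seed = 4)$weights
  disc <- "((P2,P3),P1)"
  expect_gt(w1$weight[w1$topology == disc], w0$weight[w0$topology == disc])
})
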