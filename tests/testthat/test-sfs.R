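# Outgroup polarization --------------------------------------------------

test_that("polarization keeps, flips, and drops sites per the outgroup state", {
  # 2 ingroup samples (A) + 1 outgroup sample (O); sites:
  # 1: outgroup fixed 0 -> kept unchanged; 2: outgroup fixed 1 -> flipped;
  # 3: outgroup heterozygous -> dropped; 4: outgroup missing -> dropped
  G <- rbind(
    c(0L, 1L, 0L, 1L),
    c(1L, 1L, 1L, 0L),
    c(0L, 0L, 0L, 1L),
    c(1L, 0L, 1L, 0L),
    c(0L, 1L, 0L, NA),
    c(0L, 1L, 1L, NA)
  )
  x <- toy_geno(G, c("A", "A", "O"))
  p <- polarize(x, "O")
  expect_identical(n_sites(p), 2L)
  expect_identical(unname(p$G[1:4, 1]), c(0L, 1L, 0L, 1L))
  expect_identical(unname(p$G[1:4, 2]), c(0L, 0L, 1L, 1L))  # flipped
  expect_true(all(p$ancestral_known))
  expect_error(polarize(x, "Z"), "no such population")
})

test_that("dropped-site count matches a per-site brute-force scan", {
  set.seed(42)
  G <- matrix(sample(c(0L, 1L), 8 * 20, replace = TRUE), nrow = 8)
  x <- toy_geno(G, c("A", "A", "A", "O"))
  og <- G[7:8, ]
  dropped <- sum(vapply(seq_len(20), function(s)
    length(unique(og[, s])) > 1, logical(1)))
  expect_identical(n_sites(polarize(x, "O")), 20L - dropped)
})

# Site filters ------------------------------------------------------------

test_that("greedy 2-kb thinning keeps the hand-enumerated sites", {
  G <- matrix(rep(c(0L, 1L), 6), nrow = 2)
  x <- toy_geno(G, "A", pos = c(0L, 500L, 2100L, 2200L, 5000L, 5001L))
  f <- filter_sites(x)
  expect_identical(f$pos, c(0L, 2100L, 5000L))
})

test_that("sites failing class, CpG or completeness filters are removed", {
  G <- rbind(c(0L, 0L, 0L, 1L), c(1L, 1L, NA, 0L))
  x <- toy_geno(G, "A", pos = c(0L, 4000L, 8000L, 12000L),
                site_class = c("intergenic", "genic", "intergenic",
                               "intergenic"),
                cpg = c(FALSE, FALSE, FALSE, TRUE))
  f <- filter_sites(x)
  expect_identical(f$pos, 0L)  # genic, missing and CpG sites all dropped
  allg <- toy_geno(G[, 1, drop = FALSE], "A",
                   site_class = "genic")
  expect_identical(n_sites(filter_sites(allg)), 0L)
})

test_that("thinning is independent of site order given sorted positions", {
  set.seed(1)
  pos <- sort(sample(0:50000, 40))
  G <- matrix(rep(c(0L, 1L), 40), nrow = 2)
  x <- toy_geno(G, "A", pos = pos)
  expect_identical(filter_sites(x)$pos, filter_sites(x)$pos)
  kept <- filter_sites(x)$pos
  expect_true(all(diff(kept) >= 2000))
})

# SFS construction --------------------------------------------------------

test_that("a one-population unfolded SFS counts derived alleles directly", {
  # 4 haplotypes; derived counts per site: 1, 1, 2, 3
  G <- rbind(c(1L, 0L, 1L, 1L),
             c(0L, 1L, 1L, 1L),
             c(0L, 0L, 0L, 1L),
             c(0L, 0L, 0L, 0L))
  x <- toy_geno(G, c("A", "A"))
  s <- build_sfs(x, "A")
  expect_equal(as.vector(s$counts), c(0, 2, 1, 1, 0))
  expect_equal(sfs_total(s), 4)
  expect_true(s$mask[1] && s$mask[5])
})

test_that("folding commutes with building a folded spectrum", {
  fx <- make_fixture("tt_model5", seed = 6, n_snps = 400)
  x <- subset_geno(fx$geno,
                   samples = fx$geno$sample_ids[fx$geno$pops != "CEB"])
  u <- build_sfs(x, c("NAW", "SAW", "TT"))
  f1 <- fold_sfs(u)
  f2 <- build_sfs(x, c("NAW", "SAW", "TT"), folded = TRUE)
  expect_equal(f1$counts, f2$counts)
  expect_identical(f1$mask, f2$mask)
  expect_equal(sfs_total(f1), sfs_total(u))
})

test_that("an empty matrix gives an all-zero tensor and missing data error", {
  G <- matrix(integer(), nrow = 2, ncol = 0)
  x <- toy_geno(G, "A")
  s <- build_sfs(x, "A")
  expect_true(all(s$counts == 0))
  Gna <- matrix(c(0L, NA), nrow = 2)
  expect_error(build_sfs(toy_geno(Gna, "A"), "A"), "missing")
})

test_that("unfolded mode insists on polarized sites", {
  G <- matrix(c(0L, 1L), nrow = 2)
  x <- toy_geno(G, "A", ancestral_known = FALSE)
  expect_error(build_sfs(x, "A"), "polarized")
  expect_silent(build_sfs(x, "A", folded = TRUE))
})

# Folding and projection --------------------------------------------------

test_that("folding conserves totals and halves the support", {
  counts <- array(c(0, 5, 3, 2, 1), dim = 5)  # n = 4 haplotypes
  s <- coalscan:::new_sfs(counts, "A", folded = FALSE)
  f <- fold_sfs(s)
  expect_equal(sum(f$counts), sum(counts))
  # complements: d=4 -> d=0 (corner), d=3 -> d=1; d=2 self-complementary
  expect_equal(as.vector(f$counts), c(1, 5 + 2, 3, 0, 0))
  expect_identical(fold_sfs(f)$counts, f$counts)  # idempotent
})

test_that("projection matches exhaustive hypergeometric enumeration", {
  counts <- c(0, 7, 4, 2, 1)  # n = 4
  s <- coalscan:::new_sfs(array(counts, dim = 5), "A", folded = FALSE)
  p <- project_sfs(s, 2)
  expect_equal(as.vector(p$counts), oracle_project_1pop(counts, 2),
               tolerance = 1e-12)
  expect_equal(sum(p$counts), sum(counts))
  # projecting to the same size is the identity
  same <- project_sfs(s, 4)
  expect_equal(as.vector(same$counts), counts, tolerance = 1e-12)
  expect_error(project_sfs(s, 5), "exceeds")
})

test_that("multidimensional projection conserves totals", {
  fx <- make_fixture("tt_model5", seed = 8, n_snps = 300)
  x <- subset_geno(fx$geno,
                   samples = fx$geno$sample_ids[fx$geno$pops != "CEB"])
  u <- build_sfs(x, c("NAW", "SAW", "TT"))
  p <- project_sfs(u, c(6, 6, 6))
  expect_equal(sum(p$counts), sum(u$counts), tolerance = 1e-8)
  expect_identical(dim(p$counts), c(7L, 7L, 7L))
})

test_that("SFS text serialization round-trips", {
  fx <- make_fixture("tt_model5", seed = 4, n_snps = 200)
  x <- subset_geno(fx$geno,
                   samples = fx$geno$sample_ids[fx$geno$pops != "CEB"])
  s <- build_sfs(x, c("NAW", "SAW", "TT"))
  path <- withr::local_tempfile(fileext = ".sfs")
  write_sfs(s, path)
  r <- read_sfs(path)
  expect_equal(r$counts, s$counts)
  expect_identical(r$mask, s$mask)
  expect_identical(r$pops, s$pops)
  expect_identical(r$folded, s$folded)
})

test_that("simulated single-population spectra match the neutral 1/i shape", {
  m <- demog_model(data.frame(name = "A", Ne = 10000))
  # small loci so that tree-sharing between sites is negligible
  s <- sim_genotypes(m, c(A = 5), n_loci = 60000, locus_length = 500,
                     seed = 13, mode = "sequence")
  obs <- as.vector(build_sfs(s$geno, "A")$counts)[2:10]
  p <- (1 / (1:9)) / sum(1 / (1:9))
  chi <- sum((obs - sum(obs) * p)^2 / (sum(obs) * p))
  expect_gt(stats::pchisq(chi, df = 8, lower.tail = FALSE), 0.01)
})
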