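test_that("snp mode with two haplotypes yields only singletons and is seed-deterministic", {
  m <- demog_model(data.frame(name = "A", Ne = 1000))
  s1 <- sim_genotypes(m, c(A = 1), n_loci = 20, locus_length = 100,
                      seed = 3, mode = "snp")
  s2 <- sim_genotypes(m, c(A = 1), n_loci = 20, locus_length = 100,
                      seed = 3, mode = "snp")
  expect_identical(s1$geno$G, s2$geno$G)
  expect_true(all(colSums(s1$geno$G) == 1))
  s3 <- sim_genotypes(m, c(A = 1), n_loci = 20, locus_length = 100,
                      seed = 4, mode = "snp")
  expect_false(identical(s1$geno$G, s3$geno$G))
})

test_that("sequence-mode segregating sites match Watterson's expectation", {
  m <- demog_model(data.frame(name = "A", Ne = 1000), mu = 1e-8)
  s <- sim_genotypes(m, c(A = 5), n_loci = 200, locus_length = 1e5,
                     seed = 11, mode = "sequence")
  a_n <- sum(1 / (1:9))
  expected_S <- 4 * 1000 * 1e-8 * a_n * 200 * 1e5
  expect_lt(abs(n_sites(s$geno) / expected_S - 1), 0.1)
})

test_that("pairwise diversity converges to 4*Ne*mu in a constant-size population", {
  m <- demog_model(data.frame(name = "A", Ne = 2000), mu = 5e-9)
  s <- sim_genotypes(m, c(A = 5), n_loci = 300, locus_length = 5e4,
                     seed = 7, mode = "sequence")
  p <- colMeans(s$geno$G)
  pi_site <- sum(2 * p * (1 - p) * 10 / 9) / (300 * 5e4)
  expect_lt(abs(pi_site / (4 * 2000 * 5e-9) - 1), 0.1)
})

test_that("every snp-mode site is polymorphic in the sample", {
  tpl <- get_template("TT5")
  m <- tpl$build(c(T_TT = 10000, Ne_TT = 8000, alpha = 0.5))
  s <- sim_genotypes(m, c(NAW = 3, SAW = 3, TT = 3), n_loci = 500,
                     locus_length = 2000, seed = 5, mode = "snp")
  d <- colSums(s$geno$G)
  expect_true(all(d > 0 & d < n_haplotypes(s$geno)))
})

test_that("simulate rejects unknown populations and empty sampling", {
  m <- demog_model(data.frame(name = "A", Ne = 1000))
  expect_error(sim_genotypes(m, c(B = 2), 1, 100, seed = 1), "unknown")
  expect_error(sim_genotypes(m, c(A = 0), 1, 100, seed = 1),
               "no lineages")
})

test_that("admixture pulses outside [0, 1] are rejected at model construction", {
  expect_error(demog_model(
    data.frame(name = c("A", "B"), Ne = 1000),
    data.frame(time = c(10, 50), kind = c("pulse", "split"),
               pop = c("A", "B"), dest = c("B", "A"),
               param = c(1.2, NA))),
    "\\[0, 1\\]")
})

test_that("genealogies are rooted, ultrametric to time zero, and span the haplotypes", {
  fx <- make_fixture("no_geneflow_quartet", seed = 7, n_loci = 5,
                     locus_length = 1000)
  g <- fx$genealogies[[1]]
  n <- g$n_leaves
  expect_length(g$parent, 2 * n - 1)
  expect_identical(sum(g$parent == -1), 1L)  # single root
  expect_true(all(g$time[seq_len(n)] == 0))  # leaves at sampling time
  expect_true(all(g$time[g$parent[-(2 * n - 1)] + 1] >=
                    g$time[-(2 * n - 1)]))   # parents are older
  expect_identical(g$leaf_pops, fx$geno$pops[rep(seq_along(fx$geno$pops),
                                                 each = 2)])
})

test_that("fixtures record their generating truth and are reproducible", {
  fx <- make_fixture("tt_model5", seed = 42, n_snps = 300)
  expect_identical(unname(fx$meta$truth["alpha"]), 0.5)
  expect_identical(fx$meta$model_id, "TT5")
  fx2 <- make_fixture("tt_model5", seed = 42, n_snps = 300)
  expect_identical(fx$geno$G, fx2$geno$G)
  expect_error(make_fixture("nope", seed = 1), "unknown fixture")

  tr <- make_fixture("introgressed_tract", seed = 3, n_loci = 40,
                     locus_length = 2000)
  expect_true(tr$meta$tract_start < tr$meta$tract_end)
  expect_true(tr$meta$tract_end <= 40 * 2000)

  hs <- make_fixture("hard_sweep", seed = 2, n_loci = 40,
                     locus_length = 10000)
  cols <- which(hs$geno$pos >= hs$meta$sweep_start &
                  hs$geno$pos < hs$meta$sweep_end)
  rows <- which(rep(hs$geno$pops, each = 2) == "TGT")
  carriers <- rows[seq_len(ceiling(0.9 * length(rows)))]
  sub <- hs$geno$G[carriers, cols, drop = FALSE]
  expect_true(all(apply(sub, 2, function(cl) length(unique(cl)) == 1)))
})

test_that("VCF round-trip preserves alleles, positions and ancestral flags", {
  fx <- make_fixture("tt_model5", seed = 9, n_snps = 50)
  x <- fx$geno
  x$site_class[1:10] <- "genic"
  x$cpg[5:8] <- TRUE
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, path)
  # the same seed reproduces the VCF byte-for-byte
  fx2 <- make_fixture("tt_model5", seed = 9, n_snps = 50)
  x2 <- fx2$geno
  x2$site_class[1:10] <- "genic"
  x2$cpg[5:8] <- TRUE
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x2, path2)
  expect_identical(readLines(path), readLines(path2))
  popmap <- data.frame(sample = x$sample_ids, pop = x$pops)
  y <- read_vcf(path, popmap)
  expect_identical(unname(y$G), unname(x$G))
  expect_identical(y$pos, x$pos)
  expect_identical(y$ancestral_known, x$ancestral_known)
  expect_identical(y$site_class, x$site_class)
  expect_identical(y$cpg, x$cpg)
  expect_identical(y$pops, x$pops)
})

test_that("single-record VCF and missing genotypes are handled", {
  x <- toy_geno(matrix(c(0L, 1L), nrow = 2), "A")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(x, path)
  lines <- readLines(path)
  rec <- strsplit(lines[length(lines)], "\t")[[1]]
  expect_identical(rec[10], "0|1")

  xm <- toy_geno(matrix(c(0L, 1L, NA, NA, 0L, 0L), nrow = 2),
                 pops_per_sample = "A")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(xm, path2)
  y <- read_vcf(path2, data.frame(sample = "s1", pop = "A"))
  expect_true(all(is.na(y$G[, 2])))
  expect_identical(unname(y$G[, 1]), c(0L, 1L))

  expect_error(read_vcf(path2, data.frame(sample = "zz", pop = "A")),
               "absent")
})
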