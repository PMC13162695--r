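#' Simulate genotypes and genealogies under a demographic model
#'
#' Seeded structured-coalescent simulation. Loci are independent
#' non-recombining blocks laid head-to-tail along a single chromosome, so
#' linkage exists within blocks and not between them. In `"sequence"` mode
#' each locus carries infinite-sites mutations at rate `mu * locus_length`
#' per branch-generation; in `"snp"` mode each locus contributes exactly one
#' segregating site, placed on a branch drawn with probability proportional
#' to branch length (the zero-rate limit of resampling mutationless loci).
#' The same seed always reproduces the same output byte-for-byte.
#'
#' @param model A [demog_model()].
#' @param samples_per_pop Named integer vector: diploid samples per
#'   population (subset of the model's populations).
#' @param n_loci Number of independent loci.
#' @param locus_length Locus length in bp.
#' @param seed Integer seed.
#' @param mode `"sequence"` or `"snp"`.
#'
#' @return A list of class `coal_sim` with elements `geno` (a
#'   [geno_matrix()]), `genealogies` (per-locus rooted trees: parent
#'   pointers, node times in generations, leaf populations, locus interval)
#'   and `loci` (a tibble of locus intervals).
#' @export
#' @examples
#' m <- demog_model(populations = data.frame(name = "A", Ne = 1000))
#' s <- sim_genotypes(m, c(A = 5), n_loci = 10, locus_length = 1e4, seed = 1)
#' s$geno
sim_genotypes <- function(model, samples_per_pop, n_loci, locus_length,
                          seed, mode = c("sequence", "snp")) {
  mode <- match.arg(mode)
  stop_if_not(inherits(model, "demog_model"), "`model` must be a demog_model")
  stop_if_not(n_loci >= 1 && locus_length >= 1,
              "`n_loci` and `locus_length` must be >= 1")
  pops <- model$populations$name
  stop_if_not(all(names(samples_per_pop) %in% pops),
              "unknown population in `samples_per_pop`")
  stop_if_not(sum(samples_per_pop) > 0, "no lineages sampled anywhere")
  nsamp <- setNames(integer(length(pops)), pops)
  nsamp[names(samples_per_pop)] <- as.integer(samples_per_pop)
  enc <- encode_model(model)
  raw <- cpp_simulate(enc$Ne0, enc$mig, enc$ev_time, enc$ev_kind, enc$ev_a,
                      enc$ev_b,
                      enc$ev_par, as.integer(2L * nsamp), as.integer(n_loci),
                      as.double(locus_length), model$mu,
                      if (mode == "snp") 1L else 0L,
                      as.double(mix_seed(seed)))
  assemble_sim(raw, model, nsamp, n_loci, locus_length, mode)
}

# Shared assembly of C++ locus output into geno_matrix + genealogy list.
assemble_sim <- function(raw, model, nsamp, n_loci, locus_length, mode,
                         chrom = "1") {
  pops_used <- names(nsamp)[nsamp > 0]
  sample_ids <- unlist(lapply(pops_used, function(p)
    paste0(p, "_", seq_len(nsamp[[p]]))))
  sample_pops <- rep(pops_used, times = nsamp[nsamp > 0])
  leaf_pops <- rep(sample_pops, each = 2)
  offs <- (seq_len(n_loci) - 1) * locus_length
  geno_list <- vector("list", n_loci)
  pos_list <- vector("list", n_loci)
  genealogies <- vector("list", n_loci)
  for (j in seq_len(n_loci)) {
    lc <- raw[[j]]
    geno_list[[j]] <- lc$geno
    pos_list[[j]] <- lc$pos + offs[j]
    genealogies[[j]] <- structure(
      list(parent = lc$parent, time = lc$time,
           n_leaves = nrow(lc$geno), leaf_pops = leaf_pops,
           chrom = chrom, start = offs[j], end = offs[j] + locus_length),
      class = "genealogy")
  }
  G <- do.call(cbind, geno_list)
  pos <- unlist(pos_list)
  geno <- geno_matrix(G, sample_ids, sample_pops,
                      chrom = rep(chrom, length(pos)), pos = pos,
                      ancestral_known = rep(TRUE, length(pos)))
  loci <- tibble(locus = seq_len(n_loci), chrom = chrom,
                 start = offs, end = offs + locus_length)
  structure(list(geno = geno, genealogies = genealogies, loci = loci,
                 model = model, mode = mode),
            class = "coal_sim")
}

#' @export
print.coal_sim <- function(x, ...) {
  cat("<coal_sim> ", nrow(x$loci), " loci (", x$mode, " mode), ",
      n_sites(x$geno), " segregating sites\n", sep = "")
  print(x$geno)
  invisible(x)
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy> ", x$n_leaves, " leaves, interval [", x$start, ", ",
      x$end, ") on ", x$chrom, "\n", sep = "")
  invisible(x)
}
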