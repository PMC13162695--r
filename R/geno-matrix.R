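#' Genotype matrices
#'
#' The package's genotype container: a haplotype-by-site matrix of 0/1
#' alleles (NA = missing) for phased diploid samples, with per-site
#' chromosome, 0-based position, ancestral-state flag, site class
#' (genic/intergenic) and CpG flag. When `ancestral_known` is `TRUE` at a
#' site the site is polarized so that allele 1 is the derived allele.
#'
#' @param G Integer matrix, haplotypes x sites, values 0/1/NA. Two
#'   consecutive rows per sample.
#' @param sample_ids Character vector, one id per diploid sample
#'   (`nrow(G) = 2 * length(sample_ids)`).
#' @param pops Character vector of population labels, one per sample.
#' @param chrom Character vector of chromosome names, one per site.
#' @param pos Integer vector of 0-based positions, strictly increasing
#'   within each chromosome.
#' @param ancestral_known Logical per site; sites flagged `TRUE` are
#'   polarized (allele 1 = derived).
#' @param site_class Character per site, `"intergenic"` or `"genic"`.
#' @param cpg Logical per site, `TRUE` inside a CpG island annotation.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(G, sample_ids, pops, chrom, pos,
                        ancestral_known = rep(TRUE, ncol(G)),
                        site_class = rep("intergenic", ncol(G)),
                        cpg = rep(FALSE, ncol(G))) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  ns <- length(sample_ids)
  stop_if_not(nrow(G) == 2L * ns, "G must have two haplotype rows per sample")
  stop_if_not(length(pops) == ns, "one population label per sample")
  S <- ncol(G)
  stop_if_not(length(chrom) == S && length(pos) == S &&
                length(ancestral_known) == S && length(site_class) == S &&
                length(cpg) == S,
              "per-site annotations must match the number of sites")
  stop_if_not(all(G %in% c(0L, 1L, NA_integer_)),
              "allele values must be 0, 1 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    stop_if_not(all(diff(p) > 0),
                "positions must be strictly increasing within chromosome")
  }
  rownames(G) <- paste0(rep(sample_ids, each = 2), "_", c(1, 2))
  structure(
    list(G = G,
         sample_ids = as.character(sample_ids),
         pops = as.character(pops),
         chrom = as.character(chrom),
         pos = as.integer(pos),
         ancestral_known = as.logical(ancestral_known),
         site_class = as.character(site_class),
         cpg = as.logical(cpg)),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$sample_ids), " diploid samples (",
      nrow(x$G), " haplotypes) x ", ncol(x$G), " sites\n", sep = "")
  tab <- table(x$pops)
  cat("  populations:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites / haplotypes in a genotype matrix
#' @param x A `geno_matrix`.
#' @return An integer count.
#' @export
n_sites <- function(x) ncol(x$G)

#' @rdname n_sites
#' @export
n_haplotypes <- function(x) nrow(x$G)

# Row indices of the haplotypes belonging to a population.
hap_rows <- function(x, pop) {
  idx <- which(x$pops %in% pop)
  stop_if_not(length(idx) > 0, paste0("no samples in population ", pop))
  sort(c(2L * idx - 1L, 2L * idx))
}

# Allele-1 frequency per site within a population (NA-aware).
allele_freq <- function(x, pop, sites = NULL) {
  rows <- hap_rows(x, pop)
  g <- x$G[rows, , drop = FALSE]
  if (!is.null(sites)) g <- g[, sites, drop = FALSE]
  colMeans(g, na.rm = TRUE)
}

#' Subset a genotype matrix
#'
#' @param x A `geno_matrix`.
#' @param sites Integer or logical index over sites.
#' @param samples Character sample ids (or integer index over samples).
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(x, sites = NULL, samples = NULL) {
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, x$sample_ids)
      stop_if_not(!anyNA(idx), "unknown sample id")
    } else {
      idx <- samples
    }
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    x$G <- x$G[rows, , drop = FALSE]
    x$sample_ids <- x$sample_ids[idx]
    x$pops <- x$pops[idx]
  }
  if (!is.null(sites)) {
    x$G <- x$G[, sites, drop = FALSE]
    x$chrom <- x$chrom[sites]
    x$pos <- x$pos[sites]
    x$ancestral_known <- x$ancestral_known[sites]
    x$site_class <- x$site_class[sites]
    x$cpg <- x$cpg[sites]
  }
  x
}
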