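#' Write a genotype matrix as VCF 4.2
#'
#' Alleles are encoded as REF = `A` (allele 0) and ALT = `T` (allele 1);
#' the ancestral allele is emitted in the `AA` INFO key where known, the
#' site class in `SITECLASS`, and CpG-island membership as the `CPG`
#' flag. Positions are 1-based in the file (0-based in the container).
#'
#' @param x A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=coalscan",
    "##INFO=<ID=AA,Number=1,Type=Character,Description=\"Ancestral allele\">",
    "##INFO=<ID=SITECLASS,Number=1,Type=String,Description=\"Site class (genic/intergenic)\">",
    "##INFO=<ID=CPG,Number=0,Type=Flag,Description=\"Inside a CpG island\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t")
  ), con)
  S <- n_sites(x)
  if (S > 0) {
    h1 <- x$G[seq(1, nrow(x$G), 2), , drop = FALSE]
    h2 <- x$G[seq(2, nrow(x$G), 2), , drop = FALSE]
    gt <- matrix(paste(ifelse(is.na(h1), ".", h1),
                       ifelse(is.na(h2), ".", h2), sep = "|"),
                 nrow = nrow(h1))
    gt[is.na(h1) & is.na(h2)] <- "./."
    info <- paste0(ifelse(x$ancestral_known, "AA=A;", ""),
                   "SITECLASS=", x$site_class,
                   ifelse(x$cpg, ";CPG", ""))
    lines <- paste(x$chrom, x$pos + 1L, ".", "A", "T", ".", "PASS", info,
                   "GT", apply(gt, 2, paste, collapse = "\t"),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.2 file (via the vcfR package), mapping REF to allele 0
#' and ALT to allele 1, then flipping sites whose `AA` INFO key names the
#' ALT allele so that allele 1 is always derived where the ancestral
#' state is known. Missing genotypes become `NA`.
#'
#' @param path VCF path.
#' @param popmap A data frame with columns `sample` and `pop`, or the
#'   path to a two-column whitespace-separated file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) {
    popmap <- utils::read.table(popmap, header = FALSE,
                                col.names = c("sample", "pop"),
                                stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("sample", "pop") %in% names(popmap)),
              "popmap needs columns sample and pop")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix  # CHROM POS ID REF ALT QUAL FILTER INFO
  samples <- colnames(v@gt)[-1]
  missing <- setdiff(popmap$sample, samples)
  stop_if_not(length(missing) == 0,
              paste0("popmap samples absent from VCF: ",
                     paste(missing, collapse = ", ")))
  popmap <- popmap[match(samples, popmap$sample), , drop = FALSE]
  stop_if_not(!anyNA(popmap$sample), "VCF sample missing from popmap")
  gt <- vcfR::extract.gt(v)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dec <- function(a) {
    out <- suppressWarnings(as.integer(a))
    out
  }
  S <- nrow(gt)
  G <- matrix(NA_integer_, nrow = 2 * length(samples), ncol = S)
  G[seq(1, nrow(G), 2), ] <- t(matrix(dec(a1), nrow = S))
  G[seq(2, nrow(G), 2), ] <- t(matrix(dec(a2), nrow = S))
  info <- fix[, "INFO"]
  aa <- sub(".*AA=([^;]+).*", "\\1", info)
  aa[!grepl("AA=", info)] <- NA
  siteclass <- sub(".*SITECLASS=([^;]+).*", "\\1", info)
  siteclass[!grepl("SITECLASS=", info)] <- "intergenic"
  cpg <- grepl("(^|;)CPG($|;)", info)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  ancestral_known <- !is.na(aa) & (aa == ref | aa == alt)
  flip <- which(!is.na(aa) & aa == alt)
  if (length(flip)) G[, flip] <- 1L - G[, flip]
  geno_matrix(G, samples, popmap$pop, chrom = fix[, "CHROM"],
              pos = as.integer(fix[, "POS"]) - 1L,
              ancestral_known = ancestral_known,
              site_class = siteclass, cpg = cpg)
}
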