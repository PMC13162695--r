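#' Polarize a genotype matrix with an outgroup
#'
#' Sites where all non-missing outgroup haplotypes carry one allele are
#' polarized so that this allele becomes the ancestral state (allele 0);
#' sites where the outgroup is polymorphic, or has no genotyped haplotype,
#' are dropped ("confidently inferred ancestral alleles" only).
#'
#' @param x A [geno_matrix()].
#' @param outgroup Population label used to infer ancestral states.
#' @return A `geno_matrix` containing only polarized sites, with
#'   `ancestral_known = TRUE` and allele 1 = derived.
#' @export
polarize <- function(x, outgroup) {
  stop_if_not(outgroup %in% x$pops, paste0("no such population: ", outgroup))
  og <- x$G[hap_rows(x, outgroup), , drop = FALSE]
  n1 <- colSums(og == 1L, na.rm = TRUE)
  n0 <- colSums(og == 0L, na.rm = TRUE)
  keep <- (n1 == 0L & n0 > 0L) | (n0 == 0L & n1 > 0L)
  flip <- n1 > 0L & keep
  G <- x$G
  if (any(flip)) G[, flip] <- 1L - G[, flip]
  x$G <- G
  x <- subset_geno(x, sites = which(keep))
  x$ancestral_known <- rep(TRUE, n_sites(x))
  x
}

#' Filter sites for SFS-based demographic inference
#'
#' Applies the four neutral-site filters: (1) intergenic, (2) outside CpG
#' islands, (3) no missing genotypes in any sample, (4) at least
#' `min_spacing_bp` apart. Spacing is enforced greedily left-to-right per
#' chromosome: the first passing site is kept and the next kept site must
#' be at least `min_spacing_bp` away.
#'
#' @param x A [geno_matrix()] with `site_class` and `cpg` populated.
#' @param min_spacing_bp Minimum distance between retained sites.
#' @return A filtered `geno_matrix` (possibly with zero sites).
#' @export
filter_sites <- function(x, min_spacing_bp = 2000) {
  complete <- colSums(is.na(x$G)) == 0L
  pass <- x$site_class == "intergenic" & !x$cpg & complete
  keep <- logical(n_sites(x))
  for (ch in unique(x$chrom)) {
    idx <- which(pass & x$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (x$pos[i] - last >= min_spacing_bp) {
        keep[i] <- TRUE
        last <- x$pos[i]
      }
    }
  }
  subset_geno(x, sites = which(keep))
}

#' Site frequency spectrum tensors
#'
#' `build_sfs()` tallies each site into the cell indexed by its
#' per-population derived-allele counts (unfolded) or total minor-allele
#' orientation (folded). Monomorphic corner cells (all-ancestral,
#' all-derived) are masked; masked cells are excluded from likelihoods.
#'
#' @param x A [geno_matrix()] without missing genotypes among `pops`;
#'   unfolded mode additionally requires every site to be polarized.
#' @param pops Ordered population labels spanning the SFS axes.
#' @param folded Build a minor-allele spectrum instead of a derived-allele
#'   spectrum.
#' @return An `sfs_tensor`: counts array with one axis per population
#'   (dimension = haploid sample size + 1), population order, folded flag
#'   and logical mask of excluded cells.
#' @export
build_sfs <- function(x, pops, folded = FALSE) {
  stop_if_not(all(pops %in% x$pops), "population not present in matrix")
  rows <- lapply(pops, function(p) hap_rows(x, p))
  sizes <- vapply(rows, length, integer(1))
  sub <- x$G[unlist(rows), , drop = FALSE]
  stop_if_not(!anyNA(sub), "missing genotypes among the SFS populations")
  if (!folded) {
    stop_if_not(all(x$ancestral_known),
                "unfolded SFS requires polarized sites (see polarize())")
  }
  dims <- sizes + 1L
  counts <- array(0, dim = dims)
  if (n_sites(x) > 0) {
    dcount <- vapply(rows, function(r)
      colSums(x$G[r, , drop = FALSE]), numeric(n_sites(x)))
    if (n_sites(x) == 1L) dcount <- matrix(dcount, nrow = 1)
    stride <- cumprod(c(1, dims[-length(dims)]))
    lin <- 1L + as.integer(dcount %*% stride)
    tab <- tabulate(lin, nbins = prod(dims))
    counts <- array(tab, dim = dims)
  }
  out <- new_sfs(counts, pops, folded = FALSE)
  if (folded) out <- fold_sfs(out)
  out
}

new_sfs <- function(counts, pops, folded, mask = NULL) {
  dims <- dim(counts) %||% length(counts)
  if (is.null(dim(counts))) counts <- array(counts, dim = dims)
  if (is.null(mask)) mask <- sfs_corner_mask(dims, folded)
  structure(list(counts = counts, pops = pops, folded = folded,
                 mask = mask),
            class = "sfs_tensor")
}

# Mask of structurally excluded cells: the monomorphic corners, plus (for
# folded spectra) all cells on the major-allele side of the fold.
sfs_corner_mask <- function(dims, folded) {
  mask <- array(FALSE, dim = dims)
  idx0 <- matrix(1L, nrow = 1, ncol = length(dims))
  mask[idx0] <- TRUE
  if (!folded) {
    mask[matrix(dims, nrow = 1)] <- TRUE
  } else {
    grid <- cell_counts(dims)
    tot <- rowSums(grid)
    n <- sum(dims - 1L)
    over <- tot > n / 2
    half <- tot * 2 == n
    # exact-half cells: only the canonical member of each complement pair
    # stays unmasked, so each site is counted once
    if (any(half)) over[half] <- !lex_min_half(grid[half, , drop = FALSE],
                                               dims)
    mask[grid[over, , drop = FALSE] + 1L] <- TRUE
  }
  mask
}

# All integer cell index combinations (0-based), rows in array order.
cell_counts <- function(dims) {
  as.matrix(expand.grid(lapply(dims, function(d) 0:(d - 1L))))
}

n_minus <- function(grid, dims) {
  sweep(-grid, 2, dims - 1L, `+`)
}

# For cells whose total equals half the haploid sample: TRUE when the cell
# is the canonical (lexicographically not-larger) member of its
# complement pair; self-complementary cells are canonical.
lex_min_half <- function(grid, dims) {
  comp <- n_minus(grid, dims)
  vapply(seq_len(nrow(grid)), function(i) {
    a <- grid[i, ]
    b <- comp[i, ]
    d <- which(a != b)
    length(d) == 0 || a[d[1]] < b[d[1]]
  }, logical(1))
}

#' @export
print.sfs_tensor <- function(x, ...) {
  cat("<sfs_tensor> ", if (x$folded) "folded" else "unfolded", ", dims [",
      paste(dim(x$counts), collapse = " x "), "] over (",
      paste(x$pops, collapse = ", "), "); ",
      format(sum(x$counts[!x$mask])), " sites in unmasked cells\n",
      sep = "")
  invisible(x)
}

#' Fold a derived-allele spectrum into a minor-allele spectrum
#'
#' Each cell is summed with its complement (per-population counts
#' `n - c`); cells whose total derived count exceeds half the total
#' haploid sample size land on their complement, and exact-half cells are
#' assigned once to the lexicographically smaller member of the pair.
#'
#' @param sfs An unfolded `sfs_tensor`.
#' @return A folded `sfs_tensor` with the same total site count.
#' @export
fold_sfs <- function(sfs) {
  stop_if_not(inherits(sfs, "sfs_tensor"), "not an sfs_tensor")
  if (sfs$folded) return(sfs)
  dims <- dim(sfs$counts)
  grid <- cell_counts(dims)
  tot <- rowSums(grid)
  n <- sum(dims - 1L)
  comp <- n_minus(grid, dims)
  move <- tot > n / 2
  half <- tot * 2 == n
  if (any(half)) move[half] <- !lex_min_half(grid[half, , drop = FALSE],
                                             dims)
  counts <- sfs$counts
  # complementation is a bijection between moved and kept cells, so the
  # transfer vectorizes without collisions
  stride <- cumprod(c(1, dims[-length(dims)]))
  src <- which(move)
  dst <- 1L + as.integer(comp[move, , drop = FALSE] %*% stride)
  vals <- counts[src]
  counts[src] <- 0
  counts[dst] <- counts[dst] + vals
  new_sfs(counts, sfs$pops, folded = TRUE)
}

#' Project a spectrum down to smaller sample sizes
#'
#' Replaces each cell by its expected allele-count distribution under
#' sampling without replacement (hypergeometric expectation), axis by
#' axis. Totals are conserved.
#'
#' @param sfs An `sfs_tensor`.
#' @param new_sizes Haploid sample sizes per population,
#'   `<=` current sizes.
#' @return An `sfs_tensor` on the new sizes.
#' @export
project_sfs <- function(sfs, new_sizes) {
  dims <- dim(sfs$counts)
  old_sizes <- dims - 1L
  stop_if_not(length(new_sizes) == length(dims),
              "one size per population")
  stop_if_not(all(new_sizes <= old_sizes),
              "projection size exceeds sample size")
  stop_if_not(!sfs$folded, "project before folding")
  counts <- sfs$counts
  for (ax in seq_along(dims)) {
    n_old <- old_sizes[ax]
    n_new <- new_sizes[ax]
    proj <- outer(0:n_old, 0:n_new, function(i, j)
      stats::dhyper(j, i, n_old - i, n_new))
    proj[is.na(proj)] <- 0
    counts <- apply_axis(counts, ax, function(mat) mat %*% proj)
  }
  new_sfs(counts, sfs$pops, folded = FALSE)
}

# Apply f to a (cells x dim_ax) matrix along axis ax of an array.
apply_axis <- function(arr, ax, f) {
  dims <- dim(arr)
  perm <- c(setdiff(seq_along(dims), ax), ax)
  m <- matrix(aperm(arr, perm), ncol = dims[ax])
  res <- f(m)
  newdims <- c(dims[-ax], ncol(res))
  aperm(array(res, dim = newdims),
        order(c(setdiff(seq_along(dims), ax), ax)))
}

#' Total site count in unmasked cells
#' @param sfs An `sfs_tensor`.
#' @return A number.
#' @export
sfs_total <- function(sfs) sum(sfs$counts[!sfs$mask])

#' Read and write spectra as flat text
#'
#' dadi/fastsimcoal-style flat text: a header line with the axis sizes,
#' the population order and the folded flag, one line of
#' whitespace-separated cell values in array (first-axis-fastest) order,
#' and one line of 0/1 mask flags.
#'
#' @param sfs An `sfs_tensor`.
#' @param path File path.
#' @return `read_sfs()` returns an `sfs_tensor`; `write_sfs()` returns
#'   `path` invisibly.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(paste(dim(sfs$counts), collapse = " "),
                     paste(sfs$pops, collapse = ","),
                     if (sfs$folded) "folded" else "unfolded"),
                   collapse = " | "), con)
  writeLines(paste(format(as.vector(sfs$counts), scientific = FALSE,
                          trim = TRUE), collapse = " "), con)
  writeLines(paste(as.integer(as.vector(sfs$mask)), collapse = " "), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " | ", fixed = TRUE)[[1]]
  dims <- as.integer(strsplit(hdr[1], " ")[[1]])
  pops <- strsplit(hdr[2], ",")[[1]]
  folded <- identical(hdr[3], "folded")
  counts <- array(as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]]),
                  dim = dims)
  mask <- array(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]]) == 1L,
                dim = dims)
  new_sfs(counts, pops, folded, mask = mask)
}
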