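# Shared site preparation for frequency-based ABBA-BABA statistics:
# outgroup-polarized derived frequencies at sites where the outgroup is
# fixed and every population has at least one genotyped haplotype.
abba_site_freqs <- function(x, pops, outgroup) {
  all_pops <- c(pops, outgroup)
  stop_if_not(!anyDuplicated(all_pops),
              "populations in a trio/quartet must be distinct")
  og <- x$G[hap_rows(x, outgroup), , drop = FALSE]
  n1 <- colSums(og == 1L, na.rm = TRUE)
  n0 <- colSums(og == 0L, na.rm = TRUE)
  og_fixed <- (n1 == 0L & n0 > 0L) | (n0 == 0L & n1 > 0L)
  anc1 <- n1 > 0L  # outgroup carries allele 1 => allele 0 is derived
  fr <- lapply(pops, function(p) allele_freq(x, p))
  genotyped <- Reduce(`&`, lapply(fr, function(f) !is.na(f)))
  use <- og_fixed & genotyped
  freqs <- vapply(fr, function(f) ifelse(anc1, 1 - f, f), numeric(ncol(og)))
  list(use = use, freqs = freqs[use, , drop = FALSE],
       chrom = x$chrom[use], pos = x$pos[use])
}

# Contiguous block ids for the jackknife.
jackknife_blocks <- function(chrom, pos, block_size_bp) {
  paste0(chrom, ":", floor(pos / block_size_bp))
}

# Delete-one block jackknife of a ratio statistic T = f(total sums).
# sums: matrix blocks x components; statistic computed on colSums.
jackknife_se <- function(sums, statistic) {
  B <- nrow(sums)
  tot <- colSums(sums)
  loo <- vapply(seq_len(B), function(j) statistic(tot - sums[j, ]),
                numeric(1))
  sqrt((B - 1) / B * sum((loo - mean(loo))^2))
}

#' ABBA-BABA D statistic with block-jackknife Z score
#'
#' Frequency-based Patterson's D for the rooted configuration
#' `(((P1, P2), P3), O)`. At each usable site (outgroup fixed, all
#' populations genotyped) with derived frequencies `p1, p2, p3`:
#' `ABBA += (1 - p1) p2 p3`, `BABA += p1 (1 - p2) p3`, and
#' `D = (ABBA - BABA) / (ABBA + BABA)`. A positive D means excess allele
#' sharing between `P2` and `P3`. The standard error is a delete-one
#' jackknife over contiguous blocks of `block_size_bp`, and the result is
#' flagged significant when `|Z| > 3`.
#'
#' @param x A [geno_matrix()].
#' @param P1,P2,P3,O Distinct population labels (O = outgroup).
#' @param block_size_bp Jackknife block length (use the locus length for
#'   simulated data; 5e6 is a typical real-data choice).
#' @return A one-row tibble of class `dstat_result`: `D`, `Z`, `se`,
#'   `abba`, `baba`, `n_sites`, `n_blocks`, `significant`.
#' @export
dstat <- function(x, P1, P2, P3, O, block_size_bp = 5e6) {
  sf <- abba_site_freqs(x, c(P1, P2, P3), O)
  p1 <- sf$freqs[, 1]; p2 <- sf$freqs[, 2]; p3 <- sf$freqs[, 3]
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  blk <- jackknife_blocks(sf$chrom, sf$pos, block_size_bp)
  sums <- rowsum(cbind(abba, baba), blk)
  keep <- rowSums(sums) > 0
  sums <- sums[keep, , drop = FALSE]
  A <- sum(abba); B <- sum(baba)
  stop_if_not(A + B > 0, "D undefined: ABBA + BABA = 0")
  stop_if_not(nrow(sums) >= 3, "need at least 3 non-empty blocks")
  D <- (A - B) / (A + B)
  se <- jackknife_se(sums, function(s) (s[1] - s[2]) / (s[1] + s[2]))
  Z <- if (se > 0) D / se else NA_real_
  out <- tibble(P1 = P1, P2 = P2, P3 = P3, outgroup = O, abba = A,
                baba = B, D = D, se = se, Z = Z,
                n_blocks = nrow(sums), n_sites = length(p1),
                significant = !is.na(Z) && abs(Z) > 3)
  class(out) <- c("dstat_result", class(out))
  out
}

#' Outgroup f3 statistic
#'
#' `f3(O; A, B)`: the mean over sites of `(pO - pA)(pO - pB)`, measuring
#' shared genetic drift between `A` and `B` relative to the outgroup
#' (higher = more allele sharing). Jackknife SE over contiguous blocks.
#'
#' @param x A [geno_matrix()].
#' @param A,B Test population labels.
#' @param O Outgroup label.
#' @param block_size_bp Jackknife block length.
#' @return A one-row tibble of class `f3_result` with `f3`, `se`, `Z`.
#' @export
f3_outgroup <- function(x, A, B, O, block_size_bp = 5e6) {
  stop_if_not(!anyDuplicated(c(A, B, O)) || A == B,
              "outgroup must differ from the test populations")
  pA <- allele_freq(x, A)
  pB <- if (identical(A, B)) pA else allele_freq(x, B)
  pO <- allele_freq(x, O)
  use <- !is.na(pA) & !is.na(pB) & !is.na(pO)
  prod <- (pO - pA) * (pO - pB)
  blk <- jackknife_blocks(x$chrom[use], x$pos[use], block_size_bp)
  sums <- rowsum(cbind(prod[use], 1), blk)
  stop_if_not(nrow(sums) >= 3, "need at least 3 non-empty blocks")
  f3 <- sum(prod[use]) / sum(use)
  se <- jackknife_se(sums, function(s) s[1] / s[2])
  out <- tibble(A = A, B = B, outgroup = O, f3 = f3, se = se,
                Z = if (se > 0) f3 / se else NA_real_,
                n_blocks = nrow(sums), n_sites = sum(use))
  class(out) <- c("f3_result", class(out))
  out
}

#' Sliding-window fd introgression scan
#'
#' Windowed fd of Martin et al.: in SNP windows of `window_snps` sites
#' stepped by `step_snps`, `fd = (ABBA - BABA) / (ABBA_D - BABA_D)` where
#' the denominator replaces the donor frequency by `pD = max(p2, p3)` in
#' both donor roles. Windows with `D < 0` or a non-positive denominator
#' are set to 0 (the statistic estimates the admixture fraction only in
#' the donor direction). Coordinates span the first through last SNP of
#' the window (0-based half-open).
#'
#' @inheritParams dstat
#' @param window_snps,step_snps Window size and step in usable SNPs.
#' @return A window-track tibble (class `window_track`): `chrom`, `start`,
#'   `end`, `stat = "fd"`, `value`, `n_sites`.
#' @export
fd_windows <- function(x, P1, P2, P3, O, window_snps = 100,
                       step_snps = 50) {
  sf <- abba_site_freqs(x, c(P1, P2, P3), O)
  p1 <- sf$freqs[, 1]; p2 <- sf$freqs[, 2]; p3 <- sf$freqs[, 3]
  pD <- pmax(p2, p3)
  abba <- (1 - p1) * p2 * p3
  baba <- p1 * (1 - p2) * p3
  abba_d <- (1 - p1) * pD * pD
  baba_d <- p1 * (1 - pD) * pD
  out <- list()
  for (ch in unique(sf$chrom)) {
    i <- which(sf$chrom == ch)
    S <- length(i)
    if (S < window_snps) next
    starts <- seq(1, S - window_snps + 1, by = step_snps)
    cs <- function(v) c(0, cumsum(v[i]))
    ca <- cs(abba); cb <- cs(baba); cad <- cs(abba_d); cbd <- cs(baba_d)
    ends <- starts + window_snps - 1
    num <- (ca[ends + 1] - ca[starts]) - (cb[ends + 1] - cb[starts])
    den <- (cad[ends + 1] - cad[starts]) - (cbd[ends + 1] - cbd[starts])
    fd <- pmin(ifelse(den > 0 & num > 0, num / den, 0), 1)
    out[[ch]] <- tibble(chrom = ch, start = sf$pos[i[starts]],
                        end = sf$pos[i[ends]] + 1L, stat = "fd",
                        value = fd, n_sites = window_snps)
  }
  stop_if_not(length(out) > 0, "no complete window")
  as_window_track(dplyr::bind_rows(out))
}

as_window_track <- function(tab) {
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  class(tab) <- c("window_track", class(tab))
  tab
}

#' Top-fraction windows and interval overlap
#'
#' `top_fraction_windows()` selects the `ceiling(q * N)` highest-valued
#' windows of a track; `window_overlap()` reports the fraction of `A`'s
#' windows sharing at least 1 bp with any window in `B`.
#'
#' @param track A window-track tibble.
#' @param q Fraction in (0, 1].
#' @return `top_fraction_windows()`: the selected rows (still a window
#'   track). `window_overlap()`: a scalar fraction.
#' @export
top_fraction_windows <- function(track, q = 0.01) {
  stop_if_not(q > 0 && q <= 1, "q must be in (0, 1]")
  stop_if_not(nrow(track) > 0, "empty track")
  n <- ceiling(q * nrow(track))
  as_window_track(dplyr::slice_max(track, .data$value, n = n,
                                   with_ties = FALSE))
}

#' @rdname top_fraction_windows
#' @param A,B Window-track tibbles (or any tibble with `chrom`, `start`,
#'   `end`).
#' @export
window_overlap <- function(A, B) {
  stop_if_not(nrow(A) > 0, "A has no windows")
  hit <- vapply(seq_len(nrow(A)), function(i) {
    any(B$chrom == A$chrom[i] & B$start < A$end[i] & B$end > A$start[i])
  }, logical(1))
  mean(hit)
}

#' Topology weighting over true genealogies
#'
#' For each locus genealogy, repeatedly samples one haplotype per group
#' and classifies the rooted triple of ingroup taxa by which pair
#' coalesces most recently (the outgroup only roots the quartet). Weights
#' sum to one per locus; the genome-wide weight is the locus-length
#' weighted mean.
#'
#' @param genealogies List of `genealogy` objects (from
#'   [sim_genotypes()]).
#' @param groups Named list of three ingroup taxa mapping group name to
#'   population label(s).
#' @param outgroup Outgroup population label (must not appear in
#'   `groups`).
#' @param n_samples Haplotype quartets sampled per locus.
#' @param seed Integer seed.
#' @return A list with `weights` (tibble: one row per topology,
#'   genome-wide weight) and `per_locus` (tibble: locus, topology,
#'   weight).
#' @export
topology_weights <- function(genealogies, groups, outgroup,
                             n_samples = 100, seed = 1) {
  stop_if_not(length(groups) == 3, "exactly three ingroup groups")
  stop_if_not(!outgroup %in% unlist(groups),
              "outgroup cannot be an ingroup")
  gnames <- names(groups)
  topo_labels <- c(
    sprintf("((%s,%s),%s)", gnames[1], gnames[2], gnames[3]),
    sprintf("((%s,%s),%s)", gnames[1], gnames[3], gnames[2]),
    sprintf("((%s,%s),%s)", gnames[2], gnames[3], gnames[1])
  )
  per <- purrr::map_dfr(seq_along(genealogies), function(j) {
    g <- genealogies[[j]]
    leaves <- lapply(groups, function(pp) {
      idx <- which(g$leaf_pops %in% pp) - 1L
      stop_if_not(length(idx) > 0, "a group has zero haplotypes")
      idx
    })
    cnt <- cpp_topo_counts(as.integer(g$parent), as.double(g$time),
                           leaves[[1]], leaves[[2]], leaves[[3]],
                           as.integer(n_samples),
                           as.double(mix_seed(seed, j)))
    tibble(locus = j, topology = topo_labels,
           weight = as.numeric(cnt) / n_samples,
           length = g$end - g$start)
  })
  w <- per |>
    dplyr::group_by(.data$topology) |>
    dplyr::summarise(weight = sum(.data$weight * .data$length) /
                       sum(.data$length), .groups = "drop")
  list(weights = w, per_locus = per)
}
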