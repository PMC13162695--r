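# Window grid anchored at position 0, half-open [start, end).
window_grid <- function(max_pos, window_bp, step_bp) {
  stop_if_not(window_bp > 0 && step_bp > 0,
              "window and step must be positive")
  starts <- seq(0, max(0, max_pos), by = step_bp)
  tibble(start = starts, end = starts + window_bp)
}

# Sum per-site values over a sliding window grid via cumulative sums.
window_sums <- function(pos, vals, grid) {
  o <- order(pos)
  pos <- pos[o]
  vals <- vals[o]
  cs <- c(0, cumsum(vals))
  lo <- findInterval(grid$start - 0.5, pos) + 1L
  hi <- findInterval(grid$end - 0.5, pos)
  list(sum = cs[hi + 1L] - cs[lo], n = hi - lo + 1L)
}

#' Windowed nucleotide diversity
#'
#' Mean pairwise difference per site in sliding windows:
#' `sum over sites of 2 p (1 - p) n / (n - 1)` divided by the window
#' length, with `n` the haploid sample size. Empty windows are reported
#' with value 0.
#'
#' @param x A [geno_matrix()].
#' @param pop Population label.
#' @param window_bp,step_bp Window size and step in bp.
#' @return A window-track tibble with `stat = "pi"`.
#' @export
windowed_pi <- function(x, pop, window_bp = 50000, step_bp = 20000) {
  rows <- hap_rows(x, pop)
  g <- x$G[rows, , drop = FALSE]
  n <- colSums(!is.na(g))
  p <- colMeans(g, na.rm = TRUE)
  site_pi <- ifelse(n > 1, 2 * p * (1 - p) * n / (n - 1), 0)
  out <- purrr::map_dfr(unique(x$chrom), function(ch) {
    i <- x$chrom == ch
    grid <- window_grid(max(x$pos[i]), window_bp, step_bp)
    ws <- window_sums(x$pos[i], site_pi[i], grid)
    tibble(chrom = ch, start = grid$start, end = grid$end, stat = "pi",
           value = ws$sum / window_bp, n_sites = ws$n)
  })
  as_window_track(out)
}

# Weir & Cockerham (1984) per-site variance components for two
# populations of diploid genotypes (a: among populations, b: among
# individuals within populations, c: within individuals).
wc_components <- function(x, popA, popB) {
  per_pop <- function(pop) {
    rows <- hap_rows(x, pop)
    h1 <- x$G[rows[seq(1, length(rows), 2)], , drop = FALSE]
    h2 <- x$G[rows[seq(2, length(rows), 2)], , drop = FALSE]
    gsum <- h1 + h2
    n <- colSums(!is.na(gsum))
    p <- colMeans(gsum, na.rm = TRUE) / 2
    h <- colMeans(gsum == 1L, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  A <- per_pop(popA)
  B <- per_pop(popB)
  r <- 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Windowed Weir-Cockerham Fst
#'
#' Per-site Weir & Cockerham (1984) variance components summed over
#' windows: `Fst = sum(a) / sum(a + b + c)`. Windows with a zero
#' denominator are dropped.
#'
#' @param x A [geno_matrix()].
#' @param popA,popB Population labels (each with at least 2 haplotypes).
#' @param window_bp,step_bp Window size and step in bp.
#' @return A window-track tibble with `stat = "fst"`.
#' @export
windowed_fst <- function(x, popA, popB, window_bp = 50000,
                         step_bp = 20000) {
  stop_if_not(length(hap_rows(x, popA)) >= 2 &&
                length(hap_rows(x, popB)) >= 2,
              "each population needs at least 2 haplotypes")
  wc <- wc_components(x, popA, popB)
  out <- purrr::map_dfr(unique(x$chrom), function(ch) {
    i <- x$chrom == ch
    grid <- window_grid(max(x$pos[i]), window_bp, step_bp)
    wa <- window_sums(x$pos[i], wc$a[i], grid)
    wabc <- window_sums(x$pos[i], (wc$a + wc$b + wc$c)[i], grid)
    tibble(chrom = ch, start = grid$start, end = grid$end, stat = "fst",
           value = ifelse(wabc$sum != 0, wa$sum / wabc$sum, NA_real_),
           n_sites = wa$n)
  })
  as_window_track(dplyr::filter(out, !is.na(.data$value)))
}

#' Log10 diversity ratio between two tracks
#'
#' `log10(pi_wild / pi_target)` per window on an identical grid; windows
#' where either diversity is zero are dropped (reduced-diversity outliers
#' in the target push the ratio up).
#'
#' @param track_wild,track_target `windowed_pi()` tracks on the same
#'   grid.
#' @return A window-track tibble with `stat = "pi_ratio"`.
#' @export
pi_ratio <- function(track_wild, track_target) {
  stop_if_not(identical(track_wild[c("chrom", "start", "end")],
                        track_target[c("chrom", "start", "end")]),
              "window grids differ")
  out <- tibble(chrom = track_wild$chrom, start = track_wild$start,
                end = track_wild$end, stat = "pi_ratio",
                value = log10(track_wild$value / track_target$value),
                n_sites = track_wild$n_sites + track_target$n_sites)
  as_window_track(dplyr::filter(out, is.finite(.data$value)))
}

#' Cross-population extended haplotype homozygosity (XP-EHH)
#'
#' For each core site, haplotype homozygosity is computed over windows
#' extending outward in both directions per population (EHH = 1 at the
#' core by definition), integrated over physical distance by the
#' trapezoid rule until EHH drops below `min_ehh` or the gap between
#' adjacent SNPs exceeds `max_gap_bp`. The raw score
#' `ln(iHH_A / iHH_B)` is standardized genome-wide to mean 0 and unit
#' variance; positive scores mean longer haplotypes (a harder sweep) in
#' `popA`.
#'
#' @param x A [geno_matrix()] with phased haplotypes and no missing data.
#' @param popA,popB Population labels.
#' @param min_ehh EHH truncation threshold.
#' @param max_gap_bp Maximum SNP gap before truncation.
#' @return A site-resolution window-track tibble with `stat = "xpehh"`
#'   (`start` = site position, `end` = position + 1).
#' @export
xpehh <- function(x, popA, popB, min_ehh = 0.05, max_gap_bp = 200000) {
  gA <- x$G[hap_rows(x, popA), , drop = FALSE]
  gB <- x$G[hap_rows(x, popB), , drop = FALSE]
  stop_if_not(!anyNA(gA) && !anyNA(gB),
              "XP-EHH requires complete phased haplotypes")
  raw <- rep(NA_real_, n_sites(x))
  for (ch in unique(x$chrom)) {
    i <- which(x$chrom == ch)
    poly <- colSums(gA[, i, drop = FALSE]) + colSums(gB[, i, drop = FALSE])
    n_tot <- nrow(gA) + nrow(gB)
    ok <- poly > 0 & poly < n_tot
    r <- cpp_xpehh_raw(gA[, i, drop = FALSE], gB[, i, drop = FALSE],
                       as.double(x$pos[i]), min_ehh, max_gap_bp)
    r[!ok] <- NA_real_
    raw[i] <- r
  }
  mu <- mean(raw, na.rm = TRUE)
  sdv <- stats::sd(raw, na.rm = TRUE)
  keep <- !is.na(raw)
  out <- tibble(chrom = x$chrom[keep], start = x$pos[keep],
                end = x$pos[keep] + 1L, stat = "xpehh",
                value = (raw[keep] - mu) / sdv, n_sites = 1L)
  as_window_track(out)
}

# Merge overlapping/adjacent intervals within chromosomes.
merge_intervals <- function(tab) {
  tab <- dplyr::arrange(tab, .data$chrom, .data$start)
  out <- list()
  for (ch in unique(tab$chrom)) {
    t <- tab[tab$chrom == ch, ]
    start <- t$start[1]; end <- t$end[1]
    res <- list()
    for (i in seq_len(nrow(t))[-1]) {
      if (t$start[i] <= end) {
        end <- max(end, t$end[i])
      } else {
        res[[length(res) + 1]] <- c(start, end)
        start <- t$start[i]; end <- t$end[i]
      }
    }
    res[[length(res) + 1]] <- c(start, end)
    m <- do.call(rbind, res)
    out[[ch]] <- tibble(chrom = ch, start = m[, 1], end = m[, 2])
  }
  dplyr::bind_rows(out)
}

# Intersection of two merged interval sets.
intersect_intervals <- function(A, B) {
  out <- list()
  for (ch in intersect(unique(A$chrom), unique(B$chrom))) {
    a <- A[A$chrom == ch, ]; b <- B[B$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      s <- pmax(a$start[i], b$start)
      e <- pmin(a$end[i], b$end)
      keep <- s < e
      if (any(keep)) {
        out[[length(out) + 1]] <- tibble(chrom = ch, start = s[keep],
                                         end = e[keep])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  merge_intervals(dplyr::bind_rows(out))
}

#' Three-statistic selective-sweep calls
#'
#' Takes the top-`q` windows of each statistic (site-level XP-EHH scores
#' are first aggregated to the Fst window grid by their maximum), merges
#' each top set into intervals, and intersects the three sets; genomic
#' regions in the top tail of all three statistics are the sweep calls.
#' The result is independent of the order of the tracks.
#'
#' @param tracks Named list with elements `fst`, `pi_ratio` and `xpehh`
#'   (window tracks; `xpehh` may be site-resolution).
#' @param q Top fraction per statistic (default 0.05).
#' @return A `sweep_calls` tibble of candidate regions (`chrom`, `start`,
#'   `end`) with the per-statistic top thresholds as attributes.
#' @export
intersect_top <- function(tracks, q = 0.05) {
  stop_if_not(all(c("fst", "pi_ratio", "xpehh") %in% names(tracks)),
              "tracks must contain fst, pi_ratio and xpehh")
  for (t in tracks) stop_if_not(nrow(t) > 0, "empty track")
  grid <- tracks$fst[c("chrom", "start", "end")]
  xp <- tracks$xpehh
  agg <- vapply(seq_len(nrow(grid)), function(i) {
    v <- xp$value[xp$chrom == grid$chrom[i] & xp$start < grid$end[i] &
                    xp$end > grid$start[i]]
    if (length(v)) max(v) else NA_real_
  }, numeric(1))
  xp_track <- as_window_track(
    tibble(chrom = grid$chrom, start = grid$start, end = grid$end,
           stat = "xpehh", value = agg, n_sites = NA_integer_) |>
      dplyr::filter(!is.na(.data$value)))
  tops <- list(fst = top_fraction_windows(tracks$fst, q),
               pi_ratio = top_fraction_windows(tracks$pi_ratio, q),
               xpehh = top_fraction_windows(xp_track, q))
  thresholds <- vapply(tops, function(t) min(t$value), numeric(1))
  merged <- lapply(tops, function(t) merge_intervals(t))
  calls <- Reduce(intersect_intervals, merged)
  calls$stats <- if (nrow(calls)) list(c("fst", "pi_ratio", "xpehh")) else list()
  attr(calls, "thresholds") <- thresholds
  attr(calls, "q") <- q
  class(calls) <- c("sweep_calls", class(calls))
  calls
}

#' Map candidate regions to overlapping genes
#'
#' Genes overlapping any region by at least 1 bp (half-open coordinates),
#' de-duplicated.
#'
#' @param regions A tibble with `chrom`, `start`, `end`.
#' @param annotation A data frame with columns `chrom`, `start`, `end`,
#'   `gene_id` (0-based half-open).
#' @return Character vector of unique gene ids.
#' @export
map_regions_to_genes <- function(regions, annotation) {
  stop_if_not(all(c("chrom", "start", "end", "gene_id") %in%
                    names(annotation)),
              "annotation needs chrom, start, end, gene_id")
  if (nrow(regions) == 0) return(character())
  ann <- tibble::as_tibble(annotation)
  hit <- vapply(seq_len(nrow(ann)), function(i) {
    any(regions$chrom == ann$chrom[i] & regions$start < ann$end[i] &
          regions$end > ann$start[i])
  }, logical(1))
  unique(ann$gene_id[hit])
}
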