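#' Built-in simulation fixtures
#'
#' Named, fully documented synthetic scenarios with known truth, standing in
#' for resequencing panels. Each fixture records every generating parameter
#' in its `meta` element. SFS fixtures (`tt_model*`, `x_model*`) are
#' simulated in snp mode (unlinked sites); scan fixtures are simulated in
#' sequence mode (linked blocks).
#'
#' * `tt_model1`..`tt_model5`: data generated under the corresponding
#'   origin scenario for `TT` (see [get_template()]), with an outgroup
#'   (`CEB`) and the two source groups sampled.
#' * `x_model1`..`x_model5`: data for a derived lineage `X` under the
#'   corresponding scenario, on top of `TT`'s admixed origin.
#' * `no_geneflow_quartet` / `geneflow_quartet`: four populations
#'   `P1, P2, P3, OUT` with topology `(((P1, P2), P3), OUT)` and zero
#'   migration; the gene-flow variant adds a pulse moving a fraction
#'   `alpha = 0.3` of `P2`'s ancestry to `P3` (donor `P3`, recipient `P2`).
#' * `introgressed_tract`: the quartet background with a contiguous run of
#'   loci re-simulated under a strong recent pulse (`alpha = 0.8`); the
#'   true tract coordinates are in `meta`.
#' * `hard_sweep` / `neutral_pair`: two diverged populations `TGT`
#'   (target) and `REF`; the sweep variant overwrites a focal region in
#'   `TGT` with a single core haplotype at frequency 0.9.
#'
#' @param name Fixture name (see Details).
#' @param seed Integer seed.
#' @param n_snps Number of unlinked sites for snp-mode fixtures.
#' @param n_loci,locus_length Block structure for sequence-mode fixtures
#'   (defaults depend on the fixture).
#'
#' @return A `coal_fixture` (a [sim_genotypes()] result with an extra
#'   `meta` list and `name`); the genotype matrix is in `$geno`, true
#'   genealogies in `$genealogies`.
#' @export
#' @examples
#' fx <- make_fixture("no_geneflow_quartet", seed = 7)
#' fx$meta$topology
make_fixture <- function(name, seed, n_snps = 20000,
                         n_loci = NULL, locus_length = NULL) {
  known <- c(paste0("tt_model", 1:5), paste0("x_model", 1:5),
             "no_geneflow_quartet", "geneflow_quartet",
             "introgressed_tract", "hard_sweep", "neutral_pair")
  stop_if_not(name %in% known, paste0("unknown fixture name: ", name))
  bg <- scan_background()
  if (grepl("^tt_model", name)) {
    return(sfs_fixture(name, sub("tt_model", "TT", name), seed, n_snps, bg))
  }
  if (grepl("^x_model", name)) {
    return(sfs_fixture(name, sub("x_model", "X", name), seed, n_snps, bg))
  }
  switch(
    name,
    no_geneflow_quartet = quartet_fixture(name, seed, alpha = 0,
                                          n_loci %||% 200,
                                          locus_length %||% 5e4),
    geneflow_quartet = quartet_fixture(name, seed, alpha = 0.3,
                                       n_loci %||% 200,
                                       locus_length %||% 5e4),
    introgressed_tract = tract_fixture(name, seed, n_loci %||% 400,
                                       locus_length %||% 25000),
    hard_sweep = pair_fixture(name, seed, sweep = TRUE, n_loci %||% 200,
                              locus_length %||% 5e4),
    neutral_pair = pair_fixture(name, seed, sweep = FALSE, n_loci %||% 200,
                                locus_length %||% 5e4)
  )
}

# True generating parameters for each scenario template.
fixture_truth <- function(model_id, bg) {
  switch(model_id,
    TT1 = c(T_TT = bg$T_tt, Ne_TT = bg$Ne_TT),
    TT2 = c(T_TT = bg$T_tt, Ne_TT = bg$Ne_TT),
    TT3 = c(T_TT = bg$T_tt, Ne_TT = bg$Ne_TT, m = 5e-5),
    TT4 = c(T_TT = bg$T_tt, Ne_TT = bg$Ne_TT, m = 5e-5),
    TT5 = c(T_TT = bg$T_tt, Ne_TT = bg$Ne_TT, alpha = bg$alpha_tt),
    X1 = c(T_X = bg$T_x, Ne_X = bg$Ne_X),
    X2 = c(T_X = 15000, Ne_X = bg$Ne_X, alpha_X = 0.5),
    X3 = c(T_X = bg$T_x, Ne_X = bg$Ne_X),
    X4 = c(T_X = bg$T_x, Ne_X = bg$Ne_X),
    X5 = c(T_X = 3000, Ne_X = bg$Ne_X, alpha_X = 0.5)
  )
}

# Diploid sample sizes emulating a resequencing panel: outgroup pair,
# larger wild-group panels, smaller focal groups.
fixture_samples <- function(model_id) {
  if (grepl("^TT", model_id)) {
    c(CEB = 2, NAW = 20, SAW = 25, TT = 10)
  } else {
    c(CEB = 2, NAW = 20, SAW = 25, TT = 10, X = 7)
  }
}

sfs_fixture <- function(name, model_id, seed, n_snps, bg) {
  tpl <- get_template(model_id)
  truth <- fixture_truth(model_id, bg)
  model <- tpl$build(truth)
  samples <- fixture_samples(model_id)
  sim <- sim_genotypes(model, samples, n_loci = n_snps,
                       locus_length = 2000, seed = seed, mode = "snp")
  as_fixture(sim, name, seed, meta = list(
    model_id = model_id, truth = truth, samples = samples,
    background = bg))
}

quartet_model <- function(alpha, t_pulse = 1000, Ne = 1e4) {
  ev <- tibble(
    time = c(4000, 16000, 40000), kind = "split",
    pop = c("P2", "P3", "OUT"), dest = "P1", param = NA
  )
  if (alpha > 0) {
    ev <- dplyr::bind_rows(
      tibble(time = t_pulse, kind = "pulse", pop = "P2", dest = "P3",
             param = alpha), ev)
  }
  demog_model(tibble(name = c("P1", "P2", "P3", "OUT"), Ne = Ne), ev)
}

quartet_fixture <- function(name, seed, alpha, n_loci, locus_length) {
  model <- quartet_model(alpha)
  samples <- c(P1 = 5, P2 = 5, P3 = 5, OUT = 2)
  sim <- sim_genotypes(model, samples, n_loci, locus_length, seed,
                       mode = "sequence")
  as_fixture(sim, name, seed, meta = list(
    topology = "(((P1,P2),P3),OUT)", alpha = alpha,
    t_pulse = if (alpha > 0) 1000 else NA, Ne = 1e4,
    splits = c(P1P2 = 4000, P3 = 16000, OUT = 40000), samples = samples))
}

# Replace a run of loci in a background simulation with loci simulated
# under another model (same samples), re-offsetting positions.
splice_loci <- function(bg_sim, tract_sim, at) {
  L <- bg_sim$loci$end[1] - bg_sim$loci$start[1]
  S_bg <- bg_sim
  keep_cols <- function(sim, loci_idx) {
    lapply(loci_idx, function(j) {
      sel <- sim$geno$pos >= sim$loci$start[j] & sim$geno$pos < sim$loci$end[j]
      list(G = sim$geno$G[, sel, drop = FALSE],
           pos = sim$geno$pos[sel] - sim$loci$start[j])
    })
  }
  n_loci <- nrow(bg_sim$loci)
  bg_cols <- keep_cols(bg_sim, seq_len(n_loci))
  tr_cols <- keep_cols(tract_sim, seq_along(at))
  pieces <- bg_cols
  pieces[at] <- tr_cols
  genealogies <- bg_sim$genealogies
  for (i in seq_along(at)) {
    g <- tract_sim$genealogies[[i]]
    g$start <- (at[i] - 1) * L
    g$end <- at[i] * L
    genealogies[[at[i]]] <- g
  }
  G <- do.call(cbind, lapply(pieces, `[[`, "G"))
  pos <- unlist(lapply(seq_len(n_loci), function(j)
    pieces[[j]]$pos + (j - 1) * L))
  geno <- geno_matrix(G, bg_sim$geno$sample_ids, bg_sim$geno$pops,
                      chrom = rep("1", length(pos)), pos = pos)
  out <- bg_sim
  out$geno <- geno
  out$genealogies <- genealogies
  out
}

tract_fixture <- function(name, seed, n_loci, locus_length) {
  alpha <- 0.8
  t_pulse <- 500
  samples <- c(P1 = 5, P2 = 5, P3 = 5, OUT = 2)
  tract <- seq(floor(n_loci * 0.4) + 1, floor(n_loci * 0.6))
  bg_sim <- sim_genotypes(quartet_model(0), samples, n_loci, locus_length,
                          seed = mix_seed(seed, 1), mode = "sequence")
  tr_sim <- sim_genotypes(quartet_model(alpha, t_pulse = t_pulse), samples,
                          length(tract), locus_length,
                          seed = mix_seed(seed, 2), mode = "sequence")
  sim <- splice_loci(bg_sim, tr_sim, tract)
  as_fixture(sim, name, seed, meta = list(
    topology = "(((P1,P2),P3),OUT)", alpha = alpha, t_pulse = t_pulse,
    tract_loci = range(tract),
    tract_start = (tract[1] - 1) * locus_length,
    tract_end = tract[length(tract)] * locus_length,
    samples = samples))
}

pair_fixture <- function(name, seed, sweep, n_loci, locus_length) {
  model <- demog_model(
    tibble(name = c("TGT", "REF"), Ne = 1e4),
    tibble(time = 3000, kind = "split", pop = "TGT", dest = "REF",
           param = NA))
  samples <- c(TGT = 15, REF = 15)
  sim <- sim_genotypes(model, samples, n_loci, locus_length, seed,
                       mode = "sequence")
  meta <- list(split_time = 3000, Ne = 1e4, samples = samples,
               swept = sweep)
  if (sweep) {
    lo <- floor(n_loci * 0.45) * locus_length
    hi <- floor(n_loci * 0.5) * locus_length
    freq <- 0.9
    rows <- hap_rows(sim$geno, "TGT")
    carriers <- rows[seq_len(ceiling(freq * length(rows)))]
    cols <- which(sim$geno$pos >= lo & sim$geno$pos < hi)
    core <- sim$geno$G[carriers[1], cols]
    sim$geno$G[carriers, cols] <-
      matrix(core, nrow = length(carriers), ncol = length(cols),
             byrow = TRUE)
    meta$sweep_start <- lo
    meta$sweep_end <- hi
    meta$core_freq <- freq
  }
  as_fixture(sim, name, seed, meta = meta)
}

as_fixture <- function(sim, name, seed, meta) {
  sim$name <- name
  sim$seed <- seed
  sim$meta <- meta
  class(sim) <- c("coal_fixture", class(sim))
  sim
}

#' @export
print.coal_fixture <- function(x, ...) {
  cat("<coal_fixture> ", x$name, " (seed ", x$seed, ")\n", sep = "")
  NextMethod()
}
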