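---
title: "Testing demographic origin scenarios and scanning for introgression and sweeps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing demographic origin scenarios and scanning for introgression and sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coalscan)
```

## The problem

High-altitude livestock populations often carry mixed ancestry: a focal
population (called `TT` throughout this package) may have been founded by
admixture between a northern (`NAW`) and a southern (`SAW`) wild group,
with further lineages (`X`) budding off afterwards, and may additionally
have received genes from a distant western Eurasian lineage (`WEW`). An
outgroup species (`CEB`) roots everything and supplies ancestral alleles.
`coalscan` implements the complete inference chain used to interrogate
such a system from genome-wide SNP data:

1. a seeded structured-coalescent simulator (splits, bottlenecks,
   admixture pulses, continuous unidirectional migration) that supplies
   both synthetic study panels and the Monte-Carlo engine for expected
   spectra;
2. multidimensional site frequency spectrum (SFS) construction with
   outgroup polarization, neutral-site filters, folding and
   hypergeometric projection;
3. composite-likelihood fitting of ten competing origin scenarios with
   multi-run optimization, delta-likelihood / AIC comparison, and
   parametric bootstrap intervals;
4. allele-frequency introgression statistics (Patterson's D with
   block-jackknife Z scores, outgroup f3, windowed fd, topology
   weighting); and
5. a three-statistic selective-sweep scan (windowed Weir–Cockerham Fst,
   log10 diversity ratio, XP-EHH) with top-quantile intersection and
   region-to-gene mapping.

## The composite-likelihood model

Sites are treated as unlinked. For populations with haploid sample sizes
$n_1, \dots, n_P$, every polymorphic site falls into a cell of the joint
SFS indexed by its derived-allele counts; a demographic scenario with
parameters $\theta$ implies cell probabilities $p_i(\theta)$, estimated
by simulating `n_sims` single-SNP genealogies (one mutation per
genealogy, on a branch drawn proportional to branch length). With
observed cell counts $m_i$ over $S$ sites, the composite log-likelihood
is

$$\log_{10} L(\theta) = \sum_i m_i \log_{10} p_i(\theta),$$

reported against the saturated bound
$\log_{10} L_{obs} = \sum_i m_i \log_{10}(m_i/S)$. Model fit is measured
by `delta = lnL_obs - lnL_est` (log10 units; smaller is better) and by
`AIC = 2k - 2\ln(10)\,lnL_{est}`. Fixed-ancestral and fixed-derived
corner cells are masked: the likelihood conditions on polymorphism.
Cells with zero simulated mass are floored at `1/(10 n_sims)` and the
tensor renormalized, so observed-but-unsimulated cells penalize the fit
without producing infinities.

The ten scenario templates share a fixed deep structure (outgroup
split, western Eurasian split, `NAW`/`SAW` divergence) so likelihoods
are comparable across scenarios; only parameters of the focal lineage
are free. Defaults: `Ne` bounds `1e2`–`1e6`, time bounds 10–1e5
generations, migration rates `1e-8`–`1e-2` per lineage per generation
(all searched in log10 space), admixture proportions in [0, 1]. The
scaling constants are a mutation rate of 3.6e-9 per site per generation
and a generation time of 3 years.

### Gene flow after divergence: why continuous migration

The "split with subsequent gene flow" scenarios (`TT3`/`TT4`) model the
flow as a continuous per-generation migration rate active between the
founding split and the present. An instantaneous pulse parameterization
was evaluated first and rejected: a pulse placed at the split time is
mathematically identical to the admixture-founding scenario (`TT5`), so
the pulse models strictly nest `TT5` and their maximized likelihood can
never fall below it — model choice then hinges on optimizer noise
rather than on the data. Continuous migration spreads coalescence
opportunities over the whole interval, is not nested with instantaneous
founding admixture, and is the conventional way gene flow after
divergence is parameterized in SFS fitting practice. `TT1`/`TT2` remain
boundary cases of `TT5` (`alpha` = 0 or 1), which is harmless because
the generating truth sits in the interior.

### Optimization

The objective is a Monte-Carlo estimate, so the optimizer is built
around two ideas: *staged precision* and *common random numbers* (CRN).
Each of `n_runs` runs starts from a random in-bounds vector and performs
`n_cycles_initial` cycles (one expected-SFS estimation per cycle,
driving a Nelder–Mead simplex with explicit initial steps: 0.5 log10
units coarse, 0.25 in the polish stage, smaller for proportions) at the
reduced `n_sims_initial`. All runs are then scored at full `n_sims`
under one seed shared by every run *and* every competing scenario, and
the best `n_polish` runs continue for the remaining cycles at full
precision under that shared seed. Optimizing a fixed-seed realization
makes within-stage comparisons exact and removes the re-estimation
noise that otherwise stalls simplex descent. Finally the best run is
re-evaluated with `n_sims_final` simulations under an independent
shared seed; that refined, common-condition value is the headline
`lnL_est` used for scenario ranking, so cross-model deltas are not
driven by Monte-Carlo luck. Ranking is by ascending delta, with AIC
reported alongside and exact ties broken toward fewer parameters.

Package defaults mirror common practice (25 initial cycles, 65 total,
100,000 simulations, 100 runs are typical at production scale); the
recovery studies in the test suite and acceptance script run at desk
scale: 20,000 observed sites, 3 diploids per population, 55 coarse
cycles at 1,000 simulations, 120 polish cycles at 10,000 simulations
for the two leading runs, and a 200,000-simulation refinement. At these
sizes one five-scenario comparison takes roughly 20 s on one CPU.

### Bootstrap

Confidence intervals are parametric: `S` sites are resampled from the
expected spectrum at the best fit, each replicate refitted, and
percentile intervals reported. The study's published pipeline does not
state whether its spectrum bootstrap was parametric or block-resampled;
parametric resampling matches the unlinked-sites likelihood exactly.

## The simulator and the synthetic study conditions

The simulator draws each locus as an independent non-recombining
genealogy in continuous time (coalescence rate $k(k-1)/(4N_e)$ per
population, diploid scaling), with events applied backward in time:
splits merge populations rootward, admixture pulses reassign each
lineage with probability `alpha`, sizes change instantaneously, and
continuous migration moves single lineages at an exponential rate.
Waiting times use a single rescaled exponential per realized event
(memorylessness), so demographic events consume no randomness and
models differing only by no-op events are byte-identical under the same
seed. Mutations are infinite-sites. In `sequence` mode, mutation counts
are Poisson with rate `mu * locus_length` per branch-generation; in
`snp` mode each locus yields exactly one segregating site on a branch
drawn proportional to branch length — the zero-rate limit of
"resample loci without mutations", and the same convention as the
expected-SFS engine, so observed and expected spectra in the fitting
studies share one sampling scheme. A subtlety motivates this choice:
one-site-per-tree sampling follows $E[\ell_i/\ell_{tot}]$, which
deviates from the neutral $1/i$ shape by about 2% per class. The $1/i$
calibration checks therefore use `sequence` mode with small loci
(about 0.2 expected SNPs per locus), where class frequencies are exactly
proportional to $E[\ell_i]$ and tree sharing between sites is
negligible.

The built-in fixtures define the package's study conditions once:

* deep structure: `CEB` splits at 100,000 generations, `WEW` at 33,000,
  `NAW`/`SAW` at 20,000, with sizes 5,000–30,000 chosen so the southern
  group is the most diverse, mirroring the diversity ranking seen in
  wild-boar panels;
* `TT` founded 10,000 generations ago (about 30 kya at 3 years per
  generation, matching the timescale at which the focal population's
  trajectory separates) by an even admixture pulse (`alpha` = 0.5) with
  a bottleneck size of 8,000; derived lineages split 5,000 generations
  ago;
* panels of 2 outgroup, 20 + 25 wild and 10 + 7 focal diploids for the
  fixture VCFs (roughly the published panel sizes), with SFS fitting
  run on 3 diploids per population — the analysis-scale analogue of the
  study's down-sampling to five individuals per group;
* the introgression quartet `(((P1,P2),P3),OUT)` with splits at 4,000 /
  16,000 / 40,000 generations and Ne 10,000. The internal branch is
  long enough that a recent pulse of `alpha` = 0.3 from `P3` into `P2`
  is a genuinely strong signal (near-complete power at 200 jackknife
  blocks) while the no-flow variant stays within the nominal |Z| > 3
  false-positive rate;
* an introgressed tract (the middle 20% of loci re-simulated with a
  strong recent pulse, `alpha` = 0.8) and a hard sweep (a 500-kb region
  overwritten with one core haplotype at frequency 0.9 in the target
  population) for the window-scan checks.

What these fixtures emulate: block-scale linkage (loci are
non-recombining and independent of each other), phased complete
genotypes, known ancestral states by construction. What they do not
emulate: within-block recombination, sequencing and phasing error,
missing data, non-equilibrium base composition, or reference bias.
Passing tests therefore demonstrate the statistical machinery under
clean conditions, not robustness to real-data artifacts.

## SFS construction choices

* "Confidently inferred ancestral" is operationalized as: all
  non-missing outgroup haplotypes agree; sites with outgroup
  polymorphism or missing outgroup data are dropped; surviving sites
  are flipped so allele 1 is derived.
* The neutral-site filters are intergenic location, non-CpG, zero
  missingness, and 2-kb spacing enforced greedily left-to-right (the
  first passing site is kept, the next kept site must be at least 2 kb
  away) — the thinning algorithm is unspecified in common pipelines and
  greedy scanning is deterministic and order-independent for sorted
  input.
* Folding maps each cell onto its complement when the total derived
  count exceeds half the haploid total; exact-half cells are assigned
  once to the lexicographically smaller member of the pair, so totals
  are conserved.
* Projection is the hypergeometric expectation (sampling without
  replacement), applied axis by axis.

## Introgression and sweep statistics

D uses the frequency estimator with the outgroup fixing the ancestral
state: `ABBA = (1-p1) p2 p3`, `BABA = p1 (1-p2) p3`, summed over sites;
outgroup-polymorphic sites are skipped. Standard errors are delete-one
block jackknives over contiguous blocks (one block per simulated locus;
about 5 Mb is the sensible real-data default), with |Z| > 3 flagged.
One identity worth noting: swapping `P1` and `P2` negates D exactly,
and `p1 = p2` at every site forces D = 0; the statistic is *not*
symmetric in `P2`/`P3`. fd follows the donor-maximized denominator
(`pD = max(p2, p3)` in both donor roles), computed in windows of 100
usable SNPs stepped by 50; windows with negative D or a non-positive
denominator are set to 0, because fd estimates an admixture fraction
only in the donor direction. Topology weighting samples one haplotype
per group from each true genealogy and classifies the rooted triple by
its most recent pair; weights sum to one per locus and genome-wide
weights are locus-length weighted.

For the sweep scan, Fst is the Weir–Cockerham (1984) estimator with
per-site variance components summed within 50-kb windows stepped by
20 kb; the diversity ratio is `log10(pi_wild / pi_target)` on the same
grid with zero-diversity windows dropped; XP-EHH integrates haplotype
homozygosity (EHH = 1 at the core by definition) outward by the
trapezoid rule over physical distance until EHH < 0.05 or a gap exceeds
200 kb, and standardizes `ln(iHH_A/iHH_B)` genome-wide. Site-level
XP-EHH scores are aggregated to the window grid by their maximum
(aggregation is unstated in window-based top-5% practice; the maximum
preserves narrow haplotype signals). Candidate regions are the
intersection of the per-statistic top-5% window sets after merging,
which makes the result independent of track order, and gene mapping
uses at-least-1-bp overlap on half-open coordinates.

## Numerical and degenerate-input conventions

Positions are 0-based internally and 1-based in VCF output; windows are
half-open and anchored at 0. Empty diversity windows report 0 with
`n_sites = 0`; windows with an undefined Fst denominator are dropped;
D with `ABBA + BABA = 0` and jackknives with fewer than three non-empty
blocks are errors rather than silent numbers. All randomness flows from
integer seeds through a dedicated generator in the simulation engine,
so equal seeds give byte-identical artifacts end to end.

## Known limitations

* No within-locus recombination: haplotype statistics see stepwise
  linkage, which is adequate for window-level contrasts but not for
  fine-mapping sweep edges.
* The expected SFS is Monte-Carlo; delta-likelihoods carry an
  evaluation bias of order `cells x sites / (2 n_sims_final)` that is
  common across scenarios but makes the absolute delta values
  scale-dependent.
* Scenario comparison is restricted to the ten templates; the best fit
  is the best among these, not a statement that the true history has
  been found.
* Topology weighting runs on simulator genealogies; inferring local
  trees from genotype data is out of scope.
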