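---
title: "Estimating mutation rates and spectra from mutation-accumulation lines"
author: "mamutspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation rates and spectra from mutation-accumulation lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamutspec)
```

## The experimental design this package models

A bacterial mutation-accumulation (MA) experiment starts many independent
lineages from a single colony and pushes each through repeated single-cell
bottlenecks (one colony restreaked every transfer) for thousands of
generations. The bottlenecks keep the effective population size near one, so
selection is essentially powerless and all but the most severely deleterious
mutations fix at the rate they arise. Whole-genome sequencing of the
surviving lines then gives a direct, genome-wide, nearly unbiased estimate
of the spontaneous mutation rate and spectrum.

`mamutspec` implements the statistical core of such an analysis for a
GC-rich bacterial genome, together with a forward simulator that generates
data with the same structure, so that every estimator can be validated
against planted ground truth without any external data.

The quantities the package computes:

* **Rates.** With $m$ mutations observed over $L$ lines, each with $n_l$
  analyzable sites and $T_l$ generations, the per-site per-generation rate
  is $\mu = m / \sum_l n_l T_l$. Exact 95% Poisson confidence intervals use
  the chi-square identity
  $[\tfrac12\chi^2_{\alpha/2}(2m),\ \tfrac12\chi^2_{1-\alpha/2}(2m+2)]$
  scaled by the exposure. Two standard errors are reported: the pure
  Poisson SE $\sqrt{m}/\sum n_l T_l$, and (when per-line counts are
  available) the among-line SEM, which additionally captures line-to-line
  dispersion and is the primary SE.
* **Conditional spectrum.** Substitutions collapse onto six strand-symmetric
  classes. The AT-direction rate $u = \mu_{G:C\to A:T}$ divides the
  G:C→A:T and G:C→T:A counts by G:C-site exposure only; the GC-direction
  rate $v = \mu_{A:T\to G:C}$ divides A:T→G:C and A:T→C:G counts by
  A:T-site exposure. The GC content expected under mutation pressure alone
  is $v/(u+v)$, with a line-bootstrap SE (default 1000 replicates).
* **Selection check.** Coding substitutions are classified synonymous or
  nonsynonymous by codon translation (bacterial code, table 11;
  stop-codon gains/losses count as nonsynonymous). The observed N/S ratio
  is compared to a neutral expectation derived from codon usage and the
  transition/transversion ratio, by a 1-df goodness-of-fit test.
* **Hotspots and indels.** Fold elevation of a mutation class at motif
  target sites (e.g. the adenine of 5'GACC3'/5'CACC3', a noncanonical Dam
  methylation signature) and at CpG cytosines, and an indel summary with
  simple-sequence-repeat (SSR) context.

## Consensus-based mutation calling

Mutations are identified by the line-versus-consensus principle: a fixed
mutation in one line is a site where that line's consensus allele differs
from the consensus across all lines. The implementation works from
pileup-style allele counts:

1. **Line consensus** (`call_line_consensus`). A site is analyzable for a
   line iff depth ≥ `min_depth` (default 10) and the modal allele fraction
   ≥ `min_fraction` (default 0.8); otherwise the site is unresolved (N).
   A clonal line's fixed allele should be supported by nearly every read,
   so ambiguous sites are suppressed rather than guessed. The thresholds
   are exposed because upstream pipelines differ in their read filters.
2. **Cross-line consensus and calls** (`call_mutations`). The reference at
   each site is the majority allele over lines with analyzable calls; exact
   ties exclude the site from calling and from exposure (counted and
   reported). Variants sharing site and allele across `k_share` ≥ 2 lines
   are suppressed: independent MA lines essentially never recur at the same
   site, so recurrence indicates ancestral polymorphism or
   cross-contamination. Suppression counts are attached to the call set so
   contaminated lines can be screened, but lines are never auto-removed.
3. **Indels** (`call_indels`). Indel evidence enters as per-line sequence
   deltas (the simulator's reconstructed-line differences); the caller
   normalizes placements by left-alignment in repeat tracts, caps lengths,
   and applies the same shared-variant rule. Split-read realignment of raw
   reads is deliberately out of scope.
4. **Exposure** (`compute_exposure`). Per line, analyzable sites are
   counted and split by the cross-line consensus base into G:C and A:T
   sites; conditional rates always use these analyzable-site splits, never
   the genomic GC content, because the analyzable fraction of G:C sites
   need not equal the genomic fraction.

## The simulator: what it emulates, and what it does not

`sim_config()` holds every free parameter. The defaults describe a
desk-scale version of an MMR-lacking actinobacterial MA design:

| parameter | default | meaning |
|---|---|---|
| `genome_length` | 200 kb | reference length (desk-scale stand-in for ~7 Mb) |
| `target_gc` | 0.656 | genomic GC fraction |
| `coding_fraction` | 0.9 | fraction of sites in coding regions |
| `n_lines` | 49 | surviving MA lines |
| `generations` | 100 | bottleneck transfers per line (desk-scale stand-in for ~4900) |
| `mu_bs` | 7e-7 | substitution rate per site per generation, inflated so a few hundred events accumulate |
| `mu_indel` | 1.7e-7 | indel rate, keeping the indel share of all events near 15% |
| `spectrum_weights` | 3.95/2.76/0.27/1.58/2.10/0.43 | relative conditional class rates (order: A:T→G:C, G:C→A:T, A:T→T:A, G:C→T:A, A:T→C:G, G:C→C:G) |
| `motif_hotspots` | GACC, CACC (offset 2, ×6.8) | A:T→C:G elevation at the motif adenine, either strand |
| `cpg_multiplier` | 3.5 | G:C→A:T elevation at CpG cytosines |
| `ssr_indel_fraction` | 0.787 | indels placed in SSR tracts as unit slips |
| `indel_max_len` | 27 | indel length cap (bp) |
| `insertion_bias` | 2.1 | insertion:deletion frequency ratio |
| `mean_depth` | 126 | Poisson sequencing depth |
| `seq_error_rate` | 0.002 | per read-base error probability |
| `mask_rate` | 0.03 | unanalyzable line-sites, mirroring ~97% analyzable genomes |

All estimators are scale-free in exposure (they depend only on
$m/\sum n_l T_l$), which is why a 200 kb × 100-generation experiment with an
inflated rate exercises exactly the same code paths as a 6.77 Mb ×
4900-generation one.

Design details worth knowing:

* **Rate calibration with hotspots.** Per-site class rates are
  proportional to the applicable spectrum weights; motif and CpG
  multipliers scale single class components at their target sites. `mu_bs`
  is calibrated to the multiplier-free genome average, so hotspots add
  events above that baseline. The closed form
  $\lambda = \mu\,n\,T\,L$ holds exactly when all multipliers are 1.
* **Genes** are random codon strings at the target composition with ATG
  start, TGA stop and no internal stops; there is no attempt to mimic real
  gene content or codon bias. At `target_gc = 1` the start/stop termini are
  the only non-G/C bases, so a pure-G/C sequence requires
  `coding_fraction = 0`.
* **SSR tracts and extra motif copies** are planted in intergenic gaps
  only, guaranteeing stop-free genes; background motif occurrences in
  coding sequence arise freely (a GC-rich 200 kb sequence contains on the
  order of a thousand natural GACC/CACC targets).
* **One RNG substream per line**, derived from the master seed: adding
  lines never perturbs earlier lines, and identical configs are
  bit-reproducible.
* **Pileups carry substitution evidence only.** Depth is
  Poisson(`mean_depth`), read errors flip to a uniform other base, masked
  line-sites get depth 0. Indels do not create gapped columns; their
  evidence travels as sequence deltas. There is no read-level FASTQ
  simulation, no mapping-quality, duplicate-read or coverage-bias
  modeling, and no structural variation. Consequences: caller validation
  here demonstrates the statistical logic (consensus thresholds, shared
  variant exclusion, exposure accounting), not robustness to alignment
  artifacts of real short-read data.

## Reconstructing published count structures

`fixture_from_counts()` rebuilds call and exposure tables whose marginal
counts match a stated experiment summary — six class counts, N/S split,
indel counts and sizes, SSR and motif membership — so that every summary
statistic is recomputed through the same estimator functions from tables
alone. The defaults encode a 49-line, 6.77 Mb, 4900-generation GC-rich
experiment with 856 substitutions and 207 indels.

One derived default deserves explanation: the analyzable G:C fraction is
0.674, not the genomic 0.656. Conditional rates divide by analyzable-site
exposures, and inverting the experiment's two printed conditional rates
against their class counts ($E_{GC} = 475/4.34\times10^{-10}$,
$E_{AT} = 320/6.04\times10^{-10}$) fixes the analyzable split at 67.4%
G:C. With that split, the reconstructed tables reproduce every printed
statistic at its printed precision. Note that the among-line SEM computed
from a count fixture is not meaningful (counts are spread evenly over
lines, so line-to-line dispersion is artificially small); the Poisson SE is
the relevant uncertainty there.

```{r fixture}
fx <- fixture_from_counts()
rp <- fixture_report(fx)
rp$rates$overall$rate
100 * rp$spectrum$equilibrium$gc
```

## Numerical and statistical choices

* **Poisson CIs** use the chi-square quantile identity; the test suite
  verifies it against direct root-finding on the Poisson CDF for all
  $m \le 1000$.
* **$\kappa = 2R$.** The expected N/S ratio weights single-base codon
  changes $\kappa:1:1$ where $\kappa$ is the per-site
  transition:transversion *rate* ratio. An observed *count* ratio
  $R = \mathrm{ts}/\mathrm{tv}$ corresponds to $\kappa = 2R$ because every
  site has one transition target and two transversion targets. Weighting by
  $\kappa$ alone (rather than the full six-class spectrum) matches the
  usual "codon usage + ts/tv" formulation; a full-spectrum weighting could
  be added but changes the expectation only modestly.
* **Selection-test statistic.** The package reports a plain Pearson 1-df
  goodness-of-fit statistic, cross-checked against a log-likelihood-ratio
  (G) construction; the two agree asymptotically. For the canonical
  example counts (486 N, 230 S against an expectation of 2.60) this
  statistic is ≈ 6.7 — appreciably larger than the value of 3.00
  reported alongside those counts in the source experiment, whose exact
  test construction is not documented. The package deliberately reports
  its own clearly defined statistic rather than attempting to reproduce an
  unspecified one.
* **Expected N/S of 2.60** depends on the real genome's codon usage, which
  is external input; with a synthetic genome the expectation is computed
  from the synthetic codon usage instead, and the enumeration itself is
  validated against an exhaustive oracle.
* **Cross-line ties** (equal top allele counts) exclude a site from both
  calling and exposure — with ~50 lines at 126× such ties are vanishingly
  rare and almost always reflect contamination.
* **Left-alignment** of indels follows the VCF convention (leftmost
  equivalent placement), so unit slips anywhere in a tract are reported at
  the tract boundary and shared-variant suppression compares like with
  like.
* **SSR context thresholds** — homopolymers ≥ 4 bp, units ≤ 6 bp with
  ≥ 3 copies, or an insertion completing such a tract — are this package's
  convention; published analyses rarely state theirs.
* **Coordinates are 1-based** throughout (the convention of this
  ecosystem's sequence infrastructure and of VCF/GFF3 output).

## Validation strategy and problem sizes

The test suite validates the pipeline at sizes chosen to give stable
estimates from a few thousand planted events:

* caller recall/precision: 20 seeded runs of 20 kb × 8 lines × 50
  generations at 100×, error 0.002 — aggregate recall ≥ 0.95 (the ~3%
  masked sites are the dominant loss) and precision ≥ 0.99;
* rate-CI coverage: 25 seeded runs of 20 kb × 10 lines with hotspots off —
  the planted rate falls inside the 95% CI in ≥ 21 runs;
* hotspot-fold recovery: 25 seeded plantings on 40 kb with a ×6.8 motif
  multiplier and the spectrum concentrated on A:T→C:G (≥ 500 events per
  seed) — the measured fold lands in [5.0, 9.0] in ≥ 90% of seeds;
* invariants: strand symmetry (reverse-complementing genome and pileups
  mirrors every call), permutation invariance over line labels,
  base-pair conservation through reconstructed line sequences, and
  availability-renormalized convergence of planted class frequencies.

## Known limitations

* No real-read handling: BAM/SAM parsing, alignment, mapping quality and
  duplicate reads are out of scope; pileup counts are the entry point.
* Indel discovery relies on sequence deltas rather than read realignment,
  so indel *detection* performance on real data is not addressed — only
  the downstream normalization and statistics.
* The synthetic genome has uniform composition and no mobile elements,
  rRNA operons or compositional skew; motif and CpG background densities
  are therefore more homogeneous than in a real chromosome.
* Degenerate (IUPAC) motifs and structural variants beyond the indel
  length cap are unsupported.
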