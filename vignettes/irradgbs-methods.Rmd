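---
title: "Methods: screening induced mutations and counting recombination from GBS panels"
author: "irradgbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening induced mutations and counting recombination from GBS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irradgbs)
```

## The problem

Genotyping-by-sequencing (GBS) reduces a large plant genome to a small
set of short fragments near restriction sites — typically well under 1%
of the genome — and sequences those fragments deeply in many samples at
once.  In radiation mutagenesis studies this is used for two downstream
questions that `irradgbs` implements:

1. **Mutation screening.**  How many induced single-base substitutions
   (SBS) and small (1–2 bp) insertions/deletions does an irradiated
   line carry per 10 Mb of mapped sequence, what is the substitution
   spectrum, and where do the mutations fall (exon / intron /
   intergenic)?
2. **Recombination counting.**  In backcross (BC1) progeny of an F1
   between two divergent inbreds, how many meiotic crossovers does each
   line show, inferred from switches in marker zygosity along each
   chromosome?

Both analyses start from variant tables (VCF with per-sample `DP` and
`AD`), a mapped-region BED, a gene-model GFF3 and a sample manifest —
not from reads.  Upstream trimming, alignment and variant calling are
out of scope, as are structural variants and InDels longer than 2 bp,
which short-fragment GBS cannot screen.

## Mutation screen

For a site to be **assessable**, every non-irradiated control line must
cover it with at least `min_depth` reads (default 5×) and all control
reads must carry one and the same allele; the shared allele is the
*control consensus* (`control_consensus()`).  Sites where controls
disagree, are mixed, or are under-covered are excluded rather than
guessed: residual heterozygosity and caller noise in the background
would otherwise masquerade as induced mutations.  Whether the controls'
own depth is part of the rule is a genuine design choice; here it is on
by default and exposed as `control_min_depth`.

A **mutation call** (`screen_mutations()`) requires the mutant line to
reach `min_depth` and to show an allele different from the consensus at
a read fraction of at least `min_af` (default 0.25).  Induced mutations
in one-generation designs are heterozygous, so the expected mutant
allele fraction is ~0.5; the 0.25 floor keeps heterozygous calls while
discarding low-fraction read noise, and mirrors the 25% bound used
elsewhere in the marker cascade.  InDels are kept only when the net
length difference is 1–2 bp.

Substitutions are strand-collapsed into six categories
(`classify_sbs()`): `A/T>G/C`, `G/C>A/T` (the transitions), `A/T>T/A`,
`A/T>C/G`, `G/C>T/A`, `G/C>C/G`.  Densities are reported per 10 Mb of
the assessable mapped length (`mutation_density()`, `density_table()`);
the denominator is the mapped-region total, never the genome size, and
per-line denominators are supported because each line covers its own
region set in real GBS.

**Generation back-correction** (`correct_generation_density()`): in a
selfing series a fraction of heterozygous mutations segregates away
each generation.  With carrier composition after one selfing of 1/3
homozygous and 2/3 heterozygous, and a quarter of heterozygous
mutations lost, an observed density $d$ corresponds to an
earlier-generation density $d / (1 - \tfrac{2}{3}\cdot\tfrac14)$, e.g.
1.25 → 1.5 per 10 Mb.  The carrier fraction is a documented assumption
and a parameter, not a constant.

## Recombination counting

The marker cascade (`select_markers()`) follows the pooled design:
parental and F1 pools must each reach 10×; each parental pool must be
*fixed* (every pooled read one allele); the parents must be fixed for
different alleles; and the F1 pool's allele fraction must lie in the
closed interval [0.25, 0.75].  Per progeny line, zygosity at each
marker (`call_zygosity()`) uses the recurrent-parent allele fraction:
below 5× is `MISSING`; exactly 1.0 is `HOM`; within [0.25, 0.75] is
`HET`; anything else — including fractions in (0.75, 1) — is `MISSING`
rather than forced into a class.  The recurrent-allele orientation is
deliberate: a backcross cannot produce donor homozygotes, so "100%"
means 100% recurrent reads.

`MISSING` calls are dropped before adjacency is formed: no event can be
called across a gap, but the flanking informative markers become
adjacent.  This maximizes marker use and never invents events at gaps.

The **singleton exclusion** (`singleton_filter()`) removes every
interior call whose two flanking informative calls both differ from it
— a lone discordant marker is far more likely a genotyping error than
two crossovers within one short interval.  The pass is single and
simultaneous (flags computed on the unmodified vector, terminal calls
never removed).  It is *not* iterated to a fixed point: repeated passes
would erode genuine short double-crossover tracts, and the tests assert
single-pass behaviour explicitly.

Events are then adjacent-pair mismatches (`count_recombination()`),
counted per chromosome and summed (`summarize_line()`, `count_panel()`);
no event spans a chromosome boundary.  Two structural biases are
inherent and documented rather than corrected: an even number of
crossovers inside one marker interval is invisible, and crossovers
beyond the outermost markers are invisible, so with error-free
genotypes the counted total is a lower bound on the true crossover
count.

## Group statistics

Group means are compared with the pooled-variance Student's *t*-test
(`two_sample_ttest()`; Welch available behind a flag), two-sided, with
no multiple-testing correction by default — matching the reporting
convention for small per-condition panels (*n* = 3 lines); a Bonferroni
option exists.  Spectrum composition across groups uses the Pearson
chi-square on raw counts (`spectrum_chisq()`), never on percentages,
with a warning when any expected count is below 5.  Because published
category-wise significance can be computed either on the full 6 × G
table or category-against-rest, both constructions are exposed
(`spectrum_chisq_by_category()`), and neither is asserted to be the
original one.

## The synthetic generator

`sim_config()` + `simulate_mutation_experiment()` /
`simulate_backcross_experiment()` emulate the statistical structure the
analyses assume, with full ground truth, so every stage is testable by
parameter recovery.  Design choices:

* **Genome**: 12 chromosomes; mapped regions drawn Poisson around
  144 bp and placed uniformly without overlap.  The defaults (1500
  regions of ~144 bp on a 60 Mb toy genome) keep the mapped fraction
  near 0.4%, the reduced-representation regime of a real GBS library,
  at desk scale.  Real region-length distributions are heavier-tailed;
  only total mapped length enters the analyses.
* **Cross**: parent A (recurrent) carries the reference allele, parent
  B the alternate, at divergent sites placed at `snp_rate` per mapped
  bp (default 3 × 10⁻⁴, matching a few thousand usable markers over
  ~15 Mb of mapped sequence); the F1 is heterozygous throughout.
* **Meiosis**: crossovers per chromosome are Poisson(`xo_rate`) with
  uniform positions and no interference (no interference information
  is available to calibrate; the rate is the config hook), starting
  phase fair-coin.  BC1 zygosity is `HET` exactly where the gamete
  carries the donor allele.
* **Mutations**: per mutant line, Poisson(`mutation_density` × mapped
  length / 10⁷) events placed uniformly over mapped regions only —
  unmappable mutations are invisible to GBS and would distort density
  denominators.  Categories follow `sbs_spectrum` (default: the
  reproductive-tissue spectrum with `A/T>G/C` 0.31 and `G/C>A/T` 0.38
  dominating); `indel_fraction` (default 0.1) of events are 1–2 bp
  InDels, matching SBS shares of 81–95% of polymorphisms.  Positions
  are drawn without replacement panel-wide; recurrent hits are
  vanishingly rare at these densities.
* **Observations**: depth per cell is negative-binomial
  (`depth_mean` = 35, `depth_dispersion` = 8) — GBS depth is
  overdispersed and only means are usually reported, so the size
  parameter is a calibration hook; `Inf` gives Poisson depth.  Error is
  modelled at the **read level** (each read flips allele with
  probability `genotype_error_rate`), not at the genotype level, so
  that allele-fraction filters are actually exercised.  Zero-depth
  draws are emitted as absent cells.
* **Reproducibility**: one seed in the config; all draws flow from it,
  and a fixed seed reproduces every output file byte for byte.

What the generator does **not** emulate: restriction-site placement and
its methylation sensitivity (region positions are uniform, while ApeKI
libraries enrich genic sequence), linked-read structure, mapping
artifacts, shared polymorphisms between mutant lines, and allele-
specific coverage bias.  Passing recovery tests therefore demonstrates
the correctness of the screening and counting logic under the stated
noise model, not robustness to every artifact of real libraries.

## Numerical and testing choices

* All interval bounds (0.25/0.75 allele fractions) are closed; `HOM`
  requires a recurrent fraction of exactly 1.0 on observed reads.
* Coordinates are 1-based inclusive in memory and in VCF; BED I/O
  converts to 0-based half-open at the boundary, with boundary-case
  containment covered by tests.
* Multi-allelic VCF records are split on read and merged on write;
  screening operates on biallelic records.
* Degenerate statistics are explicit: zero pooled variance with equal
  means gives *t* = 0, *p* = 1; with unequal means the result is
  flagged degenerate; groups with zero spectrum totals are excluded
  with a warning.
* Recovery tests run at deliberately clean settings — read error 0 and
  Poisson (dispersion-free) depth at mean 30 — because they verify the
  screening logic, not depth robustness; overdispersion is exercised
  separately in the depth-model tests.  Problem sizes used by the
  recovery suite: a ~2.5 Mb mapped genome with 3 controls + 3 mutants
  at 20 mutations/10 Mb for the screen, and 200 BC1 progeny with ~100
  markers per chromosome at 1.5 crossovers/chromosome for the
  recombination recovery; exhaustive oracles cover all zygosity
  vectors up to length 12 (counting) and 8 (singleton rule).
* The truth-side expectation for recombination recovery is computed by
  an independent loop implementation from the crossover lists
  restricted to each line's informative marker grid, with the
  exclusion rule applied to the implied states — so the comparison
  isolates the pipeline's read-handling rather than re-testing the
  rule itself.

## A small worked run

```{r, eval = FALSE}
cfg <- sim_config(n_regions = 3000, region_length_mean = 500,
                  mutation_density = 25, seed = 101)
sim <- simulate_mutation_experiment(cfg, n_controls = 4, n_mutants = 3)
calls <- do.call(rbind, lapply(sprintf("mutant_%d", 1:3), function(s)
  screen_mutations(sim$matrix, sprintf("control_%d", 1:4), s)))
density_table(calls, mapped_length(sim$genome),
              samples = sprintf("mutant_%d", 1:3))
```

With read error present, screened calls are compared to `sim$truth` for
recall/precision; with the defaults above the screen recovers the
injected set exactly (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`, which recompute these quantities from scratch).

## Known limitations

* The screen assumes biallelic, heterozygous induced mutations; a
  homozygous induced mutation (fraction 1.0 of a new allele) is still
  called, but mosaic fractions below 0.25 are invisible by design.
* Recombination counts are lower bounds (interval parity and terminal
  blindness, above); no genetic-map or interference estimation is
  attempted.
* The minimal VCF reader handles the dialect the pipeline emits
  (`DP`/`AD`, split multi-allelics); it is not a general VCF
  validator, and its output is cross-checked against an independent
  reader in the test suite.
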