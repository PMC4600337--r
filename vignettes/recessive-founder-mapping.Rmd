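---
title: "Mapping a recessive lethal in a founder population: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive lethal in a founder population: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recmapr)
library(dplyr)
```

## The mapping problem

A closed, inbred population (the motivating case is a horse breed with an
inbreeding rate of about 1.5 % per generation) segregates a perinatally
lethal congenital defect.  Affected offspring of healthy parents, an excess
of paternal half-sib relationships among case families, and dams that have
produced more than one affected foal all point to a fully penetrant
autosomal recessive allele descending from a single founder.  Under that
model every affected individual is *autozygous* — homozygous by descent —
for a chromosomal segment around the causal locus, and the segment shared
by all cases shrinks with every historical recombination, i.e. with every
additional case examined.

`recmapr` implements the complete discovery workflow for this situation:

1. **Quality control** of SNP-array genotypes (MAF and call-rate filters).
2. **Genotypic association**: a 2×3 (genotype-by-status) Pearson χ² scan
   with Bonferroni correction, plus an exact alternative for the
   zero-filled tables a recessive locus produces.
3. **Shared-homozygosity mapping**: runs of homozygosity per sample and
   their identical-by-state intersection across all cases, ranked by how
   few controls share them.
4. **Variant filtering**: a rule-based pileup caller for targeted
   resequencing of the candidate region, recessive case/control
   concordance filtering and coding-consequence annotation.
5. **Population genetics**: two-locus LD r² and allele-frequency
   estimation from carrier screens.

A seeded founder-population simulator generates genotypes and read pileups
with known truth, so every stage is testable end to end without external
data.

## Genotype representation

Genotypes are dosage codes counting copies of the alternative allele:
0 (homozygous reference-like), 1 (heterozygous), 2 (homozygous
alternative), `NA` missing.  The founder disease haplotype carries the
alternative allele at the disease locus, so "all cases code 2, no control
code 2" is the recessive signature throughout the package.  Tables are
tibbles: one row per sample, one integer column per marker, with the
marker map (`marker_id`, `chromosome`, `position_bp`, alleles) alongside.
All genomic coordinates are 1-based and inclusive.

## The simulator: what it emulates and what it does not

`sim_config()` defaults describe the cohort the workflow is designed for:
13 cases, 69 controls and 17 obligate-carrier dams typed on a dense array
(1,200 markers at 50 kb spacing on one chromosome in the default panel),
a founder haplotype carrying the causal allele, and a mean case autozygous
segment of 10.5 Mb.

* **Haplotype structure.** Each case haplotype copies the founder
  haplotype over an interval containing the locus; the interval extends
  left and right of the locus by independent exponential lengths with mean
  `case_ibd_length_mean_bp`.  The two haplotypes of a case are drawn
  independently and intersected, so the per-case autozygous segment (the
  minimum of two exponentials on each side) again has mean
  `case_ibd_length_mean_bp`, and the segment shared by *k* cases shrinks
  like 1/k — reproducing the recombination-driven narrowing that makes
  homozygosity mapping informative.  Segment endpoints snap to marker
  positions.
* **The causal allele is private to the founder haplotype.**  Non-founder
  haplotypes carry the reference allele at the disease locus, as expected
  for a recent mutation; control haplotypes are founder with probability
  `carrier_frequency` (default 0.085, the carrier-screen estimate for the
  motivating population), and a control is never homozygous founder at the
  locus — such an individual would have been a case.
* **Marker frequencies.** Alternative-allele frequencies are uniform on
  [0.05, 0.5], so unlinked markers pass a 5 % MAF filter by design and QC
  attrition is driven by the error/missingness model, not by the frequency
  draw.
* **Error model.** Genotyping errors are symmetric single-step flips
  (hom→het; het→either hom), the simplest model that can break a run of
  homozygosity; the default rate of 0.001 reflects typical array
  reproducibility.  Missingness (default 0.004, matching a 99.6 % mean
  call rate) is independent of genotype.
* **Pileups.** Per sample and site, depth is Poisson (default mean 216×,
  deep targeted capture); alternative-supporting reads are binomial with
  success probability ~0, ~0.5 or ~1 by genotype, perturbed by the base
  error rate; supporting observations fall in the first 25 bases of a
  50 bp read with probability one half.

The simulator is deliberately not a coalescent or pedigree-forward model:
there is no population LD beyond the founder haplotype, no relatedness
among controls beyond carrier status, one chromosome, and no X-linked
mode.  Passing tests therefore demonstrate that the algorithms recover a
planted founder signal under realistic array noise — not that the package
models breed demography.

## Statistical and numerical choices

**QC order and boundaries.** Markers are filtered first (MAF, then call
rate, both computed over all samples jointly), then samples on the
retained markers.  Thresholds are strict: a marker at exactly 5 % MAF or
exactly 90 % call rate passes.  Applying QC twice with the same thresholds
is idempotent whenever the first pass removes no samples (the usual case
at array-quality missingness); when samples are removed, downstream MAFs
can shift and exact idempotence is not guaranteed — the test suite checks
the property at the default, array-realistic rates.

**χ² with zero columns.** Genotype columns with zero total are dropped and
the degrees of freedom reduced to (non-empty columns − 1); a table with at
most one non-empty column is flagged degenerate (p = 1).  No continuity
correction is applied; the exact probability-ordering test (`fisher_2x3()`,
full enumeration of the multivariate hypergeometric outcome space, bounded
at a grand total of 500) is the remedy for sparse tables, and both paths
are exposed in `assoc_scan()`.

**Shared-region rules.**  Identity-by-state requires the *identical*
homozygous allele in every case: opposite homozygotes break sharing.
Missing case genotypes are tolerated inside a region (the consensus of the
non-missing homozygotes defines the shared allele) but cannot define its
ends; for control sharing, a missing genotype disqualifies — a control is
only counted as sharing what it demonstrably carries.  Regions need at
least `min_markers = 3` consensus markers by default (no run-length
minimum is inherent to the method; 3 suppresses single-marker noise).
Region boundaries are the first and last consensus marker positions —
never extended into inter-marker gaps — and ranking is by cases sharing
(descending), controls sharing (ascending), length (descending), start
position.

**Caller thresholds.** A variant observation passes when supported by ≥3
unique reads, seen ≥1× within the first 25 bases of a read, with raw
coverage ≥10×, mean supporting base quality ≥20 and alternative-allele
fraction ≥15 % — all comparisons inclusive, each rule reported as its own
flag.  These five rules decide *discovery* (a site is a variant iff some
sample passes all five).  Per-sample *genotyping* at a discovered site
cannot reuse the ≥15 % rule — a homozygous-reference sample has an
alternative fraction of 0 by definition — so callability requires only the
coverage rule, and the genotype is assigned from the alternative fraction
with an inclusive heterozygote band of [0.15, 0.85].  The band edges are a
documented package choice (only the 15 % discovery rule is inherent to the
method).  A case without a callable genotype *fails* recessive concordance
rather than being ignored: a conservative rule that can only cost
sensitivity, never specificity.

**LD estimation.** The default r² estimator fits the four two-locus
haplotype frequencies by EM over the double-heterozygote phase ambiguity:
initialization at linkage equilibrium (allele-frequency products),
iteration until the largest relative frequency change is below 1e-8 or
1,000 iterations, then r² = D²/(p_A(1−p_A)p_B(1−p_B)), clamped to [0, 1].
The squared genotype correlation is retained as an independent fast
cross-check; the two agree closely under random mating.  With 500
individuals the EM estimate differs from direct counting on the true
phase by about 0.01 on average (single draws carry irreducible phase
noise); the test suite asserts the mean over replicates.

**Rounding.** Reported percentages and Mb lengths round half-up at the
printed precision (1 decimal for percentages, 2 for Mb, 3 for allele
frequencies) and only in reports — internal computations are never
rounded.

**Indices.** Marker indices, CDS positions and codon numbers are 1-based;
`codon_index()` uses integer arithmetic (`(pos − 1) %/% 3 + 1`) to avoid
floating-point `ceiling()` edge cases.

## Worked example

```{r example}
sim <- simulate_population(sim_config(seed = 42))
qc <- apply_qc(sim$genotypes, sim$map)
glance(qc)

scan <- assoc_scan(qc$genotypes, qc$map)
glance(scan)

regions <- shared_homozygous_regions(qc$genotypes, qc$map) |> rank_regions()
regions |> select(start_bp, end_bp, length_mb, n_cases_sharing, n_controls_sharing) |> head(3)

# the top-ranked region contains the (here, known) disease locus
sim$truth$disease_position_bp
```

```{r manhattan, fig.width = 7, fig.height = 3}
autoplot(scan)
```

## Problem sizes used in the test suite

The suite exercises the default cohort (13/69/17 samples, 1,200 markers)
across 20 simulation seeds for locus-recovery properties, 200 label
permutations on a 50-marker panel for χ² calibration, 10,000 randomized
pileup records against a brute-force re-application of the caller rules,
exhaustive window oracles on panels of up to 30 markers, 50 replicates of
500 phased individuals for EM accuracy, and 1,000 replicate screens of 865
individuals for estimator bias.  These sizes give stable pass/fail
behaviour at comfortable runtimes and are the package's reference
conditions.

## Known limitations

* The simulator's exponential-extent segment model is a stand-in for the
  breed's unknown LD-decay profile, not an estimate of it.
* Association is a marginal per-marker test; no kinship or mixed-model
  correction is provided, so cryptic relatedness in real cohorts will
  inflate the null beyond the simulated calibration.
* Run-of-homozygosity calling is rule-based (no HMM autozygosity model),
  appropriate for long founder segments but not for short ancient ones.
* The caller handles biallelic SNVs only, consumes precomputed pileup
  summaries (read mapping and duplicate marking are upstream concerns),
  and treats "unique read support" as given by the pileup producer.
* Hardy–Weinberg and relatedness QC filters are deliberately out of scope.
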