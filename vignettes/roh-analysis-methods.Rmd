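---
title: "Methods: ROH detection, genomic inbreeding and island discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH detection, genomic inbreeding and island discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

A run of homozygosity (ROH) is a contiguous stretch of homozygous
genotypes in one diploid individual. Long runs arise when both chromosome
copies descend from a recent common ancestor; the expected genetic length
of such an autozygous segment, g generations after that ancestor, is
exponentially distributed with mean 1/(2g) Morgans. At the 1 cM/Mb map
this package assumes by default, a 0.5-Mb run points back about 100
generations, a 1-Mb run about 50, and a 2-Mb run about 25
(`generations_from_length()`).

rohscan takes a biallelic SNP genotype matrix (from a VCF), detects ROH
per individual, summarizes them per individual, group and length class,
derives the genomic inbreeding coefficients F_ROH and F_HOM, locates ROH
islands (population-level autozygosity hotspots that flag candidate
selection signatures), and estimates LD decay and historical effective
population size. Everything upstream of the genotype matrix — alignment,
variant calling, variant-quality filtering — is out of scope; the input
is assumed to contain only well-supported biallelic SNPs.

## Site filters

`filter_sites()` removes sites with missing-call rate ≥ 0.1 or minor
allele frequency < 0.05, the conventional pre-ROH site-quality screen for
livestock WGS panels. Boundary semantics are deliberate and tested: a
missing rate of exactly 0.10 fails, a MAF of exactly 0.05 passes. MAF is
computed from non-missing calls only (denominator 2 × non-missing
genotypes) and half-calls are treated as missing — both standard,
conservative choices. Filters are applied globally across the cohort; a
per-group mode would be a straightforward extension but is not what the
default pipeline does.

## ROH detection

`call_roh()` implements the sliding-window scan popularized by PLINK's
`--homozyg`, with all six defining parameters exposed in `roh_params()`:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 50 | SNPs per scanning window |
| `max_het_per_window` | 2 | heterozygous calls tolerated per window |
| `max_missing_per_window` | 5 | missing calls tolerated per window |
| `min_snps` | 100 | minimum SNPs per reported run |
| `min_length_kb` | 500 | minimum run length |
| `max_density_kb_per_snp` | 50 | maximum kb per SNP inside a run |
| `max_gap_kb` | 1000 | maximum gap between consecutive run SNPs |
| `hit_proportion` | 0.05 | window-hit fraction that flags a SNP |

For each SNP, the fraction of covering windows whose het/missing counts
stay within the allowances is computed (`window_scan()`); SNPs at or
above `hit_proportion` — the scanning tool's documented default of 0.05,
which the run definition needs but which is rarely reported alongside the
six parameters above — are candidates. Maximal stretches of consecutively
indexed candidate SNPs form runs; an intervening below-threshold SNP
breaks a run, as does a gap above `max_gap_kb` between adjacent run SNPs
(a gap of exactly 1000 kb is still bridged — the cap is read as an
inclusive allowance). Runs are trimmed at both ends to their outermost
homozygous non-missing SNP, so a segment never starts or ends on a
heterozygous or missing call, and then filtered by SNP count, length and
density. Segment length is the inclusive span `end − start + 1`; tools
differ by one bp here, so the convention is stated and tested.

Edge behavior is explicit: SNPs near chromosome ends are covered by fewer
than `window_snps` windows and use the hit fraction over the windows that
exist; a chromosome shorter than one window is evaluated as a single
truncated window.

Because this caller is the package's scientific core, it is verified
against `brute_force_roh()`, an independent oracle that re-derives the
same contract by direct enumeration (every window recounted from scratch,
runs assembled by an element-wise walk, no shared code path). The suite
asserts exact segment-set equality on hundreds of randomized instances
with planted runs, noise and randomized parameters.

## Inbreeding coefficients

F_ROH = L_ROH / L_au: an individual's summed ROH length over the
autosomal length covered by SNPs. By default L_au is measured from the
data as the summed first-to-last-SNP span per contig
(`autosomal_length_mb()`); a published assembly constant can be supplied
instead, since both readings of "autosomal genome covered by SNPs" are in
use.

F_HOM is the excess-homozygosity (method-of-moments) estimator
`(O_hom − E_hom) / (N_sites − E_hom)`, with `E_hom = Σ (1 − 2pq·n/(n−1))`
over the sites non-missing in the individual, p and q the cohort allele
frequencies and n the non-missing allele count — the small-sample
correction used by the standard toolchains. F_HOM can be negative (an
outbred individual in an inbred cohort); F_HOM ≥ F_ROH is an empirical
tendency, not an invariant, and the package does not assert it.
`correlate_f()` reports the Pearson correlation of the two coefficients
per group and returns NA, rather than failing, on degenerate groups
(n < 2 or zero variance).

## ROH islands

For a group of n individuals, `snp_occurrence()` gives each SNP the
fraction of members whose ROH cover it (values on the grid 0, 1/n, …, 1).
`island_threshold()` keeps the top 0.5% of SNPs by occurrence: the
threshold is the k-th highest value, k = ⌈0.005 · n_snps⌉, and ties at
the threshold are all retained, since occurrence values are discrete and
a strict cut could retain nothing. Two deliberate guards: SNPs with zero
occurrence are never retained even when sparse coverage drags the
order-statistic threshold to zero (a SNP in nobody's ROH cannot be a
hotspot), and constant tracks are declared degenerate with no islands
("top" is meaningless under constancy). `merge_islands()` joins strictly
adjacent retained SNPs — a literal reading of "a series of adjacent SNPs"
— into islands, dropping runs below `min_island_snps = 2` to suppress
isolated-SNP artifacts; an optional bp bridge across below-threshold SNPs
exists but is off by default. `annotate_genes()` assigns genes from a
GTF/GFF by ≥ 1-bp interval overlap, strand ignored, with gene features
collapsed to their genomic span per `gene_id`.

## LD decay and effective population size

`pairwise_r2()` computes composite (genotype-dosage) r² — the squared
Pearson correlation of 0/1/2 dosages over individuals complete at both
sites — for all same-chromosome pairs within 1 Mb by default. Dosage r²
is used throughout because the package never phases genotypes; it is
symmetric in pair order and invariant to ref/alt relabeling, both
property-tested. `ld_decay()` averages r² in half-open 50-kb distance
bins, mapping bin midpoints to recombination fractions at 1 cM/Mb.

`ne_from_ld()` inverts the Sved relation E[r²] = 1/(α + 4Nc) per bin:
after subtracting the finite-sample term 1/(2n) (floored at a small ε so
the inversion stays defined), N̂ = (1/(4c)) (1/r²_adj − α) at generation
t = 1/(2c). α = 1 by default; negative estimates are floored at zero with
a warning. The estimator is deliberately the transparent textbook form —
mutation corrections and recombination-map options found in specialized
tools are out of scope — so the package asserts exact recovery of planted
Ne on noiseless forward-generated bins, plus the rank property (stronger
simulated LD ⇒ smaller N̂) on block-haplotype populations, rather than
agreement with any particular tool's defaults.

## The simulator and what it does (not) emulate

`simulate_population()` plants autozygous tracts directly into
Hardy-Weinberg background genotypes (a copying model), rather than
running a forward-in-time pedigree: this yields exact, unambiguous ground
truth (`sim_truth`) at desk scale. Study conditions are fixed in the
defaults and were chosen once:

- background alternate-allele frequencies uniform on [0.05, 0.5] —
  post-MAF-filter spectrum;
- SNP density 300/Mb — dense enough that a 500-kb run comfortably clears
  the 100-SNP minimum, so the detector's thresholds are exercised rather
  than vacuous, while keeping a 500-Mb genome at 150k sites;
- tract lengths exponential with mean 1/(2g) Morgans (truncated below
  100 kb), or fixed-length for threshold-controlled designs;
- genotyping noise inside tracts: het rate 0.005 and missing rate 0.002,
  with background missing rate 0.01 — the residual error plausible for
  high-depth WGS after filtering;
- tract placement uniform with rejection of within-individual overlap.
  Rejection slightly disfavors long tracts once occupancy is high, so
  length-law checks are run at low target F.

Island loci are planted as shared tracts in a chosen carrier fraction of
a group. All randomness flows through one mandatory seed, and a fixed
seed reproduces the output VCF byte for byte.

Background sites are independent (no background LD) by default, so the
simulator does **not** emulate real LD structure, allele-frequency
spectra shaped by demography, mutation, or X chromosomes; an optional
block-haplotype construction (used in the LD tests) provides orderable
LD strength only. Passing recovery tests therefore demonstrates that the
algorithms implement their definitions correctly and recover planted
truth under realistic noise — not that any biological conclusion about a
real population is reproduced.

## Validation design and problem sizes

The validation suite runs at sizes chosen to exercise every rule while
staying desk-scale: oracle equivalence on 200 randomized instances of up
to 1000 SNPs; F_ROH recovery on 20 individuals over a 500-Mb genome with
target F* ∈ {0.02, 0.05, 0.10, 0.18} planted as 1.6-Mb tracts (above all
detection thresholds, per the recovery contract), asserting mean absolute
error ≤ 0.02 and Pearson r ≥ 0.95 against truth; island recovery over 50
seeded replicates of a 20-member group carrying one 2-Mb locus at 80%
frequency (plus an F* = 0 control group), asserting exactly one
overlapping island in ≥ 95% of replicates and none in controls; exact
Sved inversion for Ne ∈ {100, 500, 2000}; and conservation fuzzing
(length-class sums, island SNP sets, F_ROH bounds).
`scripts/acceptance.R` recomputes all of these from scratch against the
installed package.

## Numerical and degenerate-input choices

Length classes are half-open, [0.5, 1.0), [1.0, 1.5), [1.5, 2.0),
[2.0, ∞) Mb, so a segment of exactly 1.0 Mb falls in the second class —
the printed class bounds in common use overlap at the boundaries and
half-open intervals remove the ambiguity. The > 2.0 Mb class corresponds
to < 25 generations under the monotone length–generations relation.
Coordinates are 1-based inclusive internally (VCF convention); BED
exports are 0-based half-open. Empty inputs return empty results rather
than errors wherever a downstream stage can proceed (an empty filtered
matrix is an error; an ROH-free individual simply has F_ROH = 0).

## Limitations

The caller is the window-scan family, not an HMM, and works on unphased
genotypes: it cannot separate identity-by-descent from long stretches of
chance homozygosity beyond what the length/SNP-count rules impose.
F_HOM and F_ROH are the only inbreeding measures implemented (no
pedigree- or IBD-segment-based estimators). The Ne estimator inherits the
Sved relation's assumptions (neutrality, constant map, unlinked sampling
noise) and its known sensitivity to the α constant and binning. X
chromosomes are excluded by design; supply an autosome allow-list when
reading mixed VCFs.
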