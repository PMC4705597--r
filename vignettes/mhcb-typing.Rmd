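---
title: "SNP-panel typing of the chicken MHC-B region: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-panel typing of the chicken MHC-B region: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsnphap)
```

## The system

The chicken MHC-B region — roughly 231 kb between the *BG2* and *CD1A1*
genes on the AB268588 reference sequence — carries most of the genes that
determine genetically controlled disease resistance in chickens. bsnphap
implements an analysis pipeline for dense SNP-panel typing of this region:
a 101-SNP panel whose 90 *core* SNPs (30,189–240,933 bp) define
haplotypes, while the 11 5′ SNPs (9,551–27,791 bp) sit in a segment
subject to per-haplotype gene duplication and deletion and are therefore
excluded from haplotype identity.

Five analysis stages are implemented, each testable against a seeded
population simulator with full truth tables:

1. **Genotype calling** from KASP endpoint fluorescence (five clusters,
   including the 2:1 duplication clusters) and qPCR genome equivalents.
2. **Haplotype inference** within lines by homozygote seeding and
   subtraction, with cross-line reconciliation.
3. **Recombinant detection** under the both-parents-present rule, with
   breakpoint interval localization.
4. **Hotspot profiling** in 1000-bp bins and recombination / VNTR
   mutation-rate estimation.
5. **Family clustering** of haplotypes by neighbor joining, bootstrap
   support and a median pairwise patristic distance (MPPD) percentile.

## Data model

A diploid call at one SNP takes one of seven codes: `XX`, `YY`, `XY`,
`DUP_XXY` and `DUP_XYY` (the 2:1 endpoint-fluorescence clusters produced
when one haplotype carries a duplicated target), `AMBIG_BOTH` (both
alleles at equal signal in a bird homozygous for the rest of the
haplotype, rendered as IUPAC K/M/R/Y in tables), and `FAIL` (rendered
`-`). A haplotype is a vector over the core SNPs with states `X`, `Y`,
`B` (both; the duplication signal is part of haplotype identity) and `F`
(missing, written `F` in tables). Names follow the
`BSNP-<family letter><two-digit index>(<LEI0258 sizes>;<serology>)`
convention; recombinants are numbered `BSNP-Rec01`, `BSNP-Rec02`, … in
order of identification.

## Haplotype inference

Within a line, inference proceeds in rounds:

* **Seeding.** Birds with no heterozygous core SNP read their haplotype
  directly. Birds heterozygous at exactly *one* core SNP are also seeds:
  a single heterozygous site phases itself, yielding both haplotypes.
  This extension of the homozygotes-only seed step is needed for the
  procedure to be complete relative to the exhaustive reference below.
* **Subtraction.** A heterozygous bird compatible with exactly one known
  haplotype contributes the complement (per SNP: the other allele at
  heterozygous sites, the observed allele at homozygous sites, `B` at
  dual-allele sites, `F` at failures). Birds explained by two known
  haplotypes contribute nothing new; birds compatible with none or with
  several known haplotypes wait for later rounds.
* **Certainty pass.** Stepwise subtraction is greedy: it can miss
  haplotypes that are only determined jointly across birds, and it can
  assert a haplotype that an alternative phasing of equal parsimony
  avoids. When the residual problem is small (at most 24 non-seed birds,
  none with more than 12 heterozygous SNPs, bounded search), the package
  therefore re-phases all non-seed birds exactly, keeping a haplotype
  only if **every** phasing that adds the fewest new haplotypes contains
  it. On larger lines — where in practice almost every haplotype is
  seeded by homozygotes — the greedy chain stands and leftover birds are
  reported unresolved.

`enumerate_parsimony_phasings()` is the independent reference: a
branch-and-bound enumeration of all minimum-cardinality phasings of a
line. On small random lines the iterative procedure's haplotype set
equals the reference's forced set exactly; this is checked over hundreds
of random lines in the test suite. The "all consistent phasings" of the
reference are read as all *minimum-cardinality* phasings: without the
parsimony restriction the intersection degenerates (a heterozygous bird
with two or more heterozygous sites forces nothing in isolation), and
chained subtraction could never be validated.

Cross-line reconciliation merges haplotypes identical over their
non-missing positions, filling `F` positions from the best-supported
counterpart (merging is greedy in decreasing observation count); one
disagreement at a position where both calls are present keeps haplotypes
distinct.

## Recombinant detection and breakpoints

A candidate haplotype is called recombinant only when it is a
single-breakpoint mosaic of an ordered pair of haplotypes *both present
in the same population* — candidates whose best fit lacks a second
parent are reported separately as "apparent recombination", mirroring how
such cases must be excluded when the second parental haplotype is not
available. At most one exception SNP is tolerated by default
(`max_mismatches = 1`), annotated as a putative mutation when the allele
occurs in neither parent; a SNP failed in both the recombinant and one
parent is treated as consistently inherited (pairwise-deleted), not as an
exception. Only single-breakpoint mosaics are searched; double
recombinants are out of scope.

The breakpoint interval runs from the last informative SNP (parents
differ, all three calls present) matching the 5′ parent to the first
informative SNP matching the 3′ parent. Crossovers inside parental
identity blocks are localizable only to this interval.

In a pedigreed population, a recombinant carrier can be compatible with
two established haplotypes (for instance when the crossover lies near
either end of the core region, leaving one parent spuriously compatible),
so plain phasing leaves it unresolved. `scan_line_recombinants()`
therefore tests each complement of an unresolved bird as a candidate and,
when pedigree is available, requires each haplotype of the candidate pair
to be attributable to one parent (identical to a parental haplotype or a
clean mosaic of the parent's pair). This mirrors how a fully pedigreed
cross is analysed in practice: birds not conforming to parental
haplotypes are the recombination candidates.

## Hotspots and rates

Breakpoint intervals of unique recombinant haplotypes are profiled in
1000-bp bins anchored at coordinate 0. Two counting rules are provided:
`contained` (a bin counts when it lies inside the interval — the
convention used for reporting how often each 1000-bp segment is
encompassed by a recombination region) and `overlap`. Hotspots are
maximal runs of bins with at least 4 counts, lettered A, B, C, … in
coordinate order. Simulation-recovery tests use `overlap`, since a
crossover's interval always overlaps, but need not contain, the bin it
occurred in.

Rates are events per denominator, scaled per 100 (recombination) or per
1000 (VNTR mutation), with exact binomial 95% confidence intervals; the
conventional report rounds to one decimal, e.g. 7 recombinants among
1189 birds is 0.6 per 100, and 3 LEI0258 mutations among 2667 pedigreed
birds is 1.1 per 1000. LEI0258 mutation events are offspring allele
sizes attributable to neither parent, with the size change recorded
against the nearest parental allele (12/13-bp repeat-unit multiples are
expected; others are flagged but counted).

## Copy-number-aware genotype calling

On the normalized endpoint-fluorescence plane (signals summing to 1) the
six interpretable clusters sit at allele-dosage ratios: homozygotes at
(1,0) and (0,1), heterozygotes at (0.5,0.5), the duplication
heterozygotes at (2/3,1/3) and (1/3,2/3), and failed/no-template wells at
the origin. Real instruments report unnormalized intensities, but the
cluster geometry is carried by the ratios, which is what this model
encodes. Calling is nearest-centroid with a rejection radius
(default 0.25; points farther from every centroid are `UNDEFINED`,
i.e. aberrant products) rather than a fitted mixture: the cluster
geometry is specified, the vendor's clustering algorithm is not, and the
fixed-geometry rule is transparent and deterministic. At a per-axis noise
sd of 0.05 the nearest-centroid error is dominated by the
heterozygote-versus-duplication boundaries (centroid separation 0.236);
concordance stays above 99%.

qPCR genome equivalents are `efficiency^-(dCq_sample − dCq_calibrator)`
with `dCq = mean(target) − mean(control)`: copy number relative to a
disomic calibrator after normalization to a single-copy control gene.
Six replicates are assumed; replicates more than 1.5 Cq from their median
are dropped with a warning (replication is specified for the assay,
aggregation is not; the median rule is robust and conservative).
Efficiency defaults to 2.0 (perfect doubling) and is overridable —
per-haplotype efficiency differences, as hinted at by the anomalous
reference-genome sample, are deliberately not modelled. Zero copies give
no amplification, reported as such rather than as a number.

## Clustering into families

Distances are uncorrected fractional dissimilarities over the core SNPs
with pairwise deletion of missing calls; `B` is a fourth state (the
dual-allele signal is part of haplotype identity, so it must count as a
difference against either single allele). Pairs sharing fewer than half
their sites are refused. The NJ topology, bootstrap supports (resampling
core SNP columns, 1000 replicates by convention, majority-rule consensus
alongside per-branch support) and patristic distances go through ape —
the same toolchain this analysis tradition uses — with negative NJ branch
lengths clamped to zero.

MPPD clustering midpoint-roots the tree for clade enumeration, sets the
threshold at a percentile (default 10) of the pairwise patristic
distances over **all** nodes, internal and terminal, and selects maximal
clades whose median pairwise patristic distance is within the threshold,
walking down from the root and stopping at the first qualifying clade.
Each cluster is additionally checked against the bootstrap support of its
subtending branch (default minimum 70); clusters failing it keep their
letter but are flagged, the "dashed-line" status. Unclustered leaves
become singleton families, and letters are assigned in leaf-traversal
order to multi-member clusters and singletons alike.

One property of the percentile rule deserves emphasis: the threshold is
relative to the whole-topology distance distribution, so it presumes that
within-cluster pairs are a small minority of all pairs. With only two or
three clusters the within-cluster pairs exceed the 10th percentile and
tight clades fail the test; the packaged tests use either many families
(where the 10% convention recovers the truth exactly) or a higher
percentile for deliberately tiny topologies. Analyses of small haplotype
collections should choose the percentile accordingly.

## The simulator and what passing means

`simulate_founders()` builds lettered families around random core-allele
centres: any within-family pair differs at no more than
`within_family_diff` SNPs, any between-family pair at no fewer than
`between_family_diff` (defaults 3 and 30, the magnitudes separating
standard haplotype families). Each founder carries flank alleles, a
copy-number state for the 5′ CNV segment (defaults: 12,062–13,992 bp;
15% zero copies, 15% duplicated — the segment is deleted on some
haplotypes and duplicated on others), and a family-linked LEI0258 allele
size.

`simulate_population()` emulates the pedigreed multiple-line cross used
for rate estimation: 15 sires and 142 dams producing 1189 offspring
(defaults), founders dealt to 4 lines interleaved across families so
each line segregates a few distinct haplotypes. With probability
`recomb_rate_per_meiosis` (default 0.006) an offspring receives an
*observable* crossover: the event picks a heterozygous parent and a
position inside the parental informative span, so the product differs
from both parental haplotypes. This matches how the rate is measured —
detected recombinants per bird — a crossover between identical flanking
segments being invisible to any SNP method. LEI0258 alleles travel with
haplotypes and mutate at `lei_mutation_rate` per offspring in
12/13-bp steps, upward by default (the direction observed in pedigreed
data). Genotypes derive deterministically from the haplotype pairs, with
the CNV segment producing `FAIL` for two zero-copy haplotypes, 2:1
duplication codes for duplicated-by-single heterozygotes, and dual-allele
codes for duplicated homozygotes.

What the simulator does *not* emulate: genotyping error and allele
dropout outside the CNV segment, double crossovers and gene conversion,
per-haplotype PCR efficiency, realistic between-line allele-frequency
structure, and linkage to anything outside the panel. Passing the
recovery tests therefore demonstrates that the algorithms are correct
under the stated model — not that real plates, with rotation and
intensity drift, or real populations, with missing parents and
genotyping error, will behave as cleanly.

## Numerical choices and degenerate inputs

* Distance ties in NJ resolve as in the standard ape implementation,
  which is deterministic; two-taxon input is handled in closed form.
* The exhaustive phasing search and the certainty pass are bounded
  (node budget, per-bird heterozygosity cap); hitting a bound falls back
  to the greedy result rather than aborting.
* `fractional_dissimilarity` errors on pairs with zero comparable sites;
  the matrix builder refuses pairs sharing under half their sites.
* Hotspot binning anchors at coordinate 0 (the simplest convention; the
  origin is configurable through `bin_size` multiples in the profile).
* Rounding is applied only at reporting time; all stored rates are
  exact.
* Problem sizes in the tests (200 simulated populations for rate
  recovery, 500 random tiny lines for the phasing reference, 100 random
  trees for NJ, 50 seeds for family recovery, 200 bootstrap replicates in
  recovery runs) were chosen as the smallest sizes at which the binomial
  and resampling noise of each check is far below its decision margin.

## Known limitations

* Reproducing a *published* family partition letter-for-letter depends on
  the clade-enumeration convention of the MPPD method, which the
  underlying description leaves open; partitions are guaranteed stable
  only under this package's documented convention (midpoint rooting,
  top-down maximal clades, all-node distance distribution).
* The inference procedure reports certainty, not likelihood: it never
  guesses between equally parsimonious phasings. Statistical phasing
  (EM, pedigree likelihoods) is out of scope.
* Recombinant naming is by order of identification within a run; it is
  stable for a fixed input and seed but is not a registry of historical
  names.
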