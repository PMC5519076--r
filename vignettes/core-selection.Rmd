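---
title: "Greedy core collection selection: model, scores, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy core collection selection: model, scores, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpcore)
```

## The problem

A germplasm collection genotyped on a SNP array or by sequencing routinely
holds hundreds of accessions and 10^3–10^6 markers, many accessions being
exact or near duplicates of each other. A *core collection* is a small subset
chosen so that the genetic variation of the entire collection is retained,
cutting the cost of downstream phenotyping, GWAS panels, and breeding
programs. `snpcore` selects such a subset with a deterministic greedy
algorithm driven by genotype-class coverage, and evaluates any subset with
the field's standard statistics.

## Genotype classes and coverage

The input is an $n \times m$ matrix of genotype calls for $n$ samples and
$m$ markers. The **genotype class** at a marker is a distinct observed call
(`AA`, `AG`, `GG`, a VCF allele-index pair `0/1`, or a numeric zygosity code
taken verbatim); missing calls are not classes. Writing $GE_i$ for the
number of classes at marker $i$ in the entire collection and $GC_i$ for the
number of those classes present in a subset, the subset's coverage is

$$CV = \frac{100}{m'}\sum_{i=1}^{m'} \frac{GC_i}{GE_i},$$

the mean fraction of entire-collection classes captured, over the $m'$
markers that carry at least one non-missing call. Markers whose calls are all
missing are flagged uninformative and excluded from every statistic; they
cannot be covered by any subset and would otherwise put an arbitrary ceiling
on $CV$.

## The selection scores

Let $f_{i,c}$ be the relative frequency of class $c$ at marker $i$, computed
once over the entire collection with missing calls excluded from the
denominator (missing calls are ambiguous measurements, not a genotype). For
sample $j$ with non-missing marker set $N_j$, the **coverage score** is

$$C_j = \frac{1}{n(N_j)} \sum_{i \in N_j} f_{i,\,g_{ij}},$$

the mean frequency of the classes the sample carries. A high $C_j$ marks a
sample dense in common genotypes — the most representative single pick.
During selection, terms whose (marker, class) pair is already covered by the
chosen core are zeroed, so $C_j$ always measures what the sample would *add*;
the denominator $n(N_j)$ stays at the sample's non-missing marker count, so
scores remain comparable across iterations and the first iteration reproduces
the plain formula. The class frequencies $f$ are **not** recomputed as
samples are removed: holding them fixed keeps the greedy gain monotone and
the scores comparable across rounds (recomputing over remaining samples is a
defensible alternative, but it changes the meaning of a score mid-run and
cannot improve the class cover).

Ties in $C_j$ are resolved by the **diversity score**

$$D_j = \frac{1}{n(N_j)} \sum_{i \in N_j} (f_{i,\,g_{ij}} - C_j)^2,$$

the variance of the same (masked) frequency terms around the score; the
sample with the *smallest* $D_j$ — the most uniformly common genotype
profile — wins. $D_j$ uses the same masking as the $C_j$ it accompanies, so
the deviation is measured around the score actually compared.

## The greedy loop

Each iteration:

1. **Candidate filter.** Candidates are the remaining samples whose
   missing-call count equals the minimum among remaining samples, so
   low-quality samples never outrank complete ones. The filter is re-applied
   every round. If the filtered pool would add no new class while other
   remaining samples still would, the pool widens to all remaining samples
   for that step — the filter expresses a preference, and must not strand
   coverage that the collection actually contains (with a 100% target the
   run then always terminates at $CV = 100$, because every class retains at
   least one remaining carrier).
2. **Pick.** The candidate maximizing $C_j$ is selected; ties (equality
   after rounding to 12 decimal places, guarding against floating-point
   noise) go to minimum $D_j$.
3. **Residual ties** — samples equal in both scores — are almost always
   byte-identical duplicates, for which any member is an equivalent
   representative. The default picks the first in input order, which makes
   the selected *identifiers* identical across runs and seeds; this is what
   makes repeated runs reproduce the same core list exactly.
   `tie_break = "random"` instead draws uniformly from a stream seeded by
   `seed`, for users who prefer an unbiased choice among duplicates at the
   cost of ID-level reproducibility.
4. **Coverage update and duplicate removal.** The pick's (marker, class)
   pairs are marked covered — flags are monotone within a run — and the pick
   plus every remaining sample with a byte-identical call vector (missing
   positions included) is removed. Near-duplicate collapsing is deliberately
   out of scope: exact equality is cheap and never merges genuinely distinct
   genotypes.
5. **Stopping.** Checked in order: target coverage reached
   (`target_cv`, default 99%); CV gain of the step just taken below `delta`
   (default 0.01 percentage points); no remaining sample adds coverage
   (a defensive corner case); pool exhausted; `max_core_size` reached. Both
   defaults are expressed in percentage points, matching how users state
   them on the command line.

Because every accepted pick covers at least one new class with positive
frequency, the CV trace is strictly increasing, and the core never contains
two identical call vectors.

## Evaluation statistics

For any subset the package reports, alongside $CV$:

* **Shannon diversity** $SH = -\sum_{i} p_i \ln p_i$, where $p_i$ is the
  reference-allele frequency at marker $i$ computed *within the subset*
  (zero-frequency markers contribute 0 by the usual limit convention). The
  sum runs over the reference-allele term only, per the conventional
  definition for this report; it is a sum over markers, not a normalized
  per-marker entropy, so its scale grows with $m$.
* **Modified Rogers distance**
  $MR_{xy} = \sqrt{\tfrac{1}{2m''}\sum_i \sum_j (p_{xij}-p_{yij})^2}$
  over the $m''$ markers where both samples are called, with $p_{xij}$ the
  sample's relative dosage of allele $j$ (0, ½, 1 for diploids). The square
  root and the $2m''$ normalization keep $MR \in [0,1]$ regardless of
  missingness. The mean and the minimum over all subset pairs are reported;
  the minimum is the sharper statistic, measuring worst-case redundancy.
* **Allele-frequency spectrum**: binned reference-allele frequencies within
  a subset, and the maximum absolute difference between the normalized
  spectra of two subsets — used to check that a core preserves the
  entire collection's frequency distribution rather than enriching one tail.

The reference allele is the VCF REF allele (index `0`) for VCF input; for
matrix input, where no reference is defined, it is the major allele of the
entire collection (ties to the alphabetically first symbol, so the choice is
deterministic).

## The synthetic generator

`simulate_geno()` emulates the structure that makes core selection
non-trivial: `n_founders` distinct prototypes, each present as
`dups_per_founder` duplicate accessions, with per-marker reference-allele
frequencies drawn from a Beta distribution (default shape `(0.8, 0.8)`, a
U-shaped spectrum heavy in near-fixed markers, as SNP arrays on diverse
panels typically show) and founder genotypes in Hardy–Weinberg proportions.
`mutation_rate` re-draws individual calls of duplicates, creating
near-duplicates.

Missingness defaults to the **founder level**: missing cells are drawn once
per prototype and inherited by its duplicates, so each call is missing with
marginal probability `missing_rate` but unmutated duplicates remain
byte-identical clones. This is the regime the identical-sample removal rule
is designed for, and it models missingness driven by the assay/genotype
combination (e.g. probe failure on a particular haplotype) rather than by
the individual DNA sample. `missing_level = "sample"` gives the independent
per-call alternative; it breaks exact duplication, which is itself useful
for exercising the near-duplicate regime. Default sizes (25 founders × 20
duplicates × 2000 markers, 2% missing) are the standing study conditions
used throughout the tests.

What the generator does **not** emulate: linkage disequilibrium between
markers, pedigree or admixture structure, genotyping batch effects, or
selection/drift dynamics. Tests passing on this generator therefore show
correctness of the algorithm and its statistics, not performance claims
about any particular real panel.

## Numerical choices and degenerate inputs

* Score ties: equality after rounding to 12 decimals; target-coverage
  comparison carries a `1e-9` slack so an exactly-complete cover is never
  missed to floating point.
* A sample with no non-missing call scores 0 with a warning rather than
  failing the run.
* A pair sharing no called marker has undefined MR, signalled as `NA` with a
  warning.
* Empty matrices and all-missing collections are hard errors; all-missing
  *markers* are flagged and excluded.
* Heterozygote spellings are canonicalized on input (allele symbols sorted
  within a call; `1|0` → `0/1`), half-calls map to missing, and
  numeric zygosity codes pass through verbatim as opaque class labels.

## Problem sizes used in the test suite

The suite checks exact agreement (tolerance `1e-12`) between the production
implementations and naive loop re-implementations of $C_j$, $D_j$, $CV$,
$SH$ and $MR$ on 200+ random matrices up to 10 × 12 with random missingness
and coverage masks, and replays the full greedy loop against a brute-force
version on 100+ matrices up to 8 × 10. End-to-end properties (founder
recovery, 100-replicate reproducibility, spectrum preservation) run on
simulated collections of 500 × 2000 and 400 × 5000 — sizes chosen so the
whole suite completes in well under a minute per property while still being
an order of magnitude larger than anything the oracles cover.

## Known limitations

* The greedy criterion optimizes common-allele coverage; collections whose
  value lies in rare variants are better served by rarity-weighted methods —
  by construction a rare class is covered late.
* Exact-duplicate removal does not collapse near-duplicates; with
  `mutation_rate > 0` (or sample-level missingness) cores can exceed the
  founder count because near-clones legitimately add uncovered classes.
* $SH$ follows the reference-allele-only convention; it is not comparable
  with per-marker entropies summed over all alleles.
* With very few markers (tens), class-frequency ties are common and the
  diversity tie-break does most of the work; the method is intended for
  dense marker panels.
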