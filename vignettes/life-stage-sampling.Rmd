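---
title: "Life-stage sampling, sibship, and isolation by distance: methods"
author: "stagemix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Life-stage sampling, sibship, and isolation by distance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagemix)
```

## The problem

Population and landscape genetic studies of pond-breeding amphibians rarely
sample the life stage they would ideally sample. Adults are hard to trap;
embryos and larvae are abundant and cheap. But most amphibians have Type III
survivorship — the juvenile cohort in a pond descends from a modest number
of clutches, most of which will not survive — so a juvenile sample carries
(i) full-sib redundancy and (ii) extra cohort-level drift relative to the
breeding population. `stagemix` quantifies what those two properties do to
the standard inference pipeline: per-pond diversity summaries (observed
heterozygosity $H_o$, rarefied allelic richness $A_r$, LD-based $N_e$),
pairwise differentiation ($F_{ST}$, chord distance $D_C$), and
isolation-by-distance (IBD) tested with simple Mantel tests — with and
without sibling pruning, across mixtures of life stages, and across marker
panels of different size.

## Statistics implemented

**Weir–Cockerham $F_{ST}$.** Per locus and allele we compute the classic
variance components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals) from sample sizes, allele
frequencies and observed heterozygote frequencies, and report the
multilocus ratio of sums $\hat\theta = \sum a / \sum (a+b+c)$ ("ratio of
averages"). Estimates are kept raw — small negative values are the expected
behaviour of an unbiased estimator at zero differentiation — and should be
clamped only for presentation. Pairwise matrices recompute $\theta$ from
each pair of samples alone. Loci with no data in a group are dropped for
the affected comparison (pairwise deletion); with the sub-1% missingness
this package targets, imputation would be over-engineering.

**Chord distance.** Two variants of the Cavalli-Sforza/Edwards angular
distance are exposed, with $S_\ell = \sum_a \sqrt{p_{\ell a} q_{\ell a}}$:
the angular form $D = \sqrt{1 - \tfrac1L\sum_\ell S_\ell}$ (default,
bounded in $[0,1]$) and the Takezaki–Nei normalisation
$D = \tfrac1L \sum_\ell \tfrac2\pi\sqrt{2(1-S_\ell)}$. Field studies often
cite only the software used, which leaves the exact variant ambiguous; both
are provided and every output records which one produced it.

**Rarefied allelic richness.** The hypergeometric expectation
$A_r = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$ of the number of
distinct alleles in $g$ gene copies. The default $g$ is twice the smallest
per-group non-missing individual count over all groups and loci (the
"rarefy to the smallest sample" convention); a fixed $g$ can be supplied.

**LD-based $N_e$.** A Burrows composite-disequilibrium estimator: mean
squared composite-LD correlation $\hat r^2$ over locus and allele pairs
(alleles under 5% excluded, configurable), corrected by the $1/S$ sampling
contribution, and $\hat N_e = 1/(3(\bar r^2 - 1/S))$ under random mating.
Non-positive corrected disequilibrium is reported as an infinite estimate.
This is a deliberately standard, transparent estimator; it is *not* a
re-implementation of any particular program's likelihood machinery, and the
package documents it as such.

**Mantel tests.** $r$ is the Pearson correlation of the upper triangles;
the null permutes rows/columns of one matrix. The default tail is one-sided
upper, because IBD predicts a positive correlation; the p-value carries the
plus-one correction and ties count as extreme (both conservative choices).
With $n$ ponds there are only $n!$ distinct relabelings, so for $n \le 8$
`mantel_exact()` enumerates all of them; with five ponds the attainable
floor is $1/120 \approx 0.0083$, worth remembering when reading "p = 0.016"
in five-pond studies (that is exactly $2/120$). The permutation and exact
tests agree in the limit, which the test suite asserts.

**Comparisons.** Group sizes here are 3–5 ponds, far too small for
parametric tests, so stage comparisons use a permutation Welch-$t$
(label-shuffling; sign-flip enumeration for paired designs with $n \le 20$,
which makes the paired p exact) and a one-way $F$ with a resampling null.
For the latter, a label-permutation null is the statistically cleaner
default; a pooled with-replacement bootstrap null is also provided because
"bootstrapped ANOVA" is the phrase used in the field literature this
package mirrors, and the two agree in size on null simulations. Per-pond
summary tables use the population (denominator-$n$) standard deviation:
all five ponds of the design are observed, not sampled. Published tables in
this literature are not always consistent about the denominator, so the
sample-SD convention is available too.

## The synthetic-data generator

The generator reproduces the *statistical structure* of a five-pond
spotted-salamander study design, not its genotypes:

* **Spatial frequency field.** Per locus, ancestral frequencies are drawn
  from a symmetric Dirichlet (concentration 1.0, 2–10 alleles); pond
  deviations are multivariate normal with covariance
  $\Sigma_{ij} = F \exp(-d_{ij}/\rho)$ scaled per allele by $p_0(1-p_0)$,
  applied on the frequency scale, clipped to $[0,1]$ and renormalised.
  Nearby ponds share drift, so expected pairwise $F_{ST}$ rises with
  distance like $F(1-e^{-d/\rho})$. The clip/renormalise step attenuates
  the realized variance by roughly 0.6 at these settings, so the default
  `drift_F = 0.02` is calibrated to a *realized* mean adult pairwise
  $F_{ST}$ of about 0.01 over replicate datasets — the adult scale reported
  for this kind of system — with `ibd_range_m = 1500` over a 4 km extent.
  The frequency-scale Gaussian with clipping was chosen over a
  logistic-normal for transparency; its tail-clipping bias is acceptable at
  $F \le 0.05$ and is covered by tolerance-based tests.
* **Breeding pool vs adult sample.** Each pond holds `n_breeders = 250`
  exchangeable HWE breeders; the 25 "trapped" adults are a subset. Clutch
  parents are drawn from the breeding pool, so a sampled juvenile's parent
  is in the adult sample with probability $1-(1-25/250)^2 \approx 0.19$ —
  partial parent–offspring overlap, as in the field, rather than total.
* **Clutch-structured juveniles.** 60 clutches per pond, each founded by a
  pair of distinct breeders drawn with replacement across clutches (the
  same pair can found several clutches, creating cryptic full sibs even
  among one-embryo-per-clutch samples). Embryos: one offspring from each of
  25 distinct clutches. Larvae: 30 offspring allocated to clutches with
  Dirichlet(`larval_clumping = 1.0`) weights — clumped survival and netting
  concentrate the sample in fewer families. Juvenile cohort drift arises
  mechanistically from the finite clutch number, not from an imposed
  variance parameter. Two of five ponds yield no larvae, mirroring
  real-world sampling failure.
* **Calibration.** The two generator quantities treated as binding are the
  realized adult differentiation (~0.01, above) and the expected proportion
  of larvae flagged as redundant sibs, which Dirichlet-multinomial
  arithmetic puts at ~0.33 for 60 clutches at concentration 1.0 — the
  figure reported for larval samples in this system. Both are asserted
  over 200 replicate datasets in the acceptance suite.
* **What it does not emulate.** Genotyping error and allele dropout; adult
  sib structure (off by default; a label-level `adult_sib_fraction`
  emulates redundant adults when needed); embryo sib redundancy beyond
  chance pair collisions (field reports of ~15% embryo removals likely
  reflect sibship-inference behaviour we do not model); mutation;
  overlapping generations; selection. Passing tests therefore demonstrate
  the pipeline's behaviour under the modelled mechanisms, not the full
  messiness of real data. One visible consequence: in the field data
  allelic richness *rose* slightly with juvenile proportion, while the
  generator produces a flat-to-slightly-declining $A_r$; the mechanism
  behind the field pattern is unknown and not modelled.

## Data preparation

**Locus screening.** Monomorphic loci are dropped, and each locus is tested
for Hardy–Weinberg proportions within each pond by a Monte-Carlo exact
test: gene copies are permuted and re-paired, and the two-sided p-value is
the plus-one-corrected fraction of permuted tables whose heterozygote count
is at least as far from the permutation mean as observed. Removal requires
failing the Bonferroni-corrected threshold across loci x ponds — a
deliberately conservative screen (Bonferroni, not FDR, is the default
because the cost of wrongly discarding a locus is low and the test count is
small; the correction is configurable).

**Sibling pruning.** Pruning is label-driven: one individual per family is
retained per (pond, stage) group (`scope = "within_stage"`) or per pond
across stages (`scope = "pooled"`, which with a pedigree also removes
juveniles whose parent is a retained adult — the preparation used before
pooling life stages). The retained representative is the lexicographically
smallest id, making pruning deterministic and idempotent. Family labels
come from the simulator's truth or from `heuristic_sib_flags()`, a
Queller–Goodnight relatedness single-linkage clusterer (threshold 0.35,
halfway between the unrelated and full-sib expectations). The heuristic
takes reference allele frequencies from the whole pond rather than the
group being screened, because estimating frequencies from a sib-laden
sample depresses the estimator. Likelihood-based sibship reconstruction is
out of scope: what the downstream analysis consumes is the pruning logic,
not the inference of the labels.

## The resampling engines

`bootstrap_mixed()` pools each pond's individuals across stages and draws
`n_sample = 25` per pond per replicate, *without* replacement (the design
subsamples individuals; a with-replacement mode exists behind a flag),
recomputing $H_o$, $A_r$, $F_{ST}$ and $D_C$ each time; summaries are
percentile 95% intervals over 1,000 replicates at the fidelity preset used
for final runs.

`mixture_grid()` sweeps the juvenile proportion $\pi \in \{0, 0.05, \dots,
1\}$ and the locus count $L \in \{5, 10, 15\}$: each replicate draws
$k = \mathrm{round}(\pi \cdot 18)$ juveniles (rounding half away from zero;
the choice of rule changes $k$ by at most 1) and $18-k$ adults per pond
from the within-stage sibling-pruned dataset, plus a fresh random subset of
$L$ loci, then computes the genetic distance matrix, a Mantel test against
the fixed geographic distances, and pond-averaged $H_o$ and $A_r$. With
five ponds the per-replicate Mantel p is computed by exact enumeration of
the 120 relabelings — the exact limit of the 100,000-permutation test, at a
fraction of the cost; Monte-Carlo permutation remains available by flag.

Numerical notes: resampling statistics run on an integer-encoded copy of
the genotype table, so a full 21 x 3 grid at 1,000 replicates is minutes of
work on one core; within each replicate $A_r$ applies the smallest-sample
rule to that replicate's own gene-copy counts, so the rarefaction base
tracks the (rare) missing genotypes of the draw.

## Problem sizes used by the test and acceptance runs

The package's own checks run at reduced but statistically meaningful
scales, chosen so the full suite completes in a few minutes of one core:
200 replicate datasets for the generator calibration; 200 bootstrap
replicates per grid cell over a 21-point proportion grid at $L \in \{5,
15\}$; 100,000 Monte-Carlo subsets per rarefaction check; 100,000
permutations per Mantel cross-check; 500 replicates for the type-I-error
checks; 40 Wright–Fisher replicates at $N_e = 50$ for the LD-$N_e$
recovery check. The `fidelity = "full"` preset of `run_pipeline()` uses
1,000 bootstrap replicates throughout.

## Known limitations

* Family labels are the unit of pruning; when they come from the heuristic
  rather than truth, mislabeling propagates silently into the "pruned"
  dataset. The simulator's truth labels bound the attainable behaviour.
* The LD-$N_e$ estimator uses the plain $1/S$ correction, adequate for the
  directional and order-of-magnitude uses it serves here; it does not
  implement the refined small-sample bias corrections of dedicated tools.
* Simple Mantel tests are used deliberately, to mirror the analysis
  tradition this package examines; they are not the state of the art for
  landscape inference (dbRDA, MRM, Moran eigenvector maps and mixed models
  are, and are out of scope).
* With five ponds, Mantel p-values live on a 120-point lattice; nothing
  below 0.0083 is attainable, and single-dataset p-values should be read
  accordingly.
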