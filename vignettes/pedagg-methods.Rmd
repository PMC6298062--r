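---
title: "Familial aggregation tests on large pedigrees: models and methods"
author: "pedagg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Familial aggregation tests on large pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedagg)
```

## The problem

Familial aggregation (FA) analysis asks whether a binary trait clusters
among relatives beyond what population prevalence and chance explain. It is
typically the first step of a genetic-epidemiological study: families (or
individuals embedded in families) flagged by an FA test become candidates
for downstream variant hunting. Large population cohorts yield pedigrees
that are wide, deep, irregular, and only partially phenotyped, which rules
out classical segregation models and motivates tests built on the kinship
coefficient.

`pedagg` implements five such tests, an empirical-null machinery to
calibrate them, a Mendelian trait simulator, a synthetic pedigree
generator, and a benchmark layer that measures how reliably each test
recovers a planted case family among decoy families.

## Pedigree model

A pedigree is a table of individuals with `family`, `id`, `father`,
`mother`, `sex` and `phenotype` (`affected` / `unaffected` /
`unphenotyped`). I/O uses the 6-column PLINK-FAM text dialect
(`read_ped()` / `write_ped()`), the most widely parsed format for this
information. Structural validation enforces unique ids, existing and
sex-consistent parents, and an acyclic parentage graph.

Three conventions deserve a note:

* **Both-or-none parents.** The kinship recursion and gene dropping need
  each individual to have either two parents or none. Records with a single
  parent are completed by inserting an anonymous unphenotyped founder of
  the opposite sex (`complete_parents()`), shared by full siblings.
  `read_ped()` applies this by default and reports the inserted ids.
* **Filtering.** `filter_pedigree()` removes unknown-sex individuals, then
  iterates removal of individuals with no relatives (no parent and no
  child) to a fixed point, mirroring the standard pre-processing of
  population pedigrees. A child of a removed parent keeps its remaining
  parent link; completion is deliberately *not* re-applied after filtering,
  so the filter's output matches what survives of the raw records (kinship
  and simulation re-complete internally as needed). The operation is
  idempotent and returns a removal report (id, reason).
* **Generations.** `assign_generations()` gives founders at the top of a
  family generation 1, children one more than their deepest parent, and
  married-in founders (parentless individuals whose only tie is a shared
  child) the generation of their co-parent, propagated monotonically to a
  fixed point. The 1-based convention anchors the generation masking of the
  simulator; no standard convention exists, so this one is fixed and
  documented.

## Kinship

The kinship coefficient phi(i, j) is the probability that two alleles
drawn at random, one from each individual, are identical by descent.
`kinship_matrix()` computes it with the classical recursion in topological
order — founders: phi(i, i) = 1/2, phi(i, j) = 0; non-founder i with
parents f, m: phi(i, i) = (1 + phi(f, m))/2 and
phi(i, j) = (phi(f, j) + phi(m, j))/2 for j not a descendant of i — so
inbreeding is handled through the self-kinship term. Unphenotyped
individuals participate fully: their role is to connect phenotyped
relatives. The matrix is stored as dense per-family blocks (it is exactly
block-diagonal by family), and can be exported as long TSV or MatrixMarket.

As an independent check, `kinship_gene_drop()` estimates the same
quantity by simulation: two uniquely labelled alleles per founder are
dropped through the pedigree and the IBD probability of a random allele
pair is averaged over drops. The estimator's standard error is available in
closed form, so recursion and simulation can be compared on a z-scale; the
test suite does this on dozens of generated families.

## The five tests

For a family with affected members `A`:

* **IF** (genealogical index of familiality): mean kinship over all
  unordered pairs of affected family members. One unit per family; needs
  at least 2 affected.
* **KS** (kinship sum): for each affected individual i, the sum of
  phi(i, j) over all other affected members of i's family. One unit per
  affected individual; needs at least one other affected in the family.
* **GR / GC** (kinship-group tests): i's *kinship group* is every
  phenotyped family member at least as close to i as i's most distant
  affected relative with positive kinship (ties in "most distant" broken by
  id for determinism). GR counts the affected members of that group
  (including i); GC records the kinship of the closest affected relative in
  it. Both need an affected relative with phi > 0. Because the threshold is
  the *minimum positive* kinship to an affected relative, GR reduces
  algebraically to 1 + #(affected relatives with phi > 0) and GC to the
  maximum kinship to an affected relative; the exported statistic functions
  compute the literal group construction, the Monte-Carlo engine uses the
  reduction, and the tests assert both routes agree.
* **PB** (binomial test): the exact upper tail P(X >= k) for
  X ~ Binomial(n, R), where n is the family's phenotyped size, k its
  affected count and R the trait prevalence (by default the pool's
  affected/phenotyped ratio, overridable). Computed with `pbinom`, i.e.
  exact summation, no normal approximation.

## Empirical nulls and their conditioning

The four kinship-based statistics have no tractable closed-form null on an
arbitrary pedigree. `run_fa_tests()` therefore resamples, `B` times
(default 50 000), the observed number of affected labels uniformly without
replacement from the pool of *all* phenotyped individuals across *all*
families (`resample_null()`), recomputes each statistic per replicate, and
estimates the P value with the add-one estimator
(1 + #\{null >= observed\}) / (B_eff + 1), which is never zero and counts
ties toward the tail.

Each unit is scored against the replicates that satisfy *that unit's own
testability precondition*:

* IF, family f: replicates with >= 2 draws in f;
* KS, individual i: replicates where i is drawn *and* at least one other
  member of i's family is drawn;
* GR/GC, individual i: replicates where i is drawn and i's group is
  defined (>= 1 drawn relative with phi > 0).

This matched conditioning is what makes the P values exchangeable with the
observed data under the null: given the total affected count, a Bernoulli
phenotype assignment conditioned on a unit being testable has exactly the
law of a resampling replicate conditioned the same way. The number of
qualifying replicates is reported as `effective_B`; a unit with none gets
P = 1. The suite verifies the construction two ways: against exhaustive
enumeration of all label assignments on a small family (exact conditional
permutation P), and by calibration under control-only phenotypes (below).

Multiple testing uses Benjamini-Hochberg within one test run across its
testable units; ranking is tie-averaged and always on raw P values, which
preserves order where BH would create artificial ties.

### What calibration can and cannot show

Under control-only phenotypes (200 synthetic families, prevalence 1/16,
B = 2000) the IF and KS rejection rates at P_raw <= 0.05 sit inside the
99% binomial band, and the KS P distribution is uniform in the mid-range.
Two caveats are structural, not implementation artifacts:

* **Discrete atoms.** A sizeable share of KS units observe statistic 0
  (their co-affected family members are all kinship-unrelated); their
  conditional P is exactly 1. The P distribution is exactly calibrated at every
  achievable level (a staircase, never anti-conservative), but a
  Kolmogorov-Smirnov test against the *continuous* uniform necessarily
  rejects once such an atom exists, because D is bounded below by the
  atom's mass.
* **GR and GC.** These statistics live on very few atoms (small integer
  counts; a handful of kinship levels). Most control units sit at the
  statistic's minimum, where P = 1, and the remaining tail mass is coarse,
  so the rejection rate at 0.05 lands well outside a tight binomial band —
  below it at some pedigree realizations, above it at others (unit
  correlation within families further inflates the variance of the rate).
  This mirrors the field's experience that the group tests' significance
  calls need independent confirmation; within this package, treat GR/GC
  P values as ranking devices, not calibrated error rates.

## Trait simulator

The benchmark plants a Mendelian autosomal-dominant trait in one *case
family* per family set:

1. **Gene drop** (`gene_drop_dominant()`): one founder with descendants is
   seeded as a heterozygous carrier; each child of one carrier parent
   inherits the allele with probability 1/2 (3/4 for two carrier parents);
   carriers are affected — full penetrance, no phenocopies.
2. **Penetrance masking** (`apply_penetrance()`): exactly
   round-half-up((1 − Q)·A) of the A affected are switched to unaffected,
   drawn uniformly. The exact-count reading (rather than per-individual
   Bernoulli thinning) is deterministic in A and unbiased on the grid of
   interest.
3. **Generation masking** (`mask_generations()`): the sub-branch anchored
   at the seeded founder — the founder, its spouses, its descendants and
   their spouses within G generations counted inclusively from the
   founder — keeps its simulated status; everyone outside is reassigned by
   an independent Bernoulli(R) draw. G = "all" is the identity. The
   sub-branch definition is one of several defensible readings of
   "a sub-branch with G generations"; anchoring at the seeded founder keeps
   the masked trait a connected Mendelian island.

Control families get independent Bernoulli(R) phenotypes
(`generate_controls()`). `build_family_sets()` assembles, for each family
a, the set F_a = (case family a, all other families as controls), with
controls regenerated independently per set. Two pragmatic rules keep every
family usable: an integer G deeper than the case branch is capped at the
branch depth (the whole branch is kept), and a case pipeline that cannot
reach 2 affected within 100 redraws (possible for very small families
under penetrance masking, e.g. a 3-member family at Q = 0.6) keeps its
best draw and is simply untestable for the >= 2-affected tests.

All randomness is driven by counter-based substreams
(`substream_seed()`) derived from one master seed and the (scenario,
family-set, stage) indices, so any subset of the benchmark can be
recomputed independently and reproducibly, in any order.

The canonical scenario grid pairs penetrance Q in \{1, 0.6, 0.3\} with
prevalence R in \{1/10, 1/16, 1/25, 1/50, 1/80\} and generations G in
\{2, 3, all\}, omitting the cells where cases are indistinguishable from
background (low Q at high R) or trivial; `scenario()` warns (or errors in
strict mode) outside the grid.

## Synthetic pedigrees

`generate_pedigree()` builds independent families top-down from a founder
couple: sibships are zero-truncated Poisson with mean `mean_sibship`
(default 4.0), children marry new unrelated founders and reproduce with
probability `p_repro` (default 0.9) until the family's generation count
(uniform on [2, 5]) is reached. The defaults were tuned once so that a
415-family pedigree has a median family size close to 36 — the backbone
shape of the large breast-cancer genealogy customarily used for FA
benchmarking — and are then left alone; the suite checks the median across
five generator seeds. What the generator does *not* emulate: the real
cohort's exact size distribution (our deep families are larger than real
ones because fertility does not decline by generation), consanguinity
loops (spouses are always new founders, which keeps kinship ground truth
analytic), missing phenotypes, and the two-to-one imbalance of real
sex-specific ascertainment. Passing benchmarks on these fixtures therefore
demonstrates correctness of the machinery and qualitative method ordering,
not quantitative performance on any particular real cohort.

## Benchmark and its measures

`run_assessment()` runs, for each scenario and each family set: the
requested tests on the whole pedigree with the set's phenotypes; family
level summarization (IF/PB are family-level already; KS/GR/GC take the
lowest raw P within each family, `family_min_p()`); BH adjustment of the
family-level P values *within the set*; and the case family's tie-averaged
rank on raw P values (untestable families enter at P = 1 and rank last).
Pooling the sets gives, with n families, n cases and n(n−1) control
instances — a deliberately imbalanced design, which is why performance is
summarized by precision/recall rather than ROC:

* `bin_ranks()` — counts of case families that are significant in the top
  three, insignificant in the top three, ranked 4–10, or beyond, plus
  top-rank totals ("top-ranked" means the case shares the set's best raw
  P value);
* `overlap_sets()` — the partition of family sets by the exact subset of
  tests that top-ranked them (the UpSet-plot table);
* `pr_curve()` — a step curve of precision versus recall over every
  distinct adjusted P, no interpolation (linear interpolation is optimistic
  in PR space), with the operating point at the largest threshold at or
  below 0.05 flagged.

Classification is on within-set adjusted P by default (configurable to
raw), so the 0.05 threshold coincides with each set's significance calls.
Pooling adjusted-within-set P values mixes slightly different adjustment
scales across sets; adjusting across the pooled 415 x 415 table instead is
a one-line configuration change and gives the same qualitative ordering.

On easy scenarios (full penetrance, 4% prevalence, three generations) the
KS and PB tests top-rank at least as many planted cases as IF across
seeds, and the mean case rank under KS improves monotonically with higher
penetrance and with lower prevalence — the two directional findings the
benchmark is designed to reproduce at reduced scale. The suite runs these
checks at 50 families, B = 2000, 5 seeds; the acceptance script re-derives
them from scratch at the same sizes (these sizes are the package's
standing reduced-scale study design; full-scale runs simply raise
`n_families` and `B`).

## Numerical choices

* Empirical P: add-one estimator, ties count toward the tail with a
  relative tolerance of 1e-9 to absorb floating-point drift between the
  vectorized and scalar statistic paths.
* Penetrance masking count: round-half-up (floor(x + 0.5)), so Q = 0.6
  with A = 5 masks exactly 2.
* `most_distant_affected()` ties: lexicographically smallest id, for
  deterministic groups.
* Degenerate inputs: empty pedigrees are legal everywhere downstream of
  parsing; families with no testable unit are reported with status
  `not_applicable` and excluded from BH and ranking; PB with k = 0 is
  exactly 1.
* The Monte-Carlo engine materializes per-family draw indicators and uses
  `rowsum`-based accumulation, so a 200-family calibration run at
  B = 2000 takes seconds; memory scales with (family size x B) only for
  one family at a time.

## Limitations

* GR/GC significance is not calibrated (see above); the package reports it
  because the tests are established, but ranks are the meaningful output.
* The simulator seeds exactly one carrier founder per case family; traits
  entering a family twice (e.g. by marriage between carrier lineages) are
  out of scope, as are recessive and X-linked models.
* Numerical identity with other implementations of these tests is not
  claimed: the resampling-null details (conditioning, estimator) are fixed
  by this package's contracts and validated against enumeration, not
  against other software.
* Real cohorts with one dominating mega-family stress the family-level
  tests (IF/PB) in ways the benchmark's independent families do not; the
  per-individual KS test is the robust choice there, with PB as
  confirmation on families of moderate size.
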