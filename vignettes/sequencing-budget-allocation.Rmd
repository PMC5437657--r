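---
title: "Selecting focal individuals and allocating a sequencing budget"
author: "SeqAlloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting focal individuals and allocating a sequencing budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SeqAlloc)
```

# The problem

In a genotyped population, whole-genome sequencing is too expensive to apply
to everyone. If a small set of individuals is sequenced and their haplotypes
are phased at the sequence level, sequence alleles can be imputed into every
other individual that shares those haplotypes. Two decisions then determine
the value of the investment: *who* to sequence, and *how much* coverage to
buy for each member of the chosen individuals' families so that the
sequenced haplotypes can actually be phased. SeqAlloc treats these as a
weighted maximum-coverage problem followed by a budget-constrained
stochastic optimisation.

# The haplotype library

`buildHaplotypeLibrary()` turns a phased SNP panel into a windowed haplotype
library.

* **Eligibility filter.** Individuals with at least `minPhased` (default
  0.9) of their alleles phased are retained first; then markers with at
  least `minPhased` phased alleles across the retained individuals. The
  order (individuals, then markers) is fixed: filtering markers first would
  let a badly phased individual drag down marker statistics that are fine in
  the rest of the panel. `filterEligible()` exposes the filter on its own.
* **Window tiling.** Chromosomes are tiled into consecutive, non-overlapping
  windows of `windowLength` markers (default 250) anchored at the first
  marker; a trailing remainder shorter than the window is dropped so that
  all haplotype strings have equal length and exact identity is meaningful.
  With 1000 SNPs per chromosome the default tiles each chromosome into 4
  windows exactly.
* **Identity.** Haplotypes are matched at 100% identity on the allele
  string restricted to eligible markers inside the window. Two strings
  differing at a single marker are distinct library entries; exact matching
  makes sharing robust to the alternative of fuzzy matching silently merging
  phasing errors.
* **Missing data.** A gamete with any missing allele at an eligible marker
  inside a window contributes no haplotype for that window — a partial
  string cannot be certified identical to anything. Skipped gametes are
  counted and reported.

Within a window, copy counts sum to the number of complete gametes; this
conservation law is asserted by the class validity check after every build.

# Greedy selection of focal individuals

`selectFocalIndividuals()` ranks individuals by repeatedly picking the
candidate with the largest marginal covered copy count

$$s(i \mid M) = \sum_{h \in H(i) \setminus M} c(h),$$

then adding all of the winner's haplotypes to the mask $M$. Three
conventions matter:

* **Copy counting.** Scores count population haplotype *copies* (including
  the candidate's own two), not distinct carriers. Copy counting makes the
  conservation checks exact and weighs a haplotype by the number of gametes
  into which it could be imputed.
* **Double carriers.** An individual carrying the same haplotype on both
  gametes counts its population mass once — masking operates on haplotypes,
  so the second copy adds nothing to what sequencing that individual would
  capture.
* **Tie-break.** Equal scores are resolved toward the smallest id (numeric
  order when ids are numeric), making rankings reproducible.

Masking is global across windows and permanent: once a focal individual is
selected, its haplotypes are treated as sequenced and phased everywhere.
Since the objective is weighted coverage, marginal gains are non-increasing
(submodular); the `FocalRanking` validity check asserts this on every run.
Individuals with existing sequence data can be pre-masked
(`alreadySequenced`), and individuals without a DNA sample can be excluded
as candidates while their copies still count toward others' scores
(`doNotSequence`).

# The key-ancestors baseline

`selectKeyAncestors()` implements the classical pedigree-only comparator:
ancestors ranked by marginal expected genetic contribution to a reference
set (default: the youngest generation). The marginal contribution of a
candidate $a$ given the already selected set $S$ is defined here as the
probability that a random reference gene's line of descent passes through
$a$ and through no member of $S$ anywhere on its path. This makes
successive marginals account for disjoint portions of the reference gene
pool, so they never exceed the raw contribution and their cumulative sum is
bounded by 1 — properties the test suite verifies against a gene-dropping
Monte-Carlo oracle. The implementation exploits the decomposition of a
path at the candidate: marginal$(a) = u(a)\,v(a)$, where $u$ is the
reference gene mass reaching $a$ from below while avoiding $S$ (one reverse
sweep) and $v$ the probability that $a$'s own gene lineage avoids $S$ above
(one forward sweep), giving $O(n)$ work per pick.

# Allocating the budget

`allocateBudget()` distributes a monetary budget over the members of the
focal families (7 members each; unknown members are fixed at 0x).

* **Costs.** A member sequenced above its prior coverage pays
  `libraryCost` (unless a library exists) plus `perXCost` per incremental
  1x; defaults GBP 40 and GBP 85. Shared ancestors hold one coverage and
  are paid once, at the maximum requested across families. With 6 coverage
  levels and 7 members a family has $6^7 = 279{,}936$ possible scenarios
  (`countScenarios()`).
* **Accuracy.** The expected phasing accuracy of a scenario,
  $\varphi \in [0,1]$, is pluggable. The default surrogate
  $\varphi = s(c_\mathrm{focal})\,[0.5 + 0.3\,s(c_\mathrm{sire}+c_\mathrm{dam})
  + 0.2\,s(\textstyle\sum c_\mathrm{gp})]$ with $s(c) = 1 - e^{-c/5}$
  encodes the qualitative behaviour of family-based phasing — nothing is
  phased without focal data, parents matter more than grandparents,
  returns diminish with coverage — but its absolute scale is uncalibrated.
  Any empirical table (`accuracyFromTable()`, CSV of 7 coverages ->
  $\varphi$) can replace it, and conclusions about absolute percentages
  phased should only be drawn with a calibrated table.
* **Objective.** $G = \sum_f p_f \varphi_f - \lambda \max(0,
  \mathrm{cost}-\mathrm{budget})/\mathrm{budget}$. The penalty form is the
  simplest that uses all the ingredients (family weights, accuracies,
  budget, prior data); $\lambda = 10$ is strong enough that overruns never
  win yet finite so the search can traverse infeasible regions. A final
  greedy repair (step down the member losing the least $p_f\,\Delta\varphi$,
  ties to the largest saving) guarantees the reported solution is within
  budget whenever any feasible solution exists.
* **Search.** Standard rand/1/bin differential evolution (population 50,
  $F = 0.8$, $CR = 0.9$, 10,000 rounds by default) over per-individual
  coverage-level logits. During the search, scenarios are sampled from the
  softmax multinomial each candidate encodes; the elitist best-so-far
  solution is re-evaluated with deterministic argmax decoding (temperature
  0) so that sampling noise cannot lose it, and the best objective is
  non-decreasing across rounds by construction.

Prior sequence data reduces incremental cost, waives the library cost, and
contributes to $\varphi$ through the effective coverage
$\max(\mathrm{target}, \mathrm{prior})$.

# The population simulator

`simulatePedigreePopulation()` emulates the recent history of an
intensively selected livestock nucleus: discrete generations of
`nPerGeneration` individuals (default 1000) with an exactly equal sex ratio
(sex alternates within a cohort), the `nSiresSelected` males (default 25)
with the highest true breeding value truncation-selected as sires, all
`nDams` females (default 500) used unselected, matings drawn uniformly with
replacement (no litter structure), and gametes formed under the Haldane
model — Poisson crossovers at 1 Morgan per chromosome, uniform positions,
no interference. The additive trait has `nQtn` QTN (default 10,000) spread
equally across chromosomes with effects from $N(0, 1/n_\mathrm{QTN})$; no
dominance or epistasis. Founder chromosomes are drawn from the base
haplotypes without replacement within an individual and with replacement
across individuals (the alternative — global sampling without replacement —
would tie the founder cohort size to the base pool size for no benefit).

Base haplotypes come from `simulateBaseHaplotypes()`: marker allele
frequencies drawn from Uniform(0.05, 0.95) and alleles i.i.d. Bernoulli per
haplotype, with monomorphic markers resampled. This is a deliberately
simple neutral stand-in for a demographic history: the selection and
allocation machinery consumes only phased panels and is insensitive to
linkage-disequilibrium fine structure, which a coalescent process would add.
Consequently the simulator reproduces *structural* features of real data
(pedigree depth, drift and selection, recombination, haplotype sharing) but
not sequence-level realism: no mutation, no realistic site-frequency
spectrum, no background LD in the base generation, and fully phased panels
with no genotyping error unless missingness is introduced explicitly.
Passing tests therefore demonstrate correctness of the algorithms and the
direction of population-structure effects, not absolute percentages
expected on real livestock data.

# Problem sizes used by the test suite

The tests exercise full-scale structure where it is the point — the
31-cohort pedigree of 31,000 records runs at 2 chromosomes × 20 SNPs, since
the record count does not depend on marker density — and scale cohort size
down to 200 individuals (2 chromosomes × 200 SNPs, 400 base haplotypes, 50
SNP windows) for the multi-replicate ordering checks. In those runs the
sire count stays at 25 rather than being scaled proportionally: with 5
sires per generation the effective population size drops to ~20 and drift
collapses late-generation haplotype diversity, reversing the
depth-of-pedigree ordering that holds at realistic effective sizes (~80 and
up). Keeping the breeding structure and shrinking only the cohort preserves
the phenomenon the tests assert.

# Numerical choices and degenerate inputs

* Internal marker coordinates are 0-based; on-disk marker indices in
  window specifications are documented as 0-based starts within
  chromosomes. Panel files code a missing/unphased allele as 9.
* Windows with no eligible markers, or with no complete gamete, are dropped
  from the library rather than carried as empty columns.
* A candidate pool smaller than the requested `k` truncates with a warning;
  a zero top score stops selection early (everything coverable is covered).
* All stochastic stages (simulation, DE) take explicit seeds and restore
  the caller's RNG state; reruns are byte-identical.
* DE compares a trial against its target with `>=`, allowing drift across
  plateaus; elite updates require strict improvement of the deterministic
  decoding.

# Limitations

* Allocation requires a pedigree: focal families cannot be formed without
  parent and grandparent identities.
* The default accuracy surrogate is qualitative; absolute "proportion
  phased" values depend on a calibrated accuracy table.
* The simulator omits overlapping generations, mutation, genotyping error
  and realistic base-generation LD.
* Key-ancestor marginals use expected (pedigree) contributions, not
  realised genomic sharing — that is what makes it the baseline.
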