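---
title: "Models and methods behind gsipop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gsipop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsipop)
```

gsipop evaluates whether candidate stigmatic S-allele sequences behave like
the determinants of gametophytic self-incompatibility (GSI).  It combines
four pieces: crossing-data concordance statistics, a coalescent simulator of
pseudogene-contaminated S-locus samples, a permutation test of recombination
based on linkage disequilibrium, and nucleotide-diversity statistics.  This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical and design choices a user should know about.

## 1. Crossing analysis

Under single-locus GSI, haploid pollen is rejected when its S-allele matches
either allele of the pistil.  Crosses between full heterozygous genotypes
therefore fall into three predicted classes: *incompatible* (both genotypes
identical), *semi-compatible* (exactly one shared allele; half the pollen
succeeds, so fruit is expected), and *compatible* (no shared allele).
`predict_cross_phenotype()` implements exactly this rule and nothing more.

Two practical complications are handled explicitly rather than silently:

* **Ambiguous genotypes.** Plants with only one amplifiable product have an
  unknown second allele; no class can be forced from one known label, so such
  crosses are classed `"ambiguous"`.  `crossing_concordance()` excludes them
  by default because unexpected fruit set concentrates in them, but offers
  `include_ambiguous = TRUE` because published contingency totals
  historically pool these rows under their assumed class (the packaged
  `table2_fixture()` keeps the pooled class on the row, plus an `ambiguous`
  flag, so both conventions are one call away).
* **Linked co-segregating products.** Pairs of PCR products inherited as one
  unit (e.g. the `S3ab` and `S2de` units of the packaged tables) are
  collapsed into a single haplotype label with `collapse_linked()` *before*
  prediction.  Tetraploids with two amplified products are treated as
  diploid-like two-unit genotypes; the crossing data this package ships show
  no evidence of more than four mating types among full sibs, which is what
  that representation assumes.

The concordance statistic is the plain Pearson chi-square on the 2x2 table
(fruit / no fruit by predicted class) with **no Yates continuity
correction** — the convention under which the packaged tables reproduce
their published statistics exactly — plus Fisher's exact test, whose
two-sided p-value sums all tables with probability at most that observed.
Weak-allele behaviour (an S-allele that leaks fruit set in matching-genotype
crosses) is a property of the *data-generating* model
(`simulate_cross_records()`, via per-allele leak rates), never of the
prediction: prediction stays purely genotypic.

`prob_no_incompatible_pair()` quantifies the diallel design: with four
equally likely offspring classes (one heterozygous locus) any five sibs must
contain two of the same class, so a 5x5 diallel always exposes at least one
reciprocally incompatible pair; with 16 classes (two-locus identity model)
the probability of missing is `prod((16 - i)/16, i = 0..4)` (about 0.50).
The contrast is what makes a run of all-detected diallels informative about
a single-locus architecture.

## 2. Coalescent simulation of pseudogene contamination

A sample of putative S-alleles may unknowingly mix true S-alleles with
copies of a duplicated, non-functional paralog.  The simulator asks what
that contamination does to recombination detection.

**Model.** The genealogy of balanced allelic lineages is approximated by a
neutral coalescent with effective size inflated by a scaling factor `f`
(default 20).  Time is measured in units of `4 Ne f` generations, so an
S-class pair coalesces at rate 1 and `E[T2] = 1`; the per-site mutation
parameter of the S class is `theta_s = 4 f Ne mu`.  The pseudogene class
evolved at ordinary effective size, i.e. `theta_p = theta_s / f` and
pairwise coalescence rate `f`.  Looking backward:

* before the duplication time `t_d` (same units) the two classes are
  separate loci and never coalesce with each other;
* P-class lineages recombine at rate `rho_site = theta_s * (r/mu)` per
  adjacent-site link of their ancestral material; S-class lineages never
  recombine (complete suppression at the functional locus);
* a bottleneck of duration `t_b` (default 0.005) and mutation parameter
  `theta_b` (default `theta_s / 2e6`, i.e. pairwise coalescence rate
  `theta_s / theta_b = 2e6`) sits immediately ancestral to `t_d` and
  collapses the P class to a single lineage, enforcing the duplication's
  single origin without a hard constraint;
* above `t_d + t_b` survivors join a single panmictic S-class coalescent
  with no recombination, down to the grand MRCA of every site.

Sequences then evolve along the marginal genealogies under Jukes-Cantor
with branch lengths of (coalescent time) x `theta_s / 2` expected
substitutions per site and uniform root bases.  Substitutions are realised
as an explicit Poisson jump process, so `n_mut_events` is reported and obeys
the infinite-sites Watterson expectation `theta_s * L * sum(1/i)` exactly —
convenient for calibration, while the alignment itself is finite-sites (the
count of polymorphic *columns* is slightly deflated by multiple hits, which
matters at `theta_s` of order 1).

**Numerical choices.**

* Sites are discrete, 0-based half-open internally, 1-based in reports.
  Breakpoints live on the `L - 1` links between adjacent sites.
* The recombination rate of a lineage is proportional to its ancestral
  *material* (links interior to carried segments plus the junctions between
  them), and the breakpoint is uniform over those links.  The classic
  full-ARG convention would also let "trapped" non-ancestral gaps
  recombine; those extra events overwhelmingly reshuffle material that is
  guaranteed to re-merge and their omission is what keeps dense grids
  (e.g. `rho_site = 200` and beyond) tractable.
* A pruning rule exploits the prescribed severe bottleneck: once every site
  retains at most one P-class copy, all further within-P events before the
  class merge act on pairwise-disjoint material and can no longer alter any
  marginal tree (the bottleneck collapses the class with pairwise
  probability `1 - exp(-(theta_s/theta_b) t_b)`, about `1 - e^-10000` at
  the defaults), so the P class is frozen until the bottleneck.  The rule is
  applied only when `(theta_s/theta_b) * t_b > 50`; weaker bottlenecks run
  the unpruned process.
* The contaminant count is `round(c * n_sample)`, exact for the design's
  `c` in {0.25, 0.5, 0.75} with `n = 24`.
* One R-level RNG drives every stochastic step (the C++ core draws through
  R's generator), so `set.seed()` or the `seed` arguments give bitwise
  reproducibility; `run_grid()` derives a deterministic sub-seed per
  parameter combination so any row can be re-run in isolation.

**Defaults as study conditions.** `n_sample = 24`, `L = 327`, `f = 20`,
`t_b = 0.005`, `theta_b = theta_s / 2e6` and the full `run_grid()` default
lists (`theta_s` in {0.01, 0.1, 0.2, 0.3, 1, 2}; `t_d` in
{0.01, 0.1, 1, 2, 3}; `r/mu` in {2, 20, 60, 100, 200, 2000}; `c` in
{0.25, 0.5, 0.75}) are the conditions of the contamination design this
package embodies.  The published list of duplication times contains a
repeated 0.1 (presumably a typo for a sixth distinct value); the grid
defaults to the five distinct printed values and accepts any user list.
Whether the original implementation allowed recombination through the
bottleneck is not stated; here recombination switches off at `t_d`.

## 3. The LD-distance permutation test

Recombination makes linkage disequilibrium decay with distance.  The test
statistic is the Pearson correlation between `r^2` and inter-site distance
over all pairs of biallelic segregating sites, one-tailed toward *negative*
correlation.  The null distribution permutes the assignment of columns to
positions: each pair keeps its `r^2` but acquires permuted distances, which
is exactly the exchangeability that holds when all sites share one
genealogy.  The Monte Carlo p-value is `(1 + #{cor_perm <= cor_obs}) /
(n_perm + 1)` (super-uniform by construction); with at most seven columns
and a sufficient budget the `S!` permutations are enumerated exhaustively.
Because the pair distances form a permutation-invariant multiset, the
correlation is monotone in `sum r2_ij * d_ij`, and the inner loop (C++)
compares that sum only.

Choices: singletons are retained (no frequency filter is applied to the
site matrix); columns with gaps, ambiguity codes or more than two states
are dropped entirely, with counts kept on the `site_matrix`; alignments
with fewer than three usable columns score "not detected" with p = 1 and a
`degenerate` flag — they carry no signal, and erroring would bias grid
detection proportions upward.  Defaults `n_perm = 1000`, `alpha = 0.05`.
Pearson (not rank) correlation on all pairs is the default convention; the
original tooling's exact settings are not published, and the statistic is
deliberately exposed through small composable functions
(`segregating_sites()`, `pairwise_r2()`, `ld_distance_correlation()`) so
variants are easy to assemble.

## 4. Diversity statistics

`pairwise_pi()` is the mean over unordered pairs of (differences / compared
sites) with pairwise deletion of gap/ambiguous columns.
`nei_gojobori_pair()` implements pathway counting: per-codon synonymous
sites are the fraction of one-step changes preserving the amino acid
(changes to stops count as non-synonymous), averaged over the two
sequences; differences average the synonymous/non-synonymous step counts
over all orderings of the single-base steps, excluding pathways through
stop codons (all pathways are used in the rare case every one is blocked).
Codons containing a gap, ambiguity or stop in either sequence are skipped
pairwise, not alignment-wide.

The Jukes-Cantor correction `d = -(3/4) log(1 - 4p/3)` is applied to
`pS`/`pN` by default — synonymous divergences of the magnitude seen among
S-alleles (0.3-0.7) are only meaningful on a corrected scale — and pairs at
or beyond the `p >= 3/4` ceiling are flagged saturated and dropped from the
corrected means with a warning, never clipped.  Sliding windows default to
width 50, step 10 — fine enough to localise a 50 bp hypervariable region
while keeping ~10+ segregating pairs of sequences per window — and are fully
configurable.  `divergence_time()` returns the verbatim quotient
`ds / rate`; the conventional halving for a pairwise distance is available
as `pairwise_halving = TRUE` because the two conventions differ by exactly
a factor of two and both appear in the literature.

## 5. What the synthetic data do and do not show

`generate_family()` draws offspring by independent uniform transmission of
one haplotype unit per parent — the 1:1:1:1 model that
`segregation_gof()` tests.  `simulate_cross_records()` layers a binomial
fruit-set model with class probabilities and per-allele leak rates on top
(a leak rate of 0.59 reproduces the fixture's weak-allele behaviour).
`planted_diversity_alignment()` draws per-column minor-allele counts from
`Binomial(n, q)` with `2q(1-q)` equal to the target diversity, which makes
the expected column diversity exact and the realized global value
concentrate within ~10% for `L >= 300`.

These generators emulate segregation ratios, leak rates, contamination
mixtures and diversity profiles.  They do **not** emulate genotyping error,
PCR competition between alleles, tetrasomic inheritance, gene conversion,
selection on sequences beyond the f-rescaling, or demographic history
beyond the single bottleneck.  A passing test suite therefore validates the
statistical machinery under the stated models, not the biology of any
particular dataset; reproducing published diversity tables for real taxa
additionally requires the underlying sequence sets, which are not shipped.

## 6. Problem sizes used in validation

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the quantities tested while staying desk-scale: 10^4 replicates
for pairwise coalescence-time means, 1.5-2 x 10^3 for Watterson and KS
calibration (two-sample against an independent coalescent implementation,
msprime, in matching time units), 400 replicates for the level of the
permutation test, and a reduced detection grid (16 combinations x 500
replicates x 500 permutations) for the contamination claim, with the full
factorial design available through `run_grid()` defaults.  All of them are
seeded and reproducible.

## Known limitations

* The simulator's bottleneck semantics (an epoch of relative size
  `theta_b / theta_s` applied to the P class only) stand in for an explicit
  single-origin constraint; with the default `theta_b` the two are
  indistinguishable, but exotic parameter choices (long `t_b` with mild
  `theta_b`) are honoured literally.
* `nei_gojobori_pair()` is pathway counting with equal weights; no
  transition/transversion weighting is offered.
* The permutation test assumes exchangeable columns under the null; strong
  population structure *within* a non-recombining sample does not violate
  it, but pooling alignments of different lengths or frames would.
* Fruit set is modelled as binary per pollination; seed-set quantity is out
  of scope.
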