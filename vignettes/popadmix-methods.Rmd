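---
title: "Models and methods behind popadmix"
author: "popadmix maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popadmix)
```

popadmix estimates continental and sub-continental ancestry in admixed
human populations from three marker systems: mtDNA control-region
haplotypes, region-labelled haplotype reference databases, and autosomal
ancestry-informative markers (AIMs). This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, what
the synthetic-data generator does and does not emulate, and the known
limitations.

## mtDNA haplotypes: grammar, normalization, distance

Haplotypes are stored as sets of rCRS-relative variants with explicit
reference and alternate alleles, so comparisons never require a reference
at compare time. The parser accepts the standard forensic dialects —
flank style (`T16189C`), bare position (`16189`, resolved as the
transition of the reference base), position+allele (`16093C`), insertions
(`309.1C`), deletions (`16166d`), IUPAC-ambiguity heteroplasmies
(`C16223Y`) and back-mutation markers (`@152`, tree notation only) — and
all dialects resolve to the same canonical form. Coordinates are 1-based
with closed intervals throughout; each haplotype carries the interval(s)
it was read over (by default HVS-II 73–340 plus HVS-I 16024–16365).

Before any comparison, haplotypes are normalized under the conventional
phylogenetic exclusion rules: all variants at the length-unstable
positions 16182 and 16183, insertions and deletions in the poly-C tract
(303–315 inclusive — the tract boundary is a package choice, as the
convention is usually stated only as "around position 310"), and all
point heteroplasmies. Normalization is idempotent and only removes
variants.

The step-mutation distance between two haplotypes over a common range is
the number of (position, insertion-index) slots at which they differ; a
slot where both carry a variant but with different alleles counts once,
so the distance coincides with the Hamming distance of the implied
sequences for substitution-only haplotypes.

## Haplogroup classification

A haplogroup tree is a set of named nodes with defining variant motifs; a
node's expected variant set is the accumulation of motifs from the root,
with `@` markers toggling variants off in path order. Classification
scores every node as `|matched| − 0.5·|missing|` over the expected set
restricted to the sample's covered range (so an HVS-I-only sample is not
penalized for motifs it could not have shown), and returns the best node;
ties go to the deeper node, then the lexicographically smaller name. All
variants weigh equally — site-specific mutation-rate weights, as used by
production haplogroup callers, are deliberately not reproduced: the
simplified score is transparent, sufficient for the synthetic trees the
package ships, and exposes `matched`/`missing`/`private` lists in place
of an opaque quality number. The prefix-based continental map (L clades
to African, excluding the out-of-Africa macro-haplogroups M and N;
A2/B2/B4/C1/D1/D4 to Native American; H/HV/J/K/T/U/V/W/X to European) is
data shipped inside the tree file, not code.

## Diversity indices

All indices are computed on a common segment (HVS-I 16090–16365 by
default) under a complete-deletion site policy: any position at which any
sample carries an indel or ambiguous call is removed for all samples.
One consequence, chosen deliberately, is that haplotype identity for the
`k` and `H` statistics is also evaluated over the analyzed sites, so
every index in a summary row refers to exactly the same alignment
columns and the identity `M = π·L` is exact by construction. Haplotype
diversity uses Nei's unbiased estimator with his sampling variance;
the variance of `π` is the Tajima-type sampling variance. The analysis
range and the normalization policy are parameters; published tables
computed with other software may use a different (unstated) indel policy,
so reproduction of third-party "±" values should be expected only to
within rounding.

## Haplotype-sharing admixture (P0/P1/P2)

Each target lineage is matched against every regional database at a step
tolerance `m` (0, 1, 2 by default). Match counts are converted to
relative frequencies `f_r = c_r/N_r` before normalizing into allocation
weights: the regional databases differ in size by more than an order of
magnitude (the default generator reproduces sizes 3830/6868/522/357/1118/1010),
and raw counts would bias allocation toward the largest database. A
raw-count mode is retained for sensitivity analysis. Targets are counted
per individual (a population-level ancestry statement), with a
per-haplotype collapse available. Unmatched targets are excluded from the
normalization and reported through the coverage fraction rather than
being spread uniformly — `P` then remains interpretable as the ancestry
of assignable lineages. Match sets are nested in `m`, so coverage is
non-decreasing and `Σ_r P_r = 1` holds exactly at every tolerance.

Confidence intervals are percentile bootstrap over `B = 1000` replicates
by default. The default scheme resamples each regional database with
replacement (sizes preserved), reflecting uncertainty in the source
pools; very small target sets otherwise dominate the interval width. The
`targets` scheme resamples target individuals instead and is the
appropriate scheme when the quantity of interest is the sampling
variability of the target draw itself — the coverage experiment in the
acceptance suite uses it for exactly that reason, since database
resampling conditions on the realized targets and cannot, by
construction, cover target-draw noise. Replicates in which no target
matches are skipped and counted; more than 50% skipped aborts.

## Supervised AIM ancestry

Reference allele frequencies per population are estimated from labelled
panels with a Jeffreys-style pseudocount of 0.5, which keeps them
strictly inside (0,1) so every genotype has finite likelihood; missing
genotypes are dropped per locus. Individual ancestry maximizes the
binomial mixture likelihood over the K-simplex by EM on gene-copy
responsibilities, initialized uniform, with convergence declared at
`max|Δq| < 1e-7` (at most 2000 iterations). The log-likelihood trace is
retained and is non-decreasing; flat-likelihood inputs (identical
frequencies across populations) return the uniform vector as converged,
deterministically. Unsupervised joint re-estimation of reference
frequencies is out of scope.

IBS distances are allele-sharing distances `D = mean |g_i − g_j| / 2`
over shared non-missing loci, and classical MDS double-centers the
squared distances and eigendecomposes (via `stats::cmdscale`), dropping
non-positive eigenvalues — allele-sharing distances need not be Euclidean
— and reporting variance fractions over the positive spectrum only.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume,
with truth bookkeeping at every stage and bit-for-bit reproducibility
from a single root seed (per-stage child seeds are derived
deterministically, so stages regenerate independently).

* **Tree and reference.** A fixed topology containing the macro-structure
  (root, L0, L1, L3, M, N) and the terminal clades A2, B4, C1, D1, D4h3a,
  HV0, L0a1b2, L0a2a2a, L1c3b1a, L3d1a1a, L3d1b3, over a synthetic
  random reference sequence. Motifs are 2–4 variants at seed-dependent
  positions, disjoint across nodes (macro-haplogroups in HVS-II, terminal
  clades in HVS-I); B4 keeps its classical diagnostic HVS-I motif
  T16189C–T16217C.
* **Databases.** Per region, haplogroups are drawn from a regional
  frequency vector, and each haplotype receives Poisson(λ) private
  mutations at uniform positions with a 0.94 transition bias, avoiding
  tree-motif positions so haplogroup membership is never destroyed.
  λ = 1 by default — enough to make most database haplotypes distinct,
  as in real control-region databases — and the default region sizes are
  the six-region study sizes.
* **Targets.** Each target draws a source region (default proportions
  uniform; the standard validation mixture uses 0.5/0.3/0.2), a haplotype
  from that region's pool, and Poisson(μ) extra mutations; μ = 0.3 by
  default, a modest within-region drift that leaves most targets
  matchable at small step tolerances. Truth records the source region and
  the realized draw fractions — the quantity the sharing estimator
  actually estimates; nominal probabilities differ from realized draws by
  multinomial noise that is not estimator error.
* **Genotypes.** The Balding–Nichols model: ancestral frequencies
  Uniform(0.1, 0.9), population frequencies Beta-distributed around them
  with divergence F = 0.15 per population, reference panels of 64/158/105
  individuals, and target ancestries Dirichlet(α); α = (1,1,1) by default
  for a generic study (no preferred composition), overridden with skewed
  per-locality α in the pinned scenario.
* **Pinned scenario.** `yungas_like_scenario()` pins counts by stratified
  sampling — 85 Native American, 19 African and 1 European lineage
  (rounding to 81/18/1), with 16 of the 19 African lineages concentrated
  in a 19-sample locality (84%) — so the headline percentages are exact
  rather than stochastic, while haplotype-level detail stays random.

What the generator does **not** emulate: site-specific mutation rates
(finite-sites uniform placement with a global transition bias), coalescent
genealogy within haplogroups, linkage between loci, genotyping error, and
real database provenance. Passing tests therefore validate the
estimators' statistical behavior under the assumed structure, not the
historical claims one could draw from real data.

## Numerical choices and scale

Step-distance computations vectorize over sparse token-incidence matrices
(two sparse cross-products give exact symmetric-difference distances for
whole collections at once), which keeps bootstrap resampling at
`B = 2000` over hundreds of targets and thousands of database haplotypes
fast. The validation experiments run at deliberately chosen sizes:
the standard sharing mixture uses 300 targets against three pools of 500;
the AIM recovery experiment uses 46 loci, 3 populations and 100 targets
averaged over three replicate simulations; the bootstrap coverage
experiment uses 100 simulation repeats at `B = 2000`. Degenerate inputs
are defined, not special-cased ad hoc: empty haplotypes are valid
(reference-identical), an all-zero distance matrix embeds at the origin,
and ties in classification break deterministically.

## Known limitations

* The classification score is motif-counting, not a probabilistic model;
  on real Phylotree-scale trees with recurrent mutations it should be
  treated as a screening call with the `missing`/`private` lists as the
  audit trail.
* The sharing estimator's allocation is proportional to relative match
  frequency; it does not model database ascertainment, nor shared drift
  between source regions, and its published-scale results depend on
  databases this package does not ship.
* With 46 biallelic markers at F = 0.15, individual-level ancestry
  estimates carry irreducible noise (root-mean-square error on the order
  of 0.15 even with exact reference frequencies — the EM solution was
  verified against an independent optimizer, so this is the information
  limit of the marker panel, not an optimization gap). Population means,
  in contrast, are recovered to within a few percent; individual-level
  statements from panels of this size warrant caution.
* Y-chromosome ancestry enters only as user-supplied partitions in the
  marker-comparison report; no Y haplogrouping is performed.
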