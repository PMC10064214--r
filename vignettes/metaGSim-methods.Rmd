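---
title: "Simulating selective genotyping in a multi-breed beef programme: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating selective genotyping in a multi-breed beef programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metaGSim)
```

## The question the package addresses

Beef cattle evaluations typically pool several breeds, have shallow budgets
for genotyping, and record many traits on only one sex or on a fraction of
animals. When only a few thousand animals can be genotyped, which animals
should they be — young selection candidates, proven ancestors, males,
females? `metaGSim` answers this in silico: it simulates a five-breed beef
breeding programme forward in time, applies alternative selective-genotyping
designs crossed with phenotype-availability cases, runs the two competing
genetic evaluations, and scores each design by the prediction accuracy of
the latest generation of selection candidates.

## Population model

The population is built in four steps.

1. **Historical phase.** A neutral random-union-of-gametes population run
   for many generations to establish linkage disequilibrium (LD) and an
   allele-frequency spectrum by drift-mutation balance. Two phases: a
   constant size, then a linear size change to the final historical
   generation. Recurrent bidirectional mutation (default 2.5e-5 per locus
   and meiosis) keeps loci segregating.
2. **Expansion.** A random sample of historical founders (100 males, 100
   females at production scale) mates randomly for 8 generations at 5
   offspring per dam; a configurable cap (`maxSize`) keeps the cohort size
   bounded, with random culling above it.
3. **Breed formation.** Five disjoint random samples of 100 males + 100
   females found breeds A-E, each randomly mated in isolation for 30
   generations at 2 offspring per dam.
4. **Selected breeding.** Each breed runs 15 discrete generations with one
   offspring per dam, random mating among the active breeding animals, and
   truncation selection of replacements on estimated breeding values (EBVs)
   from a joint multi-breed pedigree BLUP refitted every generation at the
   true variance components. Per-breed sire/dam replacement fractions and
   growth rates follow the programme parameter table (e.g. breed A: 220
   sires with replacement 0.5065 and growth 0.072 per generation, 1,800
   dams with replacement 0.30 and growth 0.098). Culling is by age: the
   replacement fraction of breeding animals exits oldest-first, with the
   lowest-EBV animals leaving first within an age class.

Genome: 29 chromosomes, 2,319 cM total, 50,000 evenly spaced markers and
800 randomly placed QTL drawn from loci segregating with minor allele
frequency above 0.1 in the last historical generation (production scale).
Meiosis uses Poisson crossovers (Haldane, no interference) with uniform
breakpoint positions.

Trait: single trait, heritability 0.3, phenotypic variance 1.0. QTL effect
magnitudes are gamma(shape 0.4) with random signs, rescaled once so the
true-breeding-value (TBV) variance of the step-4 base generation equals the
additive variance; the TBV is the dosage-weighted effect sum and phenotypes
add a sex effect (+0.25 males / -0.25 females by default) and a normal
residual. Breed fixed effects are zero by design — breed differences arise
genetically through drift and selection.

## Evaluations

**Pedigree BLUP with unknown-parent groups (UPG).** All five breeds are
analysed jointly with an animal model (intercept + sex fixed). The base
animals of step 4 have unknown parents assigned to one group per breed. We
use the transformed grouped equations (groups appear as extra rows of the
grouped pedigree inverse, assembled by Henderson's rules with
Meuwissen-Luo inbreeding), so animal solutions are total EBVs, group
contribution included. One group is constrained to zero because the five
groups and the intercept are jointly confounded.

**Single-step GBLUP with metafounders.** Each breed's base population is
represented by one metafounder pseudo-ancestor. The metafounder
relationship matrix is `Gamma = 8 * Cov(P)`, the covariance taken across
markers of the per-breed allele-frequency columns `P`; by default `P` is
computed from the simulated base-generation genotypes (the simulation
truth), with the genotyped-animals-only estimator available as an option.
The pedigree relationship matrix is rebuilt with the metafounder block
initialized to `Gamma` (tabular recursion for small cases; a generalized
Meuwissen-Luo recursion plus Henderson assembly produces its sparse inverse
directly). The genomic matrix is `G = w w' / s` with `w` the {-1, 0, 1}
genotype incidence (dosage minus one) and `s` half the marker number —
deliberately without allele-frequency centering, which the metafounder
formulation absorbs into `Gamma`. The combined inverse adds
`solve(G) - solve(A22)` on the genotyped block. Every animal, genotyped or
not, receives a genomically enhanced EBV; no explicit group term remains.

**Accuracy** is the Pearson correlation between TBV and (G)EBV among the
generation-15 selection candidates — overall, by sex, and for candidates
without phenotypic records by sex.

## Scenario grid

Four genotyping designs share one budget (5,000 at production scale, 3% of
the evaluated animals); genotyping is allowed from generation 7 onward:

* **Sc1** — male candidates of generation 15 only.
* **Sc2** — 40% ancestral sires with at least 10 progeny + 60% male
  candidates.
* **Sc3** — candidates of both sexes (unrestricted draw, so the sex split
  is roughly even).
* **Sc4** — 30% ancestral sires + 30% ancestral dams + 40% candidates of
  both sexes.

"Ancestral" means a parent born in generations 7-14; the 10-progeny rule
applies only to the Sc2 sire stratum (ancestral dams and Sc4 sires need one
progeny). All strata sample uniformly at random, without replacement, from
the pooled five-breed population, so per-breed counts are proportional to
breed sizes on average. Phenotyping cases cross recording fractions
100/60/20% with both-sex, male-limited and female-limited recording; the
recorded set is drawn once per case and shared across scenarios, so cells
differ only in the information used.

## Design choices where the design was open

* **Step-4 base founding.** The base animals (e.g. 220 + 1,800 for breed A)
  outnumber a single breed-formation generation (~200). Because base
  animals are pedigree-truncated to metafounders anyway, they are generated
  as offspring of randomly drawn step-3 parent pairs of their breed: allele
  frequencies and LD are inherited correctly while the pedigree starts at
  the metafounder, which is the object of study.
* **Replacement arithmetic.** "Replacement and growth" are interpreted per
  generation: the breeding group grows to `round(n * (1 + growth))` and a
  fraction `repl` exits. With one offspring per dam, 30% dam replacement
  plus growth demands up to ~48% of a cohort in the fastest-growing breeds,
  which a Bernoulli sex ratio cannot always supply. The candidate pool is
  therefore never-bred animals of the current cohort, topped up from
  earlier unused cohorts only on shortfall; a breed that still cannot meet
  demand recruits all available candidates with a logged message (or errors
  under `strictReplacement = TRUE`).
* **Sex assignment.** Step-4 offspring sexes are Bernoulli(0.5), which
  produces the natural variation in sex splits that the genotyping designs
  see. In the unselected build-up steps (expansion, breed formation),
  sexes are assigned as a balanced random permutation: at desk scale a run
  of same-sex births in a 20-animal cohort would otherwise extinguish a
  breed line, a pure small-sample artifact.
* **Solver.** The mixed-model equations are solved by sparse Cholesky
  (CHOLMOD) with a sparse-LU fallback for the grouped (not positive
  definite before constraint) systems. At the sizes used (up to ~25,000
  equations) a direct factorization is faster and more reproducible than
  iterative conjugate gradients, and exact to machine precision.
* **Numerical repairs.** `Gamma` is clipped to positive semidefinite
  (eigenvalue floor at zero, with a warning) only if rounding makes it
  indefinite; `G` is used raw and blended 5% toward `A22` only when
  numerically singular — both events are warned about, never silent.
* **Identifiability.** Fixed effects are intercept + sex; the breed fixed
  effect of the phenotype model is dropped from the evaluations because
  the UPG/metafounder structure carries the breed genetic level.

## The desk preset

The full production-scale preset (`productionPreset()`) is expressible but slow;
tests and the acceptance script use `deskPreset()`, chosen to preserve the
structure rather than the raw size:

* Genome 5 x 80 cM with 2,000 markers and 200 QTL from a 9,000-locus pool
  (marker density 5/cM vs 21.6/cM at production scale).
* History 200 generations (150 at size 200, then growth to 400): the size
  is chosen so cumulative founder drift (expected inbreeding ~0.4) and LD
  at the marker spacing match the production history, since both control
  the information content of markers.
* Expansion and breed formation at the production sizes (they are cheap and
  they control breed differentiation).
* Step-4 breed sizes, genotyping budget (500) and all stratum counts at one
  tenth; replacement/growth rates, heritability, selection rules unchanged.

A replicate simulates ~21,000-22,000 evaluated animals and solves 45
mixed-model systems; it runs in about 40-60 seconds. The acceptance
checks use 10 replicates.

What the desk scale does **not** preserve: stochastic between-breed
divergence. The variance of a breed's mean TBV trajectory under selection
scales inversely with breed size, so at one tenth scale the spread of
gen-15 breed means is inflated roughly tenfold in variance relative to the
production scale. Because accuracy is computed on the pooled candidates,
the between-breed component (which deep pedigrees predict well) raises all
desk-scale accuracies and compresses the differences between genotyping
designs. The qualitative ordering of designs is preserved; the absolute
accuracy level is not. The tenfold smaller genotyped set (500 animals) also
carries proportionally less genomic information, further shrinking the
genomic-vs-pedigree gap relative to a production-scale run.

## Limitations

* No dominance, epistasis, genotype-by-breed interaction, maternal effects,
  or multi-trait structure; the genetic correlation across breeds is 1 by
  construction.
* Discrete generations with age-priority culling; no overlapping
  herd/contemporary-group structure, migration, or assortative mating.
* Variance components are the simulation truth; estimating them (REML) is
  out of scope.
* Sequence-level realism (nucleotide identities, recombination hotspots,
  gene conversion) is not modelled; loci are abstract biallelic positions.

## Reproducing the experiment

```{r, eval = FALSE}
library(metaGSim)
cfg <- runConfig(preset = "desk", seed = 1, nReplicates = 10,
                 outDir = "desk-run")
res <- runExperiment(cfg)
summ <- summarizeAccuracy(res)
accuracyTable(summ)        # cases x scenarios mean accuracies
scenarioAverages(summ)     # scenario averages over the nine cases
```

`scripts/acceptance.R` wraps exactly this computation and writes the
headline quantities as JSON.
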