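---
title: "Quantitative genetics of simulated Collaborative Cross populations"
author: "ccqg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of simulated Collaborative Cross populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`ccqg` implements an end-to-end quantitative-genetics workflow for
multiparent recombinant inbred (RI) mouse populations in the style of
the Collaborative Cross (CC): eight inbred founder strains are combined
by a three-generation funnel cross, inbred by sib mating, genotyped on a
SNP array, and analysed line by line. Because real CC genotype and
phenotype tables are typically not redistributable, the package ships a
breeding simulator as a first-class, tested component: every downstream
stage (genome reconstruction, heritability, QTL mapping, annotation)
can be exercised against synthetic panels whose ground truth is known
exactly.

The stages, each usable standalone or through `run_pipeline()`:

1. **Simulation** (`simulate_founders`, `breed_cc_line`,
   `genotype_line`, `simulate_phenotypes`)
2. **Genome reconstruction** (`reconstruct_descent`,
   `prune_intervals`, `founder_contributions`)
3. **Phenotype processing** (`adjust_covariates`,
   `quantile_normalize`, `line_summaries`, plus the behavioral
   readouts `discrimination_ratio`, `exceedance_fraction`)
4. **Heritability** (`kinship_from_descent`, `fit_varcomp`,
   `anova_broad_h2`)
5. **QTL scan** (`scan_genome`, `permutation_threshold`,
   `define_qtl_interval`)
6. **Annotation** (`genes_in_interval`, `rank_enrichment`)

## The breeding simulator

A CC-style line is bred as the canonical 8-way funnel: four pairwise G1
crosses, two four-way G2 crosses, one eight-way cross, then `n`
generations of sib mating (default `n_inbreeding_gens = 20`, the
generation from which such lines are conventionally regarded as fully
inbred; the exact generation of any real line is rarely known, so 20 is
a modelling choice, exposed as an argument). Gamete formation follows
the Haldane model — crossover counts Poisson with rate 1 per 100 cM per
meiosis, positions uniform, no interference. We chose Haldane over an
interference model because it is the standard neutral assumption and
makes independent verification tractable: the expected junction density
of the final mosaic can be checked against a discrete-locus pedigree
simulation written independently of the segment representation (the
test suite does exactly that).

Funnel order is randomized per line unless supplied. Residual
heterozygosity is retained by actually simulating finite inbreeding
rather than forcing homozygosity; at 20 generations the heterozygous
genome fraction is of the order of 1 %, visible in
`mosaic_heterozygosity()`. Sex chromosomes are not modelled — all
chromosomes behave as autosomes.

Genotyping noise is deliberately simple: each true dosage call (0/1/2)
is replaced by a uniformly chosen different value with probability
`error_rate` and dropped with probability `missing_rate`. Real arrays
have structured, intensity-driven error; the uniform model is enough to
exercise the reconstruction error channel without claiming to emulate a
particular platform.

Phenotypes are built per animal as intercept + additive QTL effects
(the mean of the two haplotypes' founder effects at each specified
position) + a line-level polygenic deviate with covariance
$\sigma_g^2 K$ + covariate effects (age slope, batch and origin level
effects) + residual $N(0, \sigma_e^2)$. The generating narrow-sense
heritability $\sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$ is recorded in
the output's `true_h2` attribute; QTL and covariate variance are
intentionally not counted in it, so planted-QTL simulations state their
architecture explicitly.

## Genome reconstruction

`reconstruct_descent()` runs a hidden Markov model per line and
chromosome with **8 homozygous founder states**. Emissions compare the
observed dosage with twice the founder allele: a match has probability
$1 - \varepsilon$, each of the two other calls $\varepsilon / 2$, and a
missing call is uninformative. Heterozygous calls can therefore only be
emitted through $\varepsilon$ — this is how residual heterozygosity
(and regions where founders share a haplotype) surface as posterior
ambiguity rather than hard labels. We use the haploid 8-state chain
rather than the 36-diplotype-state chain deliberately: near-inbred
lines are homozygous over almost all of the genome, the output matches
the per-founder descent-probability matrix the rest of the pipeline
consumes, and the diplotype chain would cost 36/8 times the state space
for information the downstream stages do not use. The cost is that true
heterozygous segments are represented as uncertainty, not as calls — a
documented limitation.

Transitions between markers $d$ cM apart use an effective recombination
fraction

$$ r_\mathrm{eff} = \tfrac12\bigl(1 - e^{-a d / 50}\bigr), $$

capped at 7/8 (the proper-chain limit for 8 states), with a switch
distributed evenly over the 7 other founders. The map-expansion factor
`a` absorbs the extra crossovers an RI line accumulates relative to a
single meiosis; its default `a = 2` sits between an F2 and the fully
expanded sib-mating RIL map, and it is an explicit `hmm_params()` knob
because the appropriate value depends on the panel's breeding history.
Default $\varepsilon$ is 0.01.

Forward–backward runs in scaled arithmetic (per-step normalization), so
posteriors stay finite for maps of any practical length; Viterbi runs
in log space. Where several founders are indistinguishable the
posterior is left flat — no arbitrary tie-breaking. `prune_intervals()`
thins the interval grid approximately evenly in cM (always keeping each
chromosome's ends), mirroring the common practice of pruning dense
array maps to a computationally convenient interval set.

## Heritability

`kinship_from_descent()` computes
$K_{ij} = \frac1M \sum_m \sum_f p_{imf}\, p_{jmf}$ — the probability,
averaged over intervals, that two lines descend from the same founder.
The raw dot product is reported as-is (no double centering), with a
unit-mean-diagonal rescaled copy attached for users who prefer that
normalization.

`fit_varcomp()` estimates the narrow-sense model in which the
phenotypic covariance is $V = K\sigma_g^2 + I\sigma_e^2$, with
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$. The fit is at animal
level with the kinship expanded over line membership (animals of lines
$i, j$ share covariance $\sigma_g^2 K_{ij}$): this uses every
observation and makes $\sigma_e^2$ a combined within- plus between-line
residual. Fitting on line means instead would discard the within-line
replication; the package takes the animal-level reading and documents
it. Maximization is by ML (REML behind a flag), profiling out the total
variance after one eigendecomposition of the expanded relationship
matrix, then a 101-point grid over $h^2$ refined by `optimize()` to a
$10^{-6}$ tolerance. Boundary solutions ($h^2 = 0$ or $1$) are legal
and flagged.

`anova_broad_h2()` is the classical one-way ANOVA estimator:
$V_e = \mathrm{MS}_\mathrm{within}$,
$V_g = (\mathrm{MS}_\mathrm{between} - \mathrm{MS}_\mathrm{within})/n$
with $n$ the average number of animals per line, and
$H^2 = V_g / (V_g + V_e)$. A negative $V_g$ (within-noise exceeding
between-line signal) is clamped to zero and flagged. Both estimators
are meant to be reported before and after phenotype processing.

## Phenotype processing

The processing chain is: covariate correction first, quantile
normalization second, and the provenance attribute enforces that order.
Correction is OLS residualization on age (numeric) plus batch and
origin (categorical); age-as-numeric is a choice, flagged here, since a
categorical reading is also defensible. Missing values propagate and
are never imputed. Normalization is the rank-based inverse-normal
transform with Blom offsets, $\Phi^{-1}((r - 0.375)/(n + 0.25))$, ties
sharing average ranks: "quantile normalized" admits several offset
conventions and Blom is the common default in genetic association
work. The derived behavioral readouts are small and exact: the social
discrimination ratio $t_N / (t_N + t_F)$ (above 0.5 = successful
discrimination; undefined when both times are zero) and the strict
exceedance fraction used for, e.g., animals with excessive grooming
duration (> 120 s).

## QTL scan

The scan regresses **weighted line means** (weights = animals per line)
on the 8 founder descent probabilities at each interval, testing the
founder term against the intercept-only weighted model with an F test;
$\mathrm{LogP} = -\log_{10} P$, capped at 300 to keep numerically zero
P-values finite. Because the probability columns sum to one, one column
is absorbed by the intercept; founders absent at an interval are
dropped and the interval flagged rather than returned as `NA`. There is
no kinship or covariate term inside the scan itself — phenotypes are
corrected beforehand — so heritable polygenic-only traits show visible
inflation. That is faithful to the intended procedure and stated here
as a caveat, not silently patched.

Genome-wide significance comes from permutations: line means are
shuffled across lines (weights stay attached to lines), the genome-wide
maximum LogP recorded each time, and the level-$\alpha$ threshold taken
as the empirical order statistic
$\lceil (1-\alpha) n_\mathrm{perm} \rceil$. A peak's permuted P uses
the add-one rule $(1 + \#\{\max \ge \mathrm{obs}\})/(n_\mathrm{perm}+1)$,
so the smallest reportable P is $1/(n_\mathrm{perm}+1)$. Support
intervals are LogP−1 drops: the maximal contiguous run of intervals on
the peak's chromosome staying within 1 unit of the peak.

## Annotation

QTL support intervals are intersected with a user-supplied gene table
(0-based half-open, ≥ 1 bp overlap, strand ignored), and the member
genes tested for enrichment of high positions in a supplied
genome-wide implication ranking (rank 1 = most implicated). The
underlying study design leaves the enrichment statistic unspecified, so
the package reports a one-sided Wilcoxon rank-sum test by default and
offers a mean-rank resampling test (exhaustive when the subset count is
small, Monte Carlo with the add-one rule otherwise) as the reference
oracle; the two agree within Monte Carlo error on random instances. The
background is all ranked genes, not only genes inside QTLs. Ortholog
resolution and disorder-database lookups are inputs, not computations.

## What the generator does and does not emulate

The simulator reproduces the *structural* features the analysis relies
on: eight-founder mosaic genomes with realistic segment lengths and map
expansion, balanced founder shares under balanced funnels, residual
heterozygosity, genotyping error and missingness, line-structured
phenotypes with known $h^2$ and planted QTL architectures. It does not
emulate real array marker content or cluster-calling artefacts, sex
chromosomes, selection or extinction of lines during inbreeding, or
non-normal phenotype distributions beyond what the QTL/covariate
structure induces. Passing tests therefore demonstrate that the
estimators recover truth under the stated model, not that any
particular real dataset would behave identically.

## Numerical and design choices

- Poisson/Haldane crossovers; no interference (tractable oracle).
- HMM transition cap at 7/8; per-step scaling; flat posteriors under
  ambiguity; interval coordinates 0-based half-open bp at marker
  midpoints.
- ML (not REML) as the primary variance-component criterion; negative
  $V_g$ clamped for $H^2$; kinship not double-centered.
- Permutations shuffle line means, not animal records — the scan's unit
  of analysis is the weighted line mean.
- All randomness flows through one seeded generator per exported call
  (`seed` argument, recorded in outputs); the pipeline derives stage
  seeds from the single config seed.
- Planted-QTL simulations code a biallelic variant: founder effects are
  the centered founder alleles times the allelic effect in units of the
  animal-level residual SD; lines contribute means of 5–6 animals.

## Problem sizes used by the test suite

The suite verifies small instances against brute-force oracles
(enumeration over all $8^5$ founder paths, exhaustive contiguous-run
search, 2-D likelihood grids, exhaustive gene-subset enumeration) and
runs calibration studies at the sizes the package treats as its
reference study conditions: 400 balanced lines on 19 autosomes of 70 cM
for founder-share symmetry; 50 lines × 500 intervals × 200 replicates
× 200 permutations for permutation-threshold calibration; 100 lines ×
5 animals × 50 replicates for heritability recovery (true
$h^2 = 0.75$) and null calibration; 0.5 cM marker spacing for Viterbi
accuracy (≥ 95 %). `scripts/acceptance.R` re-runs the two calibration
studies from scratch.

## Known limitations

- The haploid HMM cannot call heterozygous segments, only spread
  posterior mass.
- The scan has no mixed-model correction; polygenic background inflates
  LogP (by design, matching the modelled procedure).
- The ANOVA $H^2$ with unequal line sizes uses the arithmetic mean
  animals-per-line, a common but approximate convention.
- Breeding simulates autosomes only; X-linked loci are out of scope.
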