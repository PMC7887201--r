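---
title: "Simulating marker-assisted backcross introgression with look-ahead selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating marker-assisted backcross introgression with look-ahead selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmcbreed)
```

## The breeding problem

Trait introgression moves a small set of desirable alleles — here `Z = 3`
marker loci — from a donor line with poor agronomics into an elite
recurrent parent (RP), while recovering as much of the RP genome as
possible in the background. The standard pipeline crosses donor × RP to
produce the F1, then backcrosses to the RP for `T` generations (BC1 …
BCT), selecting "positive" individuals (those carrying a desirable allele
at every target locus) and, among positives, the best backgrounds. A final
selfing produces the BCTF2 generation, in which success requires target
*homozygosity* plus a background recovery percentage above a threshold
(95% by default).

A genotype is an `L × 2` binary matrix `G`, `G[l, m] = 1` meaning the
desirable allele on chromosome copy `m` at locus `l`. The background
recovery percentage of an individual is

    100 · Σ_{l ∉ D} Σ_m G[l, m] / (2 (L − Z)),

with `D` the target set. Everything downstream — selection metrics,
pipeline statistics, success probabilities — is built on this statistic.

## Meiosis model

Gametes are formed by a two-state first-order Markov chain over the loci:
the first locus copies from either chromosome with probability 1/2, and
between adjacent loci `l` and `l + 1` the chain switches chromosome with
the recombination frequency `r[l]` and stays with `1 − r[l]`. This is the
classical no-interference (Haldane-type) crossover model; it is fully
determined by the pairwise `r ∈ [0, 0.5]^{L−1}` parameterisation, which is
also why no interference model is attempted — nothing in a pairwise map
identifies one. Chromosome structure is encoded entirely by boundary
entries `r = 0.5`; loci on opposite sides of a boundary assort
independently. There is one flat locus axis, indexed 1-based everywhere
(files, function arguments, internals); only the compiled layer shifts to
0-based offsets.

Because the RP is fully inbred, its meiosis is deterministic: backcrosses
draw the RP gamete as its haplotype without consuming random numbers. This
is exact, not an approximation.

The package carries an exact oracle for this chain:
`gamete_probability(G, r, g)` evaluates `Pr(gamete = g)` by a two-state
forward recursion in `O(L)`, with a brute-force `2^L` path enumeration as
an independent cross-check for small `L`. The test suite verifies that the
two agree to `1e−12`, that the probabilities sum to one over all `2^L`
gametes, and that simulated gamete frequencies pass a chi-square test
against the exact law.

## Selection metrics

**Background GEBV.** With uniform marker weights the background breeding
value is simply the count of desirable background alleles,
`Σ_{l∉D} Σ_m G[l, m]`. A weight-vector hook exists for non-uniform marker
effects but the pipeline uses unit weights; estimating weights from
phenotypes is out of scope.

**Predicted cross value (PCV).** The probability that one gamete is
desirable at *every* locus. In a backcross program the co-parent is always
the RP, so the single-individual form is the right one. It is computed by
the same forward recursion as the gamete oracle, specialised to the
all-ones gamete. At `L ≈ 200` with many heterozygous loci the value
underflows doubles, so the recursion renormalises its two-state vector
whenever the running mass drops below `1e−280` and accumulates the log;
`pcv(..., log = TRUE)` is what the pipeline ranks on. Only the ordering
matters for selection, and ranking on the log is monotone, so the choice of
scale is inconsequential; it is made explicit here because a raw-double
implementation would silently rank many candidates as tied at zero.

**Look-ahead Monte Carlo (LMC).** Each backcross-positive candidate at
generation `t` is scored by simulating `P` independent descendant paths to
the terminal generation: at each remaining backcross step, gametes are
rejection-sampled until one carries every target allele (bounded by
`attempt_cap` tries), and paired with the RP haplotype; at generation `T`
the path's individual is selfed into `K` progeny. With `n` the number of
target-homozygous progeny at or above the recovery threshold and `v` the
best recovery among target-homozygous progeny, the score is

    Q = Σ_{j=1}^{P} (n_j / K) · v_j / P  ∈ [0, 100].

Design choices that the algorithm's verbal description leaves open, fixed
here once:

* "Simulate a batch of gametes, keep the positives, pick one at random" is
  implemented as rejection sampling, which is the batch procedure's limit
  as the batch grows and has bounded cost. A path that exhausts
  `attempt_cap` (default 200) is marked failed and contributes 0 to Q
  rather than being resampled — resampling would bias Q upward for
  candidates whose positive gametes are nearly impossible.
* Exactly one terminal individual per path is selfed.
* Defaults `P = 50`, `K = 200` (one cross's worth of selfed progeny),
  threshold 95%. `P` and `K` trade variance for cost; Q is unbiased in
  both, which the tests check by comparing means at `P = 10` and
  `P = 100`.
* Non-positive candidates score 0 by contract, without simulation.

A known behaviour worth understanding before using LMC: Q only
discriminates candidates through paths whose selfed progeny straddle the
threshold. If the program is easy enough (or the threshold lax enough)
that essentially all descendants clear it, Q flattens toward
`0.25 · E[v]` for every candidate and the method degenerates toward random
selection among positives, while plain background selection keeps
discriminating. Choose the LMC threshold near the recovery level you
actually care about.

## Pipeline semantics

`run_program()` implements one replicate. Readings of the program
definition that are fixed here (each is a genuine fork in the verbal
description):

* BC1 is the single (deterministic) F1 × RP cross repeated
  `crosses_per_gen` times, so every generation has
  `crosses_per_gen × progeny_per_cross` individuals (400 in scenario 1,
  1200 in scenario 2).
* The number of parents selected per generation equals `crosses_per_gen`;
  each selected parent × RP is one cross.
* The BCTF2 generation is formed by selfing each of the `crosses_per_gen`
  top BCT positives, `progeny_per_cross` progeny each, selected by the
  same metric as the backcross selections.
* Selection is truncation over positives only, with ties broken by a
  seeded uniform draw. Extinction of positives records the replicate as a
  failure rather than aborting the run.
* All summary statistics (per-generation min/mean/max, top-10 means, CDFs
  of maxima, success probabilities) are computed over positive individuals
  only; failed replicates count as non-successes.

**RNG architecture.** R-level stochastic operations (meiosis, tie-breaks)
use R's global RNG. Replicates, generation phases and LMC candidates get
independent integer streams derived from the master seed by a
multiplicative hash, and each LMC candidate's paths run on a private
counter-based generator (splitmix64) in the compiled code. Consequences:
results are bit-reproducible for a given seed, independent of thread
count, and the BC1 population depends only on the replicate seed — never
on the selection method — so methods run with the same seed are compared
on identical BC1 populations, paired by replicate.

## Synthetic study conditions

The generator emulates the structure of the empirical data the program
design targets: fully inbred parent pairs at a prescribed Nei similarity
(for homozygous biallelic lines Nei's identity reduces to the proportion
of matching loci, the form implemented), three cases
(L = 195 at 0.58, L = 173 at 0.72, L = 172 at 0.89), Z = 3 donor targets,
and a 10-chromosome map (the maize karyotype). The similarity count
includes the Z always-mismatching target loci, so the feasible range is
`[0, (L − Z)/L]`; the donor's matching background subset is placed
uniformly at random. Target positions are not specified by the study
design, so the presets place them deterministically at the 25/50/75%
quantile loci, which spreads them across chromosomes and keeps runs
comparable. Within-chromosome recombination frequencies are i.i.d.
uniform(0, 0.1) by default (a dense-map linkage scale), boundaries exactly
0.5.

What the generator does *not* emulate: the empirical heat-map structure of
real recombination maps (long tracts of near-zero `r` around centromeres),
linkage-disequilibrium-shaped allele sharing, genotyping error, or
phenotypic selection. The practical consequence is that the synthetic
presets are *easier* than real maize data — undesirable donor background
is purged quickly, and with 400–1200 progeny per generation nearly every
replicate reaches 95% recovery under every selection method. Directional
comparisons (recovery improves across generations; more resources never
hurt; look-ahead ≥ PCV ≥ GEBV at the program threshold) are therefore
meaningful on this data, but the *margins* between methods are compressed
relative to what harder empirical maps produce, and method-separation
magnitudes should not be read off synthetic runs. Quantitative replication
of the empirical success probabilities additionally requires the original
genotypes and maps, which are not distributed here (the file loaders
accept them).

## Numerical and degenerate-input choices

* Forward-pass agreement with brute force is asserted at `1e−12`; the
  recursions are exact up to floating point, so the tolerance is pure
  rounding headroom.
* `rank_select` with fewer positives than `k` returns all positives with a
  warning; with zero positives it errors, which the replicate runner
  converts into a failed-replicate record.
* An empty background (`Z = L`) is rejected — the recovery percentage has
  no denominator.
* Requesting a parent-pair similarity above `(L − Z)/L` is an error naming
  the feasible range; the achieved similarity is within `1/(2L)` of the
  nearest feasible value (rounding of the matching-subset size).
* `t = T` look-ahead paths skip the backcross phase and self immediately.

## Problem sizes used by the shipped experiments

The test suite and the acceptance script run the method comparison on the
case-2 preset with 30 replicates per method × scenario cell, 200 progeny
per cross, and the default `P = 50`, `K = 200` look-ahead. Thirty
replicates is the package's standard demonstration size: it bounds the
Monte Carlo standard error of a success probability by about 0.09 while
keeping the full six-cell comparison at desk scale. The structural and
oracle checks run at small `L` where exhaustive enumeration is exact.

## Limitations

* No crossover interference, mutation, or sex-specific maps.
* Single donor, biallelic desirability coding fixed at input; no
  re-phasing or allele-to-desirability mapping inside the core.
* GEBV here is the uniform-weight allele count, not a trained genomic
  prediction model.
* Resource allocation is even across generations by construction;
  optimising the allocation is outside the package's scope.
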