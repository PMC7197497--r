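---
title: "Polarizing introgression from divergence shifts: models and methods"
author: "dipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarizing introgression from divergence shifts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Four-taxon tests such as the D-statistic detect gene flow between a pair of
lineages but usually cannot say which lineage was the donor and which the
recipient. `dipr` addresses that polarization problem in the minimal
four-taxon setting: ingroup species *P1* and *P2* are sisters, *P3* is their
outgroup within the ingroup, *O* roots the quartet, and introgression may
have occurred between *P2* and *P3* in either or both directions.

The key observation is that introgression changes pairwise divergences in a
direction-specific way. Writing $K_{23}$, $K_{12}$, $K_{13}$ for the
pairwise divergences (substitutions/site) of the corresponding role pairs at
one locus:

* introgression in either direction replaces the deep $P2$–$P3$ divergence
  with the (recent) introgression time, depressing $K_{23}$;
* a *P3 ⇒ P2* transfer hands *P2* a *P3*-like haplotype, inflating $K_{12}$
  from the first speciation time toward the second while leaving $K_{13}$
  untouched;
* a *P2 ⇒ P3* transfer is the mirror image: $K_{13}$ collapses, $K_{12}$ is
  untouched.

## The layered statistics

Loci are first classified by the topology of a per-locus neighbor-joining
gene tree into SP (species topology, $P1P2|P3O$), INT (introgression
topology, $P2P3|P1O$) and ALT (the remaining quartet, $P1P3|P2O$, produced
only by incomplete lineage sorting under the model). Contrasting class means
gives the divergence-shift profile

$$\Delta K_{23} = \bar K_{23}^{SP} - \bar K_{23}^{INT}, \qquad
  \Delta K_{12} = \bar K_{12}^{INT} - \bar K_{12}^{SP}, \qquad
  \Delta K_{13} = \bar K_{13}^{SP} - \bar K_{13}^{INT},$$

with the subtraction order chosen so each statistic is positive when the
effect it detects is present. The first layer (`oneDip()`) tests each
statistic against zero by bootstrap and maps the significance pattern over
$(\Delta K_{23}, \Delta K_{12}, \Delta K_{13})$ to a call:
(sig, sig, ns) → *P3 ⇒ P2*; (sig, ns, sig) → *P2 ⇒ P3*; (sig, sig, sig) →
bidirectional; anything else inconclusive. "Equals zero" is operationalized
as failure to reject at the configured `alpha` (default 0.05).

The second layer (`doubleDip()`) tests asymmetry directly with
$\Delta\Delta K = \Delta K_{12} - \Delta K_{13}$: positive when *P3 ⇒ P2*
transfer predominates, negative for the reverse, zero under symmetric
exchange.

Because ILS populates the INT class with loci that were never introgressed,
$\Delta\Delta K$ acquires an upward (pro *P3 ⇒ P2*) bias when internal
branches are short. The third layer (`tripleDip()`) estimates that spurious
contribution from the ALT class, which under the model can only arise from
ILS and is expected as frequent as ILS-derived INT loci. The
ALT-substituted statistic

$$\Delta\Delta K_{ALT} =
  \left(\bar K_{12}^{ALT} - \bar K_{12}^{SP}\right) -
  \left(\bar K_{23}^{SP} - \bar K_{23}^{ALT}\right)$$

uses $K_{23}$ where the INT-based statistic uses $K_{13}$, because in the
ALT quartet *P1* and *P3* are the sisters. Treating the observed
$\Delta\Delta K$ as a count-weighted average of a clean signal and the ILS
signal and solving gives the corrected statistic

$$\Delta\Delta\Delta K =
  \frac{\Delta\Delta K \cdot N_{INT} - \Delta\Delta K_{ALT} \cdot N_{ALT}}
       {N_{INT} - N_{ALT}},$$

defined only when $N_{ALT} \ge 1$ (some ILS must be present) and
$N_{INT} \ne N_{ALT}$; both degenerate cases are flagged distinctly and
$\Delta\Delta K$ is still reported. When $N_{ALT}/N_{INT} \to 0$ the
correction vanishes and $\Delta\Delta\Delta K \to \Delta\Delta K$; the test
suite checks the bound
$|\Delta\Delta\Delta K - \Delta\Delta K| \le
 |\Delta\Delta K - \Delta\Delta K_{ALT}| \, N_{ALT}/(N_{INT}-N_{ALT})$.

### Bootstrap significance

All significance comes from resampling loci (all classes together) with
replacement to the original locus count and recomputing class means, class
counts and every statistic per replicate — `nBoot` of 1,000 by default.
Because classification is deterministic per locus, resampling the per-locus
`(class, K23, K12, K13)` records is exactly equivalent to resampling the
alignments. One-sided p-values are the proportion of replicates at or below
zero; two-sided p-values are twice the minority-side proportion, capped at
1. Ties at zero count toward both sides, so a degenerate replicate
distribution concentrated at zero reads as $p = 1$, not as significance.
Reported p-values are clamped below at the bootstrap resolution ($1/n$
one-sided, $2/n$ two-sided): a reported $p$ equal to the floor means "no
replicate crossed zero at this resolution". Replicates with an empty SP or
INT class (or, for the corrected statistic, a degenerate count
configuration) are dropped and counted; results with more than 10% dropped
replicates are flagged unreliable. For $\Delta\Delta\Delta K$ the counts
$N_{INT}$ and $N_{ALT}$ are recomputed in every replicate — holding them
fixed would understate the sampling variance of the correction.

## The simulator

`drawGeneTree()` implements a four-lineage structured coalescent. Time is
measured in units of $4N$ generations, in which each pair of lineages
within a population coalesces at rate 2. Backward in time, *P2* merges into
*P1* at $T_\alpha$, *P3* joins at $T_\beta$, *O* at $T_\gamma$; for an
introgressed locus the recipient's lineage moves to the donor population at
$T_{INT}$ with probability `pMove`. Defaults are $T_{INT} = 1$,
$T_\alpha = 4$, $T_\beta = 8$, $T_\gamma = 12$; `scaleFactor` multiplies
all four depths, and `relIntTime` re-expresses $T_{INT}$ as a fraction of
$T_\alpha$. Two small design points deserve note:

* `pMove` defaults to 1: a locus labeled introgressed actually carries an
  introgressed genealogy. Simulators that implement introgression as a
  splitting event with partial retention effectively move the sampled
  lineage with probability below one, leaving a fraction of "introgressed"
  loci without an introgressed history; setting `pMove = 0.6` reproduces
  that behavior when wanted.
* The introgression time defaults to 1 rather than coinciding with any
  published command-line value of 2; both are reachable through `tInt`, and
  the validity check only requires $0 < T_{INT} < T_\alpha$.

`evolveSequences()` multiplies branch lengths by `seqScale` (default 0.01
substitutions/site per coalescent unit, so the root-to-tip path of the
default tree carries ~0.125 subs/site) and simulates HKY sequences with
`phangorn::simSeq()`. HKY defaults are $\kappa = 2$ and equal base
frequencies — a generic vertebrate-like transition bias chosen once;
both are configurable. The `theta` parameter is carried for provenance but
is inert: sequences are evolved along the genealogy, not from coalescent
segregating sites, so only `seqScale` controls polymorphism density.

`simulateGenome()` uses deterministic composition: exactly
`round(nLoci * pInt)` loci receive an introgression history, of which
`round(. * pP3toP2)` are *P3 ⇒ P2*. Deterministic counts remove one layer
of noise from parameter-scan cells, whose purpose is to map expected
behavior as a function of the nominal composition; the per-genome order of
histories is still randomized.

`simulateChromosome()` tiles a chromosome with haplotype blocks whose
breakpoints form a Poisson process, each block drawing an independent
history and genealogy. This is deliberately an independent-block
approximation, not an ancestral recombination graph: adjacent blocks share
no genealogical correlation. The property of interest — how the ratio of
haplotype-block size to analysis-window size inflates the sampling variance
of window-based statistics — survives this approximation, and it keeps the
simulator small, fast and fully self-contained.

### What the generator does and does not emulate

Simulated data have uniform substitution rate across loci and branches, a
single instantaneous introgression episode, constant population size,
random mating, one haploid sample per population and gap-free alignments.
Real genomes violate all of these: rate heterogeneity widens the divergence
distributions (empirical hominin windows are far noisier than any setting
here), gene flow can be continuous or involve unsampled lineages, and
alignment/mapping artifacts add structured noise. Passing the simulation
suite therefore demonstrates correctness of the statistics under the model,
not robustness to everything real data can do.

## Distances, gene trees and degenerate cases

Pairwise divergences are computed with `ape::dist.dna()`. The default model
is K80 — the documented default of that routine — with JC69 and the raw
p-distance available. Sites where either sequence of a pair carries a gap
or IUPAC ambiguity are excluded for that pair only (pairwise deletion),
which maximizes usable sites in empirical windows. When the logarithm
argument of a corrected distance is non-positive (saturation), the distance
is flagged undefined rather than clipped, and any locus with an undefined
pairwise distance is excluded from all layers and reported; silently
truncating such distances would bias class means exactly where the
correction matters most.

Gene trees come from `ape::nj()` on the 4×4 matrix. For four taxa the
output is one of three resolved quartets; exact distance ties produce a
zero-length internal branch. Quartets whose internal branch is ≤ 0 are
classed UNRESOLVED and excluded from every layer — the three-class scheme
has no home for stars, and a negative NJ internal branch means the data do
not support the split. Tie-breaking inside NJ is deterministic given the
fixed role order (P1, P2, P3, O), so classification is reproducible.

## Validation design and problem sizes

The package validates itself at sizes chosen to keep the full suite
desk-scale while preserving each qualitative regime: direction-call
recovery uses 1,000-locus genomes of 2,000 bp with 500 bootstrap
replicates; the asymmetry-sign grid uses 1,000 loci of 1,000 bp over
`pInt` ∈ {0.1, 0.5} × `pP3toP2` ∈ {0, 0.25, 0.5, 0.75, 1}; the
short-branch bias and null-safety checks use 2,000 loci of 2,000 bp at
`scaleFactor` 0.1, where ILS discordance is ≈ 30%. The analytic anchors are
the closed-form ILS discordance $(2/3)e^{-2(T_\beta - T_\alpha)}$, the
expected pairwise coalescence times $t + 1/2$ (in 4N units), the JC69/K80
closed-form distances, stationarity of the substitution model, and the
equivalence of neighbor joining with the four-point condition on additive
matrices. The simulator's topology spectrum was additionally cross-checked
against an independent coalescent implementation during development.

## Known limitations

* Inference of *P3 ⇒ P2* introgression is the bias-prone direction: ILS and
  phylogenetic error both push $\Delta\Delta K$ upward at short branches.
  The correction reduces but does not eliminate this, and can itself
  misbehave when most ALT loci descend from truly introgressed material.
  Findings of *P2 ⇒ P3* flow are correspondingly conservative.
* The corrected statistic is undefined without ALT loci, so it is only
  available where ILS (or misclassification) is present — exactly where it
  is needed.
* Window partitioning assumes the window is the exchangeable unit; when
  true haplotype blocks are much larger than windows, neighboring windows
  are pseudoreplicates and bootstrap variance is understated.
* The role map must come from prior knowledge of the species tree;
  inferring it from the same divergences the statistics consume would be
  circular.
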